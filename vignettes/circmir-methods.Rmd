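---
title: "circmir: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circmir: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Circular RNAs (circRNAs) are covalently closed transcripts produced by
backsplicing. Because they lack a cap and a poly(A) tail they are unusually
stable, and a prominent proposed function is miRNA sponging: a circRNA that
carries binding sites for a miRNA can sequester it from the RISC complex and
de-repress that miRNA's other targets. Prioritizing candidate miRNA:circRNA
pairs therefore needs (i) de novo site prediction on arbitrary, often
unannotated circRNA sequences, and (ii) orthogonal evidence — consensus
between independent prediction methods, experimentally validated miRNA:RNA
interactions, and Argonaute (AGO) CLIP peaks marking where RISC actually
binds.

circmir implements that workflow in three stages: sequence extraction,
prediction, and annotation. This vignette documents the models, the pinned
parameters and the design choices.

## Sequence extraction

Input circRNAs are genomic spans (BED). Each span is classified against the
gene annotation:

* **sense-overlapping** (≥ 1 bp overlap with a gene on the same strand):
  the span is intersected with the exons of the host gene and only exonic
  blocks are kept, clipped to the circRNA boundaries;
* **antisense** (overlap only on the opposite strand) and **intergenic**:
  the whole span is used as a single block.

Gene extent is the range of a gene's exons, so a circRNA inside an intron is
still sense-overlapping; since its exon intersection is empty it falls back
to the single-block treatment with a warning rather than producing an empty
transcript. When several same-strand genes overlap a circRNA, the gene with
the largest bp overlap donates its exon model (ties broken by the
lexicographically first `gene_id`). Where the true exon/intron composition
of the circle is known, feature-coordinates mode (`--coord`) takes the
user's blocks verbatim and skips the splitting.

Block sequences are concatenated left-to-right and reverse-complemented on
the minus strand, so the transcript always reads 5'→3'; DNA is transcribed
to RNA. A bidirectional coordinate map over the blocks projects any
transcript window back to 1..k genomic intervals (k > 1 across exon
junctions) and is the inverse used for all reported coordinates.

Two conventions worth stating explicitly:

* internally all intervals are 1-based closed (`GRanges`); BED input and the
  CSV output use BED's 0-based starts, converted at the I/O boundary;
* the default transcript is linear. Backsplice-junction-spanning sites are
  invisible to a linear scan; the optional `junction_wrap` flag appends the
  first (longest miRNA length − 1) nucleotides after the junction so such
  sites become discoverable, and their genomic projection wraps around the
  circle. It is off by default to match the linear-transcript behaviour of
  the standard scanners.

## The three prediction engines

The engines are independent by design — consensus between unrelated
methods is the main false-positive filter — and run on every (miRNA,
circRNA) pair with pinned defaults and no cross-engine filtering.

### Seed taxonomy

With miRNA positions numbered from the 5' end, a site is classified (best
label wins):

| label | requirement |
|---|---|
| 8mer | WC helix over positions 2–8, target A opposite position 1 |
| 7mer-m8 | WC helix over positions 2–8 |
| 7mer-A1 | WC helix over positions 2–7, target A opposite position 1 |
| 6mer | WC helix over positions 2–7 |
| offset-6mer | WC helix over positions 3–8 |

The seed must be a contiguous Watson–Crick helix: G:U wobbles, gaps or
bulges inside it disqualify the class. The A1 is a target feature (an
adenosine opposite position 1), not a base pair. Reported windows are 8 nt
(8mer), 7 nt (7mer-m8 and 7mer-A1) and 6 nt (6mer).

### Exact seed-match engine (tag `TS`)

Scans the transcript for exact reverse-complement matches of the seed
region, anchored at the hexamer complementary to positions 2–7; matches to
position 8 and/or the A1 upgrade the category and widen the window. Each
anchor yields one site with its best category; overlapping sites at distinct
anchors are reported separately. Offset-6mer scanning exists but is disabled
by default (the enabled set is 8mer/7mer/6mer). N never matches.

### Duplex minimum-free-energy engine (tag `RH`)

Computes minimum-free-energy *intermolecular* duplexes between the miRNA and
the transcript by dynamic programming: a duplex is a monotone set of base
pairs (antiparallel strands), scored as

ΔG = ΔG_init + Σ stacks + Σ loop penalties,

with nearest-neighbor stacking for adjacent pairs and length-dependent
penalties for bulges and interior loops. Intramolecular structure (target
accessibility) is deliberately not modeled — the engine evaluates only the
stability of each possible hybrid. All locally optimal duplexes with
ΔG ≤ −20 kcal/mol whose target footprints do not overlap are reported,
selected greedily best-first (ties by smaller target start).

The energy model ships as an editable table (`default_energy_model()`,
overridable from a plain-text config): the sixteen Watson–Crick stack
energies are the canonical Turner-style 37 °C values, completed from ten
unique stacks by duplex-reversal symmetry; stacks involving G:U wobbles use
a flat approximation (−1.1 kcal/mol with one wobble, −0.4 with two); bulge
and interior-loop penalties grow logarithmically beyond tabulated lengths
(loops are capped at 15 unpaired nt per side, 30 total); initiation is
+4.09 kcal/mol. These values rank duplexes sensibly; users wanting full
Turner fidelity (asymmetry terms, sequence-dependent wobble stacks,
terminal-AU penalties) can supply their own table. The DP kernel is in C++
(Rcpp) for speed; an exhaustive plain-R enumerator over all loop-free
structures verifies it in the tests.

### Position-weighted local alignment engine (tag `M`)

Smith–Waterman-style local alignment of the reversed miRNA (3'→5') against
the transcript, so aligned columns are putative base pairs: WC +5, G:U +1,
mismatch −3, affine gaps (−9 first residue, −4 each additional).
Substitution scores at miRNA positions 2–8 are multiplied by 4, encoding the
dominance of seed pairing; gap penalties are not scaled. All non-overlapping
local maxima scoring ≥ 140 are reported (a perfect seed helix alone scores
7 × 5 × 4 = 140), then each alignment footprint is re-scored with the duplex
energy model and kept only if it can hybridize at ≤ −1 kcal/mol. These
defaults mirror the published defaults of the classic miRNA
local-alignment scanners; all are config-overridable.

### Traces and uniqueness

Every site carries a pairing trace (`|` WC pair, `:` G:U wobble, space for
mismatches/loops, `-` for gaps) and duplicate
(engine, miRNA, circRNA, window) records are dropped — only unique
interacting sites are retained.

## Merging and annotation

Predicted windows are projected to genomic coordinates (junction-spanning
sites keep all their intervals; the reported Start/End is the 5'-most one).
"Same interaction" is not self-defining when engines report windows of
different widths around one seed, so the package adopts: same miRNA, same
circRNA, and ≥ 1 bp genomic footprint overlap, grouped by transitive
closure. Per group:

* `Software Matched` = number of distinct engines present (1–3);
* the representative footprint is the seed-match window when a seed-scanner
  (or any seed-classified) site is in the group, else the union span;
* the ID tag is the highest-priority engine present (M > RH > TS), and IDs
  `INT_<tag>_<n>` number each tag from 1 in canonical output order
  (chrom, start, end, miRNA);
* the seed category is the best in the group.

Annotation flags are judged against the representative footprint, so the
reported coordinates and the flags describe the same interval: `Validated`
requires ≥ 1 bp overlap with a validated miRNA:RNA record — and, when the
record names a miRNA (`miRNA|target` in the BED name column), an exact
miRNA-name match; coordinate-only records flag on overlap alone. `AGO`
requires ≥ 1 bp overlap with any AGO peak. `circBase ID` is attached when
the circRNA's original input span matches a circBase record exactly on
(chrom, start, end, strand); a ± N bp tolerance is available but defaults
to 0.

The output is the standard 12-column CSV (Chrom, Start, End, miRNA Name,
Circ Name, Strand, Seed Category, ID, Software Matched, Validated, AGO,
circBase ID), rows ordered by (chrom, start, end, miRNA). A JSON run report
with per-stage counts is written alongside.

## Parallelism and determinism

Work units are (miRNA, circRNA) pairs, parallelized with fork workers and
collected in input order, so output is byte-identical for any worker count.
Engine failure on one pair is logged, the pair is skipped for that engine,
and the failure count is surfaced in the run report.

## The synthetic fixture

`generate_fixture()` builds the study system every test runs against: a
14 kb two-chromosome genome, three genes, and six circRNAs covering every
class — multi-exon sense-overlapping on both strands, antisense, intergenic
on both strands, and an entirely intronic circle exercising the single-block
fallback. Three synthetic 22-nt miRNAs are drawn (rejection-sampled so no
miRNA's seed core can appear inside another's planted patterns). Eight
sites are planted across the circRNAs, one per category combination
(8mer/7mer-m8/7mer-A1/6mer, plus one "strong" full-complementarity duplex
that all three engines must recover); guard bases at the window edges block
accidental category upgrades. The background is then screened: any
unplanted occurrence of a seed hexamer in any transcript is broken by a
point mutation outside the protected planted windows, so seed-engine
recovery of the truth table is exact. Validated/AGO/circBase BEDs cover a
designated subset of planted sites, including one deliberately
name-mismatched validated record that must *not* flag. The same seed always
reproduces byte-identical files.

What the fixture does not emulate: real genome composition (repeats, GC
structure), realistic miRNA families with shared seeds, expression levels,
or cross-linking noise in AGO peaks. Passing tests therefore demonstrate
algorithmic correctness (recovery, coordinates, flags, determinism), not
predictive accuracy on real data — the engines' biological calibration is
carried by their pinned, published-default parameters, not by the fixture.

Problem sizes used by the test-suite and the acceptance script — six
circRNAs (transcripts of 200–500 nt), three miRNAs, and oracle-equivalence
sweeps of 300–1000 random instances (duplex enumeration capped at 8-nt
miRNA × 12-nt windows, alignment enumeration at 6 × 10) — were chosen so the
exhaustive reference computations stay exact while covering every code
path.

## Numerical choices and degenerate inputs

* Energy comparisons use a 1e-9 tolerance; DP cell improvements require a
  1e-12 margin, making traceback deterministic.
* Ties between equally good duplexes/alignments resolve to the smaller
  target start.
* N bases: unpairable in the duplex engine, mismatch-scored in the aligner,
  never matching in the seed scanner.
* Empty miRNA or circRNA sets produce empty (header-only) results without
  error; a transcript shorter than the seed yields no seed sites.
* An entirely intronic sense-overlapping circRNA warns and keeps its full
  span rather than vanishing.

## Known limitations

* The duplex model omits Turner asymmetry/terminal corrections and uses
  flat wobble stacks; absolute ΔG values are approximate (rankings are
  robust, and the threshold is configurable).
* Seed-category assignment requires contiguous WC pairing; unusual
  wobble-containing functional sites are classified `none` (they are still
  reported if an engine scores them).
* Conservation, context features and target-site accessibility are out of
  scope, as is building species annotation databases (validated/AGO/circBase
  tables are user-supplied BEDs).
* With `junction_wrap` off (the default), sites spanning the backsplice
  junction are not discoverable.
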