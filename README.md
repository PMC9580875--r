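# circmir

Prediction and annotation of miRNA binding sites on circular RNAs.

circRNAs are covalently closed, exonuclease-resistant transcripts whose most
studied function is miRNA sponging: sequestering miRNAs away from the RISC
complex through binding sites on the circle. Most existing resources only
cover already-annotated circRNAs in a few species, while de novo scanners
produce thousands of candidate sites per sequence. circmir is for
researchers who have circRNA coordinates in *any* genome (e.g. from a
backsplice-junction caller) and want a short, prioritized list of candidate
miRNA:circRNA interactions: it combines three independent prediction engines
and flags each consensus site with orthogonal experimental evidence.

## What it computes

**Stage 1 — sequence extraction.** Each input circRNA span (BED) is
classified against the gene annotation (GTF). Sense-overlapping circRNAs are
split on their host gene's exons and only exonic blocks are kept; antisense
and intergenic circRNAs are used as a single block (as is any circRNA in
feature-coordinates mode, where the user supplies the exact blocks).
Transcript sequences are assembled strand-correctly with a bidirectional
transcript↔genome coordinate map.

**Stage 2 — prediction.** Three engines scan every (miRNA, circRNA) pair:

* `TS` — exact seed matching. With miRNA positions numbered from the 5'
  end: 8mer (Watson–Crick helix at positions 2–8 plus a target A opposite
  position 1), 7mer-m8 (2–8), 7mer-A1 (2–7 plus A1), 6mer (2–7).
* `RH` — intermolecular duplex minimum free energy by dynamic programming,
  ΔG = ΔG_init + Σ(nearest-neighbor stacks) + Σ(bulge/interior-loop
  penalties), reporting non-overlapping duplexes with ΔG ≤ −20 kcal/mol.
* `M` — position-weighted gapped local alignment of the reversed miRNA
  (WC +5, G:U +1, mismatch −3, gaps −9/−4, seed positions 2–8 scaled ×4,
  score ≥ 140), with a duplex-energy filter on each footprint.

Sites are mapped back to genomic coordinates; sites of the same miRNA and
circRNA with overlapping footprints are merged into one interaction whose
`Software Matched` column counts the supporting engines.

**Stage 3 — annotation.** Each interaction is flagged for ≥ 1 bp overlap
with experimentally validated miRNA:RNA records (optionally miRNA-name
aware: BED name `miRNA|target`) and with Argonaute CLIP/ChIP peaks, and the
circRNA gets its circBase ID when its span matches a circBase record
exactly. The result is the standard 12-column CSV.

## Worked example

The package ships a deterministic synthetic-fixture generator — a 14 kb toy
genome with three genes, six circRNAs of every class and eight planted
miRNA sites with known truth — so the whole pipeline can be exercised
without downloads:

```r
library(circmir)

fx <- generate_fixture(dir = "fixture", seed = 42)
cfg <- run_config(input_bed    = fx$paths[["circ_bed"]],
                  genome_fasta = fx$paths[["genome"]],
                  gtf          = fx$paths[["gtf"]],
                  mirna_fasta  = fx$paths[["mirna_fasta"]],
                  validated_bed = fx$paths[["validated"]],
                  ago_bed       = fx$paths[["ago"]],
                  circbase_bed  = fx$paths[["circbase"]],
                  output_csv   = "predictions.csv")
res <- run_pipeline(cfg)
```

The first rows of `predictions.csv`:

```
Chrom,Start,End,miRNA Name,Circ Name,Strand,Seed Category,ID,Software Matched,Validated,AGO,circBase ID
chrA,1109,1116,sim-miR-202-3p,circ_multi_plus,+,7mer-m8,INT_M_1,3,No,Yes,sim_circ_0000001
chrA,1354,1361,sim-miR-202-3p,circ_intronic,+,7mer-A1,INT_M_2,2,Yes,No,
chrA,1673,1681,sim-miR-101-5p,circ_multi_plus,+,8mer,INT_M_3,3,Yes,Yes,sim_circ_0000001
chrA,4173,4181,sim-miR-101-5p,circ_multi_minus,-,8mer,INT_M_4,2,Yes,No,
chrA,4189,4195,sim-miR-202-3p,circ_antisense,+,6mer,INT_M_5,2,No,Yes,
```

Reading row 4: an 8mer site for `sim-miR-101-5p` on the minus-strand
multi-exon circRNA at chrA:4173–4181 (BED-convention start), found by two
engines, overlapping a validated interaction but no AGO peak, on a circRNA
absent from the circBase table. `run_pipeline()` also writes a JSON run
report; for this run it counts 6 circRNAs (3 sense-overlapping, 1
antisense, 2 intergenic), 20 engine sites (TS 8, RH 2, M 10), 10 merged
interactions of which 2 are three-tool hits, 4 validated-overlap, 4
AGO-overlap and 4 with a circBase ID.

## Command line

```sh
Rscript inst/scripts/circmir -i circs.bed --genome genome.fa --gtf genes.gtf \
    --mirnas mirnas.fa -o out.csv \
    [--coord] [--validated v.bed] [--ago a.bed] [--circbase c.bed] \
    [--threads N] [--junction-wrap] [--params engine.conf]
```

`--coord` switches to feature-coordinates mode (input rows are the exact
exon/intron blocks per circRNA; splitting is skipped). Engine parameters and
the duplex energy table can be overridden from a plain-text config
(`inst/extdata/engine_params.conf` documents the schema). Output is
identical for any `--threads` value.

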