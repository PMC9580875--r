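# Deterministic synthetic-data generator: a toy genome with genes, circRNAs
# of every class (multi-exon sense-overlapping on both strands, antisense,
# intergenic, intronic), synthetic miRNAs, and planted miRNA binding sites at
# fully known genomic coordinates, plus validated/AGO/circBase annotation
# BEDs covering a designated subset of the planted sites. The background
# sequence is screened (rejection sampling with targeted point mutations) so
# no unplanted exact seed core for any fixture miRNA survives in any circRNA
# transcript -- planted-site recovery by the seed-match engine is exact. The
# duplex and alignment engines may legitimately report additional
# low-affinity background sites; recovery tests use superset semantics.

# Fixed toy-genome layout (1-based closed coordinates).
#' @keywords internal
fixture_layout <- function() {
  genes <- list(
    geneA1 = list(chrom = "chrA", strand = "+",
                  exons = rbind(c(1001L, 1200L), c(1601L, 1800L), c(2201L, 2400L))),
    geneA2 = list(chrom = "chrA", strand = "-",
                  exons = rbind(c(4001L, 4250L), c(4701L, 4950L))),
    geneB1 = list(chrom = "chrB", strand = "+",
                  exons = rbind(c(1001L, 1800L)))
  )
  circs <- data.frame(
    name = c("circ_multi_plus", "circ_multi_minus", "circ_antisense",
             "circ_intergenic", "circ_intergenic_minus", "circ_intronic"),
    chrom = c("chrA", "chrA", "chrA", "chrB", "chrB", "chrA"),
    start = c(1051L, 4051L, 4101L, 3001L, 4001L, 1251L),
    end = c(2350L, 4900L, 4300L, 3400L, 4300L, 1550L),
    strand = c("+", "-", "+", "+", "-", "+"),
    stringsAsFactors = FALSE
  )
  list(chrom_len = c(chrA = 8000L, chrB = 6000L), genes = genes, circs = circs)
}

#' Default planted-site plan for the synthetic fixture
#'
#' One row per planted miRNA binding site: which miRNA and circRNA, the seed
#' category to plant, whether the site is a "strong" full-complementarity
#' duplex (recoverable by all three engines), which circRNA block hosts it
#' and at which relative position, and whether the validated / AGO annotation
#' tables cover it. The plan spans all circRNA classes, both strands and
#' multi-exon structures. `mismatch_validated` plants a validated record over
#' the site but under a different miRNA's name (the flag must stay "No").
#'
#' @return a data.frame, one row per planted site
#' @export
default_site_plan <- function() {
  data.frame(
    mirna = c(1L, 2L, 1L, 3L, 2L, 3L, 1L, 2L),
    circ = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 6L),
    category = c("8mer", "7mer-m8", "8mer", "7mer-A1", "6mer", "8mer",
                 "7mer-m8", "7mer-A1"),
    strong = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    block = c(2L, 1L, 1L, 2L, 1L, 1L, 1L, 1L),
    at = c(0.30, 0.40, 0.35, 0.30, 0.45, 0.30, 0.40, 0.35),
    validated = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    mismatch_validated = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    ago = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Generate the deterministic synthetic fixture
#'
#' Writes a toy genome FASTA, gene annotation GTF, circRNA BED (plus a
#' feature-coordinates BED of the resolved blocks), miRNA FASTA, validated /
#' AGO / circBase annotation BEDs and a JSON truth table into `dir`. The same
#' seed always produces byte-identical files.
#'
#' @param dir output directory (created if needed)
#' @param seed RNG seed controlling every random choice
#' @param n_circ number of circRNAs to include (2..6, in layout order; must
#'   cover the circRNAs referenced by `site_plan`)
#' @param n_mirna number of synthetic 22-nt miRNAs (must cover `site_plan`)
#' @param site_plan planted-site plan, see [default_site_plan()]
#' @return invisibly, a list: `dir`, `paths` (named file paths), `truth`
#'   (data.frame of planted sites with genomic coordinates in BED convention
#'   and expected flags), `mirnas` (named sequences), `seed`
#' @export
generate_fixture <- function(dir = tempfile("circmir_fixture_"), seed = 42L,
                             n_circ = 6L, n_mirna = 3L,
                             site_plan = default_site_plan()) {
  stopifnot(n_circ >= 2L, n_circ <= 6L, n_mirna >= 1L,
            max(site_plan$circ) <= n_circ, max(site_plan$mirna) <= n_mirna)
  for (attempt in 0:19) {
    salt <- (as.integer(seed) + attempt * 9973L) %% .Machine$integer.max
    res <- try(with_local_seed(salt,
                               fixture_once(dir, seed, n_circ, n_mirna, site_plan)),
               silent = TRUE)
    if (!inherits(res, "try-error")) return(invisible(res))
    if (!grepl("fixture screening", as.character(res))) stop(res)
  }
  stop("fixture generation failed: background screening did not converge")
}

#' @keywords internal
fixture_once <- function(dir, seed, n_circ, n_mirna, site_plan) {
  layout <- fixture_layout()
  circs <- layout$circs[seq_len(n_circ), , drop = FALSE]

  # random background genome
  genome_chr <- lapply(layout$chrom_len, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })

  mirnas <- draw_mirnas(n_mirna)

  # resolve block structures once (blocks depend only on the layout)
  blocks <- lapply(seq_len(nrow(circs)), function(i) {
    circ_blocks_from_layout(circs[i, ], layout$genes)
  })
  cmaps <- lapply(seq_len(nrow(circs)), function(i) {
    coord_map_from_matrix(blocks[[i]], circs$strand[i], circs$chrom[i])
  })

  # plant the sites and remember every written genomic position
  protected <- list()
  truth <- data.frame()
  expected_cores <- list()   # per "mirna\rcirc": transcript core starts
  for (k in seq_len(nrow(site_plan))) {
    p <- site_plan[k, ]
    plant <- plan_site(p, mirnas[[p$mirna]], blocks[[p$circ]], cmaps[[p$circ]],
                       circs[p$circ, ])
    for (w in seq_along(plant$write_pos)) {
      gp <- plant$write_pos[[w]]
      substr(genome_chr[[gp$chrom]], gp$pos, gp$pos) <- gp$base
    }
    protected[[k]] <- plant$protected
    key <- paste(p$mirna, p$circ, sep = "\r")
    expected_cores[[key]] <- c(expected_cores[[key]], plant$core_t)
    truth <- rbind(truth, data.frame(
      mirna = names(mirnas)[p$mirna], circ = circs$name[p$circ],
      category = p$category, chrom = circs$chrom[p$circ],
      start = plant$g_start - 1L, end = plant$g_end,   # BED convention
      strand = circs$strand[p$circ],
      validated = p$validated, ago = p$ago,
      strong = p$strong, stringsAsFactors = FALSE))
  }
  protected <- unique(do.call(rbind, lapply(protected, function(m) m)))

  # screen the background: no unplanted seed core anywhere
  genome_chr <- screen_background(genome_chr, mirnas, circs, blocks, cmaps,
                                  expected_cores, protected)

  # circBase identities for a subset of circRNA spans
  cb_circ <- intersect(c(1L, 4L), seq_len(n_circ))
  circbase_ids <- stats::setNames(sprintf("sim_circ_%07d", cb_circ),
                                  circs$name[cb_circ])
  truth$circbase_id <- ifelse(truth$circ %in% names(circbase_ids),
                              circbase_ids[truth$circ], NA_character_)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fixture_files(dir, genome_chr, layout, circs, blocks, mirnas,
                               site_plan, truth, circbase_ids)
  truth_out <- list(seed = seed, mirnas = as.list(mirnas),
                    sites = truth, circbase = as.list(circbase_ids))
  jsonlite::write_json(truth_out, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(dir = dir, paths = paths, truth = truth, mirnas = mirnas,
                 seed = seed))
}

# Draw n 22-nt miRNAs; the first starts with U (so a full-complementarity
# target ends in the 8mer's A1). Redraw until no miRNA's seed core can occur
# inside another miRNA's planted patterns (keeps cross-miRNA screening
# conflict-free) and each core occurs exactly once in its own full
# complement.
#' @keywords internal
draw_mirnas <- function(n) {
  for (trial in 1:200) {
    seqs <- vapply(seq_len(n), function(i) {
      first <- if (i == 1L) "U" else sample(c("A", "C", "G", "U"), 1L)
      paste0(first, paste(sample(c("A", "C", "G", "U"), 21L, replace = TRUE),
                          collapse = ""))
    }, "")
    supers <- vapply(seqs, function(s) {
      paste(revcomp_rna(s), paste0(revcomp_rna(substr(s, 2, 8)), "A"),
            paste0(revcomp_rna(substr(s, 2, 7)), "A"), sep = "NNN")
    }, "")
    cores <- vapply(seqs, function(s) revcomp_rna(substr(s, 2, 7)), "")
    ok <- TRUE
    for (i in seq_len(n)) {
      if (count_occ(cores[i], revcomp_rna(seqs[i])) != 1L) ok <- FALSE
      for (j in seq_len(n)) {
        if (i != j && count_occ(cores[i], supers[j]) > 0L) ok <- FALSE
      }
    }
    if (ok) {
      names(seqs) <- sprintf("sim-miR-%d0%d-%s", seq_len(n), seq_len(n),
                             rep(c("5p", "3p"), length.out = n))
      return(seqs)
    }
  }
  stop("could not draw a conflict-free miRNA set")
}

#' @keywords internal
count_occ <- function(pat, s) {
  n <- nchar(s); w <- nchar(pat)
  if (w > n) return(0L)
  sum(vapply(seq_len(n - w + 1L), function(i) substr(s, i, i + w - 1L) == pat,
             TRUE))
}

# blocks for a layout circRNA, mirroring the pipeline's splitting rule
#' @keywords internal
circ_blocks_from_layout <- function(circ, genes) {
  host <- NULL
  for (g in genes) {
    if (g$chrom != circ$chrom || g$strand != circ$strand) next
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    if (span[1] <= circ$end && span[2] >= circ$start) { host <- g; break }
  }
  if (is.null(host)) return(rbind(c(circ$start, circ$end)))
  ex <- host$exons
  keep <- pmax(ex[, 1], circ$start) <= pmin(ex[, 2], circ$end)
  if (!any(keep)) return(rbind(c(circ$start, circ$end)))   # intronic fallback
  cbind(pmax(ex[keep, 1], circ$start), pmin(ex[keep, 2], circ$end))
}

#' @keywords internal
coord_map_from_matrix <- function(blocks, strand, chrom) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(blocks[, 1], blocks[, 2]),
                               strand = strand)
  coord_map(gr, strand = strand, chrom = chrom)
}

# Work out the planted window for one plan row: its transcript placement,
# the bases to write (site + guard bases blocking category upgrades), the
# protected genomic positions, and the truth genomic interval.
#' @keywords internal
plan_site <- function(p, mirna, blocks, cmap, circ) {
  site_seq <- switch(p$category,
    "8mer" = paste0(revcomp_rna(substr(mirna, 2, 8)), "A"),
    "7mer-m8" = revcomp_rna(substr(mirna, 2, 8)),
    "7mer-A1" = paste0(revcomp_rna(substr(mirna, 2, 7)), "A"),
    "6mer" = revcomp_rna(substr(mirna, 2, 7)),
    stop("unsupported planted category: ", p$category))
  if (p$strong) {
    if (p$category != "8mer" || substr(mirna, 1, 1) != "U")
      stop("strong sites require an 8mer plan and a miRNA starting with U")
    site_seq <- revcomp_rna(mirna)
  }
  len <- nchar(site_seq)
  # transcript offset of the hosting block
  ord <- if (circ$strand == "+") seq_len(nrow(blocks)) else rev(seq_len(nrow(blocks)))
  widths <- blocks[, 2] - blocks[, 1] + 1L
  tpos_in_order <- match(p$block, ord)
  toff <- if (tpos_in_order == 1L) 0L else sum(widths[ord[seq_len(tpos_in_order - 1L)]])
  w <- widths[p$block]
  if (len + 2L > w)
    stop("planted site (", len, " nt) longer than block ", p$block,
         " of ", circ$name, " allows")
  start_in_block <- max(2L, min(w - len, as.integer(floor(w * p$at))))
  t_start <- toff + start_in_block
  t_end <- t_start + len - 1L

  writes <- transcript_writes(cmap, t_start, site_seq)
  # guard bases: block category upgrades at the window edges
  needs_m8_guard <- p$category %in% c("7mer-A1", "6mer")
  needs_a1_guard <- p$category %in% c("7mer-m8", "6mer")
  if (needs_m8_guard) {
    m8c <- comp_rna(substr(mirna, 8, 8))
    guard <- setdiff(c("C", "A", "G", "U"), m8c)[1]
    writes <- c(writes, transcript_writes(cmap, t_start - 1L, guard))
  }
  if (needs_a1_guard) {
    writes <- c(writes, transcript_writes(cmap, t_end + 1L, "C"))
  }

  # truth window: for strong sites the recorded site is the embedded 8mer
  if (p$strong) {
    tw <- c(t_start + len - 8L, t_end)
    core_t <- t_start + len - 7L
  } else {
    tw <- c(t_start, t_end)
    core_t <- t_start + if (p$category %in% c("8mer", "7mer-m8")) 1L else 0L
  }
  gr <- map_to_genome(cmap, tw[1], tw[2])
  if (length(gr) != 1L)
    stop("planted window unexpectedly spans a block junction in ", circ$name)
  protected <- do.call(rbind, lapply(writes, function(x) {
    c(chrom = x$chrom, pos = as.character(x$pos))
  }))
  list(write_pos = writes, protected = protected,
       g_start = BiocGenerics::start(gr), g_end = BiocGenerics::end(gr),
       core_t = core_t)
}

# genomic single-base writes realizing a transcript-space RNA string
#' @keywords internal
transcript_writes <- function(cmap, t_start, seq_rna) {
  bases <- strsplit(seq_rna, "", fixed = TRUE)[[1]]
  lapply(seq_along(bases), function(k) {
    gr <- map_to_genome(cmap, t_start + k - 1L, t_start + k - 1L)
    b <- if (cmap$strand == "+") bases[k] else comp_rna(bases[k])
    list(chrom = cmap$chrom, pos = BiocGenerics::start(gr), base = to_dna(b))
  })
}

# Mutate background bases until no circRNA transcript contains an unplanted
# seed core for any miRNA. Planted windows and guards are protected; an
# occurrence that cannot be broken aborts (the caller retries with a fresh
# background).
#' @keywords internal
screen_background <- function(genome_chr, mirnas, circs, blocks, cmaps,
                              expected_cores, protected) {
  prot_key <- paste(protected[, "chrom"], protected[, "pos"])
  cores <- vapply(mirnas, function(s) revcomp_rna(substr(s, 2, 7)), "")
  for (iter in 1:400) {
    clean <- TRUE
    for (ci in seq_len(nrow(circs))) {
      tx <- fixture_transcript(genome_chr, blocks[[ci]], circs$strand[ci],
                               circs$chrom[ci])
      for (mi in seq_along(mirnas)) {
        found <- which(vapply(seq_len(nchar(tx) - 5L), function(i) {
          substr(tx, i, i + 5L) == cores[mi]
        }, TRUE))
        expected <- expected_cores[[paste(mi, ci, sep = "\r")]] %||% integer(0)
        for (occ in setdiff(found, expected)) {
          clean <- FALSE
          fixed <- FALSE
          for (t in occ:(occ + 5L)) {
            gr <- map_to_genome(cmaps[[ci]], t, t)
            gp <- BiocGenerics::start(gr)
            if (paste(circs$chrom[ci], gp) %in% prot_key) next
            cur <- substr(genome_chr[[circs$chrom[ci]]], gp, gp)
            new <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
            substr(genome_chr[[circs$chrom[ci]]], gp, gp) <- new
            fixed <- TRUE
            break
          }
          if (!fixed)
            stop("fixture screening: unbreakable seed-core collision")
        }
      }
    }
    if (clean) return(genome_chr)
  }
  stop("fixture screening: did not converge")
}

#' @keywords internal
fixture_transcript <- function(genome_chr, blocks, strand, chrom) {
  parts <- vapply(seq_len(nrow(blocks)), function(i) {
    substr(genome_chr[[chrom]], blocks[i, 1], blocks[i, 2])
  }, "")
  dna <- paste(parts, collapse = "")
  if (strand == "-")
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  to_rna(dna)
}

#' @keywords internal
write_fixture_files <- function(dir, genome_chr, layout, circs, blocks,
                                mirnas, site_plan, truth, circbase_ids) {
  p <- function(f) file.path(dir, f)
  paths <- c(genome = p("genome.fa"), gtf = p("genes.gtf"),
             circ_bed = p("circs.bed"), features_bed = p("circ_features.bed"),
             mirna_fasta = p("mirnas.fa"), validated = p("validated.bed"),
             ago = p("ago_peaks.bed"), circbase = p("circbase.bed"),
             truth = p("truth.json"))

  fa <- unlist(lapply(names(genome_chr), function(ch) {
    s <- genome_chr[[ch]]
    c(paste0(">", ch),
      substring(s, seq(1L, nchar(s), 70L),
                pmin(seq(1L, nchar(s), 70L) + 69L, nchar(s))))
  }))
  writeLines(fa, paths[["genome"]])

  gtf <- unlist(lapply(names(layout$genes), function(g) {
    gene <- layout$genes[[g]]
    vapply(seq_len(nrow(gene$exons)), function(i) {
      paste(gene$chrom, "sim", "exon", gene$exons[i, 1], gene$exons[i, 2],
            ".", gene$strand, ".",
            sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g),
            sep = "\t")
    }, "")
  }))
  writeLines(gtf, paths[["gtf"]])

  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", circs$chrom, circs$start - 1L,
                     circs$end, circs$name, circs$strand),
             paths[["circ_bed"]])
  feat <- unlist(lapply(seq_len(nrow(circs)), function(i) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", circs$chrom[i], blocks[[i]][, 1] - 1L,
            blocks[[i]][, 2], circs$name[i], circs$strand[i])
  }))
  writeLines(feat, paths[["features_bed"]])

  writeLines(as.vector(rbind(paste0(">", names(mirnas)), unname(mirnas))),
             paths[["mirna_fasta"]])

  val <- character(0)
  for (k in seq_len(nrow(site_plan))) {
    tr <- truth[k, ]
    if (site_plan$validated[k]) {
      val <- c(val, sprintf("%s\t%d\t%d\t%s|target_%d\t0\t%s", tr$chrom,
                            tr$start, tr$end, tr$mirna, k, tr$strand))
    }
    if (site_plan$mismatch_validated[k]) {
      other_name <- setdiff(unique(truth$mirna), tr$mirna)[1]
      val <- c(val, sprintf("%s\t%d\t%d\t%s|target_x%d\t0\t%s", tr$chrom,
                            tr$start, tr$end, other_name, k, tr$strand))
    }
  }
  writeLines(val, paths[["validated"]])

  ago <- truth[site_plan$ago, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\tago_peak_%d\t0\t.", ago$chrom,
                     pmax(0L, ago$start - 5L), ago$end + 5L,
                     seq_len(nrow(ago))),
             paths[["ago"]])

  cb_idx <- match(names(circbase_ids), circs$name)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", circs$chrom[cb_idx],
                     circs$start[cb_idx] - 1L, circs$end[cb_idx],
                     unname(circbase_ids), circs$strand[cb_idx]),
             paths[["circbase"]])
  paths
}
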