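# circRNA structure resolution: classify each circRNA against the gene
# annotation, split it into exon blocks (or keep a single span), assemble the
# strand-correct transcript sequence, and keep the bidirectional
# transcript<->genome coordinate map used to project predicted sites back.

#' Classify a circRNA against gene models
#'
#' `sense_overlapping` if the circRNA span shares >= 1 bp with a gene on the
#' same strand, else `antisense` if it overlaps a gene on the opposite strand,
#' else `intergenic`. Gene extent is the range of its exon blocks (so a
#' circRNA inside an intron still counts as overlapping the gene).
#'
#' @param circ a length-1 [GenomicRanges::GRanges] (the circRNA span)
#' @param genes a [GenomicRanges::GRangesList] of exon blocks per gene, as
#'   from [read_gtf()]
#' @return one of `"sense_overlapping"`, `"antisense"`, `"intergenic"`
#' @export
classify_circ <- function(circ, genes) {
  stopifnot(length(circ) == 1L)
  if (!length(genes)) return("intergenic")
  spans <- gene_spans(genes)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(circ, spans, ignore.strand = TRUE))
  if (!length(hits)) return("intergenic")
  same <- as.character(BiocGenerics::strand(spans))[S4Vectors::subjectHits(hits)] ==
    as.character(BiocGenerics::strand(circ))
  if (any(same)) "sense_overlapping" else "antisense"
}

# One span per gene (per chromosome, for degenerate multi-chromosome models).
#' @keywords internal
gene_spans <- function(genes) {
  spans <- unlist(range(genes))   # base range; S4 dispatch on GRangesList
  spans$gene_id <- names(spans)
  spans
}

# Host-gene choice for a sense-overlapping circRNA: largest bp overlap with
# the gene span; ties broken by first gene_id lexicographically.
#' @keywords internal
pick_host_gene <- function(circ, genes) {
  spans <- gene_spans(genes)
  same <- as.character(BiocGenerics::strand(spans)) ==
    as.character(BiocGenerics::strand(circ))
  spans <- spans[same]
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(circ, spans, ignore.strand = TRUE))
  if (!length(hits)) return(NA_character_)
  cand <- spans[S4Vectors::subjectHits(hits)]
  ov <- BiocGenerics::width(GenomicRanges::pintersect(
    rep(circ, length(cand)), cand, ignore.strand = TRUE))
  cand$gene_id[order(-ov, cand$gene_id)][1]
}

#' Split a circRNA into sequence blocks
#'
#' Sense-overlapping circRNAs are intersected with the exon blocks of their
#' host gene (the same-strand gene with the largest overlap), clipped to the
#' circRNA span; antisense and intergenic circRNAs are treated as one exon
#' covering the whole span. A sense-overlapping circRNA that lies entirely in
#' an intron falls back to the single-span treatment with a warning.
#'
#' @param circ length-1 GRanges (circRNA span)
#' @param genes GRangesList of exon blocks per gene
#' @param circ_class classification from [classify_circ()]
#' @return a GRanges of non-overlapping blocks sorted by start, on the
#'   circRNA strand
#' @export
split_to_blocks <- function(circ, genes, circ_class = classify_circ(circ, genes)) {
  stopifnot(length(circ) == 1L)
  single <- GenomicRanges::granges(circ)
  if (circ_class == "sense_overlapping") {
    host <- pick_host_gene(circ, genes)
    exons <- genes[[host]]
    blocks <- GenomicRanges::intersect(GenomicRanges::granges(exons), single,
                                       ignore.strand = TRUE)
    if (!length(blocks)) {
      warning(sprintf("circRNA %s overlaps gene %s but no exon: treated as a single block",
                      circ$name %||% "<unnamed>", host))
      blocks <- single
    }
  } else {
    blocks <- single
  }
  blocks <- BiocGenerics::sort(blocks, ignore.strand = TRUE)
  BiocGenerics::strand(blocks) <- as.character(BiocGenerics::strand(circ))
  blocks
}

#' Build circRNA structures from user-supplied feature coordinates
#'
#' In feature-coordinates mode the input BED lists, per circRNA name, the
#' exact genomic features (exons/retained introns) making up the circle;
#' intron/exon splitting is skipped and the intervals are used as-is.
#'
#' @param features a GRanges with a `name` column; rows sharing a name form
#'   one circRNA and must share chromosome and strand
#' @return a named list: blocks (GRanges, sorted) per circRNA name
#' @export
accept_user_features <- function(features) {
  stopifnot(!is.null(features$name))
  out <- lapply(split(seq_along(features), features$name), function(idx) {
    g <- features[idx]
    if (length(unique(as.character(GenomeInfoDb::seqnames(g)))) != 1L ||
        length(unique(as.character(BiocGenerics::strand(g)))) != 1L) {
      stop("features of circRNA ", g$name[1],
           " span multiple chromosomes or strands")
    }
    BiocGenerics::sort(GenomicRanges::granges(g), ignore.strand = TRUE)
  })
  out[unique(features$name)]
}

# ---- coordinate map ---------------------------------------------------------

#' Transcript/genome coordinate map over an exon block structure
#'
#' Transcript position 1 is the 5'-most transcript nucleotide: the leftmost
#' genomic base of the first block on "+", the rightmost genomic base of the
#' last block on "-". An optional junction wrap of `wrap_len` nucleotides
#' re-exposes the first `wrap_len` transcript positions after the backsplice
#' junction so junction-spanning sites become discoverable.
#'
#' @param blocks GRanges of non-overlapping blocks (sorted by genomic start)
#' @param strand "+" or "-"
#' @param chrom chromosome name (defaults to the blocks' seqname)
#' @param wrap_len junction wrap length in nucleotides (default 0 = linear)
#' @return an object of class `coord_map`
#' @export
coord_map <- function(blocks, strand = NULL, chrom = NULL, wrap_len = 0L) {
  bl <- data.frame(start = BiocGenerics::start(blocks),
                   end = BiocGenerics::end(blocks))
  bl <- bl[order(bl$start), , drop = FALSE]
  if (nrow(bl) > 1L && any(bl$start[-1] <= bl$end[-nrow(bl)]))
    stop("coord_map: blocks must be non-overlapping")
  strand <- strand %||% as.character(BiocGenerics::strand(blocks))[1]
  chrom <- chrom %||% as.character(GenomeInfoDb::seqnames(blocks))[1]
  stopifnot(strand %in% c("+", "-"))
  w <- bl$end - bl$start + 1L
  structure(list(blocks = bl, widths = w, strand = strand, chrom = chrom,
                 length = sum(w), wrap_len = as.integer(wrap_len)),
            class = "coord_map")
}

#' @export
print.coord_map <- function(x, ...) {
  cat(sprintf("coord_map: %d block(s) on %s(%s), transcript length %d%s\n",
              nrow(x$blocks), x$chrom, x$strand, x$length,
              if (x$wrap_len) sprintf(" (+%d nt junction wrap)", x$wrap_len) else ""))
  invisible(x)
}

#' Project a transcript window to genomic intervals
#'
#' Maps the (1-based, closed) transcript window `[t_start, t_end]` to 1..k
#' genomic intervals, k > 1 when the window spans a block junction (or the
#' backsplice junction, for wrapped maps). Total width is preserved and
#' intervals are returned sorted by genomic start.
#'
#' @param cmap a [coord_map()]
#' @param t_start,t_end transcript window, 1-based closed,
#'   `1 <= t_start <= t_end <= length + wrap_len`
#' @return a GRanges of genomic intervals
#' @export
map_to_genome <- function(cmap, t_start, t_end) {
  L <- cmap$length
  if (t_start < 1L || t_end < t_start || t_end > L + cmap$wrap_len)
    stop(sprintf("transcript window [%d, %d] out of range (length %d, wrap %d)",
                 t_start, t_end, L, cmap$wrap_len))
  pieces <- list()
  if (t_start <= L) pieces[[1]] <- c(t_start, min(t_end, L))
  if (t_end > L) pieces[[length(pieces) + 1L]] <- c(1L, t_end - L)
  seg <- do.call(rbind, lapply(pieces, function(p) map_linear(cmap, p[1], p[2])))
  gr <- GenomicRanges::GRanges(cmap$chrom,
                               IRanges::IRanges(start = seg[, 1], end = seg[, 2]),
                               strand = cmap$strand)
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

# Map a window fully inside the unwrapped transcript; returns matrix of
# (gstart, gend) rows in transcript order.
#' @keywords internal
map_linear <- function(cmap, a, b) {
  bl <- cmap$blocks
  w <- cmap$widths
  nb <- nrow(bl)
  ord <- if (cmap$strand == "+") seq_len(nb) else rev(seq_len(nb))
  toff <- cumsum(c(0L, w[ord]))[seq_len(nb)]   # transcript offset per block, transcript order
  out <- matrix(integer(0), ncol = 2)
  for (k in seq_len(nb)) {
    blk <- ord[k]
    lo <- max(a, toff[k] + 1L)
    hi <- min(b, toff[k] + w[blk])
    if (lo > hi) next
    if (cmap$strand == "+") {
      gs <- bl$start[blk] + (lo - toff[k] - 1L)
      ge <- bl$start[blk] + (hi - toff[k] - 1L)
    } else {
      gs <- bl$end[blk] - (hi - toff[k] - 1L)
      ge <- bl$end[blk] - (lo - toff[k] - 1L)
    }
    out <- rbind(out, c(gs, ge))
  }
  out
}

#' Project a genomic position to its transcript position
#'
#' Inverse of [map_to_genome()] for a single genomic base. Positions in the
#' wrap copy are reported at their primary (unwrapped) transcript position.
#'
#' @param cmap a [coord_map()]
#' @param gpos genomic position (1-based)
#' @return transcript position (1-based), or `NA` if `gpos` is not covered
#' @export
genome_to_transcript <- function(cmap, gpos) {
  bl <- cmap$blocks
  w <- cmap$widths
  nb <- nrow(bl)
  ord <- if (cmap$strand == "+") seq_len(nb) else rev(seq_len(nb))
  toff <- 0L
  for (k in seq_len(nb)) {
    blk <- ord[k]
    if (gpos >= bl$start[blk] && gpos <= bl$end[blk]) {
      return(if (cmap$strand == "+") toff + (gpos - bl$start[blk]) + 1L
             else toff + (bl$end[blk] - gpos) + 1L)
    }
    toff <- toff + w[blk]
  }
  NA_integer_
}

# ---- sequence assembly ------------------------------------------------------

#' Assemble the transcript sequence of a block structure
#'
#' Concatenates the genomic DNA of the blocks (left to right); on "-" the
#' concatenation is reverse-complemented, so the result always reads 5' to 3'
#' along the transcript. DNA is transcribed to RNA (T to U). N bases pass
#' through (engines treat them as unpairable). With `wrap_len > 0` the first
#' `wrap_len` nucleotides are appended after the backsplice junction.
#'
#' @param blocks GRanges of blocks sorted by genomic start
#' @param strand "+" or "-"
#' @param genome a named [Biostrings::DNAStringSet]
#' @param wrap_len junction wrap length (default 0)
#' @return list with `sequence` (RNA string, 5'->3') and `cmap` (a
#'   [coord_map()])
#' @export
assemble_sequence <- function(blocks, strand, genome, wrap_len = 0L) {
  chrom <- as.character(GenomeInfoDb::seqnames(blocks))[1]
  if (!chrom %in% names(genome))
    stop("chromosome not found in genome FASTA: ", chrom)
  chr_seq <- genome[[chrom]]
  if (any(BiocGenerics::start(blocks) < 1L) ||
      any(BiocGenerics::end(blocks) > length(chr_seq)))
    stop("block outside chromosome bounds on ", chrom)
  ord <- order(BiocGenerics::start(blocks))
  parts <- vapply(ord, function(i) {
    as.character(Biostrings::subseq(chr_seq,
                                    BiocGenerics::start(blocks)[i],
                                    BiocGenerics::end(blocks)[i]))
  }, "")
  dna <- paste(parts, collapse = "")
  if (strand == "-")
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  rna <- to_rna(dna)
  wrap_len <- min(as.integer(wrap_len), nchar(rna))
  if (wrap_len > 0L) rna <- paste0(rna, substr(rna, 1L, wrap_len))
  list(sequence = rna,
       cmap = coord_map(blocks[ord], strand = strand, chrom = chrom,
                        wrap_len = wrap_len))
}

# ---- structures -------------------------------------------------------------

#' Build circRNA structures for a whole input set
#'
#' Resolves every input circRNA into a `circ_structure`: its class, block
#' list, assembled transcript sequence and coordinate map.
#'
#' @param circs GRanges of circRNA spans with a unique `name` column
#'   (full-sequence mode), or of feature rows grouped by `name`
#'   (`mode = "features"`)
#' @param genes GRangesList from [read_gtf()] (ignored in features mode)
#' @param genome named [Biostrings::DNAStringSet]
#' @param mode `"full_sequence"` (classify + exon-split) or `"features"`
#'   (use the rows as blocks verbatim)
#' @param junction_wrap append the first `wrap_len` nucleotides after the
#'   backsplice junction (default FALSE)
#' @param wrap_len wrap length used when `junction_wrap` is TRUE (callers use
#'   the longest miRNA length minus one)
#' @return named list of `circ_structure` objects
#' @export
build_circ_structures <- function(circs, genes, genome,
                                  mode = c("full_sequence", "features"),
                                  junction_wrap = FALSE, wrap_len = 21L) {
  mode <- match.arg(mode)
  wl <- if (junction_wrap) as.integer(wrap_len) else 0L
  if (mode == "features") {
    feat <- accept_user_features(circs)
    spans <- lapply(feat, function(b) range(b))
    structs <- Map(function(nm, blocks) {
      strand <- as.character(BiocGenerics::strand(blocks))[1]
      asm <- assemble_sequence(blocks, strand, genome, wrap_len = wl)
      new_circ_structure(nm, "user_features", blocks, spans[[nm]], asm)
    }, names(feat), feat)
    return(structs)
  }
  if (anyDuplicated(circs$name))
    stop("duplicate circRNA name(s): ",
         paste(unique(circs$name[duplicated(circs$name)]), collapse = ", "))
  structs <- lapply(seq_along(circs), function(i) {
    circ <- circs[i]
    cls <- classify_circ(circ, genes)
    blocks <- split_to_blocks(circ, genes, cls)
    strand <- as.character(BiocGenerics::strand(circ))
    asm <- assemble_sequence(blocks, strand, genome, wrap_len = wl)
    new_circ_structure(circ$name, cls, blocks, GenomicRanges::granges(circ), asm)
  })
  stats::setNames(structs, circs$name)
}

#' @keywords internal
new_circ_structure <- function(name, circ_class, blocks, span, asm) {
  structure(list(name = name, circ_class = circ_class,
                 chrom = as.character(GenomeInfoDb::seqnames(blocks))[1],
                 strand = as.character(BiocGenerics::strand(blocks))[1],
                 blocks = blocks, span = span,
                 sequence = asm$sequence, cmap = asm$cmap),
            class = "circ_structure")
}

#' @export
print.circ_structure <- function(x, ...) {
  cat(sprintf("circ_structure %s: %s, %s(%s), %d block(s), %d nt\n",
              x$name, x$circ_class, x$chrom, x$strand,
              length(x$blocks), x$cmap$length))
  invisible(x)
}
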