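# Back-conversion of predicted sites to genomic coordinates, cross-engine
# consensus merging, interaction ID assignment, and annotation against
# validated miRNA:RNA interactions, AGO peaks and circBase.

#' Convert predicted sites to genomic coordinates
#'
#' Projects each site's transcript window through its circRNA's coordinate
#' map. Sites spanning block junctions map to multiple genomic intervals; the
#' reported `g_start`/`g_end` is the span of the 5'-most (transcript-wise)
#' interval and all intervals are kept in the `g_blocks` list column (the
#' multi-block fact is reported via `message()`).
#'
#' @param sites a `predicted_site` data.frame
#' @param structures named list of `circ_structure` objects covering every
#'   `circ` in `sites`
#' @return `sites` with added columns `chrom`, `strand`, `g_start`, `g_end`,
#'   `g_blocks` (list of 2-column start/end matrices)
#' @export
sites_to_genomic <- function(sites, structures) {
  n <- nrow(sites)
  chrom <- character(n); strand <- character(n)
  g_start <- integer(n); g_end <- integer(n)
  g_blocks <- vector("list", n)
  n_multi <- 0L
  for (k in seq_len(n)) {
    struct <- structures[[sites$circ[k]]]
    if (is.null(struct)) stop("no structure for circRNA ", sites$circ[k])
    gr <- map_to_genome(struct$cmap, sites$t_start[k], sites$t_end[k])
    segs <- cbind(start = BiocGenerics::start(gr), end = BiocGenerics::end(gr))
    # 5'-most transcript-wise interval: leftmost on "+", rightmost on "-"
    prim <- if (struct$strand == "+") 1L else nrow(segs)
    if (nrow(segs) > 1L) n_multi <- n_multi + 1L
    chrom[k] <- struct$chrom
    strand[k] <- struct$strand
    g_start[k] <- segs[prim, "start"]
    g_end[k] <- segs[prim, "end"]
    g_blocks[[k]] <- segs
  }
  if (n_multi)
    message(n_multi, " site(s) span a block junction; reporting the 5'-most interval")
  sites$chrom <- chrom
  sites$strand <- strand
  sites$g_start <- g_start
  sites$g_end <- g_end
  sites$g_blocks <- g_blocks
  sites
}

# Union-find over 1..n
#' @keywords internal
uf_new <- function(n) seq_len(n)
#' @keywords internal
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}
#' @keywords internal
uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a); rb <- uf_find(parent, b)
  if (ra != rb) parent[rb] <- ra
  parent
}

#' Merge identical sites across engines into consensus interactions
#'
#' Sites of the same miRNA and circRNA whose genomic footprints overlap by at
#' least 1 bp are grouped by transitive closure into one interaction.
#' `software_matched` counts the distinct engine tags in the group; the
#' representative footprint is the seed-match window when the group contains
#' a TS (or any seed-classified) site, else the union span; the ID tag is the
#' highest-priority engine present (M > RH > TS); the seed category is the
#' best in the group.
#'
#' @param sites output of [sites_to_genomic()]
#' @return interaction data.frame: `chrom`, `start`, `end`, `strand`,
#'   `mirna`, `circ`, `seed_category`, `tag`, `software_matched`,
#'   `blocks` (list column: union of member footprints)
#' @export
merge_across_engines <- function(sites) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mirna = character(0), circ = character(0),
                      seed_category = character(0), tag = character(0),
                      software_matched = integer(0))
  empty$blocks <- list()
  if (!nrow(sites)) return(empty)
  groups <- split(seq_len(nrow(sites)), paste(sites$mirna, sites$circ, sep = "\r"))
  rows <- lapply(groups, function(idx) {
    ns <- length(idx)
    parent <- uf_new(ns)
    if (ns > 1L) {
      # overlap graph over all member footprint blocks
      blk <- do.call(rbind, lapply(seq_along(idx), function(k) {
        cbind(site = k, sites$g_blocks[[idx[k]]])
      }))
      site_of <- as.integer(blk[, "site"])
      ir <- IRanges::IRanges(start = blk[, "start"], end = blk[, "end"])
      hits <- IRanges::findOverlaps(ir, minoverlap = 1L, drop.self = TRUE)
      for (h in seq_along(hits)) {
        parent <- uf_union(parent,
                           site_of[S4Vectors::queryHits(hits)[h]],
                           site_of[S4Vectors::subjectHits(hits)[h]])
      }
    }
    roots <- vapply(seq_len(ns), function(k) uf_find(parent, k), 0L)
    lapply(split(idx, roots), function(members) interaction_row(sites, members))
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' @keywords internal
interaction_row <- function(sites, members) {
  g <- sites[members, , drop = FALSE]
  tags <- unique(g$engine)
  tag <- c("M", "RH", "TS")[min(match(tags, c("M", "RH", "TS")))]
  best_cat <- best_seed_category(g$seed_category)
  # representative footprint: prefer the seed-match window of a TS site,
  # else any seed-classified site, else the union span of the group
  rep_pool <- which(g$engine == "TS")
  if (!length(rep_pool)) rep_pool <- which(g$seed_category != "none")
  if (length(rep_pool)) {
    r <- rep_pool[order(seed_rank(g$seed_category[rep_pool]),
                        g$g_start[rep_pool])][1]
    start <- g$g_start[r]; end <- g$g_end[r]
    foot <- g$g_blocks[[r]]
  } else {
    allb <- do.call(rbind, g$g_blocks)
    start <- min(allb[, "start"]); end <- max(allb[, "end"])
    ir <- IRanges::reduce(IRanges::IRanges(allb[, "start"], allb[, "end"]))
    foot <- cbind(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
  }
  out <- data.frame(chrom = g$chrom[1], start = start, end = end,
                    strand = g$strand[1], mirna = g$mirna[1], circ = g$circ[1],
                    seed_category = best_cat, tag = tag,
                    software_matched = length(tags),
                    stringsAsFactors = FALSE)
  # annotation flags are judged against the reported footprint
  out$blocks <- list(foot)
  out
}

#' Assign unique interaction IDs
#'
#' IDs have the form `INT_<tag>_<n>` where the tag names the representative
#' engine (M, RH or TS) and `n` counts that tag's interactions from 1 in
#' canonical output order (chrom, start, end, miRNA name). Deterministic for
#' identical input.
#'
#' @param interactions output of [merge_across_engines()]
#' @return interactions sorted canonically, with an `id` column
#' @export
assign_ids <- function(interactions) {
  if (!nrow(interactions)) {
    interactions$id <- character(0)
    return(interactions)
  }
  ord <- order(interactions$chrom, interactions$start, interactions$end,
               interactions$mirna, interactions$circ)
  interactions <- interactions[ord, , drop = FALSE]
  counters <- stats::ave(seq_len(nrow(interactions)), interactions$tag,
                         FUN = seq_along)
  interactions$id <- sprintf("INT_%s_%d", interactions$tag, counters)
  rownames(interactions) <- NULL
  interactions
}

#' Flag overlaps with validated interactions and AGO peaks
#'
#' `validated` is TRUE iff the interaction's genomic footprint overlaps a
#' validated miRNA:RNA record by >= 1 bp and, when the record names a miRNA,
#' that name equals the interaction's miRNA (coordinate-only records match on
#' overlap alone). `ago` is TRUE iff the footprint overlaps any AGO peak.
#' The two flags are independent.
#'
#' @param interactions output of [assign_ids()]
#' @param db an `annotation_db` from [read_annotation_db()] (tables may be
#'   empty)
#' @return interactions with logical `validated` and `ago` columns
#' @export
flag_overlaps <- function(interactions, db) {
  n <- nrow(interactions)
  interactions$validated <- logical(n)
  interactions$ago <- logical(n)
  if (!n) return(interactions)
  foot <- interaction_footprints(interactions)
  if (length(db$validated)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(foot, db$validated,
                                  minoverlap = 1L, ignore.strand = TRUE))
    qi <- foot$interaction[S4Vectors::queryHits(hits)]
    rec_mirna <- db$validated$mirna[S4Vectors::subjectHits(hits)]
    ok <- is.na(rec_mirna) | rec_mirna == interactions$mirna[qi]
    interactions$validated[unique(qi[ok])] <- TRUE
  }
  if (length(db$ago)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(foot, db$ago,
                                  minoverlap = 1L, ignore.strand = TRUE))
    interactions$ago[unique(foot$interaction[S4Vectors::queryHits(hits)])] <- TRUE
  }
  interactions
}

#' @keywords internal
interaction_footprints <- function(interactions) {
  blk <- do.call(rbind, lapply(seq_len(nrow(interactions)), function(k) {
    cbind(interaction = k, interactions$blocks[[k]])
  }))
  GenomicRanges::GRanges(interactions$chrom[blk[, "interaction"]],
                         IRanges::IRanges(blk[, "start"], blk[, "end"]),
                         interaction = blk[, "interaction"])
}

#' Attach circBase identifiers
#'
#' Sets `circbase_id` for interactions whose circRNA's original input span
#' matches a circBase record on (chrom, start, end, strand), exactly by
#' default or within `tol` bp on each boundary.
#'
#' @param interactions interaction data.frame
#' @param structures named list of `circ_structure` objects (for the original
#'   spans)
#' @param db an `annotation_db` (uses `db$circbase`)
#' @param tol per-boundary tolerance in bp (default 0 = exact)
#' @return interactions with a `circbase_id` column (NA when absent)
#' @export
circbase_lookup <- function(interactions, structures, db, tol = 0L) {
  interactions$circbase_id <- NA_character_
  if (!nrow(interactions) || !length(db$circbase)) return(interactions)
  ids <- vapply(unique(interactions$circ), function(nm) {
    struct <- structures[[nm]]
    if (is.null(struct)) return(NA_character_)
    span <- struct$span
    cb <- db$circbase
    hit <- as.character(GenomeInfoDb::seqnames(cb)) == struct$chrom &
      as.character(BiocGenerics::strand(cb)) == struct$strand &
      abs(BiocGenerics::start(cb) - BiocGenerics::start(span)) <= tol &
      abs(BiocGenerics::end(cb) - BiocGenerics::end(span)) <= tol
    if (any(hit)) cb$name[which(hit)[1]] else NA_character_
  }, "")
  interactions$circbase_id <- ids[interactions$circ]
  interactions
}
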