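# Seed-category classification and the exact seed-match engine ("TS" tag).
#
# Site types follow the canonical miRNA-target taxonomy: with miRNA positions
# numbered from the 5' end, a site is
#   8mer       WC pairing at positions 2-8 plus an A in the target opposite
#              position 1 (the A is a target feature, not a pair),
#   7mer-m8    WC pairing at positions 2-8,
#   7mer-A1    WC pairing at positions 2-7 plus the A1,
#   6mer       WC pairing at positions 2-7,
#   offset-6mer  WC pairing at positions 3-8 (disabled by default in the
#              scanner; the classifier always knows it).
# G:U wobbles count as non-Watson-Crick for seed purposes.

#' Classify the seed category of a miRNA:target pairing
#'
#' The seed match must be an uninterrupted Watson-Crick helix: the required
#' miRNA positions must pair consecutive target positions (descending along
#' the target, since the strands are antiparallel) with WC complementarity at
#' every one. G:U wobbles, gaps and bulges inside the seed disqualify it.
#'
#' @param mirna miRNA sequence, RNA alphabet, 5' to 3'
#' @param target target sequence the pairing indexes into (a window or a whole
#'   transcript), 5' to 3'
#' @param pairing integer vector, one entry per miRNA position: the (1-based)
#'   target position paired to it, or `NA` if unpaired
#' @return one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`, `"6mer"`,
#'   `"offset-6mer"`, `"none"` (highest applicable wins)
#' @export
#' @examples
#' # perfect duplex of an 8-nt miRNA 5' region against its reverse complement
#' classify_seed("UAGCUUAU", "AUAAGCUA", pairing = 8:1)
classify_seed <- function(mirna, target, pairing) {
  mi <- strsplit(to_rna(mirna), "", fixed = TRUE)[[1]]
  tg <- strsplit(to_rna(target), "", fixed = TRUE)[[1]]
  wc_at <- function(i) {
    if (i > length(pairing) || is.na(pairing[i])) return(FALSE)
    j <- pairing[i]
    j >= 1 && j <= length(tg) && is_wc_pair(mi[i], tg[j])
  }
  wc_range <- function(from, to) {
    if (!all(vapply(from:to, wc_at, TRUE))) return(FALSE)
    # contiguous helix: consecutive miRNA positions pair adjacent target bases
    all(diff(pairing[from:to]) == -1L)
  }
  # target base opposite miRNA position 1: its pairing partner if paired,
  # else the base one step 3' (in the target) of position 2's partner
  a1 <- FALSE
  if (length(pairing) >= 1 && !is.na(pairing[1])) {
    a1 <- tg[pairing[1]] == "A"
  } else if (length(pairing) >= 2 && !is.na(pairing[2]) &&
             pairing[2] + 1L <= length(tg)) {
    a1 <- tg[pairing[2] + 1L] == "A"
  }
  if (wc_range(2, 8) && a1) return("8mer")
  if (wc_range(2, 8)) return("7mer-m8")
  if (wc_range(2, 7) && a1) return("7mer-A1")
  if (wc_range(2, 7)) return("6mer")
  if (wc_range(3, 8)) return("offset-6mer")
  "none"
}

#' Exact seed-match site scanner (TS engine)
#'
#' Scans a transcript for exact reverse-complement matches of the miRNA seed
#' region and reports each site once with its best (highest-order) category.
#' A site is anchored at the target hexamer complementary to miRNA positions
#' 2-7; the presence of a match to position 8 and/or the A1 upgrades the
#' category and widens the reported window (8mer: 8 nt, 7mer-m8: 7 nt,
#' 7mer-A1: 7 nt, 6mer: 6 nt). Overlapping sites at distinct anchors are
#' reported separately. N never matches.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet)
#' @param transcript target transcript sequence
#' @param offset6 also report offset-6mer sites (positions 3-8; default FALSE)
#' @param mirna_name,circ_name labels carried into the result
#' @return a `predicted_site` data.frame (engine tag `"TS"`, `score` = seed
#'   category rank: 8mer 4, 7mer-m8 3, 7mer-A1 2, 6mer 1, offset-6mer 0.5)
#' @export
scan_seed_sites <- function(mirna, transcript, offset6 = FALSE,
                            mirna_name = "miRNA", circ_name = "circ") {
  mirna <- to_rna(mirna)
  tx <- to_rna(transcript)
  n <- nchar(tx)
  m <- nchar(mirna)
  empty <- empty_sites()
  if (m < 8L || n < 6L) return(empty)
  mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
  core6 <- revcomp_rna(substr(mirna, 2L, 7L))      # pairs m7..m2, 5'->3' target
  m8c <- comp_rna(mi[8])                            # target base pairing m8
  if (grepl("N", core6, fixed = TRUE)) return(empty)
  rows <- list()
  ranks <- c("8mer" = 4, "7mer-m8" = 3, "7mer-A1" = 2, "6mer" = 1,
             "offset-6mer" = 0.5)
  starts <- which(vapply(seq_len(n - 5L),
                         function(i) substr(tx, i, i + 5L) == core6, TRUE))
  for (i in starts) {
    m8_ok <- m8c != "N" && i > 1L && substr(tx, i - 1L, i - 1L) == m8c
    a1_ok <- i + 6L <= n && substr(tx, i + 6L, i + 6L) == "A"
    if (m8_ok && a1_ok) { cat_ <- "8mer";    w <- c(i - 1L, i + 6L) }
    else if (m8_ok)     { cat_ <- "7mer-m8"; w <- c(i - 1L, i + 5L) }
    else if (a1_ok)     { cat_ <- "7mer-A1"; w <- c(i, i + 6L) }
    else                { cat_ <- "6mer";    w <- c(i, i + 5L) }
    npair <- if (m8_ok) 7L else 6L
    trace <- paste(rep("|", npair), collapse = "")
    if (a1_ok) trace <- paste0(trace, " ")
    rows[[length(rows) + 1L]] <- data.frame(
      engine = "TS", mirna = mirna_name, circ = circ_name,
      t_start = w[1], t_end = w[2], score = ranks[[cat_]],
      seed_category = cat_, alignment = trace, stringsAsFactors = FALSE)
  }
  if (offset6) {
    core_off <- revcomp_rna(substr(mirna, 3L, 8L))  # pairs m8..m3
    if (!grepl("N", core_off, fixed = TRUE)) {
      off_starts <- which(vapply(seq_len(n - 5L),
                                 function(i) substr(tx, i, i + 5L) == core_off, TRUE))
      # an offset hit one base 5' of a 2-7 core is part of that site already
      covered <- starts - 1L
      for (i in setdiff(off_starts, covered)) {
        rows[[length(rows) + 1L]] <- data.frame(
          engine = "TS", mirna = mirna_name, circ = circ_name,
          t_start = i, t_end = i + 5L, score = ranks[["offset-6mer"]],
          seed_category = "offset-6mer", alignment = "||||||",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  dedupe_sites(out)
}

#' @keywords internal
empty_sites <- function() {
  data.frame(engine = character(0), mirna = character(0), circ = character(0),
             t_start = integer(0), t_end = integer(0), score = numeric(0),
             seed_category = character(0), alignment = character(0),
             stringsAsFactors = FALSE)
}

# Drop duplicate (engine, mirna, circ, t_start, t_end) records, keeping the
# best category/score ("only unique interacting sites are retained").
#' @keywords internal
dedupe_sites <- function(sites) {
  if (!nrow(sites)) return(sites)
  ord <- order(sites$circ, sites$mirna, sites$t_start, sites$t_end,
               seed_rank(sites$seed_category), -sites$score)
  sites <- sites[ord, , drop = FALSE]
  key <- paste(sites$engine, sites$mirna, sites$circ, sites$t_start,
               sites$t_end, sep = "\r")
  out <- sites[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
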