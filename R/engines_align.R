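# Position-weighted local alignment engine ("M" tag): Smith-Waterman-style
# local alignment of the reversed miRNA (3'->5') against the transcript
# (5'->3'), so aligned columns are putative base pairs. G:U wobbles get a
# distinct positive sub-match score, and substitution scores at miRNA seed
# positions (2-8 by default) are multiplied by a 5' scale factor. Surviving
# alignments are re-scored with the duplex energy model and kept only if
# their footprint can form a duplex at or below an energy threshold.

#' Default scoring parameters for the local alignment engine
#'
#' Match +5, G:U wobble +1, mismatch -3, gap open -9 (first gapped residue),
#' gap extend -4 (each additional residue), substitution scores at miRNA
#' positions 2-8 scaled by 4. These mirror the published defaults of the
#' classic miRNA local-alignment scanners; all values are config-overridable
#' (see [read_engine_config()]).
#'
#' @return named list of scoring parameters
#' @export
default_align_params <- function() {
  list(match = 5, wobble = 1, mismatch = -3,
       gap_open = -9, gap_extend = -4,
       scale = 4, scale_from = 2L, scale_to = 8L)
}

#' @keywords internal
validate_align_params <- function(params) {
  need <- c("match", "wobble", "mismatch", "gap_open", "gap_extend",
            "scale", "scale_from", "scale_to")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("alignment params missing: ", paste(miss, collapse = ", "))
  vals <- unlist(params[need])
  if (!all(is.finite(vals))) stop("alignment params must all be finite")
  invisible(params)
}

#' Scored local alignments of a miRNA against a transcript
#'
#' The raw alignment stage of the M engine: returns all non-overlapping local
#' alignment maxima with score at or above `score_threshold`, best-first
#' (ties: smaller target start), before any energy filtering. Exposed
#' separately so the raw optimal score can be inspected and checked.
#'
#' @param mirna miRNA sequence (5' to 3')
#' @param transcript target sequence (5' to 3')
#' @param params scoring parameters, see [default_align_params()]
#' @param score_threshold minimum alignment score to report
#' @return list of candidates, each with `score`, `t_start`, `t_end`,
#'   `pairing` (target position per miRNA position, NA = not aligned) and
#'   `alignment` trace (`|` WC, `:` G:U, `' '` mismatch, `-` gap)
#' @export
align_candidates <- function(mirna, transcript, params = default_align_params(),
                             score_threshold = 140) {
  validate_align_params(params)
  mirna <- to_rna(mirna)
  tx <- to_rna(transcript)
  m <- nchar(mirna)
  n <- nchar(tx)
  if (!m || !n) return(list())
  q <- rev(strsplit(mirna, "", fixed = TRUE)[[1]])   # 3'->5'
  t <- strsplit(tx, "", fixed = TRUE)[[1]]
  # substitution score for query row i (miRNA position m - i + 1) vs target j
  mi_pos <- m - seq_len(m) + 1L
  scaled <- mi_pos >= params$scale_from & mi_pos <= params$scale_to
  sub_score <- function(i, j) {
    a <- q[i]; b <- t[j]
    s <- if (is_wc_pair(a, b)) params$match
         else if (is_gu_pair(a, b)) params$wobble
         else params$mismatch
    if (scaled[i]) s * params$scale else s
  }
  mask <- rep(FALSE, n)
  out <- list()
  NEG <- -1e9
  repeat {
    H <- matrix(0, m + 1L, n + 1L)
    E <- matrix(NEG, m + 1L, n + 1L)   # gap in target (consumes miRNA)
    F <- matrix(NEG, m + 1L, n + 1L)   # gap in miRNA (consumes target)
    for (i in 1L + seq_len(m)) {
      for (j in 1L + seq_len(n)) {
        if (mask[j - 1L]) next
        E[i, j] <- max(H[i - 1L, j] + params$gap_open,
                       E[i - 1L, j] + params$gap_extend)
        F[i, j] <- max(H[i, j - 1L] + params$gap_open,
                       F[i, j - 1L] + params$gap_extend)
        H[i, j] <- max(0, H[i - 1L, j - 1L] + sub_score(i - 1L, j - 1L),
                       E[i, j], F[i, j])
      }
    }
    best <- max(H)
    if (best < score_threshold) break
    cells <- which(H >= best, arr.ind = TRUE)
    cells <- cells[order(cells[, 2], cells[, 1]), , drop = FALSE]
    tb <- align_traceback(H, E, F, cells[1, 1], cells[1, 2], q, t,
                          sub_score, params)
    out[[length(out) + 1L]] <- c(tb, list(score = best))
    mask[tb$t_start:tb$t_end] <- TRUE
    if (length(out) > n) break   # safety
  }
  out
}

# Recompute-decision traceback from cell (i, j) (1-based padded indices).
#' @keywords internal
align_traceback <- function(H, E, F, i, j, q, t, sub_score, params) {
  m <- length(q)
  cols <- list()   # list of c(qi or NA, tj or NA)
  state <- "H"
  eps <- 1e-9
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] <= eps) break
      if (abs(H[i, j] - (H[i - 1L, j - 1L] + sub_score(i - 1L, j - 1L))) < eps) {
        cols[[length(cols) + 1L]] <- c(i - 1L, j - 1L)
        i <- i - 1L; j <- j - 1L
      } else if (abs(H[i, j] - E[i, j]) < eps) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      cols[[length(cols) + 1L]] <- c(i - 1L, NA)
      if (abs(E[i, j] - (H[i - 1L, j] + params$gap_open)) < eps) {
        i <- i - 1L; state <- "H"
      } else {
        i <- i - 1L; state <- "E"
      }
    } else {
      cols[[length(cols) + 1L]] <- c(NA, j - 1L)
      if (abs(F[i, j] - (H[i, j - 1L] + params$gap_open)) < eps) {
        j <- j - 1L; state <- "H"
      } else {
        j <- j - 1L; state <- "F"
      }
    }
  }
  cols <- rev(cols)
  qi <- vapply(cols, `[`, 0L, 1L)
  tj <- vapply(cols, `[`, 0L, 2L)
  pairing <- rep(NA_integer_, m)
  sub <- !is.na(qi) & !is.na(tj)
  pairing[m - qi[sub] + 1L] <- tj[sub]
  sym <- vapply(seq_along(cols), function(k) {
    if (is.na(qi[k]) || is.na(tj[k])) return("-")
    a <- q[qi[k]]; b <- t[tj[k]]
    if (is_wc_pair(a, b)) "|" else if (is_gu_pair(a, b)) ":" else " "
  }, "")
  tt <- tj[!is.na(tj)]
  list(t_start = min(tt), t_end = max(tt), pairing = pairing,
       alignment = paste(sym, collapse = ""))
}

#' Position-weighted local alignment site scanner (M engine)
#'
#' Runs [align_candidates()] and retains each alignment only if its target
#' footprint can form an intermolecular duplex with free energy at or below
#' `e_threshold` under `energy_model`. `score` is the alignment score.
#'
#' @inheritParams align_candidates
#' @param e_threshold duplex free-energy cutoff applied to each alignment
#'   footprint (kcal/mol, negative; default -1)
#' @param energy_model model used for the footprint re-scoring
#' @param mirna_name,circ_name labels carried into the result
#' @return a `predicted_site` data.frame (engine tag `"M"`)
#' @export
local_align_score <- function(mirna, transcript,
                              params = default_align_params(),
                              score_threshold = 140, e_threshold = -1,
                              energy_model = default_energy_model(),
                              mirna_name = "miRNA", circ_name = "circ") {
  if (!is.finite(score_threshold)) stop("score_threshold must be finite")
  if (!is.finite(e_threshold) || e_threshold >= 0)
    stop("e_threshold must be a negative free energy (kcal/mol)")
  mirna <- to_rna(mirna)
  tx <- to_rna(transcript)
  cands <- align_candidates(mirna, tx, params, score_threshold)
  if (!length(cands)) return(empty_sites())
  mi_enc <- encode_rna(mirna)
  rows <- lapply(cands, function(cd) {
    win <- substr(tx, cd$t_start, cd$t_end)
    dp <- duplex_dp(mi_enc, encode_rna(win), energy_model$stacks,
                    energy_model$bulge, energy_model$interior,
                    energy_model$init, energy_model$max_loop,
                    rep(FALSE, nchar(win)))
    if (min(dp$E) > e_threshold + 1e-9) return(NULL)
    data.frame(engine = "M", mirna = mirna_name, circ = circ_name,
               t_start = cd$t_start, t_end = cd$t_end, score = cd$score,
               seed_category = classify_seed(mirna, tx, cd$pairing),
               alignment = cd$alignment, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_sites())
  dedupe_sites(do.call(rbind, rows))
}
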