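# Duplex hybridization engine ("RH" tag): minimum-free-energy intermolecular
# duplexes between a miRNA and a transcript, scored with the nearest-neighbor
# model in R/energy_model.R via the C++ dynamic program in src/duplex.cpp.
# No intramolecular pairing is considered: only the stability of each
# possible miRNA:target hybrid is evaluated, and the most stable,
# non-overlapping duplexes are retained.

#' Duplex minimum-free-energy site scanner (RH engine)
#'
#' Computes minimum-free-energy intermolecular duplexes of the miRNA against
#' the transcript and reports all locally optimal duplexes with free energy
#' `<= e_threshold` whose target footprints do not overlap, selected greedily
#' best-first (ties: smaller target start). `score` is the duplex free energy
#' in kcal/mol; the alignment trace marks WC pairs `|`, G:U wobbles `:`,
#' opposed unpaired bases (interior loops) `' '` and one-sided bulges `-`.
#'
#' @param mirna miRNA sequence (5' to 3')
#' @param transcript target transcript sequence (5' to 3')
#' @param energy_model a [default_energy_model()]-shaped model
#' @param e_threshold report duplexes with energy at or below this value
#'   (kcal/mol, must be negative; default -20)
#' @param mirna_name,circ_name labels carried into the result
#' @param max_sites stop after this many sites (safety cap)
#' @return a `predicted_site` data.frame, one row per retained duplex
#' @export
hybridize_mfe <- function(mirna, transcript,
                          energy_model = default_energy_model(),
                          e_threshold = -20,
                          mirna_name = "miRNA", circ_name = "circ",
                          max_sites = 1000L) {
  if (!is.finite(e_threshold) || e_threshold >= 0)
    stop("e_threshold must be a negative free energy (kcal/mol)")
  validate_energy_model(energy_model)
  mirna <- to_rna(mirna)
  tx <- to_rna(transcript)
  mi <- encode_rna(mirna)
  te <- encode_rna(tx)
  n <- length(te)
  if (!length(mi) || !n) return(empty_sites())
  mask <- rep(FALSE, n)
  rows <- list()
  repeat {
    if (length(rows) >= max_sites) break
    dp <- duplex_dp(mi, te, energy_model$stacks, energy_model$bulge,
                    energy_model$interior, energy_model$init,
                    energy_model$max_loop, mask)
    best <- min(dp$E)
    if (best > e_threshold + 1e-9) break
    hit <- best_traceback(dp, best)
    rows[[length(rows) + 1L]] <- duplex_site_row(hit, mirna, tx, best,
                                                 mirna_name, circ_name)
    mask[hit$t_start:hit$t_end] <- TRUE
  }
  if (!length(rows)) return(empty_sites())
  dedupe_sites(do.call(rbind, rows))
}

# Among all cells attaining the minimum energy, pick the duplex with the
# smallest target footprint start (deterministic tie-break), and trace it.
#' @keywords internal
best_traceback <- function(dp, best) {
  cells <- which(dp$E <= best + 1e-9, arr.ind = TRUE)
  cand <- lapply(seq_len(nrow(cells)), function(k) {
    traceback_pairs(dp, cells[k, 1], cells[k, 2])
  })
  starts <- vapply(cand, function(h) h$t_start, 0L)
  cand[[order(starts)[1]]]
}

# Follow predecessor pointers from cell (i, j); returns the pair list in
# 5'->3' miRNA order plus the target footprint.
#' @keywords internal
traceback_pairs <- function(dp, i, j) {
  mi_pos <- integer(0); tx_pos <- integer(0)
  while (i > 0L) {
    mi_pos <- c(i, mi_pos); tx_pos <- c(j, tx_pos)
    ni <- dp$Pi[i, j]; nj <- dp$Pj[i, j]
    i <- ni; j <- nj
  }
  list(mi_pos = mi_pos, tx_pos = tx_pos,
       t_start = min(tx_pos), t_end = max(tx_pos))
}

#' @keywords internal
duplex_site_row <- function(hit, mirna, tx, energy, mirna_name, circ_name) {
  pairing <- rep(NA_integer_, nchar(mirna))
  pairing[hit$mi_pos] <- hit$tx_pos
  cat_ <- classify_seed(mirna, tx, pairing)
  data.frame(engine = "RH", mirna = mirna_name, circ = circ_name,
             t_start = hit$t_start, t_end = hit$t_end, score = energy,
             seed_category = cat_,
             alignment = pairing_trace(mirna, tx, hit$mi_pos, hit$tx_pos),
             stringsAsFactors = FALSE)
}

# Column trace over a duplex: '|' WC pair, ':' G:U, then between consecutive
# pairs min(a,b) opposed-unpaired columns ' ' and |a-b| bulge columns '-'.
#' @keywords internal
pairing_trace <- function(mirna, tx, mi_pos, tx_pos) {
  mi <- strsplit(to_rna(mirna), "", fixed = TRUE)[[1]]
  tg <- strsplit(to_rna(tx), "", fixed = TRUE)[[1]]
  sym <- character(0)
  for (k in seq_along(mi_pos)) {
    if (k > 1L) {
      a <- mi_pos[k] - mi_pos[k - 1L] - 1L
      b <- tx_pos[k - 1L] - tx_pos[k] - 1L
      sym <- c(sym, rep(" ", min(a, b)), rep("-", abs(a - b)))
    }
    pa <- mi[mi_pos[k]]; pb <- tg[tx_pos[k]]
    sym <- c(sym, if (is_wc_pair(pa, pb)) "|" else if (is_gu_pair(pa, pb)) ":" else " ")
  }
  paste(sym, collapse = "")
}
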