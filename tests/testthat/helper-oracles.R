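# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (own complement tables, exhaustive enumeration) and
# share no code path with the package implementation they check.

orc_comp <- c(A = "U", C = "G", G = "C", U = "A")
orc_revcomp <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(orc_comp[v])), collapse = "")
}
orc_is_pair <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
orc_is_wc <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG")

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# ---- exact seed-match oracle ------------------------------------------------
# Enumerate every window equal to a category's site pattern by direct string
# comparison, then keep, per anchor (the target base opposite miRNA position
# 2), only the best category.
oracle_ts_sites <- function(mirna, tx) {
  n <- nchar(tx)
  pats <- list(
    list(cat = "8mer",    pat = paste0(orc_revcomp(substr(mirna, 2, 8)), "A"), anchor_off = 6L),
    list(cat = "7mer-m8", pat = orc_revcomp(substr(mirna, 2, 8)),              anchor_off = 6L),
    list(cat = "7mer-A1", pat = paste0(orc_revcomp(substr(mirna, 2, 7)), "A"), anchor_off = 5L),
    list(cat = "6mer",    pat = orc_revcomp(substr(mirna, 2, 7)),              anchor_off = 5L)
  )
  rank <- c("8mer" = 1, "7mer-m8" = 2, "7mer-A1" = 3, "6mer" = 4)
  rows <- list()
  for (p in pats) {
    w <- nchar(p$pat)
    if (w > n) next
    for (s in seq_len(n - w + 1L)) {
      if (substr(tx, s, s + w - 1L) == p$pat) {
        rows[[length(rows) + 1L]] <- data.frame(
          t_start = s, t_end = s + w - 1L, category = p$cat,
          anchor = s + p$anchor_off, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(t_start = integer(0), t_end = integer(0),
                      category = character(0)))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$anchor, rank[df$category]), ]
  df <- df[!duplicated(df$anchor), c("t_start", "t_end", "category")]
  df <- df[order(df$t_start, df$t_end), ]
  rownames(df) <- NULL
  df
}

# ---- duplex MFE oracle ------------------------------------------------------
# Exhaustive enumeration of all loop-free intermolecular duplex structures
# (monotone pairings, miRNA index increasing / target index decreasing),
# scored with the same energy model parameters: initiation + stacks + length
# penalties, loops capped at max_loop per side.
oracle_duplex_mfe <- function(mirna, tx, model) {
  mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
  tg <- strsplit(tx, "", fixed = TRUE)[[1]]
  m <- length(mi); n <- length(tg)
  best <- Inf
  pair_cost <- function(i, j, p, q) {
    a <- p - i - 1L; b <- j - q - 1L
    if (a == 0L && b == 0L)
      return(model$stacks[paste0(mi[i], tg[j]), paste0(mi[p], tg[q])])
    if (a > model$max_loop || b > model$max_loop) return(Inf)
    L <- a + b
    tab <- if (a == 0L || b == 0L) model$bulge else model$interior
    if (L > length(tab) || is.na(tab[L])) return(Inf)
    tab[L]
  }
  rec <- function(i, j, e) {
    if (e < best) best <<- e
    if (i >= m || j <= 1L) return()
    for (p in (i + 1L):m) {
      for (q in seq_len(j - 1L)) {
        if (!orc_is_pair(mi[p], tg[q])) next
        cost <- pair_cost(i, j, p, q)
        if (is.finite(cost)) rec(p, q, e + cost)
      }
    }
  }
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (orc_is_pair(mi[i], tg[j])) rec(i, j, model$init)
  }
  best
}

# ---- local alignment oracle -------------------------------------------------
# Exhaustive enumeration of all gapped local alignments as monotone matchings
# between the reversed miRNA and the target; consecutive matched pairs pay
# affine gap costs (open for the first gapped residue, extend thereafter) on
# each side. Best score over all non-empty matchings, floored at 0.
oracle_align_best <- function(mirna, tx, params) {
  q <- rev(strsplit(mirna, "", fixed = TRUE)[[1]])
  tg <- strsplit(tx, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(tg)
  mpos <- m - seq_len(m) + 1L
  sub <- function(i, j) {
    s <- if (orc_is_wc(q[i], tg[j])) params$match
         else if (orc_is_pair(q[i], tg[j])) params$wobble
         else params$mismatch
    if (mpos[i] >= params$scale_from && mpos[i] <= params$scale_to)
      s * params$scale else s
  }
  gap <- function(L) if (L == 0L) 0 else params$gap_open + (L - 1L) * params$gap_extend
  best <- 0
  rec <- function(i, j, sc) {
    if (sc > best) best <<- sc
    if (i >= m || j >= n) return()
    for (p in (i + 1L):m) {
      for (qq in (j + 1L):n) {
        rec(p, qq, sc + gap(p - i - 1L) + gap(qq - j - 1L) + sub(p, qq))
      }
    }
  }
  for (i in seq_len(m)) for (j in seq_len(n)) rec(i, j, sub(i, j))
  best
}

# ---- per-base coordinate mapping oracle ------------------------------------
# Map each transcript position of a window individually by walking the
# blocks, then merge runs of adjacent genomic positions.
oracle_map_window <- function(blocks, strand, t_start, t_end) {
  nb <- nrow(blocks)
  widths <- blocks[, 2] - blocks[, 1] + 1L
  ord <- if (strand == "+") seq_len(nb) else rev(seq_len(nb))
  map1 <- function(t) {
    for (k in seq_len(nb)) {
      b <- ord[k]
      if (t <= widths[b]) {
        return(if (strand == "+") blocks[b, 1] + t - 1L else blocks[b, 2] - t + 1L)
      }
      t <- t - widths[b]
    }
    stop("position out of range")
  }
  g <- vapply(t_start:t_end, map1, 0L)
  g <- sort(g)
  runs <- cumsum(c(1L, diff(g) != 1L))
  t(vapply(split(g, runs), function(x) c(min(x), max(x)), c(0L, 0L)))
}

# ---- overlap-grouping oracle ------------------------------------------------
# Brute-force transitive closure: same key and >= 1 bp interval overlap makes
# two sites connected; returns component labels.
oracle_group <- function(key, start, end) {
  n <- length(key)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || key[i] != key[j]) next
      if (start[i] <= end[j] && start[j] <= end[i] && comp[i] != comp[j]) {
        lab <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}
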