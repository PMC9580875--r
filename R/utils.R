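# Shared sequence helpers. All sequences are handled internally as uppercase
# RNA character strings (A/C/G/U, N allowed); genomic DNA is converted on read.

#' Convert a DNA or mixed-case sequence to uppercase RNA
#' @param x character vector of sequences
#' @return character vector with T replaced by U, uppercased
#' @keywords internal
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @keywords internal
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of an RNA string
#' @param x single RNA string (A/C/G/U/N)
#' @return reverse complement, same alphabet
#' @keywords internal
revcomp_rna <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(comp, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""),
         "", USE.NAMES = FALSE)
}

#' @keywords internal
comp_rna <- function(x) chartr("ACGUN", "UGCAN", x)

# Integer encoding used by the C++ duplex kernel: A=1 C=2 G=3 U=4, 0 for N or
# any non-standard character (encoded 0 can never pair).
#' @keywords internal
encode_rna <- function(x) {
  v <- strsplit(to_rna(x), "", fixed = TRUE)[[1]]
  i <- match(v, c("A", "C", "G", "U"))
  i[is.na(i)] <- 0L
  as.integer(i)
}

# Canonical base-pair identities. Pair order AU UA GC CG GU UG matches the
# row/column order of the energy-model stack table and the C++ kernel.
PAIR_NAMES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Is (a, b) a Watson-Crick pair?
#' @keywords internal
is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

#' Is (a, b) a G:U wobble pair?
#' @keywords internal
is_gu_pair <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")

#' @keywords internal
pair_name <- function(a, b) {
  p <- paste0(a, b)
  ifelse(p %in% PAIR_NAMES, p, NA_character_)
}

# Seed-category ordering, best first. "none" sorts last.
SEED_CATEGORIES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "offset-6mer", "none")

#' Rank of a seed category (1 = best)
#' @keywords internal
seed_rank <- function(x) match(x, SEED_CATEGORIES)

#' Pick the best (highest-order) seed category from a vector
#' @keywords internal
best_seed_category <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("none")
  SEED_CATEGORIES[min(seed_rank(x))]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run a block with a private RNG stream so callers' .Random.seed is untouched.
#' @keywords internal
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
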