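# Nearest-neighbor energy model for intermolecular RNA:RNA duplexes.
#
# The duplex engine scores a helix as the sum of stacking free energies over
# consecutive base pairs, plus length-dependent penalties for bulges and
# interior loops, plus a duplex initiation cost. Intramolecular structure of
# either strand is deliberately not modeled (hybridization-only view).
#
# Watson-Crick stack values are the canonical Turner-style 37 degC free
# energies (kcal/mol); the sixteen WC/WC entries derive from ten unique stacks
# by 180-degree duplex-reversal symmetry. Stacks involving G:U wobbles use a
# flat approximation (one wobble -1.1, two wobbles -0.4) -- adequate for
# ranking duplexes, editable via `read_engine_config()` for users who want a
# full wobble table.

#' Default nearest-neighbor duplex energy model
#'
#' Returns the energy model used by [hybridize_mfe()]: a 6x6 stacking table
#' over the pair alphabet AU, UA, GC, CG, GU, UG (rows: 5'-side pair, columns:
#' 3'-side pair, miRNA strand read 5' to 3'), bulge and interior-loop penalty
#' tables indexed by total unpaired length, the duplex initiation cost and the
#' maximum unpaired stretch allowed on one side of a loop.
#'
#' @param max_loop maximum unpaired nucleotides allowed on one side of a
#'   bulge/interior loop (default 15; longer loops end the duplex)
#' @return a list of class `duplex_energy_model` with elements `stacks`
#'   (numeric 6x6 matrix, kcal/mol), `bulge`, `interior` (numeric penalty
#'   vectors, kcal/mol, index = total loop length), `init` (initiation cost)
#'   and `max_loop`
#' @export
#' @examples
#' m <- default_energy_model()
#' m$stacks["GC", "GC"]   # 5'-GG-3'/3'-CC-5' stack
default_energy_model <- function(max_loop = 15L) {
  s <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  wc <- c(
    "AU,AU" = -0.93, "AU,UA" = -1.10, "AU,GC" = -2.08, "AU,CG" = -2.24,
    "UA,AU" = -1.33, "UA,UA" = -0.93, "UA,GC" = -2.11, "UA,CG" = -2.35,
    "GC,AU" = -2.35, "GC,UA" = -2.24, "GC,GC" = -3.26, "GC,CG" = -3.42,
    "CG,AU" = -2.11, "CG,UA" = -2.08, "CG,GC" = -2.36, "CG,CG" = -3.26
  )
  for (nm in names(wc)) {
    p <- strsplit(nm, ",", fixed = TRUE)[[1]]
    s[p[1], p[2]] <- wc[[nm]]
  }
  gu <- c("GU", "UG")
  for (p in PAIR_NAMES) for (q in PAIR_NAMES) {
    ngu <- (p %in% gu) + (q %in% gu)
    if (ngu == 1L) s[p, q] <- -1.1
    if (ngu == 2L) s[p, q] <- -0.4
  }
  maxlen <- 30L
  bulge <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
  bulge <- c(bulge, 4.4 + 1.07 * log(seq(7L, maxlen) / 6))
  interior <- c(NA, 1.5, 1.6, 1.7, 1.8, 2.0)   # minimum interior length is 2
  interior <- c(interior, 2.0 + 1.07 * log(seq(7L, maxlen) / 6))
  model <- list(stacks = s, bulge = bulge, interior = interior,
                init = 4.09, max_loop = as.integer(max_loop))
  class(model) <- "duplex_energy_model"
  validate_energy_model(model)
  model
}

#' Validate a duplex energy model
#'
#' Checks the structural invariants: complete 6x6 stack table, all WC/WC
#' stacks non-positive, non-negative loop penalties, and symmetry of the stack
#' table under duplex reversal (the stack 5'-XY/ZW-5' equals its 180-degree
#' flip).
#'
#' @param model a `duplex_energy_model`
#' @return the model, invisibly; errors if invalid
#' @export
validate_energy_model <- function(model) {
  stopifnot(is.list(model),
            is.matrix(model$stacks),
            identical(dim(model$stacks), c(6L, 6L)),
            identical(rownames(model$stacks), PAIR_NAMES),
            !anyNA(model$stacks))
  wc <- c("AU", "UA", "GC", "CG")
  if (any(model$stacks[wc, wc] > 0))
    stop("invalid energy model: WC/WC stacking energies must be <= 0")
  if (any(stats::na.omit(c(model$bulge, model$interior)) < 0))
    stop("invalid energy model: loop penalties must be >= 0")
  flip <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  for (p in PAIR_NAMES) for (q in PAIR_NAMES) {
    if (abs(model$stacks[p, q] - model$stacks[flip[[q]], flip[[p]]]) > 1e-9)
      stop("invalid energy model: stack table not symmetric under duplex reversal")
  }
  if (model$max_loop < 1L) stop("invalid energy model: max_loop must be >= 1")
  invisible(model)
}

# Loop cost shared by engine and config machinery: total unpaired length
# a + b, where a/b are the unpaired counts on the miRNA/target side.
#' @keywords internal
loop_cost <- function(model, a, b) {
  if (a > model$max_loop || b > model$max_loop) return(Inf)
  len <- a + b
  if (a == 0L && b == 0L) stop("loop_cost called on a stack")
  tab <- if (a == 0L || b == 0L) model$bulge else model$interior
  if (len > length(tab) || is.na(tab[len])) return(Inf)
  tab[len]
}
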