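# Engine orchestration: run all enabled engines over every (miRNA, circRNA)
# pair with documented defaults and no cross-engine filtering, serially or in
# parallel, with a determinism contract (identical results for any worker
# count). A plug-in seam allows substituting custom engine functions.

#' Default engine parameter set
#'
#' The pinned defaults of the three engines. `ts`: seed-match scanner
#' (offset-6mer disabled). `rh`: duplex engine, energy threshold -20 kcal/mol
#' over [default_energy_model()]. `m`: local aligner, scoring per
#' [default_align_params()], score threshold 140, footprint energy threshold
#' -1 kcal/mol.
#'
#' @return nested list of engine parameters (class `engine_params`)
#' @export
default_engine_params <- function() {
  structure(list(
    ts = list(offset6 = FALSE),
    rh = list(e_threshold = -20, energy_model = default_energy_model()),
    m = c(default_align_params(),
          list(score_threshold = 140, e_threshold = -1))
  ), class = "engine_params")
}

#' Load engine parameter overrides from a plain-text config file
#'
#' Schema: one `key = value` pair per line, `#` comments allowed. Scalar keys
#' use dotted paths into [default_engine_params()]: e.g.
#' `m.score_threshold = 120`, `rh.e_threshold = -15`, `m.scale = 2`,
#' `ts.offset6 = TRUE`. Stacking energies are overridable as
#' `stack.<pair5><pair3> = <kcal/mol>` with pairs from AU, UA, GC, CG, GU, UG
#' (e.g. `stack.GC.GC = -3.3`); the duplex-reversal-symmetric entry is set
#' together. `init`, `max_loop` adjust the energy model directly.
#'
#' @param path config file path
#' @param base parameter set to override (default [default_engine_params()])
#' @return an `engine_params` list
#' @export
read_engine_config <- function(path, base = default_engine_params()) {
  if (!file.exists(path)) stop("engine config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  flip <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad config line (need key = value): ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else as.logical(toupper(val))
    if (is.na(parsed)) stop("bad config value for ", key, ": ", val)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] == "stack") {
      if (length(parts) != 3L || !all(parts[2:3] %in% PAIR_NAMES))
        stop("bad stack key (expected stack.<pair>.<pair>): ", key)
      base$rh$energy_model$stacks[parts[2], parts[3]] <- parsed
      base$rh$energy_model$stacks[flip[[parts[3]]], flip[[parts[2]]]] <- parsed
    } else if (key %in% c("init", "max_loop")) {
      base$rh$energy_model[[key]] <- parsed
    } else if (length(parts) == 2L && parts[1] %in% c("ts", "rh", "m")) {
      base[[parts[1]]][[parts[2]]] <- parsed
    } else {
      stop("unknown config key: ", key)
    }
  }
  validate_energy_model(base$rh$energy_model)
  base
}

# Built-in engine registry. Each engine: function(mirna_seq, structure,
# params, mirna_name) -> predicted_site data.frame. Custom engines with the
# same signature can be supplied to run_engines(engines = ...), e.g. wrappers
# around external prediction binaries.
#' @keywords internal
builtin_engines <- function(config) {
  list(
    TS = function(mirna, struct, mirna_name) {
      scan_seed_sites(mirna, struct$sequence, offset6 = config$ts$offset6,
                      mirna_name = mirna_name, circ_name = struct$name)
    },
    RH = function(mirna, struct, mirna_name) {
      hybridize_mfe(mirna, struct$sequence,
                    energy_model = config$rh$energy_model,
                    e_threshold = config$rh$e_threshold,
                    mirna_name = mirna_name, circ_name = struct$name)
    },
    M = function(mirna, struct, mirna_name) {
      local_align_score(mirna, struct$sequence,
                        params = config$m[names(default_align_params())],
                        score_threshold = config$m$score_threshold,
                        e_threshold = config$m$e_threshold,
                        energy_model = config$rh$energy_model,
                        mirna_name = mirna_name, circ_name = struct$name)
    }
  )
}

#' Run all prediction engines over all (miRNA, circRNA) pairs
#'
#' Each enabled engine runs independently on every pair with its configured
#' defaults and no cross-engine filtering. Work units are (miRNA, circRNA)
#' pairs; results are collected in input order so output is identical for any
#' `workers` value. An engine failure on a pair is logged to stderr, the pair
#' is skipped for that engine, and the failure count is returned in the
#' `n_failed` attribute.
#'
#' @param mirnas named character vector of miRNA sequences
#' @param circ_structures named list of `circ_structure` objects
#' @param config an `engine_params` list
#' @param workers number of parallel workers (default 1)
#' @param engines named list of engine functions to run; defaults to the
#'   built-in TS/RH/M registry for `config` (names become engine tags)
#' @return `predicted_site` data.frame (union of all engines over all pairs)
#'   with attribute `n_failed`
#' @export
run_engines <- function(mirnas, circ_structures,
                        config = default_engine_params(),
                        workers = 1L, engines = NULL) {
  if (is.null(engines)) engines <- builtin_engines(config)
  if (!length(mirnas) || !length(circ_structures)) {
    out <- empty_sites()
    attr(out, "n_failed") <- 0L
    return(out)
  }
  units <- expand.grid(mi = seq_along(mirnas), ci = seq_along(circ_structures),
                       KEEP.OUT.ATTRS = FALSE)
  worker <- function(u) {
    mi <- units$mi[u]; ci <- units$ci[u]
    struct <- circ_structures[[ci]]
    mirna_name <- names(mirnas)[mi]
    res <- lapply(names(engines), function(tag) {
      tryCatch(engines[[tag]](mirnas[[mi]], struct, mirna_name),
               error = function(e) {
                 message(sprintf("engine %s failed on %s x %s: %s",
                                 tag, mirna_name, struct$name, conditionMessage(e)))
                 structure(empty_sites(), failed = TRUE)
               })
    })
    nfail <- sum(vapply(res, function(r) isTRUE(attr(r, "failed")), TRUE))
    list(sites = do.call(rbind, res), n_failed = nfail)
  }
  idx <- seq_len(nrow(units))
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, worker, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(idx, worker)
  }
  sites <- do.call(rbind, lapply(results, `[[`, "sites"))
  sites <- dedupe_sites(sites)
  attr(sites, "n_failed") <- sum(vapply(results, `[[`, 0L, "n_failed"))
  sites
}
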