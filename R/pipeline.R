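# End-to-end pipeline: inputs -> circRNA structures -> prediction engines ->
# genomic back-mapping -> consensus merge -> annotation -> 12-column CSV,
# plus a JSON run report and the command-line surface.

#' Build and validate a pipeline run configuration
#'
#' @param input_bed circRNA BED (spans in full-sequence mode; one row per
#'   feature, grouped by name, in features mode)
#' @param genome_fasta genome FASTA path
#' @param mirna_fasta mature miRNA FASTA path
#' @param output_csv output CSV path
#' @param gtf gene annotation GTF (required in full-sequence mode)
#' @param mode `"full_sequence"` (default: classify circRNAs against the
#'   annotation and keep exon blocks) or `"features"` (input rows are the
#'   exact blocks; splitting skipped)
#' @param validated_bed,ago_bed,circbase_bed optional annotation tables
#' @param workers parallel workers over (miRNA, circRNA) pairs (default 1)
#' @param engine_params an `engine_params` list (default
#'   [default_engine_params()])
#' @param junction_wrap expose backsplice-junction-spanning sites by
#'   appending the first (longest miRNA length - 1) nucleotides after the
#'   junction (default FALSE: linear transcript)
#' @return a validated list of class `run_config`
#' @export
run_config <- function(input_bed, genome_fasta, mirna_fasta, output_csv,
                       gtf = NULL, mode = c("full_sequence", "features"),
                       validated_bed = NULL, ago_bed = NULL,
                       circbase_bed = NULL, workers = 1L,
                       engine_params = default_engine_params(),
                       junction_wrap = FALSE) {
  mode <- match.arg(mode)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("workers must be a positive integer")
  req <- c(input_bed = input_bed, genome_fasta = genome_fasta,
           mirna_fasta = mirna_fasta)
  if (mode == "full_sequence") {
    if (is.null(gtf)) stop("full-sequence mode requires a GTF annotation (or use features mode)")
    req <- c(req, gtf = gtf)
  }
  opt <- c(validated_bed = validated_bed, ago_bed = ago_bed,
           circbase_bed = circbase_bed)
  missing <- c(req, opt)[!file.exists(c(req, opt))]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(list(input_bed = input_bed, genome_fasta = genome_fasta,
                 mirna_fasta = mirna_fasta, output_csv = output_csv,
                 gtf = gtf, mode = mode, validated_bed = validated_bed,
                 ago_bed = ago_bed, circbase_bed = circbase_bed,
                 workers = workers, engine_params = engine_params,
                 junction_wrap = junction_wrap),
            class = "run_config")
}

#' Run the full prediction pipeline
#'
#' Three stages: (1) sequence extraction -- resolve each circRNA's block
#' structure against the gene annotation (or take user feature coordinates
#' verbatim) and assemble transcript sequences; (2) prediction -- run the
#' three engines on every (miRNA, circRNA) pair, project sites back to
#' genomic coordinates and merge identical sites across engines; (3)
#' annotation -- flag overlap with validated miRNA:RNA interactions and AGO
#' peaks and attach circBase IDs. Writes the 12-column CSV (canonical row
#' order: chrom, start, end, miRNA name) and a JSON run report alongside it.
#'
#' @param config a [run_config()]
#' @return invisibly, a list: `interactions` (data.frame), `sites`
#'   (per-engine sites in genomic coordinates), `structures`, `report`
#'   (stage counts), `csv`, `report_path`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genome <- read_genome_fasta(config$genome_fasta)
  mirnas <- read_mirna_fasta(config$mirna_fasta)
  circs <- read_bed(config$input_bed,
                    unique_names = (config$mode == "full_sequence"))
  genes <- if (!is.null(config$gtf)) read_gtf(config$gtf)
           else GenomicRanges::GRangesList()
  wrap_len <- if (length(mirnas)) max(nchar(mirnas)) - 1L else 0L
  structures <- build_circ_structures(circs, genes, genome,
                                      mode = config$mode,
                                      junction_wrap = config$junction_wrap,
                                      wrap_len = wrap_len)
  sites <- run_engines(mirnas, structures, config$engine_params,
                       workers = config$workers)
  n_failed <- attr(sites, "n_failed") %||% 0L
  sites <- sites_to_genomic(sites, structures)
  interactions <- merge_across_engines(sites)
  interactions <- assign_ids(interactions)
  db <- read_annotation_db(config$validated_bed, config$ago_bed,
                           config$circbase_bed)
  interactions <- flag_overlaps(interactions, db)
  interactions <- circbase_lookup(interactions, structures, db)
  write_results_csv(interactions, config$output_csv)
  report <- list(
    n_circ = length(structures),
    n_mirna = length(mirnas),
    n_sequences = length(structures),
    circ_classes = table_to_list(vapply(structures, `[[`, "", "circ_class")),
    sites_per_engine = table_to_list(sites$engine),
    n_sites = nrow(sites),
    n_interactions = nrow(interactions),
    n_three_tool = sum(interactions$software_matched == 3L),
    n_validated = sum(interactions$validated),
    n_ago = sum(interactions$ago),
    n_circbase = sum(!is.na(interactions$circbase_id)),
    n_engine_failures = n_failed
  )
  report_path <- paste0(config$output_csv, ".report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE)
  if (n_failed > 0L)
    warning(n_failed, " engine run(s) failed and were skipped; see log")
  invisible(list(interactions = interactions, sites = sites,
                 structures = structures, report = report,
                 csv = config$output_csv, report_path = report_path))
}

#' @keywords internal
table_to_list <- function(x) {
  tb <- table(x)
  stats::setNames(as.list(as.integer(tb)), names(tb))
}

#' Parse command-line arguments into a run configuration
#'
#' Flags: `-i/--input` circRNA BED (required); `--coord` treat the input as
#' feature coordinates and skip intron/exon splitting; `--genome` FASTA
#' (required); `--gtf` annotation (required unless `--coord`); `--mirnas`
#' miRNA FASTA (required); `--validated`, `--ago`, `--circbase` optional
#' annotation BEDs; `-o/--output` CSV path (required); `--threads` workers
#' (default 1); `--junction-wrap`; `--params` engine config file (see
#' [read_engine_config()]). Unknown or incomplete flags raise a condition of
#' class `usage_error`.
#'
#' @param argv character vector of command-line arguments
#' @return a [run_config()]
#' @export
parse_args <- function(argv) {
  usage_stop <- function(...) {
    stop(structure(class = c("usage_error", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
  }
  takes_value <- c("-i", "--input", "--genome", "--gtf", "--mirnas",
                   "--validated", "--ago", "--circbase", "-o", "--output",
                   "--threads", "--params")
  flags <- c("--coord", "--junction-wrap", "-h", "--help")
  opts <- list(threads = "1", coord = FALSE, junction_wrap = FALSE)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a %in% takes_value) {
      if (i == length(argv)) usage_stop("flag ", a, " needs a value")
      key <- sub("^--?", "", a)
      if (key == "i") key <- "input"
      if (key == "o") key <- "output"
      opts[[key]] <- argv[i + 1L]
      i <- i + 2L
    } else if (a %in% flags) {
      if (a %in% c("-h", "--help")) usage_stop(cli_usage())
      if (a == "--coord") opts$coord <- TRUE
      if (a == "--junction-wrap") opts$junction_wrap <- TRUE
      i <- i + 1L
    } else {
      usage_stop("unknown flag: ", a, "\n", cli_usage())
    }
  }
  for (need in c("input", "genome", "mirnas", "output")) {
    if (is.null(opts[[need]])) usage_stop("missing required flag --", need)
  }
  if (!opts$coord && is.null(opts$gtf))
    usage_stop("--gtf is required unless --coord is given")
  threads <- suppressWarnings(as.integer(opts$threads))
  if (is.na(threads) || threads < 1L)
    usage_stop("--threads must be a positive integer")
  params <- if (!is.null(opts$params)) read_engine_config(opts$params)
            else default_engine_params()
  run_config(input_bed = opts$input, genome_fasta = opts$genome,
             mirna_fasta = opts$mirnas, output_csv = opts$output,
             gtf = opts$gtf,
             mode = if (opts$coord) "features" else "full_sequence",
             validated_bed = opts$validated, ago_bed = opts$ago,
             circbase_bed = opts$circbase, workers = threads,
             engine_params = params, junction_wrap = opts$junction_wrap)
}

#' @keywords internal
cli_usage <- function() {
  paste(
    "usage: circmir -i circs.bed --genome genome.fa --gtf genes.gtf",
    "               --mirnas mirnas.fa -o out.csv",
    "               [--coord] [--validated v.bed] [--ago a.bed]",
    "               [--circbase c.bed] [--threads N] [--junction-wrap]",
    "               [--params engine.conf]",
    sep = "\n")
}

#' Command-line entry point
#'
#' Parses `argv`, runs the pipeline, prints the run report to stderr and
#' returns an exit status (0 success, 2 usage error, 1 runtime failure).
#' Used by the `inst/scripts/circmir` launcher.
#'
#' @param argv command-line arguments (default: `commandArgs(TRUE)`)
#' @return integer exit status, invisibly
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  config <- tryCatch(parse_args(argv), usage_error = function(e) {
    message(conditionMessage(e))
    NULL
  })
  if (is.null(config)) return(invisible(2L))
  status <- tryCatch({
    res <- run_pipeline(config)
    message("wrote ", res$csv, " (", res$report$n_interactions,
            " interactions); report: ", res$report_path)
    if (res$report$n_engine_failures > 0L) 1L else 0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
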