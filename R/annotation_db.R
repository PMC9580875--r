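# Annotation database: interval indices over the optional BED tables used to
# prioritize predicted interactions.

#' Load the annotation tables used to flag predicted interactions
#'
#' All three inputs are optional BED3/BED6 files; omitted tables are empty
#' and simply flag nothing.
#'
#' Dialect of the name column (column 4):
#' \describe{
#'   \item{validated}{`"<miRNA>|<target>"` for records tied to a specific
#'     miRNA (the flag then also requires the miRNA name to match); a name
#'     without `"|"`, `"."` or a missing column makes the record
#'     coordinate-only (overlap alone flags).}
#'   \item{ago}{free-form peak label, unused.}
#'   \item{circbase}{the circBase identifier for the exact circRNA span.}
#' }
#'
#' @param validated_bed,ago_bed,circbase_bed file paths or `NULL`
#' @return an object of class `annotation_db`: list of GRanges `validated`
#'   (with `mirna` metadata column, `NA` = coordinate-only), `ago`,
#'   `circbase` (with `name` = circBase ID)
#' @export
read_annotation_db <- function(validated_bed = NULL, ago_bed = NULL,
                               circbase_bed = NULL) {
  empty <- GenomicRanges::GRanges(name = character(0))
  validated <- if (is.null(validated_bed)) empty else
    read_bed(validated_bed, auto_name_prefix = "validated")
  validated$mirna <- ifelse(grepl("|", validated$name, fixed = TRUE),
                            sub("\\|.*$", "", validated$name),
                            NA_character_)
  ago <- if (is.null(ago_bed)) empty else
    read_bed(ago_bed, auto_name_prefix = "ago_peak")
  circbase <- if (is.null(circbase_bed)) empty else
    read_bed(circbase_bed, auto_name_prefix = "circbase")
  if (length(circbase) && any(grepl("^circbase_", circbase$name))) {
    warning("circBase record(s) without an identifier in column 4")
  }
  structure(list(validated = validated, ago = ago, circbase = circbase),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("annotation_db: %d validated, %d AGO peak, %d circBase record(s)\n",
              length(x$validated), length(x$ago), length(x$circbase)))
  invisible(x)
}
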