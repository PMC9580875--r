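# Readers and writers for the standard formats the pipeline touches.
#
# Internal convention: all intervals are GRanges, 1-based closed (the native
# Bioconductor convention). BED files on disk are 0-based half-open and are
# converted on read; the output CSV prints BED-convention start coordinates,
# matching the published 12-column schema.

#' Read a BED3/BED6 file into a GRanges
#'
#' A dialect-aware BED reader for the pipeline's inputs (circRNA coordinates,
#' circRNA feature coordinates, validated-interaction / AGO-peak / circBase
#' annotation tables). Comment, `track` and `browser` lines are skipped.
#' Records missing a name (or named `"."`) are auto-named
#' `<auto_name_prefix>_<n>` by data-line number; records missing a strand get
#' `"+"` with a warning. Chromosome names are taken verbatim (no "chr"
#' normalization).
#'
#' @param path path to a tab-separated BED file with >= 3 columns
#' @param unique_names error on duplicate names (circRNA inputs use their
#'   names as join keys downstream)
#' @param auto_name_prefix prefix used to auto-name unnamed records
#' @return a [GenomicRanges::GRanges] in file order with metadata column
#'   `name`; BED coordinates converted to 1-based closed
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tcircA\t0\t+", bed)
#' read_bed(bed)
read_bed <- function(path, unique_names = FALSE, auto_name_prefix = "circ") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  skip <- grepl("^\\s*$", raw) | grepl("^#", raw) |
    grepl("^(track|browser)([[:space:]]|$)", raw)
  lines <- raw[!skip]
  lineno <- which(!skip)
  if (!length(lines)) {
    return(GenomicRanges::GRanges(name = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    stop(sprintf("line %d of %s: expected >= 3 tab-separated columns",
                 lineno[bad], path))
  }
  col <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, "")
  chrom <- col(1)
  start0 <- suppressWarnings(as.integer(col(2)))
  end0 <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stop(sprintf("line %d of %s: non-integer coordinates", lineno[bad[1]], path))
  }
  bad <- which(start0 < 0L | end0 <= start0)
  if (length(bad)) {
    stop(sprintf("line %d of %s: invalid interval [%d, %d) (need 0 <= start < end)",
                 lineno[bad[1]], path, start0[bad[1]], end0[bad[1]]))
  }
  name <- col(4)
  missing_name <- is.na(name) | name == "" | name == "."
  name[missing_name] <- sprintf("%s_%d", auto_name_prefix, which(missing_name))
  strand <- col(6)
  missing_strand <- is.na(strand) | !(strand %in% c("+", "-"))
  if (any(missing_strand)) {
    warning(sprintf("%d record(s) in %s without a +/- strand; defaulting to '+'",
                    sum(missing_strand), path))
    strand[missing_strand] <- "+"
  }
  if (unique_names && anyDuplicated(name)) {
    stop(sprintf("duplicate record name(s) in %s: %s (names are join keys)",
                 path, paste(unique(name[duplicated(name)]), collapse = ", ")))
  }
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    name = name
  )
}

#' Read gene models from a GTF annotation
#'
#' Imports `exon` features (via [rtracklayer::import]) and returns one gene
#' model per `gene_id`: overlapping exon records of a gene are merged into
#' maximal blocks, sorted by start. Exons without a `gene_id` attribute, or on
#' strand `"."`, are skipped with a warning.
#'
#' @param path path to a GTF file (1-based inclusive on disk, as usual)
#' @return a named [GenomicRanges::GRangesList]; one reduced, sorted exon set
#'   per gene
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  gid <- ex$gene_id
  if (is.null(gid)) gid <- rep(NA_character_, length(ex))
  drop <- is.na(gid) | gid == ""
  if (any(drop)) {
    warning(sprintf("%d exon record(s) without gene_id skipped in %s",
                    sum(drop), path))
    ex <- ex[!drop]; gid <- gid[!drop]
  }
  unstranded <- as.character(BiocGenerics::strand(ex)) == "*"
  if (any(unstranded)) {
    warning(sprintf("%d unstranded exon record(s) skipped in %s",
                    sum(unstranded), path))
    ex <- ex[!unstranded]; gid <- gid[!unstranded]
  }
  if (!length(ex)) return(GenomicRanges::GRangesList())
  by_gene <- GenomicRanges::split(ex, gid)
  GenomicRanges::reduce(by_gene)
}

#' Read mature miRNA sequences from FASTA
#'
#' Names are taken from the header up to the first whitespace; T is converted
#' to U so DNA- or RNA-alphabet files both work. Duplicate names and
#' characters outside A/C/G/U/T/N are errors.
#'
#' @param path path to a FASTA file of mature miRNA sequences (5' to 3')
#' @return named character vector of RNA sequences
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) stop("miRNA FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set))) {
    stop("duplicate miRNA name(s) in ", path, ": ",
         paste(unique(names(set)[duplicated(names(set))]), collapse = ", "))
  }
  seqs <- to_rna(as.character(set))
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("miRNA ", names(set)[which(bad)[1]], " in ", path,
         " contains characters outside {A,C,G,U,T,N}")
  }
  if (any(!nzchar(seqs))) stop("empty miRNA sequence in ", path)
  if (any(nchar(seqs) < 15L)) {
    warning("miRNA sequence(s) shorter than 15 nt in ", path,
            " (unusual for mature miRNAs)")
  }
  seqs
}

#' Read a genome FASTA
#'
#' @param path path to a (multi-)FASTA of chromosome sequences
#' @return a [Biostrings::DNAStringSet] named by chromosome (header up to
#'   first whitespace)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# Exact column order of the published 12-column result schema.
RESULT_COLUMNS <- c("Chrom", "Start", "End", "miRNA Name", "Circ Name",
                    "Strand", "Seed Category", "ID", "Software Matched",
                    "Validated", "AGO", "circBase ID")

#' Write the 12-column interaction table as CSV
#'
#' Emits the standard result schema: Chrom, Start, End, miRNA Name, Circ Name,
#' Strand, Seed Category, ID, Software Matched, Validated, AGO, circBase ID.
#' Start is printed in BED convention (0-based), matching the input BED
#' coordinates; Validated/AGO are rendered "Yes"/"No"; a missing circBase ID
#' is an empty string. An empty interaction set yields a header-only file.
#'
#' @param interactions an interaction data.frame as produced by
#'   [flag_overlaps()]/[circbase_lookup()] (internal 1-based coordinates)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_results_csv <- function(interactions, path) {
  yn <- function(x) ifelse(isTRUE_vec(x), "Yes", "No")
  n <- if (is.null(interactions)) 0L else nrow(interactions)
  if (n) {
    out <- data.frame(
      check.names = FALSE,
      "Chrom" = interactions$chrom,
      "Start" = interactions$start - 1L,
      "End" = interactions$end,
      "miRNA Name" = interactions$mirna,
      "Circ Name" = interactions$circ,
      "Strand" = interactions$strand,
      "Seed Category" = interactions$seed_category,
      "ID" = interactions$id,
      "Software Matched" = interactions$software_matched,
      "Validated" = yn(interactions$validated),
      "AGO" = yn(interactions$ago),
      "circBase ID" = ifelse(is.na(interactions$circbase_id), "",
                             interactions$circbase_id)
    )
  } else {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12L),
                                         RESULT_COLUMNS),
                         check.names = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @keywords internal
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
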