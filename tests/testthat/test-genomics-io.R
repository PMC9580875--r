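# BED/GTF/FASTA readers and the 12-column CSV writer.

test_that("read_bed parses coordinates, strands and names per the dialect", {
  f <- write_tmp(c(
    "# a comment",
    "track name=demo",
    "chr1\t16453189\t16453211\tsiteA\t0\t-",
    "chr2\t10\t50"
  ))
  expect_warning(b <- read_bed(f), "strand")
  expect_equal(length(b), 2L)
  expect_equal(as.character(GenomeInfoDb::seqnames(b)), c("chr1", "chr2"))
  # BED 0-based half-open -> internal 1-based closed
  expect_equal(BiocGenerics::start(b), c(16453190L, 11L))
  expect_equal(BiocGenerics::end(b), c(16453211L, 50L))
  expect_equal(as.character(BiocGenerics::strand(b)), c("-", "+"))
  expect_equal(b$name, c("siteA", "circ_2"))

  # 3-column-only file: first data line auto-named circ_1
  f3 <- write_tmp("chr2\t10\t50")
  expect_warning(b3 <- read_bed(f3))
  expect_equal(b3$name, "circ_1")
})

test_that("read_bed rejects malformed records with the offending line", {
  f <- write_tmp(c("chr1\t5\t10\tok\t0\t+", "chr1\t100\t100\tx\t0\t+"))
  expect_error(read_bed(f), "line 2")
  f2 <- write_tmp("chr1\tten\t20\tx\t0\t+")
  expect_error(read_bed(f2), "non-integer")
  f4 <- write_tmp(c("chr1\t5\t10\tdup\t0\t+", "chr1\t50\t60\tdup\t0\t+"))
  expect_error(read_bed(f4, unique_names = TRUE), "dup")
  expect_silent(read_bed(f4))  # annotation tables may repeat names
})

test_that("read_bed round-trips well-formed records", {
  set.seed(11)
  n <- 25L
  start0 <- sample.int(1e6, n)
  lines <- sprintf("chr%d\t%d\t%d\tfeat_%d\t0\t%s",
                   sample(1:3, n, TRUE), start0,
                   start0 + sample.int(500, n), seq_len(n),
                   sample(c("+", "-"), n, TRUE))
  b <- read_bed(write_tmp(lines))
  out <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                 as.character(GenomeInfoDb::seqnames(b)),
                 BiocGenerics::start(b) - 1L, BiocGenerics::end(b),
                 b$name, as.character(BiocGenerics::strand(b)))
  expect_identical(out, lines)
})

test_that("read_gtf merges overlapping exons per gene and keeps sort order", {
  f <- write_tmp(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "t1";',
    'chr1\tsrc\texon\t151\t250\t.\t+\t.\tgene_id "G1"; transcript_id "t2";',
    'chr1\tsrc\texon\t401\t500\t.\t+\t.\tgene_id "G2"; transcript_id "t3";',
    'chr1\tsrc\texon\t301\t350\t.\t+\t.\tgene_id "G2"; transcript_id "t4";'
  ), ext = ".gtf")
  genes <- read_gtf(f)
  expect_setequal(names(genes), c("G1", "G2"))
  expect_equal(BiocGenerics::start(genes[["G1"]]), 101L)
  expect_equal(BiocGenerics::end(genes[["G1"]]), 250L)
  expect_equal(BiocGenerics::start(genes[["G2"]]), c(301L, 401L))
})

test_that("GTF 1-based coordinates extract the planted exon sequence", {
  # plant a known exon sequence and check the read coordinates recover it
  set.seed(7)
  chr <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  planted <- "ACGTACGTTGCA"
  substr(chr, 101, 112) <- planted
  f <- write_tmp(sprintf('chrZ\tsrc\texon\t%d\t%d\t.\t+\t.\tgene_id "G";', 101, 112),
                 ext = ".gtf")
  genes <- read_gtf(f)
  ex <- genes[["G"]]
  got <- substr(chr, BiocGenerics::start(ex), BiocGenerics::end(ex))
  expect_identical(got, planted)
})

test_that("read_gtf skips exons without gene_id or strand with a warning", {
  f <- write_tmp(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1";',
    'chr1\tsrc\texon\t301\t400\t.\t.\t.\tgene_id "G3";'
  ), ext = ".gtf")
  expect_warning(genes <- read_gtf(f), "unstranded")
  expect_equal(names(genes), "G1")
})

test_that("read_mirna_fasta converts T to U and validates names and alphabet", {
  f <- write_tmp(c(">mmu-miR-3101-3p some description", "TAGCTTATCAGACTGATGTTGA"),
                 ext = ".fa")
  m <- read_mirna_fasta(f)
  expect_identical(names(m), "mmu-miR-3101-3p")
  expect_identical(unname(m), "UAGCUUAUCAGACUGAUGUUGA")
  expect_false(grepl("T", m))

  dup <- write_tmp(c(">x", "UAGCUUAUCAGACUGAUGU", ">x", "GGGGUUUUCCCCAAAAGGG"), ext = ".fa")
  expect_error(read_mirna_fasta(dup), "duplicate")
  bad <- write_tmp(c(">y", "UAGXUUAUCAGACUGAUGU"), ext = ".fa")
  expect_error(read_mirna_fasta(bad), "outside")
})

test_that("write_results_csv emits the exact 12-column schema", {
  # the published example row must round-trip byte-exactly
  it <- data.frame(chrom = "chr1", start = 16453190L, end = 16453211L,
                   mirna = "mmu-miR-3101-3p", circ = "CiCo_mm9_circ_000139",
                   strand = "-", seed_category = "7mer-m8", id = "INT_M_3224",
                   software_matched = 3L, validated = TRUE, ago = FALSE,
                   circbase_id = "mmu_circ_0000012", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_results_csv(it, f)
  lines <- readLines(f)
  expect_identical(lines[1], paste(c("Chrom", "Start", "End", "miRNA Name",
                                     "Circ Name", "Strand", "Seed Category",
                                     "ID", "Software Matched", "Validated",
                                     "AGO", "circBase ID"), collapse = ","))
  expect_identical(
    lines[2],
    "chr1,16453189,16453211,mmu-miR-3101-3p,CiCo_mm9_circ_000139,-,7mer-m8,INT_M_3224,3,Yes,No,mmu_circ_0000012")

  # missing circBase ID renders as the empty string
  it$circbase_id <- NA_character_
  write_results_csv(it, f)
  expect_match(readLines(f)[2], ",No,$")

  # empty set: header-only file with 12 columns
  write_results_csv(NULL, f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_length(strsplit(lines, ",")[[1]], 12L)
})
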