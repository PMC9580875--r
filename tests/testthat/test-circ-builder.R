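# circRNA classification, block splitting, sequence assembly and the
# transcript<->genome coordinate map.

toy_genes <- function() {
  g <- GenomicRanges::GRangesList(
    GENEA = gr("chr1", c(51, 301, 451), c(150, 400, 600), "+"),
    GENEB = gr("chr1", 50, 1000, "-")
  )
  g
}

test_that("circRNAs classify by strand-aware gene overlap", {
  genes <- toy_genes()
  expect_equal(classify_circ(gr("chr1", 101, 500, "+"), genes), "sense_overlapping")
  expect_equal(classify_circ(gr("chr1", 101, 500, "-"), genes), "sense_overlapping")
  genes_minus_only <- genes["GENEB"]
  expect_equal(classify_circ(gr("chr1", 101, 500, "+"), genes_minus_only), "antisense")
  expect_equal(classify_circ(gr("chr9", 11, 90, "+"), genes), "intergenic")
})

test_that("sense-overlapping circRNAs split to exon blocks clipped to the span", {
  genes <- toy_genes()
  circ <- gr("chr1", 101, 500, "+", name = "c1")
  blocks <- split_to_blocks(circ, genes)
  # brute-force per-base oracle: a base is kept iff in circ span AND in an exon
  exons <- genes[["GENEA"]]
  keep <- vapply(101:500, function(p) {
    any(p >= BiocGenerics::start(exons) & p <= BiocGenerics::end(exons))
  }, TRUE)
  kept_pos <- (101:500)[keep]
  got_pos <- unlist(lapply(seq_along(blocks), function(i) {
    BiocGenerics::start(blocks)[i]:BiocGenerics::end(blocks)[i]
  }))
  expect_identical(sort(got_pos), kept_pos)
  expect_equal(BiocGenerics::start(blocks), c(101L, 301L, 451L))
  expect_equal(BiocGenerics::end(blocks), c(150L, 400L, 500L))
})

test_that("antisense and intronic circRNAs fall back to a single block", {
  genes <- toy_genes()
  anti <- gr("chr1", 101, 500, "+", name = "a")
  blocks <- split_to_blocks(anti, genes["GENEB"], "antisense")
  expect_equal(length(blocks), 1L)
  expect_equal(BiocGenerics::start(blocks), 101L)
  expect_equal(BiocGenerics::end(blocks), 500L)

  intronic <- gr("chr1", 161, 290, "+", name = "i")  # between GENEA exons
  expect_warning(blocks <- split_to_blocks(intronic, genes["GENEA"],
                                           "sense_overlapping"),
                 "no exon")
  expect_equal(length(blocks), 1L)
  expect_equal(BiocGenerics::width(blocks), 130L)
})

test_that("multi-gene overlap picks the largest-overlap host, ties by name", {
  genes <- GenomicRanges::GRangesList(
    SMALL = gr("chr1", c(90, 180), c(120, 220), "+"),
    WIDE = gr("chr1", c(90, 400), c(350, 500), "+")
  )
  circ <- gr("chr1", 100, 360, "+", name = "c")
  # WIDE span [90,500] overlaps 261 bp, SMALL span [90,220] overlaps 121 bp
  blocks <- split_to_blocks(circ, genes, "sense_overlapping")
  expect_equal(BiocGenerics::start(blocks), c(100L))
  expect_equal(BiocGenerics::end(blocks), c(350L))
})

test_that("user feature mode passes blocks through and validates consistency", {
  feats <- gr("chr1", c(101, 301), c(150, 400), "+",
              name = c("circX", "circX"))
  out <- accept_user_features(feats)
  expect_named(out, "circX")
  expect_equal(length(out$circX), 2L)
  bad <- gr(c("chr1", "chr2"), c(1, 1), c(10, 10), "+", name = c("cx", "cx"))
  expect_error(accept_user_features(bad), "chromosomes or strands")
})

test_that("assemble_sequence extracts strand-correct RNA", {
  genome <- make_genome(chr1 = "AAACGTACAAA")
  # block covering bases 4..8 ("CGTAC")
  plus <- assemble_sequence(gr("chr1", 4, 8, "+"), "+", genome)
  expect_identical(plus$sequence, "CGUAC")
  minus <- assemble_sequence(gr("chr1", 4, 8, "-"), "-", genome)
  expect_identical(minus$sequence, "GUACG")
  two <- assemble_sequence(gr("chr1", c(4, 9), c(5, 10), "+"), "+", genome)
  expect_equal(nchar(two$sequence), 4L)   # length conservation across blocks
  expect_error(assemble_sequence(gr("chr1", 4, 99, "+"), "+", genome), "bounds")
  expect_error(assemble_sequence(gr("chrX", 1, 5, "+"), "+", genome),
               "chromosome not found")
})

test_that("map_to_genome handles offsets, minus strand, and junctions", {
  # single + block [101,200]: window 11..20 -> genomic 111..120
  cm <- coord_map(gr("chrT", 101, 200, "+"))
  g <- map_to_genome(cm, 11, 20)
  expect_equal(BiocGenerics::start(g), 111L)
  expect_equal(BiocGenerics::end(g), 120L)

  # single - block: transcript 1..10 -> genomic 191..200
  cmm <- coord_map(gr("chrT", 101, 200, "-"))
  g <- map_to_genome(cmm, 1, 10)
  expect_equal(BiocGenerics::start(g), 191L)
  expect_equal(BiocGenerics::end(g), 200L)

  # junction-spanning window over blocks [101,150]+[301,400] on +
  cm2 <- coord_map(gr("chrT", c(101, 301), c(150, 400), "+"))
  g <- map_to_genome(cm2, 46, 55)
  expect_equal(BiocGenerics::start(g), c(146L, 301L))
  expect_equal(BiocGenerics::end(g), c(150L, 305L))

  expect_error(map_to_genome(cm2, 0, 5), "out of range")
  expect_error(map_to_genome(cm2, 140, 151), "out of range")
})

test_that("interval mapper agrees with the per-base oracle on random structures", {
  set.seed(402)
  for (rep in 1:300) {
    mat <- rand_blocks(sample(1:4, 1L))
    strand <- sample(c("+", "-"), 1L)
    L <- sum(mat[, 2] - mat[, 1] + 1L)
    a <- sample.int(L, 1L)
    b <- min(L, a + sample.int(25L, 1L) - 1L)
    cm <- coord_map(blocks_gr(mat, strand), strand = strand, chrom = "chrT")
    got <- map_to_genome(cm, a, b)
    exp <- oracle_map_window(mat, strand, a, b)
    expect_equal(BiocGenerics::start(got), unname(exp[, 1]))
    expect_equal(BiocGenerics::end(got), unname(exp[, 2]))
    # conservation of length
    expect_equal(sum(BiocGenerics::width(got)), b - a + 1L)
  }
})

test_that("minus-strand mapping is monotone decreasing per base", {
  set.seed(77)
  mat <- rand_blocks(3L)
  cm <- coord_map(blocks_gr(mat, "-"), strand = "-", chrom = "chrT")
  L <- sum(mat[, 2] - mat[, 1] + 1L)
  g <- vapply(seq_len(L), function(t) BiocGenerics::start(map_to_genome(cm, t, t)), 0L)
  expect_true(all(diff(g) < 0))
  # genome_to_transcript inverts every position
  t_back <- vapply(g, function(p) genome_to_transcript(cm, p), 0L)
  expect_identical(t_back, seq_len(L))
})

test_that("mapping then re-extracting reproduces the transcript subsequence", {
  set.seed(93)
  for (rep in 1:50) {
    chr_len <- 400L
    genome_str <- paste(sample(c("A", "C", "G", "T"), chr_len, TRUE), collapse = "")
    mat <- rand_blocks(sample(1:3, 1L), block_max = 30L, gap_max = 20L)
    stopifnot(max(mat) <= chr_len)
    strand <- sample(c("+", "-"), 1L)
    st <- make_struct(genome_str, mat, strand)
    L <- st$cmap$length
    a <- sample.int(L, 1L); b <- min(L, a + sample.int(15L, 1L) - 1L)
    g <- map_to_genome(st$cmap, a, b)
    segs <- vapply(seq_along(g), function(i) {
      substr(genome_str, BiocGenerics::start(g)[i], BiocGenerics::end(g)[i])
    }, "")
    dna <- paste(segs, collapse = "")   # genomic order
    rna <- if (strand == "+") chartr("T", "U", dna) else {
      chartr("ACGT", "UGCA", paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
    }
    expect_identical(rna, substr(st$sequence, a, b))
  }
})

test_that("junction wrap exposes the backsplice junction and maps modulo length", {
  genome <- make_genome(chr1 = "AAACGTACAAA")
  asm <- assemble_sequence(gr("chr1", 4, 8, "+"), "+", genome, wrap_len = 3L)
  expect_identical(asm$sequence, "CGUACCGU")   # first 3 nt appended
  g <- map_to_genome(asm$cmap, 4, 7)           # spans the junction
  expect_equal(BiocGenerics::start(g), c(4L, 7L))
  expect_equal(BiocGenerics::end(g), c(5L, 8L))
})
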