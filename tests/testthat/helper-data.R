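# Small in-code builders shared by the tests.

make_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

gr <- function(chrom, start, end, strand = "+", name = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  if (!is.null(name)) g$name <- name
  g
}

# random non-overlapping sorted blocks on a virtual chromosome
rand_blocks <- function(n_blocks, block_max = 40L, gap_max = 30L) {
  pos <- 1L
  out <- matrix(0L, n_blocks, 2)
  for (i in seq_len(n_blocks)) {
    pos <- pos + sample.int(gap_max, 1L)
    w <- sample.int(block_max, 1L)
    out[i, ] <- c(pos, pos + w - 1L)
    pos <- pos + w
  }
  out
}

blocks_gr <- function(mat, strand = "+", chrom = "chrT") {
  gr(chrom, mat[, 1], mat[, 2], strand)
}

# assembled structure over an explicit genome string
make_struct <- function(genome_str, blocks_mat, strand, chrom = "chr1",
                        name = "circX", wrap_len = 0L) {
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, chrom))
  asm <- assemble_sequence(blocks_gr(blocks_mat, strand, chrom), strand,
                           genome, wrap_len = wrap_len)
  structure(list(name = name, circ_class = "user_features", chrom = chrom,
                 strand = strand,
                 blocks = blocks_gr(blocks_mat, strand, chrom),
                 span = gr(chrom, min(blocks_mat[, 1]), max(blocks_mat[, 2]), strand),
                 sequence = asm$sequence, cmap = asm$cmap),
            class = "circ_structure")
}

write_tmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# one shared default fixture per test run (generation is a few seconds)
fixture_42 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        generate_fixture(dir = tempfile("fx42_"), seed = 42))
    }
    cache
  }
})

run_fixture_pipeline <- function(fx, out_csv = tempfile(fileext = ".csv"),
                                 workers = 1L, ...) {
  cfg <- run_config(input_bed = fx$paths[["circ_bed"]],
                    genome_fasta = fx$paths[["genome"]],
                    mirna_fasta = fx$paths[["mirna_fasta"]],
                    gtf = fx$paths[["gtf"]],
                    output_csv = out_csv,
                    validated_bed = fx$paths[["validated"]],
                    ago_bed = fx$paths[["ago"]],
                    circbase_bed = fx$paths[["circbase"]],
                    workers = workers, ...)
  suppressWarnings(suppressMessages(run_pipeline(cfg)))
}
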