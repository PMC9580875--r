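# Genomic back-conversion, cross-engine merging, ID assignment and
# annotation flags.

# a site table builder in genomic coordinates (already back-converted)
gsite <- function(engine, mirna, circ, g_start, g_end, cat = "none",
                  chrom = "chr1", strand = "+") {
  df <- data.frame(engine = engine, mirna = mirna, circ = circ,
                   t_start = 1L, t_end = 1L + g_end - g_start,
                   score = 0, seed_category = cat, alignment = "",
                   chrom = chrom, strand = strand,
                   g_start = g_start, g_end = g_end, stringsAsFactors = FALSE)
  df$g_blocks <- list(cbind(start = g_start, end = g_end))
  df
}

test_that("sites_to_genomic projects through the coordinate map", {
  genome_str <- paste(rep("ACGT", 200), collapse = "")
  st_plus <- make_struct(genome_str, rbind(c(101, 200)), "+", name = "cp")
  st_minus <- make_struct(genome_str, rbind(c(101, 200)), "-", name = "cm")
  st_two <- make_struct(genome_str, rbind(c(101, 150), c(301, 400)), "+",
                        name = "c2")
  sites <- rbind(
    data.frame(engine = "TS", mirna = "m", circ = "cp", t_start = 11L,
               t_end = 20L, score = 1, seed_category = "6mer", alignment = ""),
    data.frame(engine = "TS", mirna = "m", circ = "cm", t_start = 1L,
               t_end = 10L, score = 1, seed_category = "6mer", alignment = ""),
    data.frame(engine = "TS", mirna = "m", circ = "c2", t_start = 46L,
               t_end = 55L, score = 1, seed_category = "6mer", alignment = "")
  )
  expect_message(
    out <- sites_to_genomic(sites, list(cp = st_plus, cm = st_minus, c2 = st_two)),
    "junction")
  expect_equal(out$g_start, c(111L, 191L, 146L))
  expect_equal(out$g_end, c(120L, 200L, 150L))
  expect_equal(nrow(out$g_blocks[[3]]), 2L)
  expect_equal(sum(out$g_blocks[[3]][, "end"] - out$g_blocks[[3]][, "start"] + 1L), 10L)
  expect_error(sites_to_genomic(sites[1, ], list()), "no structure")
})

test_that("identical sites found by several engines merge into one interaction", {
  s <- rbind(gsite("TS", "miR-1", "c1", 100, 107, "7mer-m8"),
             gsite("RH", "miR-1", "c1", 95, 116),
             gsite("M", "miR-1", "c1", 98, 118, "7mer-m8"))
  it <- merge_across_engines(s)
  expect_equal(nrow(it), 1L)
  expect_equal(it$software_matched, 3L)
  expect_equal(it$tag, "M")                 # ID tag priority M > RH > TS
  expect_equal(it$seed_category, "7mer-m8")
  expect_equal(c(it$start, it$end), c(100L, 107L))   # TS window wins

  # singleton RH site
  it2 <- merge_across_engines(gsite("RH", "miR-1", "c1", 500, 520))
  expect_equal(it2$software_matched, 1L)
  expect_equal(it2$tag, "RH")

  # same window, different miRNA: never merged
  s3 <- rbind(gsite("TS", "miR-1", "c1", 100, 107, "6mer"),
              gsite("M", "miR-2", "c1", 100, 107, "6mer"))
  expect_equal(nrow(merge_across_engines(s3)), 2L)
})

test_that("grouping equals the brute-force transitive-closure oracle", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- 20L
    start <- sample.int(300, n)
    end <- start + sample.int(25, n)
    mirna <- sample(c("miR-1", "miR-2"), n, TRUE)
    s <- do.call(rbind, lapply(seq_len(n), function(i) {
      gsite(sample(c("TS", "RH", "M"), 1L), mirna[i], "c1", start[i], end[i])
    }))
    it <- merge_across_engines(s)
    comp <- oracle_group(mirna, start, end)
    expect_equal(nrow(it), length(unique(comp)))
    # per-miRNA component counts agree with the oracle partition
    for (mn in unique(mirna)) {
      expect_equal(sum(it$mirna == mn),
                   length(unique(comp[mirna == mn])))
    }
  }
})

test_that("merging is idempotent", {
  set.seed(8)
  n <- 30L
  start <- sample.int(400, n)
  s <- do.call(rbind, lapply(seq_len(n), function(i) {
    gsite(sample(c("TS", "RH", "M"), 1L), "miR-1", "c1", start[i],
          start[i] + sample.int(30, 1L))
  }))
  it1 <- merge_across_engines(s)
  # re-feed the merged interactions as singleton sites
  s2 <- do.call(rbind, lapply(seq_len(nrow(it1)), function(i) {
    g <- gsite(it1$tag[i], it1$mirna[i], it1$circ[i], it1$start[i], it1$end[i],
               it1$seed_category[i])
    g$g_blocks <- list(it1$blocks[[i]])
    g
  }))
  it2 <- merge_across_engines(s2)
  expect_equal(nrow(it2), nrow(it1))
  expect_equal(sort(it2$start), sort(it1$start))
})

test_that("IDs number per tag in canonical order and are unique", {
  s <- rbind(gsite("M", "miR-1", "c1", 100, 110),
             gsite("RH", "miR-1", "c1", 200, 210),
             gsite("M", "miR-1", "c1", 300, 310))
  it <- assign_ids(merge_across_engines(s))
  expect_equal(it$id, c("INT_M_1", "INT_RH_1", "INT_M_2"))
  expect_false(anyDuplicated(it$id) > 0)
  # deterministic across repeated runs
  it2 <- assign_ids(merge_across_engines(s))
  expect_identical(it$id, it2$id)
})

test_that("validated and AGO flags follow overlap and miRNA-name rules", {
  it <- assign_ids(merge_across_engines(
    rbind(gsite("TS", "miR-1", "c1", 100, 107, "6mer"),
          gsite("TS", "miR-2", "c1", 300, 307, "6mer"))))
  val <- write_tmp(c("chr1\t95\t105\tmiR-1|SOMEGENE\t0\t+",     # overlaps site 1, right miRNA
                     "chr1\t295\t310\tmiR-9|SOMEGENE\t0\t+"))   # overlaps site 2, wrong miRNA
  ago <- write_tmp("chr1\t304\t400\tpeak\t0\t.")
  db <- suppressWarnings(read_annotation_db(validated_bed = val, ago_bed = ago))
  out <- flag_overlaps(it, db)
  expect_equal(out$validated, c(TRUE, FALSE))
  expect_equal(out$ago, c(FALSE, TRUE))

  # empty database: all flags stay FALSE
  out0 <- flag_overlaps(it, read_annotation_db())
  expect_false(any(out0$validated) || any(out0$ago))

  # coordinate-only record (no miRNA name) flags on overlap alone
  val2 <- write_tmp("chr1\t295\t310\tsomething\t0\t+")
  db2 <- read_annotation_db(validated_bed = val2)
  expect_equal(flag_overlaps(it, db2)$validated, c(FALSE, TRUE))
})

test_that("flags are monotone under database growth", {
  set.seed(55)
  it <- assign_ids(merge_across_engines(do.call(rbind, lapply(1:10, function(i) {
    s <- sample.int(500, 1L)
    gsite("TS", "miR-1", "c1", s, s + 7L, "6mer")
  }))))
  recs <- sprintf("chr1\t%d\t%d\tmiR-1|g\t0\t+", sample.int(500, 8L),
                  sample.int(500, 8L) + 600L)
  prev <- rep(FALSE, nrow(it))
  for (k in 1:8) {
    db <- read_annotation_db(validated_bed = write_tmp(recs[1:k]))
    cur <- flag_overlaps(it, db)$validated
    expect_true(all(cur[prev]))   # no Yes ever turns into No
    prev <- cur
  }
})

test_that("circBase lookup is exact-coordinate with optional tolerance", {
  genome_str <- paste(rep("ACGT", 300), collapse = "")
  st <- make_struct(genome_str, rbind(c(101, 200)), "+", name = "c1")
  it <- assign_ids(merge_across_engines(gsite("TS", "miR-1", "c1", 120, 127, "6mer")))
  # exact span: BED 100..200 == internal [101,200]
  cb_exact <- write_tmp("chr1\t100\t200\tmmu_circ_0000012\t0\t+")
  db <- read_annotation_db(circbase_bed = cb_exact)
  out <- circbase_lookup(it, list(c1 = st), db)
  expect_equal(out$circbase_id, "mmu_circ_0000012")

  # off-by-one span does not match at tol = 0, matches at tol = 1
  cb_off <- write_tmp("chr1\t101\t200\tmmu_circ_0000012\t0\t+")
  db_off <- read_annotation_db(circbase_bed = cb_off)
  expect_true(is.na(circbase_lookup(it, list(c1 = st), db_off)$circbase_id))
  expect_equal(circbase_lookup(it, list(c1 = st), db_off, tol = 1L)$circbase_id,
               "mmu_circ_0000012")

  # empty table
  expect_true(is.na(circbase_lookup(it, list(c1 = st),
                                    read_annotation_db())$circbase_id))
})
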