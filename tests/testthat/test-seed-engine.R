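# Seed-category classifier and the exact seed-match (TS) engine.

test_that("classify_seed implements the canonical site taxonomy", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  # 8mer target window: revcomp(m2..m8) + A = "AUAAGCUA"
  expect_equal(classify_seed(mir, "AUAAGCUA", pairing = c(NA, 7:1)), "8mer")
  # U opposite position 1 instead of A -> 7mer-m8
  expect_equal(classify_seed(mir, "AUAAGCUU", pairing = c(NA, 7:1)), "7mer-m8")
  # only 2..7 paired, with A1
  expect_equal(classify_seed(mir, "UAAGCUA", pairing = c(NA, 6:1)), "7mer-A1")
  # only 2..7 paired, no A1
  expect_equal(classify_seed(mir, "UAAGCUU", pairing = c(NA, 6:1)), "6mer")
  # G:U wobble inside the seed disqualifies all 2-7 anchored classes
  mir_gu <- "UAGCGUAUCAGACUGAUGUUGA"   # position 5 = G
  tgt <- "AUAUGCUA"                     # U opposite position 5 -> G:U
  expect_equal(classify_seed(mir_gu, tgt, pairing = c(NA, 7:1)), "none")
  # a gap inside the seed (non-consecutive target positions) disqualifies
  expect_equal(classify_seed(mir, "GAUAAGCUA", pairing = c(NA, 8, 6:1)), "none")
  # positions 3..8 as a contiguous helix -> offset-6mer
  expect_equal(classify_seed(mir, "AUAAGC", pairing = c(NA, NA, 6:1)),
               "offset-6mer")
})

test_that("scan_seed_sites finds planted sites with the right window", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  s <- scan_seed_sites(mir, "GGGAUAAGCUAGGG")
  expect_equal(nrow(s), 1L)
  expect_equal(s$seed_category, "8mer")
  expect_equal(c(s$t_start, s$t_end), c(4L, 11L))   # 8-nt window
  expect_equal(s$engine, "TS")

  # no complementarity -> empty
  expect_equal(nrow(scan_seed_sites(mir, "GGGGGGGGGGGG")), 0L)

  # the same 8mer planted twice -> two sites
  s2 <- scan_seed_sites(mir, "GGAUAAGCUAGGGGGAUAAGCUAGG")
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$seed_category, c("8mer", "8mer"))
})

test_that("TS engine equals the exhaustive window-scan oracle on random draws", {
  set.seed(515)
  n_hit <- 0L
  for (rep in 1:300) {
    mir <- rand_rna(sample(15:24, 1L))
    tx <- rand_rna(sample(30:80, 1L))
    # plant the seed region in about half the draws so hits are common
    if (rep %% 2L == 0L) {
      site <- paste0(orc_revcomp(substr(mir, 2, 8)), "A")
      at <- sample.int(nchar(tx) - 8L, 1L)
      substr(tx, at, at + 7L) <- site
    }
    got <- scan_seed_sites(mir, tx)
    exp <- oracle_ts_sites(mir, tx)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      n_hit <- n_hit + nrow(exp)
      got <- got[order(got$t_start, got$t_end), ]
      expect_equal(got$t_start, exp$t_start)
      expect_equal(got$t_end, exp$t_end)
      expect_equal(got$seed_category, exp$category)
    }
  }
  expect_gt(n_hit, 100L)   # the draw actually exercises hits
})

test_that("offset-6mer reporting is off by default and sound when enabled", {
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  # target matching miRNA 3..8 only: revcomp(m3..m8) = "AUAAGC", block 2-7 core
  tx <- "GGGAUAAGCGGG"
  expect_equal(nrow(scan_seed_sites(mir, tx)), 0L)
  s <- scan_seed_sites(mir, tx, offset6 = TRUE)
  expect_equal(s$seed_category, "offset-6mer")
  expect_equal(c(s$t_start, s$t_end), c(4L, 9L))
})

test_that("reported sites are in range, unique, and stably classified", {
  set.seed(99)
  n_sites <- 0L
  for (rep in 1:40) {
    mir <- rand_rna(20L)
    tx <- rand_rna(60L)
    if (rep %% 2L == 0L) {   # plant a seed match so sites actually occur
      at <- sample.int(50L, 1L)
      substr(tx, at, at + 6L) <- orc_revcomp(substr(mir, 2, 8))
    }
    s <- scan_seed_sites(mir, tx, offset6 = TRUE)
    if (!nrow(s)) next
    n_sites <- n_sites + nrow(s)
    expect_true(all(s$t_start >= 1L & s$t_end <= nchar(tx) & s$t_start < s$t_end))
    expect_false(any(duplicated(s[, c("engine", "mirna", "circ", "t_start", "t_end")])))
  }
  expect_gte(n_sites, 20L)
})
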