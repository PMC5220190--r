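test_that("pfm construction and validation", {
  expect_error(pfm(matrix(1, 3, 4)), "4 rows")
  expect_error(pfm(matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 4)), "column sums")
  p <- pfm(c("ACGT", "ACGT", "ACGA"))
  expect_equal(unname(p["A", ]), c(3, 0, 0, 1))
  expect_equal(unique(colSums(p)), 3)
  t8 <- teil_pfm()
  expect_equal(dim(t8), c(4L, 8L))
  expect_equal(unique(colSums(t8)), 20)
  expect_equal(unname(t8[, 2]), c(0, 10, 0, 10))  # Y = C/T
  expect_equal(unname(t8[, 4]), c(10, 0, 0, 10))  # W = A/T
  # file fixture parses to the same matrix
  path <- system.file("extdata", "teil_pfm_synthetic.txt", package = "bindscape")
  expect_equal(unclass(read_pfm(path)), unclass(t8))
})

test_that("pwm_from_pfm: degenerate matrices are rejected; consensus is optimal", {
  uni <- pfm(matrix(5, 4, 6))
  expect_error(pwm_from_pfm(uni), "degenerate")
  pwm <- pwm_from_pfm(pfm(c("ACGTACGT")))
  expect_equal(score_normalized(pwm, "ACGTACGT"), 1)
  # any single mismatch strictly lowers the score
  for (j in 1:8) {
    s <- strsplit("ACGTACGT", "")[[1]]
    for (b in setdiff(c("A", "C", "G", "T"), s[j])) {
      s2 <- s; s2[j] <- b
      expect_lt(score_normalized(pwm, paste(s2, collapse = "")), 1)
    }
  }
})

test_that("normalised scores: consensus 1, anti-consensus 0, N excluded", {
  pwm <- pwm_from_pfm(teil_pfm())
  w <- pwm$weights
  best <- paste(c("A", "C", "G", "T")[apply(w, 2, which.max)], collapse = "")
  worst <- paste(c("A", "C", "G", "T")[apply(w, 2, which.min)], collapse = "")
  expect_equal(score_normalized(pwm, best), 1)
  expect_equal(score_normalized(pwm, worst), 0)
  expect_true(is.na(score_normalized(pwm, "ACGNACGT")))
  expect_error(score_normalized(pwm, "ACGT"), "length")
  # every consensus realisation of AYGWAYCT scores >= 0.91
  for (y1 in c("C", "T")) for (w1 in c("A", "T")) for (y2 in c("C", "T")) {
    oct <- paste0("A", y1, "G", w1, "A", y2, "CT")
    expect_gte(score_normalized(pwm, oct), 0.91)
  }
})

test_that("scan_pwm counts hits exactly like the naive oracle", {
  set.seed(19)
  pwm <- pwm_from_pfm(teil_pfm())
  # planted single consensus in random background, threshold 1.0
  bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  best <- paste(c("A", "C", "G", "T")[apply(pwm$weights, 2, which.max)],
                collapse = "")
  seq1 <- paste0(substr(bg, 1, 150), best, substr(bg, 151, 300))
  res <- scan_pwm(pwm, seq1, threshold = 1.0, both_strands = FALSE)
  expect_gte(res$hits, 1)
  expect_equal(res$hits, oracle_scan_hits(pwm, seq1, 1.0, both_strands = FALSE))

  # random PWMs and sequences (with Ns): exact agreement with the oracle
  for (rep in 1:4) {
    m <- matrix(sample(1:9, 4 * 6, replace = TRUE), 4)
    m <- sweep(m, 2, colSums(m), "/") * 12  # equalise column sums
    pw <- pwm_from_pfm(pfm(m))
    seqs <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T", "N"), 400, replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""), "")
    for (th in c(0.5, 0.8, 0.95)) {
      got <- scan_pwm(pw, seqs, threshold = th, both_strands = TRUE)
      expect_equal(got$hits, oracle_scan_hits(pw, seqs, th, both_strands = TRUE))
    }
  }
})

test_that("scan invariants: reverse-complement symmetry, threshold monotonicity", {
  set.seed(29)
  pwm <- pwm_from_pfm(teil_pfm())
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  rc <- oracle_revcomp(s)
  h1 <- scan_pwm(pwm, s, threshold = 0.85)$hits
  h2 <- scan_pwm(pwm, rc, threshold = 0.85)$hits
  expect_equal(h1, h2)
  hits <- vapply(c(0.5, 0.7, 0.85, 0.91, 1),
                 function(th) scan_pwm(pwm, s, threshold = th)$hits, 1L)
  expect_true(all(diff(hits) <= 0))
  # sequence shorter than the motif contributes no positions
  expect_equal(scan_pwm(pwm, "ACGT")$positions, 0)
  expect_true(is.na(scan_pwm(pwm, "ACGT")$density))
})

test_that("density_compare: identity, the 10/0 table, and Bonferroni flags", {
  mk <- function(hits, pos) structure(list(positions = pos, hits = hits,
                                           density = hits / pos),
                                      class = "scan_result")
  same <- density_compare(list(a = mk(30, 300)), list(a = mk(30, 300)),
                          n_tests = 8)
  expect_gt(same$p, 0.99)
  expect_false(same$significant)
  tab <- density_compare(list(x = mk(10, 10)), list(x = mk(0, 10)), n_tests = 8)
  expect_equal(tab$p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_true(tab$significant)
  zero <- density_compare(list(x = mk(0, 0)), list(x = mk(5, 10)), n_tests = 8)
  expect_true(is.na(zero$p))
  expect_match(zero$note, "no scorable")
})

test_that("density_threshold_curve reports foreground/background enrichment", {
  set.seed(37)
  pwm <- pwm_from_pfm(teil_pfm())
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  planted <- plant_motifs(Biostrings::DNAStringSet(c(fg = bg)), rates = 3,
                          seed = 37)
  curve <- density_threshold_curve(pwm, planted$sequences, bg,
                                   thresholds = c(0.85, 0.91))
  expect_equal(nrow(curve), 2)
  expect_true(all(curve$density_fg >= curve$density_bg))
})
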