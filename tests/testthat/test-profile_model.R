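test_that("occurrence_profile: degenerate cases and the per-base oracle", {
  tx <- fix_tx("chr1", c("+", "-"), tss = c(5000, 9000), aug = c(5100, 8900),
               tes = c(7000, 7500))
  # track covering every TSS exactly -> value 1 at offset 0
  tss_track <- track("chr1", c(5000, 9000), c(5000, 9000))
  prof <- occurrence_profile(tss_track, tx, window = c(-10, 10))
  expect_equal(prof$values[prof$offsets == 0], 1)
  expect_equal(prof$values[prof$offsets == 5], 0)
  expect_equal(length(prof$values), 21)
  # empty track -> all-zero profile
  empty <- track(character(0), numeric(0), numeric(0))
  expect_true(all(occurrence_profile(empty, tx, c(-50, 50))$values == 0))
  expect_error(occurrence_profile(tss_track, tx[0, ], c(-10, 10)), "non-empty")

  # 50-gene fixture with random peaks: equality with the boolean-array oracle
  set.seed(17)
  g <- make_genome(n_genes = 50, n_chromosomes = 1, seed = 17, sequences = FALSE)
  tr <- random_track(120, g$chrom_lengths)
  win <- c(-800, 100)
  prof2 <- occurrence_profile(tr, g$transcripts, window = win)
  len <- unname(g$chrom_lengths[1])
  covered <- oracle_cover(tr, "chr1", len)
  offs <- seq(win[1], win[2])
  want <- sapply(offs, function(o) {
    hit <- mapply(function(tss, st) {
      p <- if (st == "-") tss - o else tss + o
      p >= 1 && p <= len && covered[p]
    }, g$transcripts$tss, g$transcripts$strand)
    mean(hit)
  })
  expect_equal(prof2$values, unname(want))
})

test_that("eval_bimodal closed forms", {
  p0 <- bimodal_params(0.2, 0, 1, 100, 0, -500, 200)
  expect_equal(eval_bimodal(c(-1000, 0, 50), p0), rep(0.2, 3))
  p1 <- bimodal_params(0.1, 1, 0, 1, 0, -500, 200)
  expect_equal(eval_bimodal(0, p1), 0.1 + 1 / sqrt(2 * pi), tolerance = 1e-6)
  expect_equal(eval_bimodal(1, p1) - 0.1, 0.24197, tolerance = 1e-4)
  # sigma scaling: contribution at m +/- sigma is A * 0.24197 / sigma
  p2 <- bimodal_params(0, 3, -100, 50, 0, -500, 200)
  expect_equal(eval_bimodal(-150, p2), 3 * 0.24197 / 50, tolerance = 1e-4)
  # model >= C everywhere and -> C far away
  expect_true(all(eval_bimodal(seq(-5000, 5000, 10), p2) >= 0))
  expect_lt(eval_bimodal(-5000, p2), 1e-10)
})

test_that("fit_bimodal recovers known parameters from a noise-free profile", {
  truth <- bimodal_params(0.02, 40, -150, 100, 25, -900, 400)
  offs <- seq(-1500, 100)
  prof <- structure(list(offsets = offs, values = eval_bimodal(offs, truth),
                         n_genes = 2000, window = c(-1500, 100)),
                    class = "occurrence_profile")
  fit <- fit_bimodal(prof)
  for (f in c("C", "A_prox", "m_prox", "sigma_prox", "A_dist", "m_dist",
              "sigma_dist")) {
    expect_equal(fit[[f]], truth[[f]], tolerance = 1e-3)
  }
  expect_lt(attr(fit, "rss"), 1e-8)
})

test_that("fit_bimodal: translation invariance and unimodal shrinkage", {
  truth <- bimodal_params(0.03, 30, -200, 120, 18, -800, 300)
  offs <- seq(-1500, 100)
  prof <- structure(list(offsets = offs, values = eval_bimodal(offs, truth),
                         n_genes = 1000, window = c(-1500, 100)),
                    class = "occurrence_profile")
  delta <- -300
  prof_shift <- structure(list(offsets = offs + delta,
                               values = prof$values, n_genes = 1000,
                               window = c(-1500, 100) + delta),
                          class = "occurrence_profile")
  f1 <- fit_bimodal(prof)
  f2 <- fit_bimodal(prof_shift)
  expect_equal(f2$m_prox - f1$m_prox, delta, tolerance = 2)
  expect_equal(f2$m_dist - f1$m_dist, delta, tolerance = 5)

  uni <- bimodal_params(0.02, 40, -150, 100, 0, -900, 400)
  prof_uni <- structure(list(offsets = offs, values = eval_bimodal(offs, uni),
                             n_genes = 1000, window = c(-1500, 100)),
                        class = "occurrence_profile")
  fu <- fit_bimodal(prof_uni)
  expect_lt(fu$A_dist, 0.05 * fu$A_prox)
  expect_error(fit_bimodal(structure(list(offsets = 1:5, values = rep(1, 5)),
                                     class = "occurrence_profile")),
               "degenerate")
})

test_that("stratified profiles sum position-wise to the total profile", {
  g <- make_genome(n_genes = 150, n_chromosomes = 1, seed = 23, sequences = FALSE)
  sm <- make_state_map(g, seed = 23)
  pk <- make_peaks(g, n_peaks = 400, seed = 23)
  ebrs <- peak_filter(pk, 7)
  tx5 <- g$transcripts[g$transcripts$has_5utr, ]
  win <- c(-1200, 100)
  total <- occurrence_profile(ebrs, tx5, window = win)
  strat <- stratified_profile(ebrs, sm, tx5, window = win)
  expect_named(strat, c("1", "2", "4", "rest"))
  sum_prof <- Reduce(`+`, lapply(strat, `[[`, "values"))
  expect_equal(sum_prof, total$values, tolerance = 1e-12)

  # track entirely inside state-2 domains: state-2 stratum = total, others 0
  dom2 <- sm$domains[["2"]]
  inside <- GenomicRanges::resize(dom2[BiocGenerics::width(dom2) >= 60][1:20],
                                  width = 40, fix = "center")
  strat2 <- stratified_profile(inside, sm, tx5, window = win)
  tot2 <- occurrence_profile(inside, tx5, window = win)
  expect_equal(strat2[["2"]]$values, tot2$values)
  expect_true(all(strat2[["1"]]$values == 0))
  expect_true(all(strat2[["4"]]$values == 0))
  expect_true(all(strat2[["rest"]]$values == 0))
})
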