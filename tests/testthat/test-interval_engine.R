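test_that("classify_locations follows the class definitions and precedence", {
  tx <- fix_tx("chr1", "+", tss = 100, aug = 130, tes = 400)
  cls <- classify_locations(track("chr1", c(95, 200, 900), c(105, 250, 950)), tx)
  expect_equal(as.character(cls$class), c("TSS", "GENE", "INTERGENIC"))
  expect_equal(sum(cls$counts), cls$n)
  expect_equal(sum(cls$fractions), 1, tolerance = 1e-12)
  # unknown chromosome -> INTERGENIC with a warning
  expect_warning(cls2 <- classify_locations(track("chrX", 5, 10), tx), "absent")
  expect_equal(as.character(cls2$class), "INTERGENIC")
  expect_error(classify_locations(track("chr1", 1, 5), tx[0, ]), "non-empty")
})

test_that("classify_locations agrees with the naive oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:5) {
    n_tx <- 30
    tss <- sort(sample(3000:97000, n_tx))
    strand <- sample(c("+", "-"), n_tx, replace = TRUE)
    glen <- sample(300:2000, n_tx, replace = TRUE)
    tx <- fix_tx("chr1", strand, tss = tss,
                 aug = ifelse(strand == "+", tss + 100, tss - 100),
                 tes = ifelse(strand == "+", tss + glen, tss - glen))
    tr <- random_track(60, c(chr1 = 1e5))
    got <- classify_locations(tr, tx)
    expect_equal(as.character(got$class), oracle_classify(tr, tx))
    expect_equal(sum(got$counts), 60L)
  }
})

test_that("track_intersect matches the per-base boolean oracle", {
  a <- track("chr1", 1, 100)
  b <- track("chr1", 51, 150)
  got <- track_intersect(a, b)
  expect_equal(BiocGenerics::start(got), 51)
  expect_equal(BiocGenerics::end(got), 100)
  expect_equal(length(track_intersect(track("chr1", 1, 10), track("chr1", 50, 60))), 0)

  set.seed(7)
  g <- make_genome(n_genes = 80, n_chromosomes = 1, seed = 7, sequences = FALSE)
  sm <- make_state_map(g, seed = 7)
  len <- unname(g$chrom_lengths[1])
  tr <- random_track(200, g$chrom_lengths)
  all_states <- do.call(c, lapply(unname(sm$domains), GenomicRanges::granges))
  for (s in c("1", "2", "4")) {
    got <- track_intersect(tr, sm$domains[[s]])
    want <- oracle_cover(tr, "chr1", len) & oracle_cover(sm$domains[[s]], "chr1", len)
    expect_equal(track_length(got), sum(want))
  }
  # intersect(a, a) = a after normalisation; commutative total length
  red <- GenomicRanges::reduce(tr, ignore.strand = TRUE)
  expect_equal(track_intersect(tr, tr), red)
  expect_equal(track_length(track_intersect(tr, all_states)),
               track_length(track_intersect(all_states, tr)))
})

test_that("overlap_fraction definition, bounds, and error on empty query", {
  expect_equal(overlap_fraction(track("chr1", 1, 100), track("chr1", 51, 150)), 0.5)
  expect_equal(overlap_fraction(track("chr1", 60, 80), track("chr1", 1, 1000)), 1)
  expect_equal(overlap_fraction(track("chr1", 1, 10), track("chr1", 500, 600)), 0)
  expect_error(overlap_fraction(track(character(0), numeric(0), numeric(0)),
                                track("chr1", 1, 10)), "empty")
  # genome-covering reference -> 1 for any query
  set.seed(5)
  q <- random_track(40, c(chr1 = 5e4))
  expect_equal(overlap_fraction(q, track("chr1", 1, 5e4)), 1)
})

test_that("upstream datasets: isolated gene keeps one region per dataset", {
  tx <- fix_tx("chr1", "+", tss = 50000, aug = 50200, tes = 53000)
  ups <- build_upstream_datasets(tx, chrom_lengths = c(chr1 = 1e5))
  expect_equal(unname(ups$counts), rep(1L, 8))
  # geometry of the first and last bins
  expect_equal(BiocGenerics::start(ups$tracks[[1]]), 50000 - 3500)
  expect_equal(BiocGenerics::end(ups$tracks[[1]]), 50000 - 3001)
  expect_equal(BiocGenerics::start(ups$tracks[[7]]), 50000 - 500)
  expect_equal(BiocGenerics::end(ups$tracks[[7]]), 50000 - 1)
  expect_equal(BiocGenerics::start(ups$tracks[[8]]), 50000)
  expect_equal(BiocGenerics::end(ups$tracks[[8]]), 50199)
  # minus-strand mirror
  txm <- fix_tx("chr1", "-", tss = 50000, aug = 49800, tes = 47000)
  upm <- build_upstream_datasets(txm, chrom_lengths = c(chr1 = 1e5))
  expect_equal(unname(upm$counts), rep(1L, 8))
  expect_equal(BiocGenerics::start(upm$tracks[[1]]), 50000 + 3001)
  expect_equal(BiocGenerics::end(upm$tracks[[1]]), 50000 + 3500)
  expect_equal(BiocGenerics::start(upm$tracks[[8]]), 49801)
  expect_equal(BiocGenerics::end(upm$tracks[[8]]), 50000)
})

test_that("upstream datasets on the two-gene 600-bp-gap fixture match the hand enumeration", {
  # gene A [8000, 9999] and gene B [10600, 12599], both +, 600-bp gap.
  # Hand-worked: B's bins 2-6 overlap gene A's span or A's gene region; B's
  # bin 1 [7100, 7599] falls inside A's nested [-3000; +1] window; A survives
  # everywhere. Datasets 7 and 8 keep both genes.
  ups <- build_upstream_datasets(fix_two_genes(), chrom_lengths = c(chr1 = 2e4))
  expect_equal(unname(ups$counts), c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(BiocGenerics::start(ups$tracks[[7]]), c(7500, 10100))
  # invariant: datasets 1-7 never overlap any transcript span
  spans <- track("chr1", c(8000, 10600), c(9999, 12599))
  for (k in 1:7) {
    if (length(ups$tracks[[k]]) == 0) next
    expect_equal(track_length(track_intersect(ups$tracks[[k]], spans)), 0)
  }
})

test_that("upstream invariants hold on a synthetic genome", {
  g <- make_genome(n_genes = 150, n_chromosomes = 2, seed = 9, sequences = FALSE)
  tx <- g$transcripts
  ups <- build_upstream_datasets(tx, chrom_lengths = g$chrom_lengths)
  spans <- track(tx$chrom, pmin(tx$tss, tx$tes), pmax(tx$tss, tx$tes))
  for (k in 1:7) {
    if (length(ups$tracks[[k]]) == 0) next
    expect_equal(track_length(track_intersect(ups$tracks[[k]], spans)), 0)
  }
  # dataset k <= 6 avoids every [-(3500 - 500k); +1] window
  minus <- tx$strand == "-"
  for (k in 1:6) {
    up <- 3500 - 500 * k
    ws <- ifelse(minus, tx$tss + 1, tx$tss - up)
    we <- ifelse(minus, tx$tss + up, tx$tss - 1)
    win <- track(tx$chrom, pmax(1, ws), we)
    if (length(ups$tracks[[k]]) == 0) next
    expect_equal(track_length(track_intersect(ups$tracks[[k]], win)), 0)
  }
})

test_that("a transcript with tss == aug contributes nothing to dataset 8", {
  tx <- fix_tx("chr1", "+", tss = c(50000, 80000), aug = c(50000, 80200),
               tes = c(52000, 82000))
  ups <- build_upstream_datasets(tx, chrom_lengths = c(chr1 = 1e5))
  expect_equal(ups$counts[[8]], 1L)
  expect_equal(BiocGenerics::start(ups$tracks[[8]]), 80000)
})

test_that("link_genes respects exact window edges and matches the oracle", {
  tx <- fix_tx("chr1", "+", tss = 10000, aug = 10100, tes = 12000)
  # window [-3500; +1] spans genomic [6500, 10000]
  expect_equal(names(link_genes(track("chr1", 6500, 6500), tx)), "g01")
  expect_equal(length(link_genes(track("chr1", 6499, 6499), tx)), 0)
  expect_equal(names(link_genes(track("chr1", 10000, 10005), tx)), "g01")
  # minus strand: window spans [tss, tss + 3500]
  txm <- fix_tx("chr1", "-", tss = 10000, aug = 9900, tes = 8000)
  expect_equal(names(link_genes(track("chr1", 13500, 13600), txm)), "g01")
  expect_equal(length(link_genes(track("chr1", 13501, 13600), txm)), 0)

  set.seed(21)
  g <- make_genome(n_genes = 60, n_chromosomes = 1, seed = 21, sequences = FALSE)
  tr <- random_track(80, g$chrom_lengths)
  links <- link_genes(tr, g$transcripts)
  len <- unname(g$chrom_lengths[1])
  covered <- oracle_cover(tr, "chr1", len)
  for (i in seq_len(nrow(g$transcripts))) {
    t <- g$transcripts[i, ]
    w <- if (t$strand == "+") c(t$tss - 3500, t$tss) else c(t$tss, t$tss + 3500)
    w <- pmax(1, pmin(w, len))
    linked_oracle <- any(covered[w[1]:w[2]])
    expect_equal(t$gene_id %in% names(links), linked_oracle)
  }
})
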