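test_that("GFF3 transcripts round-trip and follow the coordinate conventions", {
  # three transcripts: two protein-coding with 5'UTR, one without
  tx <- fix_tx("chr1", c("+", "-", "+"),
               tss = c(1000, 5000, 8000), aug = c(1150, 4800, 8000),
               tes = c(2999, 3500, 9500))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tx, path, chrom_lengths = c(chr1 = 20000))
  got <- read_gff_transcripts(path)
  expect_equal(nrow(got), 3)
  expect_equal(sum(got$has_5utr), 2)
  got <- got[match(tx$transcript_id, got$transcript_id), ]
  expect_equal(got$tss, tx$tss)
  expect_equal(got$aug, tx$aug)
  expect_equal(got$tes, tx$tes)
  expect_equal(got$strand, tx$strand)
  # minus-strand gene spanning 1000-2000: TSS is the upstream-most base 2000
  tx2 <- fix_tx("chr1", "-", tss = 2000, aug = 1900, tes = 1000)
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tx2, p2)
  expect_equal(read_gff_transcripts(p2)$tss, 2000)
})

test_that("GFF errors: malformed lines are located, CDS-less transcripts skipped", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t1\t100"), path)
  expect_error(read_gff_transcripts(path), "line 3")

  tx <- fix_tx("chr1", "+", tss = c(100, 700), aug = c(150, 750),
               tes = c(500, 999))
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tx, p2)
  lines <- readLines(p2)
  writeLines(lines[!grepl("g02.1.cds", lines)], p2)
  expect_warning(got <- read_gff_transcripts(p2), "without CDS")
  expect_equal(got$transcript_id, "g01.1")
})

test_that("read_peaks handles BED-like tables, headers, and bad rows", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tp1\t1", "chr1\t200\t300\tp2\t6",
               "chr1\t400\t500\tp3\t7", "chr2\t10\t90\tp4\t8",
               "chr2\t100\t250\tp5\t20"), path)
  pk <- read_peaks(path)
  expect_equal(nrow(pk), 5)
  expect_equal(pk$height, c(1, 6, 7, 8, 20))
  expect_equal(pk$start[1], 1)  # BED 0-based -> internal 1-based

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_peaks(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tp\t5", "chr1\t300\t300\tq\t5"), bad)
  expect_error(read_peaks(bad), "row 2")

  nocol <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", nocol)
  expect_error(read_peaks(nocol), "height column")

  # MACS-style 1-based table with tag column 6 and a header line
  macs <- withr::local_tempfile(fileext = ".xls")
  writeLines(c("chr\tstart\tend\tlength\tsummit\ttags",
               "chr1\t11\t110\t100\t50\t12"), macs)
  pk2 <- read_peaks(macs, format = "macs")
  expect_equal(pk2$start, 11)
  expect_equal(pk2$height, 12)
})

test_that("peak_filter matches brute-force enumeration and is monotone", {
  pk <- data.frame(chrom = "chr1", start = seq(1, 401, 100),
                   end = seq(50, 450, 100), height = c(1, 6, 7, 8, 20))
  expect_equal(length(peak_filter(pk, 7)), 3)
  expect_equal(length(peak_filter(pk, 0)), 5)

  set.seed(42)
  pk2 <- data.frame(chrom = "chr1", start = 1:100 * 10, end = 1:100 * 10 + 5,
                    height = sample(1:10, 100, replace = TRUE))
  expect_equal(length(peak_filter(pk2, 7)), sum(pk2$height >= 7))
  sizes <- vapply(0:11, function(h) length(peak_filter(pk2, h)), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("state maps validate labels and disjointness and round-trip", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\t%d", 0:8 * 1000, 0:8 * 1000 + 500, 1:9),
             path)
  sm <- read_state_map(path)
  expect_s3_class(sm, "state_map")
  expect_equal(sum(vapply(sm$domains, length, 1L)), 9)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t500\t2", "chr1\t300\t800\t4"), bad)
  expect_error(read_state_map(bad), "overlap")

  bad2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t500\t12", bad2)
  expect_error(read_state_map(bad2), "1..9")

  # synthetic map round-trips through write + read with identical domains
  g <- make_genome(n_genes = 60, n_chromosomes = 1, seed = 3, sequences = FALSE)
  sm2 <- make_state_map(g, seed = 3)
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_state_map(sm2, p2)
  sm3 <- read_state_map(p2)
  for (s in as.character(1:9)) {
    expect_equal(track_length(sm3$domains[[s]]), track_length(sm2$domains[[s]]))
    expect_equal(length(sm3$domains[[s]]), length(sm2$domains[[s]]))
  }
})

test_that("track construction enforces invariants; BED round-trip is identity", {
  expect_error(track("chr1", 0, 10), ">= 1")
  expect_error(track("chr1", 10, 5), "end < start")
  expect_error(track("", 1, 10), "non-empty")
  tr <- track("chr1", c(500, 1), c(700, 100))
  expect_equal(BiocGenerics::start(tr), c(1, 500))  # sorted
  expect_equal(track_length(tr), 100 + 201)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(tr, path)
  back <- read_bed(path)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(tr))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(tr))
  expect_equal(track_length(back), track_length(tr))
})

test_that("distinct_tss deduplicates by (chrom, strand, tss)", {
  tx <- rbind(fix_tx("chr1", "+", tss = c(100, 100, 900), aug = c(150, 180, 950),
                     tes = c(500, 600, 1200)))
  expect_equal(nrow(distinct_tss(tx)), 2)
})
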