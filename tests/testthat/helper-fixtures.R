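# Fixtures built in code and naive oracles kept independent of the package's
# fast paths: per-base boolean genome arrays and O(n*L) PWM scoring.

fix_tx <- function(chrom, strand, tss, aug, tes, gene_id = NULL) {
  n <- length(tss)
  if (is.null(gene_id)) gene_id <- sprintf("g%02d", seq_len(n))
  data.frame(transcript_id = paste0(gene_id, ".1"), gene_id = gene_id,
             chrom = rep_len(chrom, n), strand = rep_len(strand, n),
             tss = tss, aug = aug, tes = tes,
             has_5utr = tss != aug, is_protein_coding = TRUE,
             stringsAsFactors = FALSE)
}

# the two-gene head-to-tail fixture with a 600-bp gap used for the frozen
# upstream-dataset enumeration: gene A [8000, 9999] (+, AUG 8150), gene B
# [10600, 12599] (+, AUG 10700), chr1 of 20 kb
fix_two_genes <- function() {
  fix_tx("chr1", "+", tss = c(8000, 10600), aug = c(8150, 10700),
         tes = c(9999, 12599), gene_id = c("gA", "gB"))
}

# per-base logical cover of a track on one chromosome of length len
oracle_cover <- function(gr, chrom, len) {
  v <- logical(len)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   s = BiocGenerics::start(gr), e = BiocGenerics::end(gr))
  df <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    v[max(1, df$s[i]):min(len, df$e[i])] <- TRUE
  }
  v
}

# naive location classification straight from the definitions
oracle_classify <- function(gr, tx) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   s = BiocGenerics::start(gr), e = BiocGenerics::end(gr))
  vapply(seq_len(nrow(df)), function(i) {
    same <- tx$chrom == df$chrom[i]
    if (any(same & tx$tss >= df$s[i] & tx$tss <= df$e[i])) return("TSS")
    gs <- pmin(tx$tss, tx$tes); ge <- pmax(tx$tss, tx$tes)
    if (any(same & gs <= df$e[i] & ge >= df$s[i])) return("GENE")
    "INTERGENIC"
  }, "")
}

# naive PWM scoring of every window of one sequence; returns normalised
# forward-strand scores (NA for ambiguous windows)
oracle_window_scores <- function(pwm, seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  L <- pwm$L
  n <- length(b) - L + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) {
    idx <- match(b[i:(i + L - 1)], c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    raw <- sum(vapply(seq_len(L), function(j) pwm$weights[idx[j], j], 1))
    (raw - pwm$s_min) / (pwm$s_max - pwm$s_min)
  }, 1)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(s)), "")[[1]]), collapse = "")
}

# naive hit count over a sequence set
oracle_scan_hits <- function(pwm, seqs, threshold, both_strands = TRUE) {
  tot <- 0
  for (s in seqs) {
    fwd <- oracle_window_scores(pwm, s)
    if (length(fwd) == 0) next
    if (both_strands) {
      n <- length(fwd); L <- pwm$L
      rc <- oracle_window_scores(pwm, oracle_revcomp(s))
      rev_at <- rc[n - seq_len(n) + 1]  # window i reverse-oriented score
      hit <- !is.na(fwd) & (fwd >= threshold | rev_at >= threshold)
    } else {
      hit <- !is.na(fwd) & fwd >= threshold
    }
    tot <- tot + sum(hit)
  }
  tot
}

# exact two-sided Fisher p by enumeration over the hypergeometric support,
# using choose() directly (independent of dhyper)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  supp <- max(0, n1 - m2):min(n1, m1)
  tot <- choose(m1 + m2, n1)
  probs <- choose(m1, supp) * choose(m2, n1 - supp) / tot
  p_obs <- choose(m1, a) * choose(m2, n1 - a) / tot
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_track <- function(n, chrom_lengths, min_w = 50, max_w = 500) {
  chrom <- sample(names(chrom_lengths), n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- floor(runif(n, 1, unname(chrom_lengths[chrom]) - w + 1))
  track(chrom, s, s + w - 1)
}
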