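# Seeded generators for every input the pipeline ingests: genome + annotation,
# nine-state chromatin map, peaks with bimodal TSS-relative placement, motif
# planting, and GO annotation tables.  Each generator is a pure function of
# its seed and parameters, and records its ground truth alongside the data.

#' Generate a synthetic genome with transcript annotation
#'
#' Lays genes head-to-tail per chromosome with lognormal gene lengths and
#' intergenic gaps, random strands, and 5'UTRs present with probability
#' `utr_prob` (a transcript has a 5'UTR iff its TSS differs from its
#' translation start).  Base composition is i.i.d. with the configured GC
#' content.  The defaults emulate a compact plant genome: ~2 kb genes, ~3 kb
#' spacers, ~1 gene per 5 kb.
#'
#' @param n_genes number of genes (one transcript each), default 2000.
#' @param n_chromosomes default 2.
#' @param seed RNG seed (the generator is a pure function of seed + spec).
#' @param mean_gene_length,mean_intergenic,mean_utr lognormal means in bp
#'   (defaults 2000 / 3000 / 150).
#' @param utr_prob probability a transcript carries a 5'UTR (default 0.8).
#' @param gc GC content of the random sequence (default 0.36).
#' @param sequences generate nucleotide sequences (default `TRUE`; set
#'   `FALSE` for annotation-only work).
#' @return `synthetic_genome` object: `$transcripts` (as from
#'   [read_gff_transcripts()]), `$chrom_lengths`, `$sequences`
#'   (`DNAStringSet` or `NULL`), `$truth` (parameters + seed).
#' @export
make_genome <- function(n_genes = 2000, n_chromosomes = 2, seed = 1,
                        mean_gene_length = 2000, mean_intergenic = 3000,
                        mean_utr = 150, utr_prob = 0.8, gc = 0.36,
                        sequences = TRUE) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1, utr_prob >= 0, utr_prob <= 1)
  set.seed(seed)
  per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chromosomes + 1)))
  glen <- pmax(500, round(rlnorm(n_genes, log(mean_gene_length), 0.4)))
  gap <- pmax(300, round(rlnorm(n_genes, log(mean_intergenic), 0.5)))
  has_utr <- runif(n_genes) < utr_prob
  ulen <- ifelse(has_utr,
                 pmax(20, pmin(round(rlnorm(n_genes, log(mean_utr), 0.5)),
                               glen - 100)),
                 0)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  rows <- vector("list", n_genes)
  chrom_lengths <- numeric(n_chromosomes)
  names(chrom_lengths) <- paste0("chr", seq_len(n_chromosomes))
  g <- 0
  for (ci in seq_len(n_chromosomes)) {
    pos <- 4000  # lead-in so the first gene has room for upstream windows
    for (k in seq_len(per_chrom[ci])) {
      g <- g + 1
      s <- pos + gap[g]
      e <- s + glen[g] - 1
      gid <- sprintf("GENE%05d", g)
      if (strand[g] == "+") {
        tss <- s; tes <- e; aug <- s + ulen[g]
      } else {
        tss <- e; tes <- s; aug <- e - ulen[g]
      }
      rows[[g]] <- data.frame(
        transcript_id = paste0(gid, ".1"), gene_id = gid,
        chrom = names(chrom_lengths)[ci], strand = strand[g],
        tss = tss, aug = aug, tes = tes, has_5utr = has_utr[g],
        is_protein_coding = TRUE, stringsAsFactors = FALSE)
      pos <- e
    }
    chrom_lengths[ci] <- pos + 4000
  }
  tx <- do.call(rbind, rows)
  seqs <- NULL
  if (sequences) {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
            collapse = "")
    }, ""))
    names(seqs) <- names(chrom_lengths)
  }
  structure(list(transcripts = tx, chrom_lengths = chrom_lengths,
                 sequences = seqs,
                 truth = list(seed = seed, n_genes = n_genes,
                              n_chromosomes = n_chromosomes,
                              mean_gene_length = mean_gene_length,
                              mean_intergenic = mean_intergenic,
                              mean_utr = mean_utr, utr_prob = utr_prob,
                              gc = gc)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d transcripts on %d chromosome(s), %.2f Mb%s\n",
              nrow(x$transcripts), length(x$chrom_lengths),
              sum(x$chrom_lengths) / 1e6,
              if (is.null(x$sequences)) " (no sequence)" else ""))
  invisible(x)
}

#' Write a synthetic genome as FASTA + GFF3 + truth sidecar
#'
#' @param genome `synthetic_genome`.
#' @param dir output directory (created if needed).  Writes `genome.fa`
#'   (if sequences exist), `annotation.gff3`, `truth.json`.
#' @return the directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(genome$sequences)) {
    Biostrings::writeXStringSet(genome$sequences, file.path(dir, "genome.fa"))
  }
  write_gff3(genome$transcripts, file.path(dir, "annotation.gff3"),
             chrom_lengths = genome$chrom_lengths)
  jsonlite::write_json(genome$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write transcript models as GFF3
#'
#' Emits `gene`, `mRNA`, `five_prime_UTR` and `CDS` features (1-based closed,
#' per the GFF3 standard) so the annotation round-trips through
#' [read_gff_transcripts()].
#'
#' @param transcripts transcript data frame.
#' @param path output file.
#' @param chrom_lengths optional, written as `##sequence-region` pragmas.
#' @export
write_gff3 <- function(transcripts, path, chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("##sequence-region %s 1 %d", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  }
  fmt <- function(chrom, src, type, s, e, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, src, type, as.integer(s), as.integer(e), strand,
            ifelse(type == "CDS", "0", "."), attrs)
  }
  out <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    s <- min(t$tss, t$tes); e <- max(t$tss, t$tes)
    out <- c(out,
             fmt(t$chrom, "bindscape", "gene", s, e, t$strand,
                 paste0("ID=", t$gene_id)),
             fmt(t$chrom, "bindscape", "mRNA", s, e, t$strand,
                 paste0("ID=", t$transcript_id, ";Parent=", t$gene_id)))
    if (t$has_5utr && t$tss != t$aug) {
      us <- if (t$strand == "+") t$tss else t$aug + 1
      ue <- if (t$strand == "+") t$aug - 1 else t$tss
      out <- c(out, fmt(t$chrom, "bindscape", "five_prime_UTR", us, ue,
                        t$strand,
                        paste0("ID=", t$transcript_id, ".utr5;Parent=",
                               t$transcript_id)))
    }
    cs <- min(t$aug, t$tes); ce <- max(t$aug, t$tes)
    out <- c(out, fmt(t$chrom, "bindscape", "CDS", cs, ce, t$strand,
                      paste0("ID=", t$transcript_id, ".cds;Parent=",
                             t$transcript_id)))
  }
  writeLines(out, con)
  invisible(path)
}

#' Generate a nine-state chromatin map for a synthetic genome
#'
#' Emulates the canonical layout of plant chromatin states: state 1 in a
#' narrow band around the TSS, state 2 over the proximal promoter, state 3
#' over gene bodies, state 4 in distal upstream intergenic bands (for a
#' random subset of genes), and the remaining genome partitioned into chunks
#' labelled with states 5-9.  The nine state tracks partition the genome
#' (every base gets exactly one state).
#'
#' @param genome `synthetic_genome`.
#' @param core_halfwidth half-width of the state-1 TSS band (default 100 bp).
#' @param proximal_width width of the state-2 proximal band upstream of the
#'   state-1 band (default 500 bp).
#' @param state4_band distal band for state 4, offsets relative to TSS,
#'   default `c(-3000, -1200)`.
#' @param state4_prob probability a gene receives a state-4 distal band
#'   (default 0.7).
#' @param chunk chunk size for the residual states 5-9 (default 2000 bp).
#' @param rest_probs relative frequencies of states 5-9 in the residual
#'   genome (default equal).
#' @param seed RNG seed.
#' @return `state_map` with attribute `truth` (parameters + the ids of
#'   state-4 genes).
#' @export
make_state_map <- function(genome, core_halfwidth = 100, proximal_width = 500,
                           state4_band = c(-3000, -1200), state4_prob = 0.7,
                           chunk = 2000, rest_probs = rep(0.2, 5), seed = 1) {
  set.seed(seed)
  tx <- genome$transcripts
  lens <- genome$chrom_lengths
  minus <- tx$strand == "-"
  clipgr <- function(s, e, chrom) {
    s <- pmax(1, s); e <- pmin(unname(lens[chrom]), e)
    keep <- s <= e
    GenomicRanges::reduce(GenomicRanges::GRanges(
      chrom[keep], IRanges::IRanges(s[keep], e[keep])), ignore.strand = TRUE)
  }
  s1 <- clipgr(tx$tss - core_halfwidth, tx$tss + core_halfwidth, tx$chrom)
  p_lo <- ifelse(minus, tx$tss + core_halfwidth + 1,
                 tx$tss - core_halfwidth - proximal_width)
  p_hi <- ifelse(minus, tx$tss + core_halfwidth + proximal_width,
                 tx$tss - core_halfwidth - 1)
  s2 <- GenomicRanges::setdiff(clipgr(p_lo, p_hi, tx$chrom), s1,
                               ignore.strand = TRUE)
  gene_spans <- clipgr(pmin(tx$tss, tx$tes), pmax(tx$tss, tx$tes), tx$chrom)
  s3 <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(gene_spans, s1, ignore.strand = TRUE), s2,
    ignore.strand = TRUE)
  pick4 <- runif(nrow(tx)) < state4_prob
  b_lo <- ifelse(minus, tx$tss - state4_band[2], tx$tss + state4_band[1])
  b_hi <- ifelse(minus, tx$tss - state4_band[1], tx$tss + state4_band[2])
  s4 <- clipgr(b_lo[pick4], b_hi[pick4], tx$chrom[pick4])
  for (g in list(s1, s2, s3)) s4 <- GenomicRanges::setdiff(s4, g,
                                                           ignore.strand = TRUE)
  whole <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1, unname(lens)))
  rest <- whole
  for (g in list(s1, s2, s3, s4)) rest <- GenomicRanges::setdiff(rest, g,
                                                                 ignore.strand = TRUE)
  # split the residual genome into chunks and label them with states 5..9
  rs <- BiocGenerics::start(rest); re <- BiocGenerics::end(rest)
  rch <- as.character(GenomicRanges::seqnames(rest))
  cs <- list(); ce <- list(); cch <- list()
  for (i in seq_along(rs)) {
    st <- seq(rs[i], re[i], by = chunk)
    cs[[i]] <- st
    ce[[i]] <- pmin(st + chunk - 1, re[i])
    cch[[i]] <- rep(rch[i], length(st))
  }
  cs <- unlist(cs); ce <- unlist(ce); cch <- unlist(cch)
  lab <- sample(5:9, length(cs), replace = TRUE, prob = rest_probs)
  doms <- setNames(vector("list", 9), as.character(1:9))
  doms[["1"]] <- s1; doms[["2"]] <- s2; doms[["3"]] <- s3; doms[["4"]] <- s4
  for (s in 5:9) {
    i <- lab == s
    doms[[as.character(s)]] <- if (any(i))
      GenomicRanges::reduce(GenomicRanges::GRanges(
        cch[i], IRanges::IRanges(cs[i], ce[i])), ignore.strand = TRUE)
    else GenomicRanges::GRanges()
  }
  out <- state_map(doms)
  attr(out, "truth") <- list(seed = seed, core_halfwidth = core_halfwidth,
                             proximal_width = proximal_width,
                             state4_band = state4_band,
                             state4_prob = state4_prob, chunk = chunk,
                             rest_probs = rest_probs,
                             state4_genes = tx$gene_id[pick4])
  out
}

#' Generate ChIP-Seq-like peaks with a bimodal TSS-relative placement
#'
#' Peak centres are drawn from a three-component mixture over the genome: a
#' uniform background (the realisation of the flat baseline `C`,
#' i.e. non-specific binding anywhere in the genome) and two strand-aware
#' Gaussian components of TSS-relative offsets (proximal and distal binding
#' modes).  Peak lengths are lognormal with >95% of mass below 500 bp;
#' heights follow a geometric law calibrated so that the height filter at
#' `height_threshold` retains `retain_prob` of the peaks in expectation.
#'
#' @param genome `synthetic_genome`.
#' @param n_peaks number of peaks (default 2577).
#' @param weights mixture weights `c(bg, prox, dist)`, summing to 1.
#' @param m_prox,sigma_prox,m_dist,sigma_dist Gaussian offset parameters in
#'   bp relative to TSS (negative = upstream).
#' @param length_meanlog,length_sdlog,min_length peak length distribution.
#' @param retain_prob expected fraction of peaks at or above
#'   `height_threshold` (default 0.85).
#' @param height_threshold reference height cutoff (default 7).
#' @param states_map optional `state_map`; with `state_bias > 0`, distal
#'   peaks are snapped into nearby state-4 domains with that probability.
#' @param state_bias probability a distal peak is relocated into a state-4
#'   domain within 2 kb of its drawn centre (default 0).
#' @param seed RNG seed.
#' @return peak data frame (`chrom`, `start`, `end`, `height`, `component`)
#'   with attribute `truth` recording every parameter.
#' @export
make_peaks <- function(genome, n_peaks = 2577,
                       weights = c(bg = 0.30, prox = 0.45, dist = 0.25),
                       m_prox = -150, sigma_prox = 100,
                       m_dist = -900, sigma_dist = 400,
                       length_meanlog = log(220), length_sdlog = 0.45,
                       min_length = 50, retain_prob = 0.85,
                       height_threshold = 7, states_map = NULL,
                       state_bias = 0, seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, n_peaks >= 1)
  set.seed(seed)
  tx <- genome$transcripts
  lens <- genome$chrom_lengths
  comp <- sample(c("bg", "prox", "dist"), n_peaks, replace = TRUE,
                 prob = unname(weights))
  len <- pmax(min_length, round(rlnorm(n_peaks, length_meanlog, length_sdlog)))
  center <- numeric(n_peaks)
  chrom <- character(n_peaks)
  i_bg <- comp == "bg"
  if (any(i_bg)) {
    chrom[i_bg] <- sample(names(lens), sum(i_bg), replace = TRUE,
                          prob = unname(lens) / sum(lens))
    center[i_bg] <- floor(runif(sum(i_bg), 1, unname(lens[chrom[i_bg]]) + 1))
  }
  for (cc in c("prox", "dist")) {
    i <- comp == cc
    if (!any(i)) next
    gi <- sample.int(nrow(tx), sum(i), replace = TRUE)
    off <- rnorm(sum(i), if (cc == "prox") m_prox else m_dist,
                 if (cc == "prox") sigma_prox else sigma_dist)
    sgn <- ifelse(tx$strand[gi] == "-", -1, 1)
    center[i] <- round(tx$tss[gi] + sgn * off)
    chrom[i] <- tx$chrom[gi]
  }
  if (!is.null(states_map) && state_bias > 0) {
    idx4 <- lapply(split(states_map$domains[["4"]],
                         as.character(GenomicRanges::seqnames(states_map$domains[["4"]]))),
                   function(g) list(start = BiocGenerics::start(g),
                                    end = BiocGenerics::end(g)))
    move <- which(comp == "dist" & runif(n_peaks) < state_bias)
    for (i in move) {
      d4 <- idx4[[chrom[i]]]
      if (is.null(d4) || length(d4$start) == 0) next
      dist_to <- pmax(d4$start - center[i], center[i] - d4$end, 0)
      j <- which.min(dist_to)
      if (dist_to[j] <= 2000) {
        center[i] <- floor(runif(1, d4$start[j], d4$end[j] + 1))
      }
    }
  }
  start <- pmax(1, round(center - len / 2))
  end <- pmin(unname(lens[chrom]), start + len - 1)
  start <- pmax(1, pmin(start, end))
  # geometric heights (support 1, 2, ...) with P(H >= t) = retain_prob
  pgeo <- 1 - retain_prob^(1 / (height_threshold - 1))
  height <- 1 + rgeom(n_peaks, pgeo)
  out <- data.frame(chrom = chrom, start = start, end = end, height = height,
                    component = comp, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(
    seed = seed, n_peaks = n_peaks, weights = as.list(weights),
    m_prox = m_prox, sigma_prox = sigma_prox,
    m_dist = m_dist, sigma_dist = sigma_dist,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_length = min_length, retain_prob = retain_prob,
    height_threshold = height_threshold, state_bias = state_bias)
  out
}

#' Write a peak table in a BED-like layout (height in column 5)
#' @param peaks peak data frame.
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  tab <- data.frame(chrom = peaks$chrom, start = peaks$start - 1,
                    end = peaks$end, name = sprintf("peak%d", seq_len(nrow(peaks))),
                    height = peaks$height, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Plant motif instances into genome sequences
#'
#' Writes consensus-drawn motif instances (degenerate positions sampled
#' uniformly among their allowed bases, random strand) at Poisson-distributed
#' positions: one rate per chromatin state when a `state_map` is supplied, or
#' one genome-wide rate otherwise.  A position colliding with a previous
#' plant is re-drawn.
#'
#' @param sequences `DNAStringSet` (e.g. `genome$sequences`).
#' @param rates per-kb planting rates: named by state label (`"1"`..`"9"`)
#'   with `states_map`, or a single number without.
#' @param states_map optional `state_map`.
#' @param consensus IUPAC consensus of the motif (default `"AYGWAYCT"`).
#' @param seed RNG seed.
#' @return list: `$sequences` (modified `DNAStringSet`), `$truth` data frame
#'   (`chrom`, `start`, `strand`, `site`, `state`).
#' @export
plant_motifs <- function(sequences, rates, states_map = NULL,
                         consensus = "AYGWAYCT", seed = 1) {
  stopifnot(all(rates >= 0))
  set.seed(seed)
  L <- nchar(consensus)
  chars <- lapply(as.character(sequences), identity)
  planted <- lapply(chars, function(x) integer(0))
  names(planted) <- names(chars)
  draw_site <- function() {
    paste(vapply(strsplit(toupper(consensus), "")[[1]], function(b) {
      allowed <- .IUPAC[[b]]
      allowed[sample.int(length(allowed), 1)]
    }, ""), collapse = "")
  }
  truth <- list()
  domains <- if (is.null(states_map)) {
    lapply(seq_along(chars), function(i)
      data.frame(chrom = names(chars)[i], start = 1,
                 end = nchar(chars[[i]]), state = NA_character_,
                 rate = rates[1], stringsAsFactors = FALSE))
  } else {
    out <- list()
    for (s in names(states_map$domains)) {
      g <- states_map$domains[[s]]
      if (length(g) == 0) next
      r <- if (s %in% names(rates)) rates[[s]] else 0
      if (r <= 0) next
      out[[s]] <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                             start = BiocGenerics::start(g),
                             end = BiocGenerics::end(g), state = s,
                             rate = r, stringsAsFactors = FALSE)
    }
    out
  }
  domains <- do.call(rbind, domains)
  if (!is.null(domains)) {
    for (i in seq_len(nrow(domains))) {
      d <- domains[i, ]
      width <- d$end - d$start + 1
      if (width < L) next
      n <- rpois(1, d$rate * width / 1000)
      if (n == 0) next
      for (k in seq_len(n)) {
        for (attempt in 1:50) {
          p <- floor(runif(1, d$start, d$end - L + 2))
          prev <- planted[[d$chrom]]
          if (!any(abs(prev - p) < L)) break
        }
        planted[[d$chrom]] <- c(planted[[d$chrom]], p)
        site <- draw_site()
        strand <- sample(c("+", "-"), 1)
        written <- if (strand == "-")
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
        else site
        substr(chars[[d$chrom]], p, p + L - 1) <- written
        truth[[length(truth) + 1]] <- data.frame(
          chrom = d$chrom, start = p, strand = strand, site = site,
          state = d$state, stringsAsFactors = FALSE)
      }
    }
  }
  out_seq <- Biostrings::DNAStringSet(unlist(chars))
  names(out_seq) <- names(chars)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = integer(0), strand = character(0),
               site = character(0), state = character(0))
  list(sequences = out_seq, truth = truth)
}

#' Generate a gene-to-GO annotation table with planted list differences
#'
#' Per term, each gene is annotated independently with a probability that
#' depends on which designated subset it belongs to, so term-frequency
#' differences between two gene lists can be planted at exact targets.
#'
#' @param genes character vector of all gene ids (the universe).
#' @param listA,listB designated gene subsets (may be empty).
#' @param n_terms number of terms (default 30).
#' @param fractionsA,fractionsB per-term membership probability for genes of
#'   each subset; single number or length-`n_terms` vector; default =
#'   `bg_fraction`.
#' @param bg_fraction membership probability for all other genes
#'   (default 0.05).
#' @param seed RNG seed.
#' @return annotation data frame (`gene_id`, `term_id`, `vocabulary`) with
#'   attribute `truth`.
#' @export
make_go_annotations <- function(genes, listA = character(0),
                                listB = character(0), n_terms = 30,
                                fractionsA = NULL, fractionsB = NULL,
                                bg_fraction = 0.05, seed = 1) {
  set.seed(seed)
  if (is.null(fractionsA)) fractionsA <- rep(bg_fraction, n_terms)
  if (is.null(fractionsB)) fractionsB <- rep(bg_fraction, n_terms)
  fractionsA <- rep_len(fractionsA, n_terms)
  fractionsB <- rep_len(fractionsB, n_terms)
  stopifnot(all(fractionsA >= 0 & fractionsA <= 1),
            all(fractionsB >= 0 & fractionsB <= 1))
  vocab <- rep_len(c("BP", "MF", "CC"), n_terms)
  inA <- genes %in% listA
  inB <- genes %in% listB
  rows <- list()
  for (t in seq_len(n_terms)) {
    p <- ifelse(inA, fractionsA[t], ifelse(inB, fractionsB[t], bg_fraction))
    memb <- runif(length(genes)) < p
    if (!any(memb)) next
    rows[[t]] <- data.frame(gene_id = genes[memb],
                            term_id = sprintf("TERM%03d", t),
                            vocabulary = vocab[t], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), term_id = character(0),
               vocabulary = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "truth") <- list(seed = seed, n_terms = n_terms,
                             fractionsA = fractionsA, fractionsB = fractionsB,
                             bg_fraction = bg_fraction)
  out
}
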