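# End-to-end orchestration: configuration object, synthetic preset, and the
# run_all() driver that executes ingest -> classify -> permutation tests ->
# profile/fit -> state stratification -> upstream datasets -> PWM scan ->
# GO comparison, writing TSV/JSON artifacts with provenance.

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis.  Defaults: height filter
#' 7; profile window \[-1500, +100\]; gene-linkage window \[-3500; +1\];
#' seven 500-bp upstream bins over a 3500-bp span; PWM threshold 0.91;
#' GO robust-term fraction 3% and FDR 0.05; Bonferroni divisor 8 for the
#' per-interval site-density tests; 10000 permutations.
#'
#' @param min_height peak height cutoff (default 7).
#' @param profile_window profile offsets relative to TSS (0 = TSS), default
#'   `c(-1500, 100)`.
#' @param linkage_window gene-linkage window, promoter +1 convention,
#'   default `c(-3500, 1)`.
#' @param upstream_span,upstream_bin upstream datasets geometry (3500, 500).
#' @param pwm_threshold normalised PWM score cutoff (default 0.91).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed master RNG seed; each stage derives its own stream from it.
#' @param fdr FDR level for GO comparisons (default 0.05).
#' @param bonferroni_n divisor for per-interval Bonferroni correction
#'   (default 8).
#' @param min_go_fraction robust GO term fraction threshold (default 0.03).
#' @param synth named list of overrides passed to the synthetic generators
#'   (e.g. `list(n_genes = 500, n_peaks = 800)`).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(min_height = 7, profile_window = c(-1500, 100),
                            linkage_window = c(-3500, 1),
                            upstream_span = 3500, upstream_bin = 500,
                            pwm_threshold = 0.91, n_perm = 10000, seed = 1,
                            fdr = 0.05, bonferroni_n = 8,
                            min_go_fraction = 0.03, synth = list()) {
  stopifnot(min_height >= 0, pwm_threshold >= 0, pwm_threshold <= 1,
            n_perm >= 100, fdr > 0, fdr < 1, min_go_fraction >= 0,
            min_go_fraction < 1, upstream_span %% upstream_bin == 0)
  structure(list(min_height = min_height, profile_window = profile_window,
                 linkage_window = linkage_window,
                 upstream_span = upstream_span, upstream_bin = upstream_bin,
                 pwm_threshold = pwm_threshold, n_perm = n_perm, seed = seed,
                 fdr = fdr, bonferroni_n = bonferroni_n,
                 min_go_fraction = min_go_fraction, synth = synth),
            class = "pipeline_config")
}

# substring sequences under a track; returns DNAStringSet
.track_sequences <- function(x, sequences) {
  chars <- as.character(sequences)
  df <- .track_df(x)
  out <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    out[i] <- substr(chars[[df$chrom[i]]], df$start[i], df$end[i])
  }
  Biostrings::DNAStringSet(out)
}

#' Run the full pipeline
#'
#' With no explicit inputs, generates the default synthetic dataset from
#' the config seed (genome + annotation, nine-state map, bimodally placed
#' peaks with distal peaks biased into state-4 domains, motif-planted
#' sequences with the state-4 rate three times the state-1/2 rate, and a GO
#' table with ethylene-like terms elevated in the state-4 gene list), then
#' executes every stage and writes artifacts to `outdir`.
#'
#' @param config `pipeline_config`.
#' @param outdir output directory (created). Default: a fresh temporary
#'   directory.
#' @param inputs optional named list of file paths (`gff`, `peaks`, `states`,
#'   `fasta`, `go`) replacing the synthetic preset; peak files are read with
#'   `peak_format`/`height_col`.
#' @param peak_format,height_col passed to [read_peaks()].
#' @return invisibly, a list with every stage result plus `$outdir`.
#' @export
run_all <- function(config = pipeline_config(), outdir = tempfile("bindscape_"),
                    inputs = NULL, peak_format = "bed", height_col = NULL) {
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf("[%s] %s",
                                             format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))
  seed <- config$seed
  synth_used <- is.null(inputs)

  if (synth_used) {
    log_stage("synth: generating dataset (seed %d)", seed)
    sy <- config$synth
    gpar <- function(name, default) if (!is.null(sy[[name]])) sy[[name]] else default
    genome <- make_genome(n_genes = gpar("n_genes", 2000),
                          n_chromosomes = gpar("n_chromosomes", 2),
                          seed = seed,
                          sequences = gpar("sequences", TRUE))
    smap <- make_state_map(genome, seed = seed + 1)
    peaks <- make_peaks(genome, n_peaks = gpar("n_peaks", 2577),
                        states_map = smap, state_bias = gpar("state_bias", 0.8),
                        seed = seed + 2)
    rates <- gpar("motif_rates", c("1" = 1, "2" = 1, "4" = 3))
    sequences <- NULL
    if (!is.null(genome$sequences)) {
      planted <- plant_motifs(genome$sequences, rates = rates,
                              states_map = smap, seed = seed + 3)
      sequences <- planted$sequences
    }
    transcripts <- genome$transcripts
    chrom_lengths <- genome$chrom_lengths
  } else {
    log_stage("ingest: reading inputs")
    transcripts <- read_gff_transcripts(inputs$gff)
    peaks <- read_peaks(inputs$peaks, format = peak_format,
                        height_col = height_col)
    smap <- read_state_map(inputs$states)
    sequences <- if (!is.null(inputs$fasta))
      Biostrings::readDNAStringSet(inputs$fasta) else NULL
    chrom_lengths <- if (!is.null(sequences))
      setNames(BiocGenerics::width(sequences),
               sub(" .*", "", names(sequences))) else NULL
    genome <- NULL
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- .infer_chrom_lengths(
      track(peaks$chrom, peaks$start, peaks$end), transcripts)
  }

  log_stage("filter: height >= %g", config$min_height)
  ebrs <- peak_filter(peaks, min_height = config$min_height)
  write_bed(ebrs, file.path(outdir, "binding_regions.bed"))

  log_stage("classify: %d regions vs %d transcripts", length(ebrs),
            nrow(transcripts))
  cls <- classify_locations(ebrs, transcripts)
  cls_test <- location_class_test(ebrs, transcripts,
                                  chrom_lengths = chrom_lengths,
                                  n_perm = config$n_perm, seed = seed + 10)
  write.table(data.frame(class = names(cls$counts), count = cls$counts,
                         fraction = cls$fractions),
              file.path(outdir, "location_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_perm_report(cls_test, file.path(outdir, "location_class_test.tsv"))

  log_stage("profile: window [%d, %d]", config$profile_window[1],
            config$profile_window[2])
  tx5 <- transcripts[transcripts$has_5utr, , drop = FALSE]
  prof <- occurrence_profile(ebrs, tx5, window = config$profile_window)
  fit <- fit_bimodal(prof)
  strat <- stratified_profile(ebrs, smap, tx5, window = config$profile_window)
  write_profile(prof, file.path(outdir, "profile.tsv"), strata = strat)
  jsonlite::write_json(
    c(unclass(fit), list(rss = attr(fit, "rss"))),
    file.path(outdir, "bimodal_fit.json"), auto_unbox = TRUE, digits = NA)

  log_stage("upstream-sets: span %d, bin %d", config$upstream_span,
            config$upstream_bin)
  ups <- build_upstream_datasets(transcripts, chrom_lengths = chrom_lengths,
                                 span = config$upstream_span,
                                 bin_width = config$upstream_bin)
  for (i in seq_along(ups$tracks)) {
    write_bed(ups$tracks[[i]], file.path(outdir, sprintf("upstream_set_%d.bed", i)))
  }
  ups_tests <- lapply(seq_along(ups$tracks), function(i) {
    if (length(ups$tracks[[i]]) == 0) return(NULL)
    track_overlap_test(ebrs, ups$tracks[[i]], chrom_lengths = chrom_lengths,
                       n_perm = config$n_perm, seed = seed + 20 + i)
  })
  names(ups_tests) <- ups$labels
  write_perm_report(Filter(Negate(is.null), ups_tests),
                    file.path(outdir, "upstream_overlap_tests.tsv"))

  log_stage("gene lists by chromatin state")
  lists <- compile_state_gene_lists(ebrs, smap, transcripts,
                                    window = config$linkage_window)
  writeLines(lists$states12, file.path(outdir, "genes_states12.txt"))
  writeLines(lists$state4, file.path(outdir, "genes_state4.txt"))

  log_stage("GO comparison: %d vs %d genes", length(lists$states12),
            length(lists$state4))
  if (synth_used) {
    # plant ethylene-like terms elevated in the state-4 list
    nt <- 30
    frB <- rep(0.05, nt); frB[c(5, 11, 17)] <- 0.20
    go_ann <- make_go_annotations(unique(transcripts$gene_id),
                                  listA = lists$states12,
                                  listB = lists$state4,
                                  n_terms = nt, fractionsB = frB,
                                  seed = seed + 4)
    write_go_annotations(go_ann, file.path(outdir, "go_annotations.tsv"))
  } else {
    go_ann <- read_go_annotations(inputs$go)
  }
  go <- if (length(lists$states12) && length(lists$state4)) {
    go_compare(lists$states12, lists$state4, go_ann,
               min_fraction = config$min_go_fraction, fdr = config$fdr)
  } else NULL
  if (!is.null(go)) {
    write.table(go, file.path(outdir, "go_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  scan_tab <- NULL
  if (!is.null(sequences)) {
    log_stage("PWM scan: threshold %.2f", config$pwm_threshold)
    pwm <- pwm_from_pfm(teil_pfm(), threshold = config$pwm_threshold)
    dom12 <- GenomicRanges::reduce(
      c(GenomicRanges::granges(smap$domains[["1"]]),
        GenomicRanges::granges(smap$domains[["2"]])), ignore.strand = TRUE)
    frag12 <- track_intersect(ebrs, dom12)
    frag4 <- track_intersect(ebrs, smap$domains[["4"]])
    genome_scan <- scan_pwm(pwm, sequences)
    scans4 <- list(); scans12 <- list()
    for (i in seq_along(ups$tracks)) {
      lab <- ups$labels[i]
      f4 <- track_intersect(frag4, ups$tracks[[i]])
      f12 <- track_intersect(frag12, ups$tracks[[i]])
      scans4[[lab]] <- if (length(f4)) scan_pwm(pwm, .track_sequences(f4, sequences))
        else structure(list(positions = 0L, hits = 0L, density = NA_real_,
                            threshold = config$pwm_threshold),
                       class = "scan_result")
      scans12[[lab]] <- if (length(f12)) scan_pwm(pwm, .track_sequences(f12, sequences))
        else structure(list(positions = 0L, hits = 0L, density = NA_real_,
                            threshold = config$pwm_threshold),
                       class = "scan_result")
    }
    scan_tab <- density_compare(scans4, scans12, n_tests = config$bonferroni_n)
    scan_tab$norm_density_a <- scan_tab$density_a / genome_scan$density
    scan_tab$norm_density_b <- scan_tab$density_b / genome_scan$density
    write.table(scan_tab, file.path(outdir, "site_density.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  prov <- list(package = "bindscape",
               version = as.character(utils::packageVersion("bindscape")),
               seed = seed, config = unclass(config),
               synthetic = synth_used,
               elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done in %.1f s -> %s", prov$elapsed_sec, outdir)

  invisible(list(outdir = outdir, transcripts = transcripts, peaks = peaks,
                 binding_regions = ebrs, states_map = smap,
                 location_classes = cls, location_test = cls_test,
                 profile = prof, fit = fit, stratified = strat,
                 upstream = ups, upstream_tests = ups_tests,
                 gene_lists = lists, go = go, site_density = scan_tab,
                 chrom_lengths = chrom_lengths,
                 genome = if (synth_used) genome else NULL))
}
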