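# Monte-Carlo permutation tests for genome tracks.
#
# Null model: each interval is re-placed uniformly at random on its own
# chromosome with its length preserved, independently of the others (overlaps
# among permuted intervals are allowed).  The cited literature leaves the
# shuffling scheme unspecified; this is the simplest defensible null and is
# isolated in permute_track() so it can be swapped.

#' Permute a track
#'
#' Re-places every interval uniformly at random on its own chromosome,
#' preserving interval lengths.
#'
#' @param x track (`GRanges`).
#' @param chrom_lengths named numeric vector of chromosome lengths covering
#'   every chromosome in `x`.
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   permutation is reproducible.
#' @return permuted track.
#' @export
permute_track <- function(x, chrom_lengths, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- .track_df(x)
  w <- df$end - df$start + 1
  L <- unname(chrom_lengths[df$chrom])
  if (any(is.na(L))) stop("chromosome missing from chrom_lengths: ",
                          paste(unique(df$chrom[is.na(L)]), collapse = ", "))
  if (any(w > L)) stop("interval longer than its chromosome")
  start <- floor(runif(nrow(df), min = 1, max = L - w + 2))
  start <- pmin(start, L - w + 1)  # guard the max = L - w + 2 boundary
  track(df$chrom, start, start + w - 1)
}

# vectorised permutation on plain columns (hot loop; no GRanges)
.permute_starts <- function(w, L) {
  s <- floor(runif(length(w), min = 1, max = L - w + 2))
  pmin(s, L - w + 1)
}

.perm_result <- function(observed, null, n_perm, statistic, seed = NULL) {
  null_mean <- mean(null)
  null_sd <- sd(null)
  direction <- if (observed > null_mean) "enriched"
               else if (observed < null_mean) "depleted" else "neutral"
  # fixed upper (enrichment) tail: uniform under the null and never 0; the
  # depletion tail is 1 - p_empirical + 1/(n_perm + 1)
  r <- sum(null >= observed)
  p_emp <- (r + 1) / (n_perm + 1)
  z <- if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_
  p_norm <- if (is.na(z)) NA_real_ else
    pnorm(abs(z), lower.tail = FALSE)
  structure(list(observed = observed, null_mean = null_mean, null_sd = null_sd,
                 n_perm = n_perm, p_empirical = p_emp, p_normal = p_norm,
                 z = z, direction = direction, statistic = statistic,
                 seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "permutation test [%s]: observed = %.6g, null = %.6g +/- %.3g (n = %d)\n  %s, p_empirical = %.3g, p_normal = %.3g\n",
    x$statistic, x$observed, x$null_mean, x$null_sd, x$n_perm,
    x$direction, x$p_empirical,
    if (is.na(x$p_normal)) NA else x$p_normal))
  invisible(x)
}

#' Monte-Carlo test of per-location-class region counts
#'
#' Classifies the observed track against the transcript annotation, then
#' compares each class count (TSS, GENE, INTERGENIC) to its null distribution
#' under uniform re-placement of the track intervals.
#'
#' @param x track of regions.
#' @param transcripts transcript data frame.
#' @param chrom_lengths named chromosome lengths; if `NULL`, inferred as the
#'   per-chromosome maximum of annotation and track coordinates.
#' @param n_perm number of permutations, `>= 100` (default 1000).
#' @param seed optional RNG seed.
#' @return named list of three `perm_result` (TSS, GENE, INTERGENIC).
#' @export
location_class_test <- function(x, transcripts, chrom_lengths = NULL,
                                n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom_lengths)) chrom_lengths <- .infer_chrom_lengths(x, transcripts)
  obs <- classify_locations(x, transcripts)
  ann <- .annotation_index(transcripts)
  df <- .track_df(x)
  w <- df$end - df$start + 1
  L <- unname(chrom_lengths[df$chrom])
  if (any(w > L)) stop("interval longer than its chromosome")
  null <- matrix(0L, nrow = n_perm, ncol = 3)
  for (i in seq_len(n_perm)) {
    s <- .permute_starts(w, L)
    code <- .classify_codes(df$chrom, s, s + w - 1, ann)
    null[i, ] <- tabulate(code, nbins = 3L)
  }
  lev <- c("TSS", "GENE", "INTERGENIC")
  res <- lapply(1:3, function(j)
    .perm_result(obs$counts[[lev[j]]], null[, j], n_perm,
                 statistic = paste0("count[", lev[j], "]"), seed = seed))
  setNames(res, lev)
}

.infer_chrom_lengths <- function(x, transcripts = NULL) {
  m1 <- tapply(BiocGenerics::end(x), as.character(GenomicRanges::seqnames(x)), max)
  lens <- setNames(as.numeric(m1), names(m1))
  if (!is.null(transcripts)) {
    m2 <- tapply(pmax(transcripts$tes, transcripts$tss), transcripts$chrom, max)
    for (ch in names(m2)) lens[ch] <- max(lens[ch], m2[[ch]], na.rm = TRUE)
  }
  lens
}

#' Monte-Carlo test of overlap between two genome tracks
#'
#' The statistic is the \emph{fraction of overlap}: total shared bases divided
#' by the total length of the permuted track.  By default the query is
#' permuted, so observed = [overlap_fraction]`(query, reference)` and the null
#' re-places the query intervals uniformly per chromosome.
#'
#' @param query,reference tracks; `query` must be non-empty.
#' @param chrom_lengths named chromosome lengths (inferred from the two tracks
#'   when `NULL`).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @param permute which track to permute, `"query"` (default) or
#'   `"reference"`.
#' @return a `perm_result`: observed statistic, null moments, `p_empirical`
#'   (the upper-tail/enrichment empirical p-value `(r + 1) / (n_perm + 1)`,
#'   uniform under the null and never 0), `p_normal` (normal-approximation
#'   tail in the observed direction, usable below the 1/n_perm resolution),
#'   and `direction` (`enriched`/`depleted`/`neutral` by comparison with the
#'   null mean; depletion strength is judged via `direction` + `p_normal` or
#'   `1 - p_empirical + 1/(n_perm+1)`).
#' @export
track_overlap_test <- function(query, reference, chrom_lengths = NULL,
                               n_perm = 1000, seed = NULL,
                               permute = c("query", "reference")) {
  permute <- match.arg(permute)
  if (!is.null(seed)) set.seed(seed)
  if (permute == "reference") { tmp <- query; query <- reference; reference <- tmp }
  if (length(query) == 0) stop("the permuted track must be non-empty")
  if (is.null(chrom_lengths)) {
    lens <- .infer_chrom_lengths(c(GenomicRanges::granges(query),
                                   GenomicRanges::granges(reference)))
    chrom_lengths <- lens
  }
  ridx <- .cover_index(reference)
  df <- .track_df(query)
  w <- df$end - df$start + 1
  L <- unname(chrom_lengths[df$chrom])
  if (any(is.na(L))) stop("chromosome missing from chrom_lengths")
  if (any(w > L)) stop("interval longer than its chromosome")
  qlen <- sum(as.numeric(w))
  ov <- function(s, e) {
    tot <- 0
    for (ch in unique(df$chrom)) {
      i <- df$chrom == ch
      idx <- ridx[[ch]]
      if (is.null(idx)) next
      tot <- tot + sum(.overlap_len(idx, s[i], e[i]))
    }
    tot
  }
  observed <- ov(df$start, df$end) / qlen
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    s <- .permute_starts(w, L)
    null[i] <- ov(s, s + w - 1) / qlen
  }
  .perm_result(observed, null, n_perm,
               statistic = sprintf("overlap_fraction[permuted %s]", permute),
               seed = seed)
}

#' Write permutation results as a TSV report
#' @param results a `perm_result` or list of them.
#' @param path output TSV.
#' @export
write_perm_report <- function(results, path) {
  if (inherits(results, "perm_result")) results <- list(results)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(test = if (!is.null(names(results))) names(results)[i] else i,
               statistic = r$statistic, observed = r$observed,
               null_mean = r$null_mean, null_sd = r$null_sd,
               p_empirical = r$p_empirical, p_normal = r$p_normal,
               direction = r$direction, n_perm = r$n_perm,
               seed = if (is.null(r$seed)) NA else r$seed,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
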