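# Interval arithmetic on tracks and transcript models: location classes,
# intersection fragments, overlap fractions, upstream-region datasets.
#
# Offset conventions: upstream offsets are strand-aware and use the promoter
# "+1" convention for interval names ([-3500; +1] etc.), where +1 is the TSS
# base itself and there is no offset 0.  Profile offsets (profile_model.R) use
# 0 = TSS.  The helper .offset_pos() maps +1-convention offsets to genomic
# positions.

# genomic position of +1-convention offset o relative to tss on a strand:
# o >= 1 -> tss + (o - 1) downstream; o <= -1 -> tss + o upstream (strand-aware)
.offset_pos <- function(tss, o, strand) {
  shift <- ifelse(o >= 1, o - 1, o)
  ifelse(strand == "-", tss - shift, tss + shift)
}

# annotation index for fast classification: per-chrom sorted TSS positions and
# reduced gene-span cover index
.annotation_index <- function(transcripts) {
  spans <- track(transcripts$chrom,
                 pmin(transcripts$tss, transcripts$tes),
                 pmax(transcripts$tss, transcripts$tes))
  tss_by_chrom <- lapply(split(transcripts$tss, transcripts$chrom),
                         function(x) sort(unique(x)))
  list(tss = tss_by_chrom, genes = .cover_index(spans))
}

# classify plain vectors; returns integer codes 1=TSS, 2=GENE, 3=INTERGENIC
.classify_codes <- function(chrom, s, e, ann) {
  code <- rep.int(3L, length(s))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    tss <- ann$tss[[ch]]
    gidx <- ann$genes[[ch]]
    hit_tss <- if (is.null(tss)) rep(FALSE, length(i)) else
      .points_in(tss, s[i], e[i]) > 0
    hit_gene <- if (is.null(gidx)) rep(FALSE, length(i)) else
      .overlap_len(gidx, s[i], e[i]) > 0
    code[i][hit_gene] <- 2L
    code[i][hit_tss] <- 1L
  }
  code
}

#' Classify regions by location relative to gene structure
#'
#' Each region receives exactly one class: `TSS` if it overlaps at least one
#' transcription start position, otherwise `GENE` if it overlaps at least one
#' base of any gene body, otherwise `INTERGENIC`.
#'
#' @param x track of regions (`GRanges`).
#' @param transcripts transcript data frame ([read_gff_transcripts()]).
#' @return `location_classes` object: `$class` (factor per region), `$counts`,
#'   `$fractions`, `$n`.
#' @examples
#' tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'                  strand = "+", tss = 100, aug = 130, tes = 400,
#'                  has_5utr = TRUE, is_protein_coding = TRUE)
#' classify_locations(track("chr1", c(95, 200, 900), c(105, 250, 950)), tx)
#' @export
classify_locations <- function(x, transcripts) {
  if (nrow(transcripts) == 0L) stop("transcripts must be non-empty")
  df <- .track_df(x)
  known <- unique(transcripts$chrom)
  if (any(!df$chrom %in% known)) {
    warning("regions on chromosome(s) absent from the annotation classified INTERGENIC: ",
            paste(unique(setdiff(df$chrom, known)), collapse = ", "))
  }
  ann <- .annotation_index(transcripts)
  code <- .classify_codes(df$chrom, df$start, df$end, ann)
  lev <- c("TSS", "GENE", "INTERGENIC")
  cls <- factor(lev[code], levels = lev)
  counts <- table(cls)
  structure(list(class = cls,
                 counts = setNames(as.integer(counts), lev),
                 fractions = setNames(as.numeric(counts) / length(cls), lev),
                 n = length(cls)),
            class = "location_classes")
}

#' @export
print.location_classes <- function(x, ...) {
  cat("location classes over", x$n, "regions\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-10s %6d  (%.2f%%)\n", k, x$counts[[k]], 100 * x$fractions[[k]]))
  }
  invisible(x)
}

#' Intersect two tracks
#'
#' Returns the maximal continuous fragments present in both tracks (both
#' reduced first; strand ignored).
#'
#' @param a,b tracks.
#' @return track of fragments; fragment count is `length()` of the result and
#'   total length is [track_length()].
#' @export
track_intersect <- function(a, b) {
  GenomicRanges::intersect(GenomicRanges::reduce(a, ignore.strand = TRUE),
                           GenomicRanges::reduce(b, ignore.strand = TRUE),
                           ignore.strand = TRUE)
}

#' Fraction of a query track overlapped by a reference track
#'
#' `sum(overlap bases) / track_length(query)`.  The denominator is the query's
#' unreduced total length, and each query interval contributes its own overlap,
#' so duplicated query intervals count twice in both numerator and denominator.
#'
#' @param query non-empty track (denominator).
#' @param reference track.
#' @return proportion in \[0, 1\].
#' @export
overlap_fraction <- function(query, reference) {
  qlen <- track_length(query)
  if (qlen <= 0) stop("overlap_fraction undefined for an empty query track")
  ridx <- .cover_index(reference)
  df <- .track_df(query)
  tot <- 0
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    idx <- ridx[[ch]]
    if (is.null(idx)) next
    tot <- tot + sum(.overlap_len(idx, df$start[i], df$end[i]))
  }
  tot / qlen
}

#' Build the eight strand-aware upstream-region datasets
#'
#' For each distinct-TSS transcript, eight candidate regions are laid out
#' relative to its TSS (promoter +1 convention): seven disjoint 500-bp bins
#' covering offsets \[-3500; -1\] — named \[-3500; -3000\], ..., \[-500; +1\] —
#' and the 5'UTR \[+1; AUG\].  Then:
#' \itemize{
#'   \item datasets 1-7 drop every region overlapping any transcript span;
#'   \item dataset k (k = 1..6) additionally drops regions overlapping the
#'     nested proximal window \[-(3500 - 500k); +1\] of any transcript;
#'   \item dataset 8 drops regions overlapping any translated span
#'     (translation start to end) or any \[-500; +1\] proximal window.
#' }
#' Regions truncated at chromosome boundaries are kept if non-empty; a
#' transcript with `tss == aug` contributes nothing to dataset 8.
#'
#' @param transcripts transcript data frame; deduplicated to distinct TSS
#'   internally via [distinct_tss()].
#' @param chrom_lengths optional named vector for boundary clipping.
#' @param span,bin_width total upstream span (default 3500) and bin width
#'   (default 500); `span` must be a multiple of `bin_width`.
#' @return `upstream_datasets` object: `$tracks` (list of 8 `GRanges`),
#'   `$counts`, `$labels`.
#' @export
build_upstream_datasets <- function(transcripts, chrom_lengths = NULL,
                                    span = 3500, bin_width = 500) {
  stopifnot(span %% bin_width == 0)
  tx <- distinct_tss(transcripts)
  n_bins <- span %/% bin_width
  minus <- tx$strand == "-"

  clip <- function(ch, s, e) {
    s <- pmax(1, s)
    if (!is.null(chrom_lengths)) e <- pmin(unname(chrom_lengths[ch]), e)
    keep <- !is.na(s) & !is.na(e) & s <= e
    list(ch = ch[keep], s = s[keep], e = e[keep], keep = keep)
  }
  mk <- function(ch, s, e) {
    cl <- clip(ch, s, e)
    track(cl$ch, cl$s, cl$e)
  }

  # candidate bins: bin k covers offsets -(span - (k-1)*w) .. -(span - k*w) - 1
  cand <- vector("list", n_bins + 1)
  for (k in seq_len(n_bins)) {
    up <- span - (k - 1) * bin_width   # e.g. 3500
    lo <- span - k * bin_width + 1     # e.g. 3001
    s_plus <- tx$tss - up; e_plus <- tx$tss - lo
    s <- ifelse(minus, tx$tss + lo, s_plus)
    e <- ifelse(minus, tx$tss + up, e_plus)
    cand[[k]] <- mk(tx$chrom, s, e)
  }
  # dataset 8: 5'UTR = TSS .. AUG-1 strand-aware; empty when tss == aug
  utr_len <- abs(tx$aug - tx$tss)
  has <- utr_len >= 1
  s8 <- ifelse(minus, tx$aug + 1, tx$tss)
  e8 <- ifelse(minus, tx$tss, tx$aug - 1)
  cand[[n_bins + 1]] <- mk(tx$chrom[has], s8[has], e8[has])

  spans <- track(tx$chrom, pmin(tx$tss, tx$tes), pmax(tx$tss, tx$tes))
  span_idx <- .cover_index(spans)
  overlaps_any <- function(gr, idx) {
    if (length(gr) == 0) return(logical(0))
    df <- .track_df(gr)
    out <- logical(nrow(df))
    for (ch in unique(df$chrom)) {
      i <- df$chrom == ch
      out[i] <- .overlap_len(idx[[ch]], df$start[i], df$end[i]) > 0
    }
    out
  }
  win_track <- function(up_offset) {
    # proximal window offsets -up_offset .. -1 of every transcript
    s <- ifelse(minus, tx$tss + 1, tx$tss - up_offset)
    e <- ifelse(minus, tx$tss + up_offset, tx$tss - 1)
    mk(tx$chrom, s, e)
  }

  out <- vector("list", n_bins + 1)
  for (k in seq_len(n_bins)) {
    g <- cand[[k]]
    g <- g[!overlaps_any(g, span_idx)]
    if (k < n_bins) {
      w_idx <- .cover_index(win_track(span - k * bin_width))
      g <- g[!overlaps_any(g, w_idx)]
    }
    out[[k]] <- g
  }
  pc <- tx$is_protein_coding
  cds_spans <- track(tx$chrom[pc], pmin(tx$aug, tx$tes)[pc], pmax(tx$aug, tx$tes)[pc])
  filt8 <- GenomicRanges::reduce(c(cds_spans, win_track(bin_width)),
                                 ignore.strand = TRUE)
  f8_idx <- .cover_index(filt8)
  g8 <- cand[[n_bins + 1]]
  out[[n_bins + 1]] <- g8[!overlaps_any(g8, f8_idx)]

  ks <- seq_len(n_bins)
  labels <- c(sprintf("[%d; %s]", -(span - (ks - 1) * bin_width),
                      ifelse(ks == n_bins, "+1",
                             as.character(-(span - ks * bin_width)))),
              "[+1; AUG]")
  names(out) <- labels
  structure(list(tracks = out,
                 counts = setNames(vapply(out, length, 1L), labels),
                 labels = labels, span = span, bin_width = bin_width),
            class = "upstream_datasets")
}

#' @export
print.upstream_datasets <- function(x, ...) {
  cat("upstream-region datasets (", length(x$tracks), " sets)\n", sep = "")
  for (i in seq_along(x$tracks)) {
    cat(sprintf("  %d %-14s %6d regions\n", i, x$labels[i], x$counts[i]))
  }
  invisible(x)
}

#' Link regions to genes through their upstream windows
#'
#' A gene is linked to a region iff at least one base of the region overlaps
#' the gene's strand-aware window (promoter +1 convention; the default
#' \[-3500; +1\] spans 3500 bp upstream plus the TSS base).  Genes with several
#' transcripts use the union of their transcript windows.
#'
#' @param x track of regions.
#' @param transcripts transcript data frame.
#' @param window two offsets in the +1 convention, default `c(-3500, 1)`.
#' @return named list: `gene_id` -> integer indices of linked regions in `x`.
#' @export
link_genes <- function(x, transcripts, window = c(-3500, 1)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  tss <- transcripts$tss
  st <- transcripts$strand
  p1 <- .offset_pos(tss, window[1], st)
  p2 <- .offset_pos(tss, window[2], st)
  w <- GenomicRanges::GRanges(transcripts$chrom,
                              IRanges::IRanges(pmax(1, pmin(p1, p2)), pmax(p1, p2)))
  hits <- GenomicRanges::findOverlaps(w, x, ignore.strand = TRUE)
  if (length(hits) == 0) return(setNames(list(), character(0)))
  gene <- transcripts$gene_id[S4Vectors::queryHits(hits)]
  lapply(split(S4Vectors::subjectHits(hits), gene), function(i) sort(unique(i)))
}
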