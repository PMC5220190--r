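#' Build a genomic track
#'
#' A track is the universal region container of the package: peaks, chromatin
#' state domains, upstream regions, intersection fragments.  It is represented
#' as a [GenomicRanges::GRanges] sorted within each chromosome; an optional
#' `name` is kept in its metadata.
#'
#' @param chrom character vector of chromosome identifiers (non-empty strings).
#' @param start,end 1-based closed interval bounds, `start <= end`, `start >= 1`.
#' @param strand `"+"`, `"-"` or `"*"` (default, unstranded).
#' @param name optional track label.
#' @return A `GRanges` with the track name in `metadata(x)$track_name`.
#' @examples
#' tr <- track("chr1", c(1, 501), c(100, 700), name = "demo")
#' track_length(tr)  # 300
#' @export
track <- function(chrom, start, end, strand = "*", name = NULL) {
  chrom <- as.character(chrom)
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    if (any(!nzchar(chrom))) stop("chromosome identifiers must be non-empty")
    start <- as.numeric(start); end <- as.numeric(end)
    if (any(is.na(start) | is.na(end))) stop("start/end must be numeric")
    if (any(start < 1)) stop("start must be >= 1 (1-based coordinates)")
    if (any(end < start)) stop("interval end < start")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
  }
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  if (!is.null(name)) S4Vectors::metadata(gr)$track_name <- name
  gr
}

#' Coerce to a track
#'
#' Accepts a `GRanges` or a data frame with `chrom`/`start`/`end` columns
#' (1-based closed).
#' @param x object to coerce.
#' @param name optional track label.
#' @return `GRanges` track.
#' @export
as_track <- function(x, name = NULL) {
  if (inherits(x, "GRanges")) {
    gr <- BiocGenerics::sort(x, ignore.strand = TRUE)
    if (!is.null(name)) S4Vectors::metadata(gr)$track_name <- name
    return(gr)
  }
  if (is.data.frame(x)) {
    strand <- if ("strand" %in% names(x)) x$strand else "*"
    return(track(x$chrom, x$start, x$end, strand = strand, name = name))
  }
  stop("cannot coerce class '", class(x)[1], "' to a track")
}

#' Total track length
#'
#' Sum of interval widths, without merging overlaps (each interval counts its
#' own bases).
#' @param x a track (`GRanges`).
#' @return numeric total length in bp.
#' @export
track_length <- function(x) {
  sum(as.numeric(BiocGenerics::width(x)))
}

#' @rdname track
#' @param x a track.
#' @export
track_name <- function(x) S4Vectors::metadata(x)$track_name

# --- internal fast interval index -------------------------------------------
#
# A "cover index" holds, per chromosome, the reduced (disjoint, sorted)
# intervals of a track plus cumulative covered length, so that the number of
# covered bases within any [s, e] is computed by two findInterval lookups.
# This keeps permutation loops free of GRanges overhead.

.cover_index <- function(gr) {
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  sp <- split(red, as.character(GenomicRanges::seqnames(red)))
  lapply(sp, function(g) {
    st <- BiocGenerics::start(g); en <- BiocGenerics::end(g)
    o <- order(st)
    st <- st[o]; en <- en[o]
    list(start = st, end = en, cum = cumsum(as.numeric(en - st + 1)))
  })
}

# covered bases of the index in [1, x]; x vectorised
.covered_upto <- function(idx, x) {
  i <- findInterval(x, idx$start)
  below <- ifelse(i > 1, idx$cum[pmax(i - 1, 1)], 0)
  below[i == 0] <- 0
  partial <- numeric(length(x))
  inside <- i >= 1
  ii <- i[inside]
  partial[inside] <- pmax(0, pmin(x[inside], idx$end[ii]) - idx$start[ii] + 1)
  below + partial
}

# overlap length of query intervals [s, e] (same chromosome) with the index
.overlap_len <- function(idx, s, e) {
  if (is.null(idx)) return(numeric(length(s)))
  .covered_upto(idx, e) - .covered_upto(idx, s - 1)
}

# number of sorted points falling inside [s, e]; vectorised
.points_in <- function(points, s, e) {
  if (length(points) == 0L) return(integer(length(s)))
  findInterval(e, points) - findInterval(s - 1, points)
}

# plain-vector view of a track, used by permutation hot loops
.track_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}
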