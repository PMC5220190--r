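#' Read transcript models from a GFF3 annotation
#'
#' Parses a TAIR-style GFF3 and returns one transcript model per mRNA feature:
#' strand-aware TSS, translation start (AUG), transcript end, and whether a
#' 5'UTR is annotated.  Coordinates are returned 1-based closed, as in GFF3.
#' Transcripts without any CDS feature are skipped with a warning (they carry
#' no translation start).
#'
#' @param path GFF3 file. `gene`, `mRNA`, `five_prime_UTR` and `CDS` features
#'   are used; other feature types are ignored.
#' @return data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tss`, `aug`, `tes`, `has_5utr`, `is_protein_coding`.  `tss` is
#'   the upstream-most transcribed base (`start` on `+`, `end` on `-`);
#'   `has_5utr` is `TRUE` iff a `five_prime_UTR` feature is present (and then
#'   `tss != aug`).
#' @export
read_gff_transcripts <- function(path) {
  .validate_gff_lines(path)
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx <- gff[is_tx]
  if (length(tx) == 0L) stop("no mRNA/transcript features in ", path)
  tx_id <- as.character(tx$ID)
  parent_of <- function(gr) {
    p <- gr$Parent
    if (is.null(p)) rep(NA_character_, length(gr))
    else vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_, "")
  }
  gene_id <- parent_of(tx)
  gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]

  cds <- gff[type == "CDS"]
  utr5 <- gff[type == "five_prime_UTR"]
  cds_parent <- parent_of(cds)
  utr_parent <- parent_of(utr5)

  strand <- as.character(GenomicRanges::strand(tx))
  start <- BiocGenerics::start(tx)
  end <- BiocGenerics::end(tx)
  tss <- ifelse(strand == "-", end, start)
  tes <- ifelse(strand == "-", start, end)

  # translation start = CDS bound nearest the TSS
  cds_min <- tapply(BiocGenerics::start(cds), cds_parent, min)
  cds_max <- tapply(BiocGenerics::end(cds), cds_parent, max)
  aug <- ifelse(strand == "-", as.numeric(cds_max[tx_id]), as.numeric(cds_min[tx_id]))

  has_cds <- tx_id %in% cds_parent
  if (any(!has_cds)) {
    warning(sum(!has_cds), " transcript(s) without CDS skipped: ",
            paste(utils::head(tx_id[!has_cds], 3), collapse = ", "))
  }
  has_utr <- tx_id %in% utr_parent

  out <- data.frame(
    transcript_id = tx_id, gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = strand, tss = tss, aug = aug, tes = tes,
    has_5utr = has_utr, is_protein_coding = has_cds,
    stringsAsFactors = FALSE)
  out <- out[has_cds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.validate_gff_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1]]
    stop("malformed GFF line ", bad, " in ", path, " (expected 9 fields)")
  }
  invisible(TRUE)
}

#' Deduplicate transcripts to distinct TSS
#'
#' Keeps one transcript per unique (chrom, strand, tss) triple, mirroring the
#' construction of "distinct TSS" transcript sets.
#' @param transcripts transcript data frame from [read_gff_transcripts()].
#' @return subset of `transcripts`.
#' @export
distinct_tss <- function(transcripts) {
  key <- paste(transcripts$chrom, transcripts$strand, transcripts$tss)
  transcripts[!duplicated(key), , drop = FALSE]
}

#' Read a peak table
#'
#' Reads a BED-like file or a MACS-1.4 style peak table into a peak data frame.
#' "Height" (the summit pileup value used for filtering) comes from a
#' configurable column because peak callers differ in where they store it.
#'
#' @param path peak file.  Comment lines (`#`) and a single non-numeric header
#'   line are tolerated.
#' @param format `"bed"` (0-based half-open starts, default) or `"macs"`
#'   (1-based closed, as in MACS `.xls` tables).
#' @param height_col column index holding the height.  Default: column 6 for
#'   `"macs"` (the tag pileup column of MACS-1.4) and column 5 for `"bed"`
#'   (the score field).
#' @return data frame with columns `chrom`, `start`, `end` (1-based closed)
#'   and `height`, input order preserved.
#' @export
read_peaks <- function(path, format = c("bed", "macs"), height_col = NULL) {
  format <- match.arg(format)
  if (is.null(height_col)) height_col <- if (format == "macs") 6L else 5L
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      height = numeric(), stringsAsFactors = FALSE))
  }
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))) {
    lines <- lines[-1]  # header
  }
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      height = numeric(), stringsAsFactors = FALSE))
  }
  tab <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("peak table needs at least chrom/start/end columns")
  if (ncol(tab) < height_col) {
    stop("height column ", height_col, " missing (table has ", ncol(tab),
         " columns); set height_col")
  }
  start <- as.numeric(tab[[2]]); end <- as.numeric(tab[[3]])
  if (format == "bed") start <- start + 1  # BED is 0-based half-open
  bad <- which(!(start <= end) | is.na(start) | is.na(end))
  if (length(bad)) stop("peak row ", bad[1], ": start >= end after conversion")
  height <- as.numeric(tab[[height_col]])
  if (any(is.na(height))) stop("non-numeric height values in column ", height_col)
  if (any(height < 0)) stop("negative peak height")
  data.frame(chrom = as.character(tab[[1]]), start = start, end = end,
             height = height, stringsAsFactors = FALSE)
}

#' Filter peaks by height
#'
#' Retains peaks whose height is at least `min_height` and returns their
#' intervals as a track.  The conventional cutoff of 7 reflects the practice
#' of keeping only well-supported ChIP-Seq peaks as binding regions.
#'
#' @param peaks peak data frame from [read_peaks()] or [make_peaks()].
#' @param min_height minimum height, `>= 0` (default 7).
#' @return track (`GRanges`) of retained peak intervals.
#' @export
peak_filter <- function(peaks, min_height = 7) {
  stopifnot(min_height >= 0)
  keep <- peaks$height >= min_height
  kept <- peaks[keep, , drop = FALSE]
  gr <- track(kept$chrom, kept$start, kept$end, name = "peaks")
  gr
}

#' Read a chromatin-state map
#'
#' Reads a BED-like file whose 4th column is a state label in 1..9 and groups
#' domains per state.  Domains of distinct states must not overlap.
#'
#' @param path BED4 file (0-based half-open starts).
#' @return a `state_map` object: named list of per-state tracks under
#'   `$domains` (names `"1"`..`"9"`; absent states hold empty tracks).
#' @export
read_state_map <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("state map needs 4 BED columns (4th = state label)")
  lab <- suppressWarnings(as.integer(tab[[4]]))
  if (any(is.na(lab)) || any(lab < 1 | lab > 9)) {
    bad <- which(is.na(lab) | lab < 1 | lab > 9)[1]
    stop("state label outside 1..9 at row ", bad)
  }
  gr <- GenomicRanges::GRanges(tab[[1]],
                               IRanges::IRanges(as.numeric(tab[[2]]) + 1,
                                                as.numeric(tab[[3]])),
                               state = lab)
  gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
  state_map(split(gr, factor(gr$state, levels = 1:9)))
}

#' Construct a chromatin-state map
#'
#' @param domains named list (or `GRangesList`) of per-state tracks; names must
#'   be state labels in `1..9`.  Domains of different states must be disjoint.
#' @return `state_map` object.
#' @export
state_map <- function(domains) {
  domains <- as.list(domains)
  if (is.null(names(domains)) || any(!names(domains) %in% as.character(1:9)))
    stop("state labels must be in 1..9")
  full <- setNames(vector("list", 9), as.character(1:9))
  for (s in as.character(1:9)) {
    full[[s]] <- if (s %in% names(domains)) as_track(domains[[s]]) else
      GenomicRanges::GRanges()
  }
  all <- suppressWarnings(do.call(c, unname(full[lengths(full) > 0])))
  if (!is.null(all) && length(all)) {
    red <- GenomicRanges::reduce(all, ignore.strand = TRUE)
    if (track_length(red) != track_length(all))
      stop("domains of different chromatin states overlap")
  }
  structure(list(domains = full), class = "state_map")
}

#' @export
print.state_map <- function(x, ...) {
  n <- vapply(x$domains, length, 1L)
  len <- vapply(x$domains, track_length, 1)
  cat("chromatin state map: 9 states,", sum(n), "domains,",
      format(sum(len), big.mark = ","), "bp\n")
  for (s in names(x$domains)) {
    cat(sprintf("  state %s: %5d domains %12.0f bp\n", s, n[[s]], len[[s]]))
  }
  invisible(x)
}

#' Write a chromatin-state map as BED4
#' @param x `state_map`.
#' @param path output file.
#' @export
write_state_map <- function(x, path) {
  rows <- list()
  for (s in names(x$domains)) {
    g <- x$domains[[s]]
    if (length(g) == 0) next
    rows[[s]] <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                            start = BiocGenerics::start(g) - 1,
                            end = BiocGenerics::end(g),
                            state = s, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$chrom, tab$start), ]
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a track as BED
#'
#' @param x track (`GRanges`), 1-based closed internally; written 0-based
#'   half-open.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                    start = BiocGenerics::start(x) - 1,
                    end = BiocGenerics::end(x), stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file as a track
#' @param path BED file.
#' @return track (`GRanges`).
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  track(tab[[1]], as.numeric(tab[[2]]) + 1, as.numeric(tab[[3]]))
}
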