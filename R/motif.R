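# Position-weight-matrix construction and scanning with min-max normalised
# scores.  The default weight function is log-odds with background-
# proportional pseudocounts; it is a plug-in so alternative weighting schemes
# can be substituted without touching the scanner.

.DNA <- c("A", "C", "G", "T")
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"), N = .DNA)

#' Position frequency matrix from aligned sites or an IUPAC consensus
#'
#' @param x either a 4 x L numeric count matrix (rows A, C, G, T) or a
#'   character vector of equal-length aligned site sequences.
#' @return `pfm` object (4 x L count matrix with equal column sums).
#' @export
pfm <- function(x) {
  if (is.character(x)) {
    L <- unique(nchar(x))
    if (length(L) != 1) stop("aligned sites must have equal length")
    m <- matrix(0, 4, L, dimnames = list(.DNA, NULL))
    for (s in x) {
      b <- strsplit(toupper(s), "")[[1]]
      if (any(!b %in% .DNA)) stop("sites must be ACGT only")
      for (j in seq_len(L)) m[b[j], j] <- m[b[j], j] + 1
    }
    x <- m
  }
  x <- as.matrix(x)
  if (nrow(x) != 4) stop("pfm must have 4 rows (A, C, G, T)")
  if (any(x < 0)) stop("pfm counts must be non-negative")
  cs <- colSums(x)
  if (any(cs == 0)) stop("pfm has an all-zero column")
  if (max(cs) - min(cs) > 1e-6 * max(cs))
    stop("pfm column sums differ (not the same number of aligned sites)")
  rownames(x) <- .DNA
  structure(x, class = c("pfm", class(x)))
}

#' Reconstructed TEIL position frequency matrix
#'
#' The TEIL octamer motif (consensus `AYGWAYCT`; Y = C/T, W = A/T) is the
#' binding site of the tobacco EIN3 homolog.  The original site counts are not
#' redistributable, so this PFM is a \emph{synthetic reconstruction} from the
#' consensus: `n_sites` aligned sites with degenerate positions split evenly
#' between their allowed bases.
#'
#' @param n_sites number of pseudo-aligned sites (default 20, even).
#' @return `pfm` object, 4 x 8.
#' @export
teil_pfm <- function(n_sites = 20) {
  stopifnot(n_sites >= 2, n_sites %% 2 == 0)
  consensus_pfm("AYGWAYCT", n_sites)
}

#' PFM from an IUPAC consensus
#' @param consensus IUPAC string.
#' @param n_sites sites per column; degenerate columns split counts evenly.
#' @return `pfm` object.
#' @export
consensus_pfm <- function(consensus, n_sites = 20) {
  b <- strsplit(toupper(consensus), "")[[1]]
  if (any(!b %in% names(.IUPAC))) stop("unknown IUPAC code in consensus")
  m <- matrix(0, 4, length(b), dimnames = list(.DNA, NULL))
  for (j in seq_along(b)) {
    allowed <- .IUPAC[[b[j]]]
    if (n_sites %% length(allowed) != 0)
      stop("n_sites must be divisible by the degeneracy of every column")
    m[allowed, j] <- n_sites / length(allowed)
  }
  pfm(m)
}

#' Read a PFM from a whitespace-separated 4-row count file
#'
#' Format: an optional `#`-comment header naming the row order, then four
#' rows of counts (A, C, G, T).
#' @param path input file.
#' @return `pfm` object.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  pfm(m)
}

#' Build a PWM with min-max score normalisation
#'
#' Default weights are log-odds with background-proportional pseudocounts:
#' \deqn{w(b,j) = \ln\frac{n(b,j) + p \cdot q_b}{(N + p) \cdot q_b}}
#' where `n(b,j)` are the PFM counts, `N` the column sum, `q` the background
#' base probabilities and `p` the pseudocount.  Raw window scores (sums of one
#' weight per column) are normalised to \[0,1\] by the column-wise minimum and
#' maximum achievable sums, so a threshold such as 0.91 is expressed on the
#' normalised scale.
#'
#' @param x a `pfm`.
#' @param background base probabilities (A, C, G, T), must sum to 1; default
#'   uniform.
#' @param pseudocount positive pseudocount (default 1).
#' @param threshold default normalised-score cutoff stored with the model
#'   (default 0.91).
#' @param weight_fun optional plug-in `function(counts, background,
#'   pseudocount)` returning a 4 x L weight matrix, replacing the default.
#' @return `pwm_model` object: `$weights`, `$s_min`, `$s_max`, `$threshold`,
#'   `$background`, `$pseudocount`, `$L`.
#' @export
pwm_from_pfm <- function(x, background = rep(0.25, 4), pseudocount = 1,
                         threshold = 0.91, weight_fun = NULL) {
  stopifnot(inherits(x, "pfm"), pseudocount > 0,
            length(background) == 4, all(background > 0))
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  counts <- unclass(x)
  if (is.null(weight_fun)) {
    N <- colSums(counts)
    w <- log((counts + pseudocount * background) /
               rep((N + pseudocount), each = 4) / background)
  } else {
    w <- weight_fun(counts, background, pseudocount)
  }
  s_min <- sum(apply(w, 2, min))
  s_max <- sum(apply(w, 2, max))
  if (s_max - s_min < 1e-12)
    stop("degenerate PWM: identical minimal and maximal scores")
  structure(list(weights = w, s_min = s_min, s_max = s_max,
                 threshold = threshold, background = background,
                 pseudocount = pseudocount, L = ncol(w)),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("PWM model: width %d, raw score range [%.4g, %.4g], threshold %.2f\n",
              x$L, x$s_min, x$s_max, x$threshold))
  invisible(x)
}

#' Min-max normalised PWM score of one window
#'
#' @param pwm a `pwm_model`.
#' @param seq DNA string of length `pwm$L` (ACGT; any other letter makes the
#'   score undefined and returns `NA`).
#' @return normalised score `(raw - s_min) / (s_max - s_min)` in \[0, 1\], or
#'   `NA` for windows with ambiguous bases.
#' @export
score_normalized <- function(pwm, seq) {
  vapply(seq, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    if (length(b) != pwm$L) stop("sequence length must equal PWM width")
    i <- match(b, .DNA)
    if (anyNA(i)) return(NA_real_)
    raw <- sum(pwm$weights[cbind(i, seq_len(pwm$L))])
    (raw - pwm$s_min) / (pwm$s_max - pwm$s_min)
  }, numeric(1), USE.NAMES = FALSE)
}

# integer codes 1..4 for A,C,G,T, NA otherwise
.encode_dna <- function(s) {
  match(strsplit(toupper(as.character(s)), "")[[1]], .DNA)
}

# normalised scores of every width-L window of one coded sequence (both
# strand variants); windows containing NA codes get NA
.window_scores <- function(code, pwm, both_strands) {
  L <- pwm$L
  n <- length(code) - L + 1
  if (n < 1) return(list(fwd = numeric(0), rev = numeric(0)))
  raw <- numeric(n)
  na <- logical(n)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n - 1)]
    na <- na | is.na(cj)
    wj <- pwm$weights[, j]
    raw <- raw + ifelse(is.na(cj), 0, wj[cj])
  }
  fwd <- (raw - pwm$s_min) / (pwm$s_max - pwm$s_min)
  fwd[na] <- NA_real_
  rev <- NULL
  if (both_strands) {
    # score of the reverse complement of each window with the same PWM ==
    # score of the window with the complement-reversed weight matrix
    wrc <- pwm$weights[4:1, L:1, drop = FALSE]
    raw2 <- numeric(n)
    for (j in seq_len(L)) {
      cj <- code[j:(j + n - 1)]
      wj <- wrc[, j]
      raw2 <- raw2 + ifelse(is.na(cj), 0, wj[cj])
    }
    rev <- (raw2 - pwm$s_min) / (pwm$s_max - pwm$s_min)
    rev[na] <- NA_real_
  }
  list(fwd = fwd, rev = rev)
}

#' Scan sequences for PWM hits
#'
#' Slides a width-`L` window with step 1 over every sequence and counts
#' windows whose min-max normalised score reaches the threshold.  With
#' `both_strands` a window is a hit if either orientation passes; each
#' position is counted once.  Windows containing ambiguous bases are excluded
#' from both the position and the hit count; sequences shorter than `L`
#' contribute no positions.
#'
#' @param pwm a `pwm_model`.
#' @param sequences `DNAStringSet`, character vector, or FASTA path.
#' @param threshold normalised cutoff; defaults to `pwm$threshold`.
#' @param both_strands scan both orientations (default `TRUE`).
#' @return `scan_result` object: `$positions`, `$hits`, `$density`
#'   (`hits/positions`, `NA` when no scorable position exists), and
#'   `$per_sequence` data frame.
#' @export
scan_pwm <- function(pwm, sequences, threshold = NULL, both_strands = TRUE) {
  if (is.null(threshold)) threshold <- pwm$threshold
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  seqs <- as.character(sequences)
  if (length(seqs) == 0) stop("sequences must be non-empty")
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  pos <- integer(length(seqs)); hit <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    sc <- .window_scores(.encode_dna(seqs[i]), pwm, both_strands)
    ok <- !is.na(sc$fwd)
    pos[i] <- sum(ok)
    if (both_strands) {
      hit[i] <- sum(ok & (sc$fwd >= threshold | sc$rev >= threshold))
    } else {
      hit[i] <- sum(ok & sc$fwd >= threshold)
    }
  }
  positions <- sum(pos); hits <- sum(hit)
  structure(list(positions = positions, hits = hits,
                 density = if (positions > 0) hits / positions else NA_real_,
                 threshold = threshold, both_strands = both_strands,
                 per_sequence = data.frame(name = nm, positions = pos,
                                           hits = hit, stringsAsFactors = FALSE)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("PWM scan: %d hits / %d positions (density %.4g) at threshold %.2f\n",
              x$hits, x$positions,
              if (is.na(x$density)) NA else x$density, x$threshold))
  invisible(x)
}

#' Compare site densities between two region classes across intervals
#'
#' For each upstream interval, a Fisher exact test contrasts hit/miss window
#' counts between the two classes (e.g. chromatin state 4 versus states 1/2),
#' with Bonferroni-corrected significance flags at `alpha/n_tests` and
#' `alpha2/n_tests`.
#'
#' @param scans_a,scans_b named lists of `scan_result`, one per interval, with
#'   matching names/order (the same interval definitions).
#' @param n_tests Bonferroni divisor (default: number of intervals).
#' @param alpha,alpha2 significance levels before correction (0.05, 0.01).
#' @return data frame: interval, hits/positions per class, densities,
#'   `p` (two-sided Fisher), `significant` (`p < alpha/n_tests`),
#'   `significant2` (`p < alpha2/n_tests`).  Intervals with zero scorable
#'   positions in either class get `NA` p with a note.
#' @export
density_compare <- function(scans_a, scans_b, n_tests = NULL,
                            alpha = 0.05, alpha2 = 0.01) {
  stopifnot(length(scans_a) == length(scans_b))
  if (is.null(n_tests)) n_tests <- length(scans_a)
  nm <- names(scans_a)
  if (is.null(nm)) nm <- paste0("interval", seq_along(scans_a))
  rows <- lapply(seq_along(scans_a), function(i) {
    a <- scans_a[[i]]; b <- scans_b[[i]]
    if (a$positions == 0 || b$positions == 0) {
      return(data.frame(interval = nm[i], hits_a = a$hits, positions_a = a$positions,
                        hits_b = b$hits, positions_b = b$positions,
                        density_a = a$density, density_b = b$density,
                        p = NA_real_, significant = NA, significant2 = NA,
                        note = "no scorable positions", stringsAsFactors = FALSE))
    }
    p <- fisher_exact(matrix(c(a$hits, a$positions - a$hits,
                               b$hits, b$positions - b$hits),
                             2, byrow = TRUE))$p
    data.frame(interval = nm[i], hits_a = a$hits, positions_a = a$positions,
               hits_b = b$hits, positions_b = b$positions,
               density_a = a$density, density_b = b$density, p = p,
               significant = p < alpha / n_tests,
               significant2 = p < alpha2 / n_tests,
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Density-versus-threshold calibration curve
#'
#' Generic threshold-calibration routine: compares hit density in a foreground
#' sequence set to a background set over a grid of normalised thresholds, to
#' choose a cutoff where the foreground is enriched while the background
#' (false positive) rate stays permissive.
#'
#' @param pwm a `pwm_model`.
#' @param foreground,background sequence sets (as in [scan_pwm()]).
#' @param thresholds numeric grid, default `seq(0.80, 1.00, by = 0.01)`.
#' @param both_strands passed to [scan_pwm()].
#' @return data frame: threshold, density_fg, density_bg, ratio.
#' @export
density_threshold_curve <- function(pwm, foreground, background,
                                    thresholds = seq(0.80, 1.00, by = 0.01),
                                    both_strands = TRUE) {
  rows <- lapply(thresholds, function(th) {
    fg <- scan_pwm(pwm, foreground, threshold = th, both_strands = both_strands)
    bg <- scan_pwm(pwm, background, threshold = th, both_strands = both_strands)
    data.frame(threshold = th, density_fg = fg$density, density_bg = bg$density,
               ratio = fg$density / bg$density)
  })
  do.call(rbind, rows)
}
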