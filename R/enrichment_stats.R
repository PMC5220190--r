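# Exact 2x2 statistics (Fisher, EASE), Benjamini-Hochberg step-up, gene-list
# compilation by chromatin state, and the two-list GO-term comparison.
#
# fisher_exact(), ease_score() and bh_adjust() are authored here (the exact
# hypergeometric tail and the EASE jackknife are central to the analysis);
# stats::fisher.test and stats::p.adjust are used only as independent oracles
# in the test suite.

#' Fisher's exact test of a 2x2 contingency table
#'
#' Exact hypergeometric test.  Layout: rows = criterion 1 (e.g. the two gene
#' lists), columns = criterion 2 (e.g. in-term / not-in-term):
#' `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#'
#' @param x 2x2 non-negative integer matrix (or vector `c(a, b, c, d)` read
#'   row-wise).
#' @param alternative `"two.sided"` (default; sums probabilities of all tables
#'   at most as probable as the observed one), `"greater"` or `"less"` (tail
#'   on the top-left cell `a`).
#' @return list with `p`, `odds_ratio` (sample odds ratio `ad/bc`), and the
#'   table.  An empty row or column margin gives `p = 1` with a warning.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))$p  # ~1.08e-5
#' @export
fisher_exact <- function(x, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(x)) x <- matrix(x, 2, byrow = TRUE)
  if (any(dim(x) != 2) || any(x < 0) || any(x != round(x)))
    stop("need a 2x2 table of non-negative integers")
  a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  if (a + b + c + d == 0) stop("empty table")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    warning("empty margin: p = 1")
    return(list(p = 1, odds_ratio = NaN, table = x))
  }
  m1 <- a + b            # row 1 margin
  m2 <- c + d            # row 2 margin
  n1 <- a + c            # column 1 margin
  supp <- max(0, n1 - m2):min(n1, m1)
  probs <- dhyper(supp, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[supp >= a]),
              less = sum(probs[supp <= a]))
  or <- (as.numeric(a) * as.numeric(d)) / (as.numeric(b) * as.numeric(c))
  list(p = min(p, 1), odds_ratio = or, table = x)
}

#' EASE score: conservative one-sided Fisher enrichment p-value
#'
#' The one-gene jackknife of the one-sided (enrichment) Fisher exact test:
#' the term-positive count in the query list is reduced by one before the
#' test, which penalises terms supported by very few genes.
#'
#' @param x 2x2 table as in [fisher_exact()], with `a = x[1,1]` the
#'   term-positive count of the query list.
#' @return p-value; `a = 0` returns 1.
#' @export
ease_score <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, 2, byrow = TRUE)
  a <- x[1, 1]
  if (a < 1) return(1)
  x[1, 1] <- a - 1
  # the jackknife can empty a margin by construction; p = 1 then, silently
  suppressWarnings(fisher_exact(x, alternative = "greater")$p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Compile state-exclusive gene lists from binding regions
#'
#' Links every region to the genes whose upstream `window` it overlaps
#' ([link_genes()]), flags each gene by the chromatin states its linked
#' regions touch, and returns the two exclusive lists: genes whose regions
#' touch states 1 or 2 but never state 4, and genes whose regions touch state
#' 4 but never states 1 or 2.  Genes qualifying for both lists are removed
#' from both.
#'
#' @param x track of binding regions.
#' @param states_map a `state_map`.
#' @param transcripts transcript data frame.
#' @param window linkage window in the promoter +1 convention, default
#'   `c(-3500, 1)`.
#' @return list with character vectors `states12` and `state4` (disjoint by
#'   construction) and the per-gene flag table `$flags`.
#' @export
compile_state_gene_lists <- function(x, states_map, transcripts,
                                     window = c(-3500, 1)) {
  links <- link_genes(x, transcripts, window = window)
  if (length(links) == 0) {
    return(list(states12 = character(0), state4 = character(0),
                flags = data.frame(gene_id = character(0),
                                   in12 = logical(0), in4 = logical(0))))
  }
  dom12 <- GenomicRanges::reduce(c(GenomicRanges::granges(states_map$domains[["1"]]),
                                   GenomicRanges::granges(states_map$domains[["2"]])),
                                 ignore.strand = TRUE)
  dom4 <- GenomicRanges::reduce(GenomicRanges::granges(states_map$domains[["4"]]),
                                ignore.strand = TRUE)
  idx12 <- .cover_index(dom12)
  idx4 <- .cover_index(dom4)
  df <- .track_df(x)
  ov_flag <- function(idx, i) {
    out <- logical(length(i))
    ch <- df$chrom[i]
    for (u in unique(ch)) {
      j <- ch == u
      out[j] <- .overlap_len(idx[[u]], df$start[i][j], df$end[i][j]) > 0
    }
    out
  }
  genes <- names(links)
  in12 <- vapply(links, function(i) any(ov_flag(idx12, i)), TRUE)
  in4 <- vapply(links, function(i) any(ov_flag(idx4, i)), TRUE)
  flags <- data.frame(gene_id = genes, in12 = unname(in12), in4 = unname(in4),
                      stringsAsFactors = FALSE)
  list(states12 = sort(genes[in12 & !in4]),
       state4 = sort(genes[in4 & !in12]),
       flags = flags)
}

#' Read / write gene-to-GO annotation tables
#'
#' Tab-separated with columns `gene_id`, `term_id`, `vocabulary`
#' (`BP`/`MF`/`CC`); one row per direct annotation.
#' @param path TSV file.
#' @return data frame.
#' @export
read_go_annotations <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "vocabulary")
  if (!all(need %in% names(tab))) stop("annotation TSV needs columns: ",
                                       paste(need, collapse = ", "))
  tab
}

#' @rdname read_go_annotations
#' @param annotations annotation data frame.
#' @export
write_go_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-list GO-term comparison
#'
#' Reproduces the two-stage scheme: (1) per list, \emph{robust} terms are
#' those annotating more than `min_fraction` of the list's genes with a
#' BH-adjusted EASE enrichment p-value (against the background universe)
#' below `fdr`; (2) the union of robust terms is then compared between the
#' two lists with a two-sided Fisher exact test on the
#' lists-by-(in-term/not-in-term) table, BH-adjusted, flagged at `fdr`.
#'
#' @param listA,listB character vectors of gene ids.
#' @param annotations annotation data frame (`gene_id`, `term_id`,
#'   `vocabulary`); only direct annotations are used.
#' @param background background gene universe; default: all genes in the
#'   annotation table plus both lists.
#' @param min_fraction robust-term fraction threshold (default 0.03).
#' @param fdr FDR threshold for both stages (default 0.05).
#' @return data frame (class `term_comparison`), one row per term in the
#'   robust union: per-list counts and fractions, per-list enrichment EASE p
#'   and BH values, robust flags, between-list Fisher `p_lists`,
#'   `p_lists_adj`, `enriched_in` (`"A"`/`"B"`), `significant`.
#' @export
go_compare <- function(listA, listB, annotations, background = NULL,
                       min_fraction = 0.03, fdr = 0.05) {
  listA <- unique(as.character(listA)); listB <- unique(as.character(listB))
  if (is.null(background)) {
    background <- unique(c(annotations$gene_id, listA, listB))
  }
  background <- unique(as.character(background))
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  terms <- unique(ann[, c("term_id", "vocabulary")])
  term_genes <- split(ann$gene_id, ann$term_id)
  nA <- length(listA); nB <- length(listB); nU <- length(background)
  if (nA == 0 || nB == 0) stop("both gene lists must be non-empty")

  enrich <- function(genes_in_term, lst, n_lst) {
    a <- sum(lst %in% genes_in_term)
    m <- length(unique(genes_in_term))
    # list vs rest-of-universe layout
    tab <- matrix(c(a, n_lst - a, m - a, (nU - n_lst) - (m - a)), 2, byrow = TRUE)
    list(a = a, p = ease_score(tab))
  }
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tid <- terms$term_id[i]
    g <- unique(term_genes[[tid]])
    eA <- enrich(g, listA, nA); eB <- enrich(g, listB, nB)
    data.frame(term_id = tid, vocabulary = terms$vocabulary[i],
               genes_A = eA$a, genes_B = eB$a,
               fraction_A = eA$a / nA, fraction_B = eB$a / nB,
               p_enrich_A = eA$p, p_enrich_B = eB$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$genes_A + tab$genes_B > 0, , drop = FALSE]  # absent from both
  if (nrow(tab) == 0) {
    out <- cbind(tab, p_enrich_A_adj = numeric(0), p_enrich_B_adj = numeric(0),
                 robust_A = logical(0), robust_B = logical(0),
                 p_lists = numeric(0), p_lists_adj = numeric(0),
                 enriched_in = character(0), significant = logical(0))
    class(out) <- c("term_comparison", class(out))
    return(out)
  }
  tab$p_enrich_A_adj <- bh_adjust(tab$p_enrich_A)
  tab$p_enrich_B_adj <- bh_adjust(tab$p_enrich_B)
  tab$robust_A <- tab$fraction_A > min_fraction & tab$p_enrich_A_adj < fdr
  tab$robust_B <- tab$fraction_B > min_fraction & tab$p_enrich_B_adj < fdr
  keep <- tab$robust_A | tab$robust_B
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) > 0) {
    tab$p_lists <- vapply(seq_len(nrow(tab)), function(i) {
      fisher_exact(matrix(c(tab$genes_A[i], nA - tab$genes_A[i],
                            tab$genes_B[i], nB - tab$genes_B[i]),
                          2, byrow = TRUE))$p
    }, 1)
    tab$p_lists_adj <- bh_adjust(tab$p_lists)
    tab$enriched_in <- ifelse(tab$fraction_A >= tab$fraction_B, "A", "B")
    tab$significant <- tab$p_lists_adj < fdr
  } else {
    tab$p_lists <- numeric(0); tab$p_lists_adj <- numeric(0)
    tab$enriched_in <- character(0); tab$significant <- logical(0)
  }
  rownames(tab) <- NULL
  class(tab) <- c("term_comparison", class(tab))
  tab
}
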