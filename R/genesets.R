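# DEG significance filtering and gene-set overlap enrichment.

#' Filter a DEG table into significant up/down gene sets
#'
#' A gene is significant iff its adjusted p-value is present and strictly
#' below `fdr_threshold` AND `|log2fc|` is strictly above `lfc_threshold`
#' (both inequalities strict, matching the printed criteria `|log2 FC| > 1`
#' and `FDR < 0.05`).  Genes with missing `padj` are non-significant — the
#' convention of independent-filtering output, where untestable genes get
#' `NA` adjusted p-values.
#'
#' @param table DEG data frame from [read_deg_table()] (`gene_id`, `log2fc`,
#'   `pvalue`, `padj`).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 1).
#' @param fdr_threshold Adjusted-p threshold (default 0.05).
#' @return Object of class `deg_sets`: list with `up`, `down` (character
#'   vectors of gene ids partitioned by the sign of `log2fc`),
#'   `all_significant` (their union) and `thresholds`.
#' @export
filter_degs <- function(table, lfc_threshold = 1.0, fdr_threshold = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(table)))
  sig <- !is.na(table$padj) & table$padj < fdr_threshold &
    abs(table$log2fc) > lfc_threshold
  up <- table$gene_id[sig & table$log2fc > 0]
  down <- table$gene_id[sig & table$log2fc < 0]
  structure(
    list(up = up, down = down, all_significant = c(up, down),
         thresholds = c(lfc = lfc_threshold, fdr = fdr_threshold)),
    class = "deg_sets"
  )
}

#' @export
print.deg_sets <- function(x, ...) {
  cat(sprintf("<deg_sets> %d up, %d down (|log2fc| > %g, padj < %g)\n",
              length(x$up), length(x$down),
              x$thresholds[["lfc"]], x$thresholds[["fdr"]]))
  invisible(x)
}

#' Log-space upper-tail hypergeometric probability
#'
#' Natural log of `P(X >= k)` where `X` is the overlap of two fixed-size
#' sets drawn at random from a universe of `n_universe` genes:
#' `sum_{i=k}^{min(n_a, n_b)} C(n_a, i) C(N - n_a, n_b - i) / C(N, n_b)`.
#' Computed with log-gamma terms combined by log-sum-exp, so probabilities
#' far below 1e-300 are representable on the log scale.
#'
#' @param k Overlap count (>= 0).
#' @param n_a,n_b Set sizes.
#' @param n_universe Universe size `N >= max(n_a, n_b)`.
#' @return The natural-log probability (0 when the tail is certain).
#' @export
log_hyper_tail <- function(k, n_a, n_b, n_universe) {
  stopifnot(k >= 0, n_a >= 0, n_b >= 0, n_universe >= max(n_a, n_b))
  lo <- max(0, n_a + n_b - n_universe)  # smallest feasible overlap
  hi <- min(n_a, n_b)
  if (k > hi) return(-Inf)              # impossible tail: probability 0
  if (k <= lo) return(0)                # certain tail: probability 1
  i <- k:hi
  terms <- lchoose(n_a, i) + lchoose(n_universe - n_a, n_b - i) -
    lchoose(n_universe, n_b)
  m <- max(terms)
  min(m + log(sum(exp(terms - m))), 0)
}

#' Overlap statistics for two gene sets
#'
#' Overlap count `k`, representation factor `k / (n_a n_b / N)` (observed
#' overlap over the overlap expected by chance), and the exact upper-tail
#' hypergeometric probability of an overlap at least as large, in natural
#' log space (see [log_hyper_tail()]).  The universe size `N` must be given
#' explicitly: there is no defensible default, and silently assuming one
#' would fabricate enrichment.
#'
#' @param set_a,set_b Character vectors of gene ids (duplicates ignored).
#' @param n_universe Universe size; must be at least `|set_a U set_b|`.
#' @return Object of class `overlap_result`: list with `k`, `n_a`, `n_b`,
#'   `n_universe`, `representation_factor` (`NA` when either set is empty),
#'   `log_p_upper` (0, i.e. p = 1, when either set is empty) and `shared`
#'   (the intersecting gene ids).
#' @export
overlap_stats <- function(set_a, set_b, n_universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  n_a <- length(set_a)
  n_b <- length(set_b)
  n_union <- length(union(set_a, set_b))
  if (n_universe < n_union) {
    stop("n_universe (", n_universe, ") smaller than |set_a U set_b| (",
         n_union, ")")
  }
  shared <- intersect(set_a, set_b)
  k <- length(shared)
  if (n_a == 0 || n_b == 0) {
    rf <- NA_real_
    lp <- 0
  } else {
    rf <- k * n_universe / (n_a * n_b)
    lp <- log_hyper_tail(k, n_a, n_b, n_universe)
  }
  structure(
    list(k = k, n_a = n_a, n_b = n_b, n_universe = n_universe,
         representation_factor = rf, log_p_upper = lp, shared = shared),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> k = %d of (%d, %d) in N = %d; representation factor = %.3g; log10 p_upper = %.3f\n",
    x$k, x$n_a, x$n_b, x$n_universe, x$representation_factor,
    x$log_p_upper / log(10)))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' `adj_i = min_{j >= i} (p_j * m / j)` clipped to 1, returned in input
#' order.  Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
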