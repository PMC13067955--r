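#' Hypergeometric probability mass
#'
#' P(X = k): the probability of drawing exactly `k` category members in a
#' selection of `n` from a universe of `N` genes of which `K` belong to
#' the category. Arguments outside the support return 0.
#'
#' @param N Universe size.
#' @param K Category size in the universe (0 <= K <= N).
#' @param n Selection size (0 <= n <= N).
#' @param k Observed category count in the selection.
#' @return Probability in \[0, 1\].
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  if (K < 0 || K > N || n < 0 || n > N || N < 0)
    stop("require 0 <= K <= N and 0 <= n <= N")
  if (k < max(0, n - (N - K)) || k > min(K, n)) return(0)
  stats::dhyper(k, K, N - K, n)
}

#' Fold change of a category in a selection
#'
#' `(k/n) / (K/N)`: the category's frequency in the selection relative to
#' its frequency in the universe.
#'
#' @inheritParams hypergeom_pmf
#' @return Non-negative scalar.
#' @export
fold_change <- function(k, n, K, N) {
  if (n <= 0 || K <= 0) stop("fold change needs n > 0 and K > 0")
  (k / n) / (K / N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over/under-representation of categories in a selection
#'
#' For each category with more than `min_category` genes in the universe,
#' tests both tails of the hypergeometric distribution: over-
#' representation `P(X >= k)` and under-representation `P(X <= k)`. The
#' smaller tail is reported with its direction (`+` iff the fold change
#' exceeds 1; ties count as `-`). BH adjustment runs across the tested
#' categories only — sparse categories are excluded before correction.
#' A two-tailed Fisher exact option is available for GO-style analyses.
#'
#' @param selection Character vector of gene ids (subset of `universe`).
#' @param universe Character vector of gene ids defining N.
#' @param annotations An [annotation_map()].
#' @param min_category Universe-count threshold below which a category is
#'   not tested (default 10, i.e. categories with more than 10 genes).
#' @param method `"hypergeometric"` (one-tailed pair, default) or
#'   `"fisher"` (two-tailed).
#' @return Data frame with columns `category`, `N`, `K`, `n`, `k`, `fc`,
#'   `direction`, `p`, `q`, sorted by `q`.
#' @export
enrich_categories <- function(selection, universe, annotations,
                              min_category = 10L,
                              method = c("hypergeometric", "fisher")) {
  method <- match.arg(method)
  selection <- unique(as.character(selection))
  universe <- unique(as.character(universe))
  if (length(selection) == 0) stop("empty selection")
  if (!all(selection %in% universe)) stop("selection must be a subset of universe")
  g2c <- annotations$gene_to_categories
  uni_cats <- g2c[intersect(universe, names(g2c))]
  cat_counts <- table(unlist(uni_cats, use.names = FALSE))
  tested <- names(cat_counts)[cat_counts > min_category]
  if (length(tested) == 0)
    return(data.frame(category = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), fc = numeric(),
                      direction = character(), p = numeric(), q = numeric()))
  sel_cats <- g2c[intersect(selection, names(g2c))]
  sel_counts <- table(factor(unlist(sel_cats, use.names = FALSE), levels = tested))
  N <- length(universe); n <- length(selection)
  rows <- lapply(tested, function(cat) {
    K <- as.integer(cat_counts[[cat]])
    k <- as.integer(sel_counts[[cat]])
    fc <- fold_change(k, n, K, N)
    if (method == "fisher") {
      p <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - (n - k)), 2))$p.value
      direction <- if (fc > 1) "+" else "-"
    } else {
      p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      p_under <- stats::phyper(k, K, N - K, n)
      if (fc > 1) { p <- p_over; direction <- "+" }
      else { p <- p_under; direction <- "-" }
    }
    data.frame(category = cat, N = N, K = K, n = n, k = k, fc = fc,
               direction = direction, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$q, out$p, out$category), ]
}

#' Enrichment of categories among genes surviving data cleaning
#'
#' Treats the cleaned gene set as the selection and the pre-cleaning set
#' as the universe, so categories preferentially retained come out `+`
#' and categories preferentially removed come out `-`.
#'
#' @param before Character vector of gene ids before cleaning (universe).
#' @param after Character vector of gene ids after cleaning (must be a
#'   subset of `before`).
#' @inheritParams enrich_categories
#' @return The [enrich_categories()] data frame.
#' @export
cleaning_enrichment <- function(before, after, annotations,
                                min_category = 10L) {
  if (!all(after %in% before)) stop("after must be a subset of before")
  enrich_categories(after, before, annotations, min_category)
}
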