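#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' background of `N` of which `K` carry the term, the probability of seeing
#' at least the observed overlap `k`. Computed in log space via the
#' cumulative distribution.
#'
#' @param k Observed overlap (0 <= k <= min(n, K)).
#' @param n Query size.
#' @param K Term size in the background.
#' @param N Background size.
#' @return Probability in (0, 1]; vectorized over its arguments.
#' @examples
#' hypergeom_tail(5, 10, 5, 20)   # 3003/184756
#' @export
hypergeom_tail <- function(k, n, K, N) {
  bad <- k < 0 | k > pmin(n, K) | n > N | K > N | n < 0 | K < 0
  if (any(bad)) stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1; preserves the
#' order of the raw p-values.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a flat gene-to-term annotation map from TSV
#'
#' @param path 2-column TSV (`gene_id`, `term_id`), optional further
#'   columns ignored.
#' @param term_names_path Optional TSV with columns `term_id`, `name` (and
#'   optionally `namespace`).
#' @return A named list term_id -> character vector of gene ids, with the
#'   optional metadata attached as attribute `term_info`.
#' @export
read_term_map_tsv <- function(path, term_names_path = NULL) {
  tab <- utils::read.delim(path, comment.char = "#")
  terms <- split(as.character(tab[[1]]), as.character(tab[[2]]))
  terms <- lapply(terms, unique)
  if (!is.null(term_names_path))
    attr(terms, "term_info") <- utils::read.delim(term_names_path,
                                                  comment.char = "#")
  terms
}

#' Hypergeometric over-representation analysis
#'
#' For every term with at least one query member, tests whether the query
#' set overlaps the term more than expected from uniform draws out of the
#' background; p-values are BH-adjusted across the tested terms. The rich
#' factor is the fraction `k / K` of the term's background genes hit by the
#' query. Significance is flagged at `p <= alpha` (inclusive) on the raw
#' p-value, or on the adjusted one with `use_adjusted = TRUE`.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of gene ids (the tested universe).
#' @param terms Named list term_id -> gene ids, as from
#'   [read_term_map_tsv()].
#' @param alpha Significance level (default 0.05).
#' @param use_adjusted Flag significance on the BH-adjusted p-value.
#' @return Data frame `term`, `k`, `n`, `K`, `N`, `rich_factor`, `p`,
#'   `padj`, `significant`, sorted by increasing `p`.
#' @export
enrich <- function(query, background, terms, alpha = 0.05,
                   use_adjusted = FALSE) {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  if (!length(query)) {
    warning("empty query set")
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), rich_factor = numeric(),
                      p = numeric(), padj = numeric(),
                      significant = logical()))
  }
  terms <- lapply(terms, function(g) intersect(unique(g), background))
  terms <- terms[lengths(terms) > 0]
  N <- length(background)
  n <- length(query)
  K <- lengths(terms)
  k <- vapply(terms, function(g) sum(query %in% g), 0L)
  keep <- k >= 1
  res <- data.frame(term = names(terms)[keep], k = k[keep], n = n,
                    K = K[keep], N = N,
                    rich_factor = k[keep] / K[keep],
                    p = hypergeom_tail(k[keep], n, K[keep], N))
  res$padj <- bh_adjust(res$p)
  res$significant <- (if (use_adjusted) res$padj else res$p) <= alpha
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
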