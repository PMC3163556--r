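# Hypergeometric over-representation analysis with Benjamini-Hochberg
# adjustment and deterministic ranking.

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for a hypergeometric draw of \code{n} from a universe of
#' \code{N} containing \code{K} successes:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' Computed in log space (log-binomials combined by log-sum-exp), so it is
#' stable for universes up to at least 1e5.
#'
#' @param N universe size.
#' @param K category size within the universe.
#' @param n query size within the universe.
#' @param k overlap between query and category.
#' @return p-value in \code{(0, 1]}.
#' @examples
#' hypergeomUpperTail(10, 5, 5, 5)  # 1/252
#' hypergeomUpperTail(6, 3, 3, 2)   # 0.5
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L, length(k) == 1L)
  if (is.na(N) || is.na(K) || is.na(n) || is.na(k) ||
      k < 0 || k > n || n > N || K > N || K < 0 || k > K)
    stop(sprintf("invalid hypergeometric bounds (N=%s, K=%s, n=%s, k=%s)",
                 N, K, n, k), call. = FALSE)
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  logterms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logterms)
  if (!is.finite(m)) return(0)
  p <- exp(m + log(sum(exp(logterms - m))))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with cumulative-minimum
#' monotonicity; input order is preserved. Values must lie in \code{(0, 1]}.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
adjustBH <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of a query set in an ontology
#'
#' Intersects the query and every category with the universe, scores each
#' category by the upper-tail hypergeometric probability of the observed
#' overlap, adjusts across categories (Benjamini-Hochberg) and ranks by raw
#' p ascending, ties broken by overlap descending then category name.
#'
#' @param query character vector of protein/gene identifiers.
#' @param ont an \linkS4class{Ontology}.
#' @param universe optional override of the ontology universe.
#' @return data.frame with one row per category: \code{category}, \code{N},
#'   \code{K}, \code{n}, \code{k}, \code{p_value}, \code{p_adjusted},
#'   \code{rank}.
#' @export
enrichSet <- function(query, ont, universe = NULL) {
  stopifnot(is(ont, "Ontology"))
  uni <- if (is.null(universe)) ont@universe else sort(unique(universe))
  query <- unique(as.character(query))
  q <- intersect(query, uni)
  dropped <- length(query) - length(q)
  if (!length(q))
    stop(sprintf("query is disjoint from the universe (%d id(s) dropped)",
                 dropped), call. = FALSE)
  N <- length(uni)
  n <- length(q)
  res <- do.call(rbind, lapply(names(ont@categories), function(nm) {
    cat_u <- intersect(ont@categories[[nm]], uni)
    K <- length(cat_u)
    k <- length(intersect(cat_u, q))
    data.frame(category = nm, N = N, K = K, n = n, k = k,
               p_value = hypergeomUpperTail(N, K, n, k),
               stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- adjustBH(res$p_value)
  ord <- order(res$p_value, -res$k, res$category)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "ontology") <- ont@name
  res
}
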