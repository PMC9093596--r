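#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing \code{n} genes from a
#' universe of \code{N} of which \code{K} carry the term, the chance of at
#' least \code{k} hits. Computed as \code{phyper(k - 1, K, N - K, n,
#' lower.tail = FALSE)}, which works in a numerically stable tail
#' formulation.
#'
#' @param k Observed hits in the query (vectorised).
#' @param n Query size.
#' @param K Term size in the universe.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, n, K, N) {
  args <- cbind(k, n, K, N)
  if (any(args < 0) || any(args[, "k"] > pmin(args[, "n"], args[, "K"])) ||
      any(args[, "n"] > args[, "N"]) || any(args[, "K"] > args[, "N"]))
    stop("require 0 <= k <= min(n, K) and n, K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving wrapper over \code{p.adjust(method = "BH")}:
#' \code{q_i = min_{j: p_j >= p_i} p_(j) * m / rank(j)}, capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of annotation terms
#'
#' Tests every term with at least one annotated universe gene for
#' over-representation in the query set. The universe defaults to all
#' annotated genes; query genes outside the universe are dropped with a
#' warning. BH adjustment is applied within each annotation category
#' (e.g. BP/CC/MF/pathway) by default, or jointly.
#'
#' @param query Character vector of gene ids.
#' @param annotations data.frame with \code{gene_id}, \code{term_id},
#'   \code{term_name} and optionally \code{category}.
#' @param universe Optional character vector overriding the background.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @param per_category BH within category (default) or across all terms.
#' @return data.frame sorted by q then p: term_id, term_name, category, k,
#'   n, K, N, p, q, significant.
#' @export
enrich_terms <- function(query, annotations, universe = NULL,
                         q_threshold = 0.05, per_category = TRUE) {
  empty <- data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (length(query) == 0L || nrow(annotations) == 0L) return(empty)
  if (is.null(annotations$category)) annotations$category <- "all"
  annotations <- unique(annotations[, c("gene_id", "term_id", "term_name",
                                        "category")])
  universe <- unique(universe %||% annotations$gene_id)
  annotations <- annotations[annotations$gene_id %in% universe, ,
                             drop = FALSE]
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L || nrow(annotations) == 0L) return(empty)
  N <- length(universe)
  n <- length(query)
  terms <- unique(annotations[, c("term_id", "term_name", "category")])
  K <- vapply(terms$term_id, function(t) length(unique(
    annotations$gene_id[annotations$term_id == t])), integer(1))
  k <- vapply(terms$term_id, function(t) length(intersect(
    query, annotations$gene_id[annotations$term_id == t])), integer(1))
  p <- hypergeometric_tail(k, n, K, N)
  q <- numeric(length(p))
  if (per_category) {
    for (cat in unique(terms$category)) {
      idx <- terms$category == cat
      q[idx] <- bh_adjust(p[idx])
    }
  } else q <- bh_adjust(p)
  out <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    category = terms$category, k = k, n = n, K = K, N = N,
                    p = p, q = q, significant = q <= q_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
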