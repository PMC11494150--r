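#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the query set contains more
#' term genes than expected by drawing `n = |query|` genes from the
#' universe: `p = P[X >= k]` with
#' `X ~ Hypergeometric(N = |universe|, K = |term in universe|, n)`.
#' One-sided (over-representation only); BH correction across the tested
#' terms; rows sorted by p-value. Terms are intersected with the universe
#' first and terms that become empty are dropped.
#'
#' @param query character vector of gene ids (must be a subset of
#'   `universe`).
#' @param annotation an [annotation_map()].
#' @param universe character vector; background gene set, typically all
#'   detected genes.
#' @return data.frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `fold_enrichment`, `p_value`, `fdr`.
#' @export
enrich <- function(query, annotation, universe) {
  stopifnot(inherits(annotation, "AnnotationMap"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  query <- unique(as.character(query))
  if (length(setdiff(query, universe)))
    stop("query is not a subset of the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotation$terms), function(id) {
    term <- intersect(annotation$terms[[id]], universe)
    K <- length(term)
    if (K == 0) return(NULL)
    k <- length(intersect(term, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(term_id = id, term_name = annotation$term_names[[id]],
               k = k, K = K, n = n, N = N, fold_enrichment = fe,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), fold_enrichment = numeric(),
                      p_value = numeric(), fdr = numeric()))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}
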