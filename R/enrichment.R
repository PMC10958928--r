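#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing `k` or
#' more members of a `K`-sized term when sampling `n` genes without
#' replacement from a universe of `N`. Evaluated through the stable
#' survival-function route.
#'
#' @param k overlap count, `0 <= k <= min(n, K)`. Vectorized.
#' @param K term size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return numeric vector of tail probabilities.
#' @examples
#' hypergeom_tail(2, 2, 2, 10)  # 1/45
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k < 0) || any(k > pmin(n, K)))
    nf_stop("inconsistent counts: need 0 <= k <= min(n, K), K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1; the input order is preserved.
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    nf_stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric gene-set enrichment
#'
#' Tests the overrepresentation of each term of a collection within a
#' query gene list. The query is intersected with the universe first
#' (dropped genes are reported with a warning); only terms overlapping the
#' query (`k >= 1`) are tested, and the BH adjustment runs over those
#' tested terms.
#'
#' @param query character vector of gene ids.
#' @param gene_sets a `gene_set_collection` ([read_gene_sets()]).
#' @param universe optional universe override; term memberships are
#'   intersected with it.
#' @return data.frame with columns `term_id`, `description`, `k`, `K`,
#'   `n`, `N`, `pval`, `fdr`, sorted by `pval` then `term_id`.
#' @export
enrich <- function(query, gene_sets, universe = NULL) {
  uni <- if (is.null(universe)) gene_sets$universe else
    sort(unique(as.character(universe)))
  query <- unique(as.character(query))
  inside <- intersect(query, uni)
  if (!length(inside))
    nf_stop("none of the %d query genes belong to the %d-gene universe",
            length(query), length(uni))
  if (length(inside) < length(query))
    nf_warn("%d of %d query genes outside the universe were dropped",
            length(query) - length(inside), length(query))
  sets <- lapply(gene_sets$sets, intersect, uni)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, inside)), 0L)
  keep <- k >= 1L
  if (!any(keep)) {
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), pval = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  n <- length(inside); N <- length(uni)
  pval <- hypergeom_tail(k[keep], K[keep], n, N)
  out <- data.frame(term_id = names(sets)[keep],
                    description = unname(gene_sets$descriptions[names(sets)[keep]]),
                    k = k[keep], K = K[keep], n = n, N = N,
                    pval = pval, fdr = bh_adjust(pval),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pval, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared-term co-association curve
#'
#' Compares two ranked enrichment results (e.g. formula targets vs disease
#' targets). At each depth `n` up to `top_n`, `C(n)` counts the terms
#' shared by the two top-`n` lists. The curve summary reports
#' `similarity = C(N)/N`, the top-N overlap fraction in `[0, 1]`, and
#' `auc = mean(C(n))`, the average shared count over the curve (an
#' unnormalized quantity that can exceed 1). The effective depth is
#' truncated to the shorter list.
#'
#' @param rows_a,rows_b enrichment tables from [enrich()] (sorted by
#'   p-value then term id), or character vectors of ranked term ids.
#' @param top_n curve depth.
#' @return a `shared_term_curve`: list with `depth`, `shared` (vector
#'   `C(1..depth)`), `similarity` and `auc`.
#' @export
shared_term_curve <- function(rows_a, rows_b, top_n = 30) {
  term_ids <- function(x) if (is.data.frame(x)) x$term_id else as.character(x)
  a <- term_ids(rows_a); b <- term_ids(rows_b)
  if (!length(a) || !length(b))
    nf_stop("both enrichment lists must be non-empty")
  if (top_n < 1) nf_stop("top_n must be >= 1")
  depth <- min(top_n, length(a), length(b))
  shared <- vapply(seq_len(depth), function(n)
    length(intersect(a[seq_len(n)], b[seq_len(n)])), 0L)
  structure(list(depth = depth, shared = shared,
                 similarity = shared[depth] / depth,
                 auc = mean(shared)),
            class = "shared_term_curve")
}

#' @export
print.shared_term_curve <- function(x, ...) {
  cat(sprintf("<shared_term_curve> depth %d, similarity %.3f, AUC %.3f\n",
              x$depth, x$similarity, x$auc))
  invisible(x)
}

# Tabular form of a curve for CSV export.
curve_as_table <- function(curve) {
  data.frame(n = seq_len(curve$depth), shared = curve$shared,
             similarity = curve$similarity, auc = curve$auc)
}
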