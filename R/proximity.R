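# Map a gene set onto graph vertices; drop (with a warning) ids absent
# from the graph, error when nothing is left.
match_nodes <- function(graph, genes, label) {
  genes <- unique(as.character(genes))
  nodes <- igraph::V(graph)$name
  idx <- match(genes, nodes)
  if (anyNA(idx)) {
    if (all(is.na(idx)))
      nf_stop("no gene of %s is present in the network", label)
    nf_warn("%d gene(s) of %s absent from the network were dropped",
            sum(is.na(idx)), label)
    idx <- idx[!is.na(idx)]
  }
  idx
}

# Sparse adjacency powers A, A^2, ..., A^max_len.
adjacency_powers <- function(graph, max_len) {
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  powers <- vector("list", max_len)
  powers[[1L]] <- A
  M <- A
  for (l in seq_len(max_len - 1L)) {
    M <- M %*% A
    powers[[l + 1L]] <- M
  }
  powers
}

katz_from_powers <- function(powers, ia, ib, overlap, beta) {
  paths <- vapply(powers, function(M) sum(M[ia, ib, drop = FALSE]), 0)
  total <- overlap + sum(beta^seq_along(powers) * paths)
  list(paths = paths, total = total)
}

#' KATZ components between two gene sets
#'
#' Counts the walks of length 1..`max_len` between two node sets on the
#' network (entries of adjacency-matrix powers, summed over all cross-set
#' pairs) plus the node overlap, and combines them into the KATZ total
#' `overlap + sum_l beta^l * path_l`. Larger totals indicate closer
#' network proximity.
#'
#' @param graph an undirected simple igraph (e.g. from [read_ppi()]).
#' @param set_a,set_b character vectors of gene ids; ids absent from the
#'   graph are dropped with a warning.
#' @param beta path score coefficient (default 0.001).
#' @param max_len maximum walk length (default 3).
#' @return a `katz_result`: list with `overlap`, `paths` (named
#'   `path1..path<max_len>`), `total`.
#' @export
katz_components <- function(graph, set_a, set_b, beta = 0.001, max_len = 3) {
  ia <- match_nodes(graph, set_a, "set_a")
  ib <- match_nodes(graph, set_b, "set_b")
  powers <- adjacency_powers(graph, max_len)
  overlap <- length(intersect(ia, ib))
  kz <- katz_from_powers(powers, ia, ib, overlap, beta)
  structure(list(overlap = overlap,
                 paths = setNames(kz$paths, paste0("path", seq_len(max_len))),
                 total = kz$total, beta = beta),
            class = "katz_result")
}

#' @export
print.katz_result <- function(x, ...) {
  cat(sprintf("<katz_result> overlap %d | %s | total %.6g",
              x$overlap,
              paste(sprintf("%s %d", names(x$paths), x$paths), collapse = " "),
              x$total))
  if (!is.null(x$pval))
    cat(sprintf(" | random median %.6g | p = %.4g", x$random_median, x$pval))
  cat("\n")
  invisible(x)
}

#' KATZ permutation test
#'
#' Compares the observed KATZ total with a null of `n_perm` totals from
#' uniformly drawn node-set pairs of the same sizes. The p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (1 + n_perm)`, so it can
#' never be 0, and the run is reproducible under `config$seed`.
#'
#' @inheritParams katz_components
#' @param config an [nf_config()]; uses `beta`, `max_path_len`, `n_perm`,
#'   `seed`.
#' @return a `katz_result` with added `random_median`, `random_mean`,
#'   `null_totals` and `pval`.
#' @export
katz_test <- function(graph, set_a, set_b, config = nf_config()) {
  ia <- match_nodes(graph, set_a, "set_a")
  ib <- match_nodes(graph, set_b, "set_b")
  nv <- igraph::vcount(graph)
  if (length(ia) > nv || length(ib) > nv)
    nf_stop("set size exceeds the number of network nodes")
  powers <- adjacency_powers(graph, config$max_path_len)
  obs <- katz_from_powers(powers, ia, ib, length(intersect(ia, ib)),
                          config$beta)
  nulls <- with_seed(config$seed, vapply(seq_len(config$n_perm), function(i) {
    ra <- sample.int(nv, length(ia))
    rb <- sample.int(nv, length(ib))
    katz_from_powers(powers, ra, rb, length(intersect(ra, rb)),
                     config$beta)$total
  }, 0))
  structure(list(overlap = length(intersect(ia, ib)),
                 paths = setNames(obs$paths,
                                  paste0("path", seq_len(config$max_path_len))),
                 total = obs$total, beta = config$beta,
                 random_median = stats::median(nulls),
                 random_mean = mean(nulls),
                 null_totals = nulls,
                 pval = (1 + sum(nulls >= obs$total)) / (1 + config$n_perm)),
            class = "katz_result")
}

closest_from_matrix <- function(D) {
  ra <- apply(D, 1L, min)
  cb <- apply(D, 2L, min)
  finite <- c(is.finite(ra), is.finite(cb))
  if (!any(finite))
    nf_stop("no finite distance between the two sets (different components)")
  vals <- c(ra, cb)[finite]
  structure(mean(vals), n_excluded = sum(!finite))
}

#' Symmetric closest-distance between two gene sets
#'
#' The average, over the nodes of each set, of the unweighted
#' shortest-path distance to the nearest node of the other set:
#' `d(A,B) = (sum_a min_b d(a,b) + sum_b min_a d(a,b)) / (|A| + |B|)`.
#' Identical sets give 0. Nodes with no finite distance to the other set
#' are excluded from numerator and denominator; their count is attached as
#' the `"n_excluded"` attribute.
#'
#' @inheritParams katz_components
#' @return a single numeric distance.
#' @export
closest_distance <- function(graph, set_a, set_b) {
  ia <- match_nodes(graph, set_a, "set_a")
  ib <- match_nodes(graph, set_b, "set_b")
  D <- igraph::distances(graph, v = ia, to = ib)
  closest_from_matrix(D)
}

#' Network distance permutation test
#'
#' Observed [closest_distance()] against a null of uniformly drawn
#' same-size set pairs; one-sided, closer-than-random. Reports the null
#' mean and standard deviation, the z-score (NA when the null is
#' degenerate) and the add-one empirical p-value
#' `(1 + #{null <= observed}) / (1 + n_perm)`.
#'
#' @inheritParams katz_test
#' @return a `distance_result`: list with `mean_distance`, `random_mean`,
#'   `random_sd`, `z`, `pval`, `null_distances`, `n_excluded`.
#' @export
distance_test <- function(graph, set_a, set_b, config = nf_config()) {
  ia <- match_nodes(graph, set_a, "set_a")
  ib <- match_nodes(graph, set_b, "set_b")
  D <- igraph::distances(graph)
  obs <- closest_from_matrix(D[ia, ib, drop = FALSE])
  nv <- igraph::vcount(graph)
  nulls <- with_seed(config$seed, vapply(seq_len(config$n_perm), function(i) {
    ra <- sample.int(nv, length(ia))
    rb <- sample.int(nv, length(ib))
    as.numeric(closest_from_matrix(D[ra, rb, drop = FALSE]))
  }, 0))
  sd0 <- stats::sd(nulls)
  structure(list(mean_distance = as.numeric(obs),
                 random_mean = mean(nulls),
                 random_sd = sd0,
                 z = if (isTRUE(sd0 > 0)) (as.numeric(obs) - mean(nulls)) / sd0
                     else NA_real_,
                 pval = (1 + sum(nulls <= as.numeric(obs))) /
                   (1 + config$n_perm),
                 null_distances = nulls,
                 n_excluded = attr(obs, "n_excluded")),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> mean distance %.4f | random %.4f +/- %.4f | z %.3f | p = %.4g\n",
              x$mean_distance, x$random_mean, x$random_sd, x$z, x$pval))
  invisible(x)
}

#' Seed subnetwork of a PPI network
#'
#' Projects a seed gene set onto the network. Without expansion, the
#' induced subgraph on the seeds (isolated seeds retained). With
#' expansion, non-seed connector nodes adjacent to at least two seeds are
#' added before inducing.
#'
#' @param graph an undirected igraph.
#' @param seeds character vector of seed gene ids; at least one must be in
#'   the graph (missing seeds are reported).
#' @param expand add connector nodes adjacent to >= 2 seeds.
#' @return an igraph subnetwork; seed membership is stored in the vertex
#'   attribute `is_seed`.
#' @export
seed_subnetwork <- function(graph, seeds, expand = FALSE) {
  seeds <- unique(as.character(seeds))
  nodes <- igraph::V(graph)$name
  missing <- setdiff(seeds, nodes)
  if (length(missing) == length(seeds))
    nf_stop("no seed is present in the network: %s",
            paste(missing, collapse = ", "))
  if (length(missing))
    nf_warn("seed(s) absent from the network: %s",
            paste(missing, collapse = ", "))
  present <- setdiff(seeds, missing)
  keep <- present
  if (expand) {
    idx <- match(present, nodes)
    A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
    seed_deg <- Matrix::colSums(A[idx, , drop = FALSE])
    connectors <- setdiff(nodes[seed_deg >= 2], present)
    keep <- c(present, connectors)
  }
  sub <- igraph::induced_subgraph(graph, keep)
  igraph::V(sub)$is_seed <- igraph::V(sub)$name %in% present
  sub
}
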