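#' Build the weighted herb co-occurrence network
#'
#' Nodes are herbs; an edge joins two herbs that co-occur in at least one
#' prescription, weighted by the number of prescriptions containing both.
#'
#' @param ds a `prescription_dataset`.
#' @return an undirected weighted igraph (edge attribute `weight`).
#' @export
build_herb_network <- function(ds) {
  M <- herb_incidence(ds)
  if (nrow(M) < 2L) nf_stop("prescriptions contain fewer than 2 distinct herbs")
  co <- Matrix::tcrossprod(M)  # herbs x herbs co-occurrence counts
  co <- methods::as(Matrix::triu(co, k = 1), "TsparseMatrix")
  keep <- co@x >= 1
  if (!any(keep)) nf_stop("no herb pair co-occurs (all prescriptions singleton)")
  herbs <- rownames(M)
  edges <- data.frame(from = herbs[co@i[keep] + 1L],
                      to = herbs[co@j[keep] + 1L],
                      weight = co@x[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = herbs)
  igraph::delete_vertices(g, igraph::degree(g) == 0)
}

# Sparse herb x prescription 0/1 incidence matrix.
herb_incidence <- function(ds) {
  herbs <- sort(unique(unlist(ds$herbs)))
  j <- rep(seq_along(ds$herbs), lengths(ds$herbs))
  i <- match(unlist(ds$herbs), herbs)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(herbs), ds$n_prescriptions),
                       dimnames = list(herbs, NULL))
}

#' Binarize a weighted herb network
#'
#' Keeps edges with weight at or above the threshold and drops nodes left
#' isolated, producing the unweighted graph that maximal-clique
#' enumeration operates on.
#'
#' @param net weighted igraph from [build_herb_network()].
#' @param threshold minimum co-occurrence count (>= 1).
#' @return an unweighted igraph (possibly empty).
#' @export
binarize_network <- function(net, threshold) {
  if (threshold < 1) nf_stop("binarization threshold must be >= 1")
  g <- igraph::subgraph_from_edges(
    net, igraph::E(net)[igraph::E(net)$weight >= threshold],
    delete.vertices = TRUE)
  igraph::delete_edge_attr(g, "weight")
}

#' Enumerate maximal cliques (Bron-Kerbosch with pivoting)
#'
#' All maximal cliques of size >= 2 of a simple undirected graph, via the
#' recursive Bron-Kerbosch procedure with pivot selection (the pivot is
#' the candidate vertex with the most neighbours among the remaining
#' candidates, which prunes the recursion). The output is canonically
#' ordered: clique size descending, then lexicographically by the sorted
#' member list.
#'
#' @param graph an igraph with named vertices.
#' @return list of character vectors (sorted members); empty for an
#'   edgeless graph.
#' @export
maximal_cliques <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L || igraph::ecount(graph) == 0L) return(list())
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  out <- vector("list", 64L); n_out <- 0L
  emit <- function(R) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * length(out)
    out[[n_out]] <<- R
  }
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      if (length(R) >= 2L) emit(R)
      return(invisible(NULL))
    }
    PX <- c(P, X)
    nb <- vapply(PX, function(v) sum(P %in% adj[[v]]), 0L)
    u <- PX[which.max(nb)]
    for (v in P[!P %in% adj[[u]]]) {
      Nv <- adj[[v]]
      bk(c(R, v), P[P %in% Nv], X[X %in% Nv])
      P <- P[P != v]
      X <- c(X, v)
    }
    invisible(NULL)
  }
  bk(integer(0), seq_len(n), integer(0))
  out <- out[seq_len(n_out)]
  names <- igraph::V(graph)$name
  cliques <- lapply(out, function(idx) sort(names[idx]))
  key <- vapply(cliques, paste, "", collapse = "\r")
  cliques[order(-lengths(cliques), key)]
}

#' Confidence of a formula in a prescription
#'
#' The fraction of the formula's herbs present in the prescription.
#'
#' @param formula character vector of herbs (non-empty).
#' @param prescription character vector of herbs.
#' @return value in `[0, 1]`.
#' @export
formula_confidence <- function(formula, prescription) {
  if (!length(formula)) nf_stop("'formula' must be non-empty")
  length(intersect(formula, prescription)) / length(unique(formula))
}

# Confidence of one formula across every prescription, via the incidence
# matrix (rows herbs, columns prescriptions).
confidence_vector <- function(formula, M) {
  formula <- unique(formula)
  present <- intersect(formula, rownames(M))
  if (!length(present)) return(numeric(ncol(M)))
  as.numeric(Matrix::colSums(M[present, , drop = FALSE])) / length(formula)
}

#' Support and average confidence of a formula
#'
#' `S_alpha` is the fraction of prescriptions whose confidence for the
#' formula reaches `alpha`; the average confidence is the mean over all
#' prescriptions.
#'
#' @param formula character vector of herbs.
#' @param ds a `prescription_dataset`.
#' @param alpha confidence level in `(0, 1]`.
#' @return list with `support`, `avg_confidence`, `n_supporting`.
#' @export
formula_support <- function(formula, ds, alpha = 0.9) {
  if (!(alpha > 0 && alpha <= 1)) nf_stop("alpha must lie in (0, 1]")
  if (!ds$n_prescriptions) nf_stop("empty prescription dataset")
  conf <- confidence_vector(formula, herb_incidence(ds))
  list(support = mean(conf >= alpha),
       avg_confidence = mean(conf),
       n_supporting = sum(conf >= alpha))
}

#' Patient-based support of a formula
#'
#' Each patient contributes their best visit: the maximum confidence over
#' their prescriptions. The person support is the fraction of patients
#' whose maximum reaches `alpha`.
#'
#' @inheritParams formula_support
#' @return fraction in `[0, 1]`.
#' @export
person_support <- function(formula, ds, alpha = 0.9) {
  conf <- confidence_vector(formula, herb_incidence(ds))
  best <- tapply(conf, ds$pid, max)
  mean(best >= alpha)
}

#' Mine core formulas from prescriptions
#'
#' The full pipeline: build the weighted herb co-occurrence network, scan
#' binarization thresholds over the distinct edge weights (descending),
#' enumerate maximal cliques at each with [maximal_cliques()], and keep
#' cliques meeting the size constraint (`min_herbs`, or exactly
#' `desired_herbs` when `enforce_size`) and the support constraint
#' `S_alpha >= s_min`. The chosen threshold maximizes the number of
#' qualifying formulas, ties resolved toward the larger (sparser)
#' threshold. Optionally merges highly similar formulas
#' ([merge_formulas()]) and attaches patient-based support.
#'
#' @param ds a `prescription_dataset`.
#' @param config an [nf_config()]; uses `s_min`, `alpha`, `min_herbs`,
#'   `desired_herbs`, `enforce_size`, `fallback`, `merge`,
#'   `merge_method`, `merge_threshold`, `person_stats`.
#' @return a `mining_result`: list with `formulas` (data.frame `herbs`
#'   list-column, `herbs_str`, `size`, `avg_confidence`, `support`,
#'   `n_supporting`, `source_threshold`, optionally `person_support`),
#'   `chosen_threshold` (NA when nothing qualifies), `summary` (qualifying
#'   count per scanned threshold), `network` (the weighted herb network)
#'   and `binarized` (the network at the chosen threshold, or NULL).
#' @export
mine_core_formulas <- function(ds, config = nf_config()) {
  if (config$s_min < 0.01 && config$s_min != 0)
    nf_warn("s_min below 0.01 will admit almost any clique")
  net <- build_herb_network(ds)
  M <- herb_incidence(ds)
  thresholds <- sort(unique(igraph::E(net)$weight), decreasing = TRUE)

  size_ok <- function(sz) {
    if (config$enforce_size && !is.null(config$desired_herbs))
      sz == config$desired_herbs
    else sz >= config$min_herbs
  }
  qualifying_at <- function(thr, size_filter) {
    cliques <- maximal_cliques(binarize_network(net, thr))
    cliques <- cliques[size_filter(lengths(cliques))]
    if (!length(cliques)) return(list())
    Filter(function(f) mean(confidence_vector(f, M) >= config$alpha) >=
             config$s_min, cliques)
  }

  counts <- vapply(thresholds, function(thr)
    length(qualifying_at(thr, size_ok)), 0L)
  summary <- data.frame(threshold = thresholds, n_qualifying = counts)

  used_fallback <- FALSE
  if (all(counts == 0L) && config$enforce_size && config$fallback) {
    size_ok <- function(sz) sz >= config$min_herbs
    counts <- vapply(thresholds, function(thr)
      length(qualifying_at(thr, size_ok)), 0L)
    used_fallback <- TRUE
  }

  if (all(counts == 0L)) {
    return(structure(list(formulas = empty_formula_table(config$person_stats),
                          chosen_threshold = NA_integer_,
                          summary = summary, network = net,
                          binarized = NULL, fallback_used = used_fallback),
                     class = "mining_result"))
  }
  best <- max(counts)
  chosen <- max(thresholds[counts == best])  # tie -> sparser network
  cliques <- qualifying_at(chosen, size_ok)
  formulas <- formula_table(cliques, ds, M, config$alpha, chosen)
  if (config$merge && nrow(formulas) > 1L) {
    formulas <- merge_formulas(formulas, ds, method = config$merge_method,
                               threshold = config$merge_threshold,
                               alpha = config$alpha)
  }
  if (config$person_stats) {
    formulas$person_support <- vapply(formulas$herbs, person_support,
                                      numeric(1), ds = ds,
                                      alpha = config$alpha)
  }
  structure(list(formulas = formulas, chosen_threshold = chosen,
                 summary = summary, network = net,
                 binarized = binarize_network(net, chosen),
                 fallback_used = used_fallback),
            class = "mining_result")
}

empty_formula_table <- function(person_stats = FALSE) {
  df <- data.frame(herbs_str = character(0), size = integer(0),
                   avg_confidence = numeric(0), support = numeric(0),
                   n_supporting = integer(0), source_threshold = integer(0),
                   stringsAsFactors = FALSE)
  df$herbs <- list()
  if (person_stats) df$person_support <- numeric(0)
  df[c("herbs", "herbs_str", "size", "avg_confidence", "support",
       "n_supporting", "source_threshold",
       if (person_stats) "person_support")]
}

formula_table <- function(cliques, ds, M, alpha, source_threshold) {
  stats <- lapply(cliques, function(f) {
    conf <- confidence_vector(f, M)
    list(avg = mean(conf), sup = mean(conf >= alpha),
         n = sum(conf >= alpha))
  })
  df <- data.frame(
    herbs_str = vapply(cliques, paste, "", collapse = ";"),
    size = lengths(cliques),
    avg_confidence = vapply(stats, `[[`, 0, "avg"),
    support = vapply(stats, `[[`, 0, "sup"),
    n_supporting = vapply(stats, function(s) as.integer(s$n), 0L),
    source_threshold = if (length(cliques))
      rep(as.integer(source_threshold), length(cliques)) else integer(0),
    stringsAsFactors = FALSE)
  df$herbs <- cliques
  df <- df[order(-df$support, -df$size, df$herbs_str), , drop = FALSE]
  rownames(df) <- NULL
  df[c("herbs", "herbs_str", "size", "avg_confidence", "support",
       "n_supporting", "source_threshold")]
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("<mining_result> %d core formula(s) at threshold %s (%d threshold(s) scanned)\n",
              nrow(x$formulas),
              if (is.na(x$chosen_threshold)) "none" else x$chosen_threshold,
              nrow(x$summary)))
  invisible(x)
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Merge highly similar core formulas
#'
#' Similarity between formulas is the Jaccard index of their herb sets.
#' `"Together"` merges each connected component of the
#' similarity-at-or-above-threshold graph into the union of its herb sets
#' in one pass. `"Step"` repeatedly merges the single most similar pair at
#' or above the threshold (ties: the pair with the lexicographically
#' smallest union) and recomputes similarities until no pair qualifies.
#' Support and confidence metrics are recomputed on the dataset after
#' merging.
#'
#' @param formulas a formula table (from [mine_core_formulas()]) or a list
#'   of herb-set character vectors.
#' @param ds the `prescription_dataset` used to recompute metrics.
#' @param method `"Together"` or `"Step"`.
#' @param threshold Jaccard similarity at or above which formulas merge.
#' @param alpha confidence level for the recomputed support.
#' @return a formula table of the merged formulas; `source_threshold` is
#'   kept when unanimous among the merged constituents, else NA.
#' @export
merge_formulas <- function(formulas, ds, method = c("Together", "Step"),
                           threshold = 0.6, alpha = 0.9) {
  method <- match.arg(method)
  if (!(threshold >= 0 && threshold <= 1))
    nf_stop("merge threshold must lie in [0, 1]")
  sets <- if (is.data.frame(formulas)) formulas$herbs else formulas
  src <- if (is.data.frame(formulas) && "source_threshold" %in% names(formulas))
    formulas$source_threshold else rep(NA_integer_, length(sets))
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (length(sets) > 1L) {
    if (method == "Together") {
      n <- length(sets)
      pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
      sim <- apply(pairs, 1L, function(ij)
        jaccard(sets[[ij[1L]]], sets[[ij[2L]]]))
      qual <- pairs[sim >= threshold, , drop = FALSE]
      g <- igraph::make_empty_graph(n, directed = FALSE)
      if (nrow(qual)) g <- igraph::add_edges(g, t(qual))
      comp <- igraph::components(g)$membership
      merged <- lapply(split(seq_len(n), comp), function(idx)
        sort(unique(unlist(sets[idx]))))
      src <- vapply(split(src, comp), function(s)
        if (length(unique(s)) == 1L) s[1L] else NA_integer_, 0L)
      sets <- merged
    } else {
      repeat {
        n <- length(sets)
        if (n < 2L) break
        best <- NULL
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          s <- jaccard(sets[[i]], sets[[j]])
          if (s >= threshold) {
            u <- paste(sort(union(sets[[i]], sets[[j]])), collapse = "\r")
            if (is.null(best) || s > best$s || (s == best$s && u < best$u))
              best <- list(i = i, j = j, s = s, u = u)
          }
        }
        if (is.null(best)) break
        merged_set <- sort(union(sets[[best$i]], sets[[best$j]]))
        merged_src <- if (!is.na(src[best$i]) && identical(src[best$i],
                                                           src[best$j]))
          src[best$i] else NA_integer_
        keep <- setdiff(seq_len(n), c(best$i, best$j))
        sets <- c(sets[keep], list(merged_set))
        src <- c(src[keep], merged_src)
      }
    }
    # collapse exact duplicates produced by merging
    key <- vapply(sets, paste, "", collapse = "\r")
    first <- !duplicated(key)
    sets <- sets[first]; src <- src[first]
  }
  M <- herb_incidence(ds)
  out <- formula_table(sets, ds, M, alpha, NA_integer_)
  out$source_threshold <- as.integer(src[match(
    vapply(out$herbs, paste, "", collapse = "\r"),
    vapply(sets, paste, "", collapse = "\r"))])
  out
}
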