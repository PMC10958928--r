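# Independent oracles used against the package implementation. Each is a
# deliberately naive, straight-line computation with no code shared with
# the functions it checks.

# Binomial upper tail by exhaustive enumeration of all 2^n outcomes.
enum_binom_tail <- function(k, n, p) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(outcomes, 1L, function(x) prod(ifelse(x == 1, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= k])
}

# Hypergeometric upper tail by enumerating every n-subset of the universe.
enum_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "term" members
  mean(hits >= k)
}

# All maximal cliques (size >= 2) by checking every vertex subset.
brute_cliques <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  nms <- igraph::V(graph)$name
  is_clique <- function(idx) all(A[idx, idx][upper.tri(diag(length(idx)))] == 1)
  out <- list()
  for (size in 2:n) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      if (!is_clique(idx)) next
      outside <- setdiff(seq_len(n), idx)
      maximal <- !any(vapply(outside, function(v) all(A[v, idx] == 1), TRUE))
      if (maximal) out[[length(out) + 1L]] <- sort(nms[idx])
    }
  }
  key <- vapply(out, paste, "", collapse = "\r")
  out[order(-lengths(out), key)]
}

# Straight-line QED evaluation: published asymmetric-double-sigmoid
# parameters transcribed independently of the package source.
oracle_qed <- function(v, weights = c(0.66, 0.46, 0.05, 0.61, 0.06, 0.65,
                                      0.48, 0.95)) {
  P <- list(
    c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
    c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
    c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
    c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
    c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
    c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
    c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
    c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140))
  d <- numeric(8)
  for (i in 1:8) {
    a <- P[[i]][1]; b <- P[[i]][2]; cc <- P[[i]][3]; dd <- P[[i]][4]
    e <- P[[i]][5]; f <- P[[i]][6]; dmax <- P[[i]][7]
    x <- v[i]
    val <- a + b / (1 + exp(-(x - cc + dd / 2) / e)) *
      (1 - 1 / (1 + exp(-(x - cc - dd / 2) / f)))
    d[i] <- max(val / dmax, 1e-6)
  }
  exp(sum(weights * log(d)) / sum(weights))
}

oracle_qed_desirabilities <- function(v) {
  # returns the floored desirability vector (for the geometric-mean check)
  w <- rep(1, 8)
  vapply(1:8, function(i) {
    vi <- v; wi <- numeric(8); wi[i] <- 1
    oracle_qed(vi, wi)  # with a single unit weight QED reduces to d_i
  }, 0)
}

# Random descriptor vector spanning realistic small-molecule ranges.
random_descriptors <- function(n) {
  cbind(MW = runif(n, 50, 900), ALOGP = runif(n, -4, 9),
        HBA = sample(0:16, n, TRUE), HBD = sample(0:10, n, TRUE),
        PSA = runif(n, 0, 250), ROTB = sample(0:20, n, TRUE),
        AROM = sample(0:6, n, TRUE), ALERTS = sample(0:6, n, TRUE))
}

# Small Erdos-Renyi graph with named vertices, for clique/KATZ oracles.
random_named_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- paste0("v", sprintf("%02d", seq_len(n)))
    g
  })
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
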