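tiny_ds <- function(herb_sets, pid = NULL, vid = NULL) {
  n <- length(herb_sets)
  prescription_dataset(pid %||% paste0("p", seq_len(n)),
                       vid %||% rep("v1", n), herb_sets)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("herb networks count pairwise co-occurrence", {
  ds <- tiny_ds(list(c("a", "b", "c"), c("a", "b")))
  net <- build_herb_network(ds)
  w <- function(x, y) igraph::E(net)$weight[
    igraph::get_edge_ids(net, c(x, y))]
  expect_equal(w("a", "b"), 2)
  expect_equal(w("a", "c"), 1)
  expect_equal(w("b", "c"), 1)
  expect_false(igraph::any_loop(net))

  disjoint <- build_herb_network(tiny_ds(list(c("a", "b"), c("c", "d"))))
  expect_equal(igraph::components(disjoint)$no, 2L)

  expect_error(build_herb_network(tiny_ds(list("a", "b"))), "singleton|pair")
})

test_that("binarization thresholds edges and drops isolated nodes", {
  ds <- tiny_ds(list(c("a", "b", "c"), c("a", "b")))
  net <- build_herb_network(ds)
  b2 <- binarize_network(net, 2)
  expect_setequal(igraph::V(b2)$name, c("a", "b"))
  expect_equal(igraph::ecount(b2), 1L)
  expect_equal(igraph::ecount(binarize_network(net, 3)), 0L)
  b1 <- binarize_network(net, 1)
  expect_equal(igraph::ecount(b1), igraph::ecount(net))
  # edge sets shrink monotonically with the threshold
  for (thr in 1:3) {
    hi <- igraph::as_edgelist(binarize_network(net, thr))
    lo <- igraph::as_edgelist(binarize_network(net, 1))
    expect_true(all(paste(hi[, 1], hi[, 2]) %in% paste(lo[, 1], lo[, 2])))
  }
})

test_that("maximal cliques match brute force and igraph on small graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(maximal_cliques(k4), list(letters[1:4]))

  g <- igraph::make_graph(~ a - b, b - c, c - a, c - d)
  expect_equal(maximal_cliques(g), list(c("a", "b", "c"), c("c", "d")))
  expect_equal(maximal_cliques(g), brute_cliques(g))

  empty <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(empty)$name <- letters[1:3]
  expect_equal(maximal_cliques(empty), list())

  for (seed in 1:15) {
    rg <- random_named_graph(sample(4:12, 1), runif(1, 0.2, 0.8), seed)
    if (igraph::ecount(rg) == 0) next
    mine <- maximal_cliques(rg)
    expect_equal(mine, brute_cliques(rg))
    ig <- lapply(igraph::max_cliques(rg, min = 2), function(v)
      sort(igraph::V(rg)$name[v]))
    expect_setequal(vapply(mine, paste, "", collapse = ";"),
                    vapply(ig, paste, "", collapse = ";"))
  }
})

test_that("confidence and support follow their counting definitions", {
  expect_equal(formula_confidence(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(formula_confidence(letters[1:5], letters[1:4]), 0.8)
  expect_equal(formula_confidence(c("a", "b"), c("x", "y")), 0)
  expect_error(formula_confidence(character(0), "a"), "non-empty")

  sets <- c(rep(list(c("F1", "F2", "F3")), 3),
            rep(list(c("x", "y")), 7))
  ds <- tiny_ds(sets)
  fs <- formula_support(c("F1", "F2", "F3"), ds, alpha = 0.9)
  expect_equal(fs$support, 0.3)
  expect_equal(fs$n_supporting, 3L)
  expect_equal(fs$avg_confidence, 0.3)
  all_in <- formula_support(c("x", "y"), tiny_ds(rep(list(c("x", "y")), 4)),
                            alpha = 0.9)
  expect_equal(all_in$support, 1)
  expect_equal(all_in$avg_confidence, 1)
  # S_alpha is non-increasing in alpha
  partial <- tiny_ds(c(rep(list(c("F1", "F2")), 2),
                       rep(list(c("F1", "z")), 5),
                       rep(list("q"), 3)))
  s <- vapply(c(0.25, 0.5, 0.9, 1), function(a)
    formula_support(c("F1", "F2"), partial, a)$support, 0)
  expect_true(all(diff(s) <= 0))
})

test_that("mining recovers structure, honours filters, reports diagnostics", {
  spec <- fixture_spec(seed = 21, n_prescriptions = 200, n_patients = 100)
  ds <- gen_prescriptions(spec)
  res <- mine_core_formulas(ds, nf_config(s_min = 0.3, alpha = 0.9,
                                          min_herbs = 4))
  expect_equal(res$formulas$herbs[[1]], paste0("PF", 1:5))
  expect_false(is.na(res$chosen_threshold))
  # every returned formula is a clique of the binarized network
  bin <- binarize_network(res$network, res$chosen_threshold)
  for (f in res$formulas$herbs) {
    sub <- igraph::induced_subgraph(bin, f)
    expect_equal(igraph::ecount(sub), choose(length(f), 2))
  }

  nothing <- mine_core_formulas(ds, nf_config(s_min = 0.99, alpha = 0.9,
                                              min_herbs = 4))
  expect_equal(nrow(nothing$formulas), 0L)
  expect_true(is.na(nothing$chosen_threshold))
  expect_true(all(nothing$summary$n_qualifying == 0L))
  expect_gt(nrow(nothing$summary), 0L)

  sized <- mine_core_formulas(ds, nf_config(s_min = 0.3, alpha = 0.9,
                                            min_herbs = 4,
                                            desired_herbs = 4,
                                            enforce_size = TRUE))
  expect_false(any(sized$formulas$size != 4L))
})

test_that("merging follows the Together and Step procedures", {
  ds <- tiny_ds(list(c("a", "b", "c", "d", "e", "f", "g"), c("a", "b", "c")))
  fa <- c("a", "b", "c", "d", "e")    # J(fa, fb) = 4/6
  fb <- c("a", "b", "c", "d", "f")    # J(fb, fc) = 4/6
  fc <- c("b", "c", "d", "f", "g")    # J(fa, fc) = 3/7
  together <- merge_formulas(list(fa, fb, fc), ds, method = "Together",
                             threshold = 0.6)
  expect_equal(nrow(together), 1L)
  expect_equal(together$herbs[[1]], letters[1:7])
  step <- merge_formulas(list(fa, fb, fc), ds, method = "Step",
                         threshold = 0.6)
  # the tied top pairs (both 4/6) resolve to the lexicographically smaller
  # union fa+fb = {a..f}; its Jaccard with fc is 4/7 < 0.6, so Step stops
  expect_equal(nrow(step), 2L)
  expect_setequal(vapply(step$herbs, paste, "", collapse = ";"),
                  c("a;b;c;d;e;f", "b;c;d;f;g"))

  ident <- merge_formulas(list(fa, fa), ds, threshold = 0.6)
  expect_equal(nrow(ident), 1L)
  low <- merge_formulas(list(fa, fc), ds, threshold = 0.6)
  expect_equal(nrow(low), 2L)  # J = 0.5 below threshold: unchanged

  # idempotence for both methods
  for (m in c("Together", "Step")) {
    once <- merge_formulas(list(fa, fb, fc), ds, method = m, threshold = 0.6)
    twice <- merge_formulas(once, ds, method = m, threshold = 0.6)
    expect_equal(twice$herbs, once$herbs)
  }
})

test_that("person-based support takes each patient's best visit", {
  ds <- prescription_dataset(
    pid = c("p1", "p1", "p2", "p3"),
    vid = c("v1", "v2", "v1", "v1"),
    herbs = list(c("a", "b"), c("x", "y"), c("a", "b"), c("q", "r")))
  expect_equal(person_support(c("a", "b"), ds, alpha = 0.9), 2 / 3)
  one_visit <- tiny_ds(list(c("a", "b"), c("a", "b"), c("x", "y")))
  expect_equal(person_support(c("a", "b"), one_visit, 0.9),
               formula_support(c("a", "b"), one_visit, 0.9)$support)
  expect_equal(person_support(c("zz", "ww"), ds, 0.9), 0)
})
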