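path_graph <- function() {
  igraph::make_graph(~ a - b, b - c)
}

test_that("KATZ components equal hand-computed walk counts", {
  g <- path_graph()
  kz <- katz_components(g, "a", "c", beta = 0.001)
  expect_equal(kz$overlap, 0L)
  expect_equal(unname(kz$paths), c(0, 1, 0))
  expect_equal(kz$total, 1e-6)

  star <- igraph::make_graph(~ s - x, s - y, s - z)
  self <- katz_components(star, "s", "s")
  expect_equal(self$overlap, 1L)
  expect_equal(unname(self$paths[["path2"]]), 3)  # A^2 diagonal = degree

  two_comp <- igraph::make_graph(~ a - b, c - d)
  far <- katz_components(two_comp, "a", "c")
  expect_equal(far$total, 0)
})

test_that("KATZ walk counts equal adjacency powers on random graphs", {
  for (seed in 1:20) {
    g <- random_named_graph(sample(5:20, 1), 0.3, seed = seed)
    if (igraph::ecount(g) == 0) next
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    A2 <- A %*% A; A3 <- A2 %*% A
    n <- igraph::vcount(g)
    ia <- withr::with_seed(seed, sample(n, min(4, n)))
    ib <- withr::with_seed(seed + 100, sample(n, min(3, n)))
    kz <- katz_components(g, igraph::V(g)$name[ia], igraph::V(g)$name[ib])
    expect_equal(unname(kz$paths),
                 c(sum(A[ia, ib]), sum(A2[ia, ib]), sum(A3[ia, ib])))
    expect_equal(kz$total,
                 length(intersect(ia, ib)) + 1e-3 * sum(A[ia, ib]) +
                   1e-6 * sum(A2[ia, ib]) + 1e-9 * sum(A3[ia, ib]))
  }
})

test_that("KATZ permutation test is seeded, bounded and errors cleanly", {
  g <- gen_ppi(60, 2, seed = 5)
  cfg <- nf_config(n_perm = 99, seed = 7)
  a <- paste0("G", 1:5); b <- paste0("G", 10:14)
  r1 <- katz_test(g, a, b, cfg)
  r2 <- katz_test(g, a, b, cfg)
  expect_identical(r1$null_totals, r2$null_totals)
  expect_identical(r1$pval, r2$pval)
  expect_gte(r1$pval, 1 / 100)
  expect_lte(r1$pval, 1)
  expect_error(nf_config(n_perm = 0), "n_perm")
  expect_error(katz_test(g, "nope", b, cfg), "set_a")
})

test_that("closest distance handles identity, paths, stars and symmetry", {
  expect_equal(as.numeric(closest_distance(path_graph(), c("a", "b"),
                                           c("a", "b"))), 0)
  expect_equal(as.numeric(closest_distance(path_graph(), "a", "c")), 2)
  star <- igraph::make_graph(~ s - x, s - y)
  expect_equal(as.numeric(closest_distance(star, "x", "y")), 2)
  g <- gen_ppi(40, 2, seed = 9)
  a <- paste0("G", 1:4); b <- paste0("G", 20:24)
  expect_equal(as.numeric(closest_distance(g, a, b)),
               as.numeric(closest_distance(g, b, a)))
  two_comp <- igraph::make_graph(~ a - b, c - d)
  expect_error(closest_distance(two_comp, "a", "c"), "component")
})

test_that("distance test is reproducible and reports a null summary", {
  g <- gen_ppi(60, 2, seed = 5)
  cfg <- nf_config(n_perm = 99, seed = 3)
  a <- paste0("G", 1:5); b <- paste0("G", 30:34)
  r1 <- distance_test(g, a, b, cfg)
  r2 <- distance_test(g, a, b, cfg)
  expect_identical(r1$null_distances, r2$null_distances)
  expect_gte(r1$pval, 1 / 100); expect_lte(r1$pval, 1)
  expect_equal(r1$z, (r1$mean_distance - r1$random_mean) / r1$random_sd)
})

test_that("seed subnetworks follow the induced and connector rules", {
  tri <- igraph::make_graph(~ a - b, b - c, c - a)
  sub <- seed_subnetwork(tri, c("a", "b"))
  expect_setequal(igraph::V(sub)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub), 1L)

  pathg <- path_graph()  # a - b - c: b connects the two seeds
  exp1 <- seed_subnetwork(pathg, c("a", "c"), expand = TRUE)
  expect_setequal(igraph::V(exp1)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(exp1), 2L)
  expect_setequal(igraph::V(exp1)$name[igraph::V(exp1)$is_seed],
                  c("a", "c"))
  noexp <- seed_subnetwork(pathg, c("a", "c"), expand = FALSE)
  expect_equal(igraph::ecount(noexp), 0L)  # isolated seeds retained

  expect_error(seed_subnetwork(tri, c("q", "r")), "no seed")
  expect_warning(sub2 <- seed_subnetwork(tri, c("a", "zz")), "zz")
  expect_setequal(igraph::V(sub2)$name, "a")
})
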