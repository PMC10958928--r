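test_that("binomial tail matches closed cases and rejects bad input", {
  expect_identical(binomial_tail(0, 5, 0.1), 1)
  expect_equal(binomial_tail(1, 2, 0.5), 0.75)
  expect_equal(binomial_tail(3, 3, 0.2), 0.2^3)
  expect_error(binomial_tail(4, 3, 0.2), "k <= n")
  expect_error(binomial_tail(1, 3, 1.2), "\\[0, 1\\]")
})

test_that("binomial tail is monotone in k and p", {
  for (n in c(3, 8)) {
    for (p in c(0.1, 0.5)) {
      tails <- binomial_tail(0:n, n, p)
      expect_true(all(diff(tails) <= 1e-15))
    }
    ps <- seq(0.05, 0.95, by = 0.1)
    expect_true(all(diff(binomial_tail(2, n, ps)) >= -1e-15))
  }
})

test_that("background probabilities are compound fractions after filtering", {
  links <- data.frame(
    compound_id = c(paste0("C", 1:50), "C1", "C2"),
    target = c(rep("T1", 5), rep("Tother", 45), "T2", "T2"),
    score = c(rep(500L, 50), 300L, 9999L))
  bg <- background_probs(links, 400)
  expect_equal(unname(bg["T1"]), 5 / 50)
  # C1's 300-score link to T2 is filtered out; C2's 9999 sentinel survives
  expect_equal(unname(bg["T2"]), 1 / 50)
  no_sentinel <- links[links$score != 9999L, ]
  expect_error(background_probs(no_sentinel, 1001), "threshold")
})

test_that("gene scores follow the piecewise -log(p)/rank rule", {
  tab <- netformula:::rank_gene_scores(
    target = c("Ta", "Tb", "Tc"), k = c(5L, 3L, 1L),
    pval = c(1e-6, 1e-3, 0.2), psig = 0.05, log_base = 10)
  expect_equal(tab$gene_score, c(6, 1.5, 0))
  expect_equal(tab$rank, c(1L, 2L, NA))
  expect_equal(mean(tab$gene_score), 2.5)  # chem score over those targets
  # ties on pval break by larger k, then target id
  tie <- netformula:::rank_gene_scores(
    target = c("T2", "T1", "T3"), k = c(2L, 4L, 4L),
    pval = c(0.001, 0.001, 0.001), psig = 0.05, log_base = 10)
  expect_equal(tie$target, c("T1", "T3", "T2"))
})

test_that("formula profiling wires k, background and chem scores together", {
  # 10 background compounds; target TA hit by 1 of them, TB by 5 of them.
  links <- rbind(
    data.frame(compound_id = "C1", target = "TA", score = 900L),
    data.frame(compound_id = paste0("C", 1:5), target = "TB", score = 900L),
    data.frame(compound_id = paste0("C", 1:10), target = "TC", score = 900L))
  cfg <- nf_config(psig = 0.2)
  prof <- profile_formula(c("C1", "C2"), links, config = cfg)
  tab <- prof$targets
  expect_equal(tab$n, rep(2L, 3))
  expect_equal(tab$p[tab$target == "TA"], 0.1)
  expect_equal(tab$k[tab$target == "TB"], 2L)
  expect_equal(tab$pval[tab$target == "TA"], binomial_tail(1, 2, 0.1))
  expect_equal(tab$pval[tab$target == "TC"], 1)  # p = 1, always hit
  # rank-1 target scores exactly -log10(pval)
  top <- tab[which.min(tab$pval), ]
  expect_equal(top$gene_score, -log10(top$pval))
  # chem score = mean gene score over each compound's profiled targets
  score_of <- setNames(tab$gene_score, tab$target)
  expect_equal(unname(prof$chem_scores["C1"]),
               mean(score_of[c("TA", "TB", "TC")]))
  expect_equal(unname(prof$chem_scores["C2"]),
               mean(score_of[c("TB", "TC")]))
  # sum over a compound's targets of gene_score / N_i equals its chem score
  expect_equal(sum(score_of[c("TA", "TB", "TC")] / 3),
               unname(prof$chem_scores["C1"]))
})

test_that("profiling errors when a hit target lacks background coverage", {
  links <- data.frame(compound_id = "C1", target = "TA", score = 900L)
  expect_error(profile_formula("C1", links, background = c(TB = 0.1)),
               "TA")
})

test_that("core targets filter to positive scores with stable ordering", {
  links <- rbind(
    data.frame(compound_id = paste0("C", 1:6), target = "TA", score = 900L),
    data.frame(compound_id = "C1", target = "TB", score = 900L),
    data.frame(compound_id = paste0("C", 1:40), target = "TC", score = 900L))
  prof <- profile_formula(paste0("C", 1:6), links,
                          background = c(TA = 0.05, TB = 0.5, TC = 0.9),
                          config = nf_config())
  ct <- core_targets(prof)
  expect_true(all(ct$gene_score > 0))
  expect_equal(ct$gene_score, sort(ct$gene_score, decreasing = TRUE))
  prof_ns <- profile_formula("C1", links,
                             background = c(TA = 0.9, TB = 0.9, TC = 0.9),
                             config = nf_config())
  expect_equal(nrow(core_targets(prof_ns)), 0L)
})

test_that("an impossible-under-null target is flagged, not crashed", {
  links <- data.frame(compound_id = "C1", target = "TA", score = 900L)
  prof <- profile_formula("C1", links, background = c(TA = 0),
                          config = nf_config())
  expect_true(prof$targets$degenerate)
  expect_gt(prof$targets$gene_score, 0)
})
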