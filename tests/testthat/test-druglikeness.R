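test_that("QED agrees with a straight-line desirability evaluation", {
  v <- c(300, 2.5, 3, 1, 60, 3, 2, 0)
  expect_equal(qed(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8]),
               oracle_qed(v), tolerance = 1e-12)
  vs <- withr::with_seed(1, random_descriptors(50))
  got <- qed(vs[, 1], vs[, 2], vs[, 3], vs[, 4], vs[, 5], vs[, 6],
             vs[, 7], vs[, 8])
  want <- apply(vs, 1L, oracle_qed)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("QED under equal weights is the geometric mean of desirabilities", {
  v <- c(420, 4.2, 7, 3, 110, 8, 3, 1)
  d <- oracle_qed_desirabilities(v)
  expect_equal(qed(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8],
                   weights = rep(1, 8)),
               prod(d)^(1 / 8), tolerance = 1e-12)
})

test_that("QED is weight-order invariant and decreasing in alerts", {
  v <- c(350, 1.5, 5, 2, 90, 5, 1, 0)
  w <- qed_weights()
  shuffled <- w[c("ALERTS", "MW", "PSA", "HBD", "AROM", "ALOGP", "ROTB",
                  "HBA")]
  expect_equal(qed(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8],
                   weights = shuffled),
               qed(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8]))
  expect_gt(qed(v[1], v[2], v[3], v[4], v[5], v[6], v[7], 0),
            qed(v[1], v[2], v[3], v[4], v[5], v[6], v[7], 5))
  expect_error(qed(-10, 0, 0, 0, 0, 0, 0, 0), "positive")
  expect_error(qed(300, 0, -1, 0, 0, 0, 0, 0), "non-negative")
})

test_that("Lipinski violations count with inclusive boundaries", {
  expect_equal(lipinski_violations(400, 3, 2, 5), 0L)
  expect_equal(lipinski_violations(600, 6, 6, 11), 4L)
  expect_equal(lipinski_violations(500, 5, 5, 10), 0L)  # "no more than"
})

test_that("Veber violations treat the PSA/HB criterion as a disjunction", {
  expect_equal(veber_violations(3, 60, 1, 3), 0L)
  expect_equal(veber_violations(12, 150, 6, 8), 2L)
  expect_equal(veber_violations(5, 150, 4, 6), 0L)  # HBD+HBA = 10 <= 12
})

test_that("violation counts are monotone in each offending descriptor", {
  base <- withr::with_seed(4, random_descriptors(25))
  for (i in seq_len(nrow(base))) {
    v <- base[i, ]
    l0 <- lipinski_violations(v["MW"], v["ALOGP"], v["HBD"], v["HBA"])
    expect_gte(lipinski_violations(v["MW"] + 300, v["ALOGP"], v["HBD"],
                                   v["HBA"]), l0)
    expect_gte(lipinski_violations(v["MW"], v["ALOGP"] + 4, v["HBD"],
                                   v["HBA"]), l0)
    v0 <- veber_violations(v["ROTB"], v["PSA"], v["HBD"], v["HBA"])
    expect_gte(veber_violations(v["ROTB"] + 8, v["PSA"] + 100, v["HBD"] + 5,
                                v["HBA"] + 5), v0)
  }
})

test_that("screening flags the pass set and stricter thresholds nest", {
  compounds <- data.frame(
    compound_id = c("good", "heavy", "mid"),
    name = NA_character_,
    MW = c(300, 700, 480), ALOGP = c(2, 7, 4.5), HBA = c(3, 12, 9),
    HBD = c(1, 7, 4), PSA = c(60, 190, 120), ROTB = c(3, 14, 9),
    AROM = c(2, 5, 3), ALERTS = c(0, 4, 1))
  res <- screen_compounds(compounds, nf_config())
  expect_equal(nrow(res), 3L)
  expect_false(res$passed[res$compound_id == "heavy"])
  expect_true(res$passed[res$compound_id == "good"])
  expect_equal(res$qed, sort(res$qed, decreasing = TRUE))

  vacuous <- nf_config(qed_min = 0, lipinski_max_violations = 4,
                       veber_max_violations = 2)
  expect_true(all(screen_compounds(compounds, vacuous)$passed))

  strict <- screen_compounds(compounds,
                             nf_config(qed_min = 0.6,
                                       lipinski_max_violations = 0,
                                       veber_max_violations = 0))
  loose <- screen_compounds(compounds, nf_config())
  expect_true(all(strict$compound_id[strict$passed] %in%
                    loose$compound_id[loose$passed]))

  hopeless <- compounds
  hopeless[, c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM",
               "ALERTS")] <-
    list(900, 9, 16, 10, 240, 20, 6, 6)
  res0 <- screen_compounds(hopeless, nf_config())
  expect_equal(sum(res0$passed), 0L)
})
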