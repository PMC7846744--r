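# brute-force AUC oracle: exhaustive pair counting, ties worth one half
pairCountAuc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

test_that("rocAuc equals exhaustive pair counting", {
  expect_equal(rocAuc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(rocAuc(rep(0.5, 4), rep(0.5, 7)), 0.5)
  expect_equal(rocAuc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)  # 3 of 4 pairs
  set.seed(202)
  for (i in 1:50) {
    pos <- round(runif(sample(1:50, 1)), 2)   # rounding forces ties
    neg <- round(runif(sample(1:50, 1)), 2)
    expect_equal(rocAuc(pos, neg), pairCountAuc(pos, neg))
  }
  expect_error(rocAuc(numeric(), c(0.1)), "non-empty")
})

test_that("rocAuc is invariant under strictly increasing transforms", {
  set.seed(7)
  pos <- runif(30); neg <- runif(40)
  expect_equal(rocAuc(pos, neg), rocAuc(exp(3 * pos), exp(3 * neg)))
  expect_equal(rocAuc(pos, neg), rocAuc(qlogis(pos), qlogis(neg)))
})

test_that("confusion metrics match hand-computed values", {
  m <- confusionMetrics(40, 10, 70, 30)
  expect_equal(unname(m[c("sensitivity", "specificity", "tss", "omission")]),
               c(0.8, 0.7, 0.5, 0.2))
  # kappa oracle: po = 110/150, pe from the marginals
  po <- 110 / 150
  pe <- (70 * 50 + 80 * 100) / 150^2
  expect_equal(unname(m["kappa"]), (po - pe) / (1 - pe))
  perfect <- confusionMetrics(25, 0, 75, 0)
  expect_equal(unname(perfect[c("tss", "kappa", "omission")]), c(1, 1, 0))
  expect_error(confusionMetrics(0, 0, 5, 5), "marginal")
  expect_error(confusionMetrics(-1, 1, 5, 5), "non-negative")
})

test_that("all registered learners separate a separable cloud and honor contracts", {
  d <- separableCloud()
  set.seed(1)
  test <- sample(length(d$y), 60)
  for (alg in c("MAXENT", "BRT", "CART")) {
    m <- fitSuitability(alg, d$x[-test, ], d$y[-test], seed = 17)
    p <- predictSuitability(m, d$x[test, ])
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(rocAuc(p[d$y[test] == 1], p[d$y[test] == 0]), 0.95)
    # same seed and data: identical predictions
    m2 <- fitSuitability(alg, d$x[-test, ], d$y[-test], seed = 17)
    expect_equal(predictSuitability(m2, d$x[test, ]), p)
  }
  expect_error(fitSuitability("MARS", d$x, d$y, seed = 1), "unknown algorithm")
  expect_error(fitSuitability("CART", d$x, rep(1L, nrow(d$x)), seed = 1),
               "single class")
})

test_that("algorithm screening tabulates mean metrics ordered by TSS", {
  w <- generateClimateWorld(smallWorldSpec(seed = 13))
  bioc <- computeBioclim(baselineClimatology(w@observed))
  sp <- generateVirtualSpecies(w, 2, seed = 3)
  # single-algorithm registry selection gives a one-row table
  one <- screenAlgorithms(sp, bioc, w@realms, algorithms = "CART",
                          nPerRealm = 1, nRuns = 1, seed = 6)
  expect_equal(nrow(one), 1)
  expect_equal(one$algorithm, "CART")
  tab <- screenAlgorithms(sp, bioc, w@realms, nPerRealm = 1, nRuns = 1,
                          seed = 6)
  expect_setequal(tab$algorithm, c("MAXENT", "BRT", "CART"))
  expect_equal(tab$tss, sort(tab$tss, decreasing = TRUE))
})

test_that("the TSS rule excludes at the boundary inclusively", {
  metrics <- data.frame(
    species_id = rep(c("a", "b", "c"), each = 2),
    algorithm = "CART",
    tss = c(0.40, 0.40, 0.41, 0.41, 0.9, 0.9))
  res <- excludePoorModels(metrics)
  expect_setequal(unique(res$retained$species_id), c("b", "c"))
  expect_equal(res$excluded$species_id, "a")
  expect_equal(res$excluded$reason, "TSS")
  # an empty retained set is allowed
  all4 <- excludePoorModels(metrics, tssMin = 1)
  expect_equal(nrow(all4$retained), 0)
})
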