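mkMap <- function(cells, id = "sp", alg = "CART", scen = "RCP85",
                  h = 2070L, g = gridSpec(20, 20)) {
  new("BinaryRangeMap", speciesId = id, cells = as.integer(cells), grid = g,
      scenario = scen, horizon = h, algorithm = alg, criterion = "P10TP")
}

test_that("range change follows the proportional-loss formula in both dispersal modes", {
  cur <- mkMap(1:100, scen = "current")
  expect_equal(rangeChange(cur, mkMap(1:25), "full")$q, 0.75)
  expect_equal(rangeChange(cur, mkMap(1:100), "full")$q, 0)
  # doubling the range under full dispersal is q = -1 (expansion)
  cur50 <- mkMap(1:50, scen = "current")
  expect_equal(rangeChange(cur50, mkMap(1:100), "full")$q, -1)
  # total loss
  expect_equal(rangeChange(cur, mkMap(integer()), "full")$q, 1)
  # no dispersal counts only persisting cells, so q >= 0 always
  shifted <- mkMap(51:150)
  expect_equal(rangeChange(cur, shifted, "none")$p2, 50)
  expect_equal(rangeChange(cur, shifted, "none")$q, 0.5)
  expect_gte(rangeChange(cur, shifted, "none")$q,
             rangeChange(cur, shifted, "full")$q)
  # linearity in p2
  qs <- vapply(c(0, 25, 50, 75, 100), function(p2)
    rangeChange(cur, mkMap(seq_len(p2)), "full")$q, 0)
  expect_equal(qs, seq(1, 0, by = -0.25))
  # an empty current range is an error, not silent q = 1
  expect_error(rangeChange(mkMap(integer(), scen = "current"), mkMap(1:5),
                           "full"), "empty current")
  expect_error(rangeChange(cur, mkMap(1:5, alg = "BRT"), "full"), "share")
})

test_that("the ensemble averages q over contributing algorithms", {
  rows <- do.call(rbind, lapply(
    list(c("MAXENT", 0.6), c("BRT", 0.7), c("CART", 0.8)),
    function(z) data.frame(species_id = "sp", realm = "r", family = "f",
                           status = "LC", scenario = "D", horizon = 2070,
                           dispersal = "full", algorithm = z[1], p1 = 100,
                           p2 = 40, q = as.numeric(z[2]))))
  ens <- ensembleRangeChange(rows)
  expect_equal(ens$q, 0.7)
  expect_equal(ens$algorithm, "ENSEMBLE")
  expect_equal(ens$contributors, "BRT+CART+MAXENT")
  # one algorithm excluded upstream: mean of the remaining two
  ens2 <- ensembleRangeChange(rows[1:2, ])
  expect_equal(ens2$q, 0.65)
  expect_equal(ens2$contributors, "BRT+MAXENT")
  # single retained algorithm passes through
  expect_equal(ensembleRangeChange(rows[3, ])$q, 0.8)
})

test_that("contraction summaries filter, take medians and bootstrap deterministically", {
  rec <- data.frame(scenario = "D", horizon = 2070, dispersal = "full",
                    q = c(-0.2, 0.3, 0.6))
  s <- summarizeContractions(rec, nBoot = 200, seed = 5)
  expect_equal(s$n, 2)            # the expansion is filtered out
  expect_equal(s$median_q, 0.45)
  sAll <- summarizeContractions(rec, contractingOnly = FALSE, nBoot = 200,
                                seed = 5)
  expect_equal(sAll$n, 3)
  expect_equal(sAll$median_q, 0.3)
  # symmetric set
  sym <- data.frame(scenario = "A", horizon = 2030, dispersal = "none",
                    q = c(0.2, 0.5, 0.8))
  expect_equal(summarizeContractions(sym, nBoot = 100, seed = 1)$median_q, 0.5)
  # seeded bootstrap: identical CIs on reruns, ordered around the median
  set.seed(31)
  big <- data.frame(scenario = "D", horizon = 2070, dispersal = "full",
                    q = runif(60))
  a <- summarizeContractions(big, nBoot = 500, seed = 77)
  b <- summarizeContractions(big, nBoot = 500, seed = 77)
  expect_identical(a, b)
  expect_lte(a$ci_lower, a$median_q)
  expect_gte(a$ci_upper, a$median_q)
})
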