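makeSpecies <- function(mu, sigma = rep(1, 5), sStar = 0.5, cells = 1:60,
                        realm = "realm_1") {
  new("VirtualSpecies", speciesId = "sp1", family = "f", status = "LC",
      realm = realm, presenceCells = as.integer(cells),
      mu = stats::setNames(mu, c("bio1", "bio5", "bio6", "bio12", "bio15")),
      sigma = stats::setNames(sigma, c("bio1", "bio5", "bio6", "bio12", "bio15")),
      sStar = sStar)
}

test_that("true suitability is 1 at the optimum and 1 everywhere as breadth grows", {
  mu <- c(10, 25, -5, 900, 40)
  sp <- makeSpecies(mu)
  x <- matrix(mu, nrow = 1, dimnames = list(NULL, names(sp@mu)))
  expect_equal(trueSuitability(sp, x), 1)
  # far-away cell under enormous breadth is still fully suitable
  far <- x + 100
  wide <- makeSpecies(mu, sigma = rep(1e9, 5))
  expect_equal(trueSuitability(wide, far), 1, tolerance = 1e-6)
  expect_lt(trueSuitability(sp, x + 2), 1)
})

test_that("every generated species satisfies its type invariants", {
  w <- generateClimateWorld(smallWorldSpec(seed = 21))
  sp <- generateVirtualSpecies(w, 12, seed = 8)
  expect_length(sp, 12)
  for (s in sp) {
    expect_true(validObject(s))
    expect_gte(length(s@presenceCells), 50)
    expect_true(all(s@sigma > 0))
    expect_gt(s@sStar, 0); expect_lt(s@sStar, 1)
    # all presence cells within the species' single realm
    expect_setequal(unique(realmOf(w@realms, s@presenceCells)), s@realm)
    # presence is exactly deterministic thresholding of true suitability
    bioc <- computeBioclim(baselineClimatology(w@observed))
    cellsR <- realmCells(w@realms, s@realm)
    su <- trueSuitability(s, bioc, cells = cellsR)
    expect_setequal(s@presenceCells, cellsR[su >= s@sStar])
  }
  # regeneration with the same seed is identical
  sp2 <- generateVirtualSpecies(w, 12, seed = 8)
  expect_identical(lapply(sp, slot, "presenceCells"),
                   lapply(sp2, slot, "presenceCells"))
})

test_that("true range change has the identity, total-loss and ordering properties", {
  w <- generateClimateWorld(worldSpec(nrow = 10, ncol = 10, nRealms = 1,
    cellSize = 1, ymax = 60, baselineYears = c(1981, 1990),
    scenarioYears = c(2006, 2086), horizons = c(2070), seed = 31))
  bioc <- computeBioclim(baselineClimatology(w@observed))
  sp <- generateVirtualSpecies(w, 4, seed = 5, minPresence = 10,
                               nicheSpec = list(maxPresenceFrac = 0.6))
  for (s in sp) {
    # identity climate: the realized range is recovered exactly, q = 0
    same <- trueRangeChange(s, bioc, "full", w@realms)
    expect_equal(same$q, 0)
    expect_setequal(same$futureCells, s@presenceCells)
    # a world warmed far past the envelope loses everything, q = 1
    hot <- bioc
    hot@values[, c("bio1", "bio5", "bio6")] <-
      hot@values[, c("bio1", "bio5", "bio6")] + 1000
    expect_equal(trueRangeChange(s, hot, "full", w@realms)$q, 1)
    expect_equal(trueRangeChange(s, hot, "none", w@realms)$q, 1)
  }
  # dispersal ordering, verified against explicit set enumeration
  fut <- computeBioclim(deltaBiasCorrect(
    baselineClimatology(w@modelBaseline), baselineClimatology(w@observed),
    horizonMean(w@scenarios$RCP85, 2070)))
  for (s in sp) {
    full <- trueRangeChange(s, fut, "full", w@realms)
    none <- trueRangeChange(s, fut, "none", w@realms)
    expect_gte(none$q, full$q)
    expect_setequal(none$futureCells,
                    intersect(full$futureCells, s@presenceCells))
    expect_gte(none$q, 0)
  }
})

test_that("an empty current range is an error, not q = 1", {
  # the type itself rejects an empty presence set at construction
  expect_error(makeSpecies(c(10, 25, -5, 900, 40), cells = integer()),
               "non-empty")
  sp <- makeSpecies(c(10, 25, -5, 900, 40), cells = 1:25)
  sp@presenceCells <- integer()   # simulate a degraded record
  g <- gridSpec(5, 5)
  mask <- new("RealmMask", realm = rep(1L, 25), levels = "realm_1", grid = g)
  bioc <- new("BioclimStack",
              values = matrix(rep(c(10, 25, -5, 900, 40), each = 25), 25,
                              dimnames = list(NULL, names(sp@mu))),
              grid = g, label = "x")
  expect_error(trueRangeChange(sp, bioc, "full", mask), "undefined")
})
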