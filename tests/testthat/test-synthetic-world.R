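test_that("scenario specifications carry the prescribed forcings", {
  sc <- defaultScenarios(hosingRegion = "realm_1")
  expect_equal(sc$RCP85@forcingSv, 0)
  expect_equal(sc$A@forcingSv, 0.11)
  expect_equal(sc$B@forcingSv, 0.22)
  expect_equal(sc$C@forcingSv, 0.34)
  expect_equal(sc$D@forcingSv, 0.68)
  expect_equal(sc$D@forcingWindow, c(2020L, 2070L))
  # control carries no hosing terms
  expect_equal(sc$RCP85@hosingCooling, 0)
  expect_equal(sc$RCP85@precipAnomaly, 0)
  expect_length(sc$RCP85@hosingRegion, 0)
  # near-saturating response: A within 5% of D's amplitude
  expect_gt(sc$A@hosingCooling / sc$D@hosingCooling, 0.95)
})

test_that("a nonexistent hosing realm is a configuration error", {
  expect_error(
    worldSpec(nrow = 6, ncol = 12, nRealms = 2, seed = 1,
              scenarios = defaultScenarios(hosingRegion = "Atlantis")),
    "nonexistent realm")
})

test_that("world generation is deterministic and respects cube invariants", {
  spec <- smallWorldSpec(seed = 7)
  w1 <- generateClimateWorld(spec)
  w2 <- generateClimateWorld(spec)
  expect_identical(w1@observed@tmean, w2@observed@tmean)
  expect_identical(w1@scenarios$D@prec, w2@scenarios$D@prec)
  expect_identical(w1@realms@realm, w2@realms@realm)
  # type invariants hold on every cube
  for (cube in c(list(w1@observed, w1@modelBaseline), w1@scenarios))
    expect_true(validObject(cube))
  # realms partition the grid into contiguous longitudinal bands
  expect_setequal(unique(w1@realms@realm), 1:2)
  cc <- cellCenters(w1@realms@grid)
  expect_true(all(tapply(cc$col, w1@realms@realm, function(cols)
    length(unique(cols)) == diff(range(cols)) + 1)))
})

test_that("zero-forcing scenarios are statistically indistinguishable from the model baseline", {
  sc <- list(scenarioSpec("RCP85", warmingRate = 0))
  spec <- smallWorldSpec(seed = 3, scenarios = sc)
  w <- generateClimateWorld(spec)
  cellMeanDiff <- apply(w@scenarios$RCP85@tmean, 3, mean) -
    apply(w@modelBaseline@tmean, 3, mean)
  se <- stats::sd(cellMeanDiff) / sqrt(length(cellMeanDiff))
  expect_lt(abs(mean(cellMeanDiff)), 3 * se)
})

test_that("hosing anomalies are confined to the hosing region", {
  w <- generateClimateWorld(smallWorldSpec(seed = 5))
  outside <- realmCells(w@realms, "realm_2")
  for (lab in c("A", "D")) {
    expect_identical(w@scenarios[[lab]]@tmean[, , outside],
                     w@scenarios$RCP85@tmean[, , outside])
    expect_identical(w@scenarios[[lab]]@prec[, , outside],
                     w@scenarios$RCP85@prec[, , outside])
  }
  # and inside the region the anomaly is real: colder winters, drier
  inside <- realmCells(w@realms, "realm_1")
  late <- w@scenarios$D@years >= 2060
  expect_lt(mean(w@scenarios$D@tmin[late, 1, inside]),
            mean(w@scenarios$RCP85@tmin[late, 1, inside]) - 1)
  expect_lt(mean(w@scenarios$D@prec[late, , inside]),
            mean(w@scenarios$RCP85@prec[late, , inside]))
})

test_that("six realms take the six biogeographic realm names", {
  expect_setequal(realmLevels(6),
                  c("Afrotropical", "Australasian", "Indomalayan",
                    "Nearctic", "Neotropical", "Palearctic"))
  w <- generateClimateWorld(worldSpec(nrow = 6, ncol = 12, nRealms = 6,
    seed = 2, scenarios = defaultScenarios(hosingRegion = "Palearctic")))
  expect_setequal(unique(realmOf(w@realms, seq_len(nCell(w@realms@grid)))),
                  realmLevels(6))
})
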