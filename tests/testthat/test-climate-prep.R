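test_that("horizon means reduce constants, single years and linear trends correctly", {
  const <- makeCube(years = 2000:2029, tmean = rep(10, 12))
  clim <- horizonMean(const, 2015, width = 30)
  expect_equal(unname(clim@tmean), matrix(10, 12, 4))
  # width 1 picks out the single year's monthly fields
  trend <- makeCube(years = 2000:2029, tmean = 1:12, yearTrend = 0.5)
  one <- horizonMean(trend, 2004, width = 1)
  expect_equal(one@tmean[, 1], 1:12 + 0.5 * 4)
  # a linear trend averages to the value at the window midpoint
  win <- horizonMean(trend, 2015, width = 30)
  midpointYears <- 2000:2029
  expect_equal(win@tmean[3, 1], 3 + 0.5 * mean(midpointYears - 2000))
  # windows beyond the cube are range errors
  expect_error(horizonMean(const, 2040, width = 30), "exceeds")
  expect_error(horizonMean(const, 1999, width = 30), "exceeds")
})

test_that("delta bias correction shifts by the monthly bias and clamps precipitation", {
  g <- gridSpec(3, 3)
  obs <- horizonMean(makeCube(3, 3, 2000:2001, tmean = rep(10, 12),
                              prec = rep(30, 12)), 2001, 2)
  biased <- obs
  biased@tmean <- obs@tmean + 2
  biased@tmin <- obs@tmin + 2
  biased@tmax <- obs@tmax + 2
  biased@prec <- obs@prec + 25
  target <- obs
  target@tmean <- obs@tmean + 5
  target@prec <- matrix(10, 12, 9)
  # zero bias: target unchanged
  expect_equal(deltaBiasCorrect(obs, obs, target)@tmean, target@tmean)
  # +2 degree bias: corrected = target - 2 everywhere
  expect_equal(deltaBiasCorrect(biased, obs, target)@tmean, target@tmean - 2)
  # +25 mm bias on a 10 mm target: clamped at zero
  expect_equal(unname(deltaBiasCorrect(biased, obs, target)@prec),
               matrix(0, 12, 9))
  # correcting the model baseline itself recovers the observed baseline
  expect_equal(deltaBiasCorrect(biased, obs, biased)@tmean, obs@tmean)
  # grid mismatch is an alignment error
  other <- horizonMean(makeCube(2, 2, 2000:2001), 2001, 2)
  expect_error(deltaBiasCorrect(obs, obs, other), "grid")
})

test_that("bioclim variables match hand-derived values", {
  cube <- makeCube(2, 2, 2000:2000, tmean = rep(10, 12), spread = 5,
                   prec = rep(100, 12))
  b <- computeBioclim(horizonMean(cube, 2000, 1))@values
  expect_equal(unname(b[1, ]), c(10, 15, 5, 1200, 0))
  # monthly tmax 1..12 -> bio5 = 12
  cube2 <- makeCube(2, 2, 2000:2000, tmean = 1:12 - 5, spread = 5)
  expect_equal(unname(computeBioclim(horizonMean(cube2, 2000, 1))@values[1, "bio5"]),
               12)
  # alternating 50/150 precipitation: bio12 = 1200 and bio15 follows the
  # +1 mm, sample-sd convention (oracle: stats::sd on the offset months)
  alt <- makeCube(2, 2, 2000:2000, prec = rep(c(50, 150), 6))
  b3 <- computeBioclim(horizonMean(alt, 2000, 1))@values
  expect_equal(unname(b3[1, "bio12"]), 1200)
  expect_equal(unname(b3[1, "bio15"]),
               100 * stats::sd(rep(c(51, 151), 6)) / mean(rep(c(51, 151), 6)))
})

test_that("bioclim computation commutes with uniform temperature shifts", {
  cube <- makeCube(2, 2, 2000:2004, tmean = c(3, 5, 8, 12, 15, 18, 20, 19, 14, 9, 6, 4))
  base <- computeBioclim(horizonMean(cube, 2002, 5))@values
  shifted <- cube
  shifted@tmean <- cube@tmean + 2.5
  shifted@tmin <- cube@tmin + 2.5
  shifted@tmax <- cube@tmax + 2.5
  shift <- computeBioclim(horizonMean(shifted, 2002, 5))@values
  expect_equal(shift[, c("bio1", "bio5", "bio6")],
               base[, c("bio1", "bio5", "bio6")] + 2.5)
  expect_equal(shift[, c("bio12", "bio15")], base[, c("bio12", "bio15")])
})

test_that("bio15 is scale-invariant up to the +1 offset for wet climates", {
  prec <- c(120, 180, 240, 200, 160, 140, 100, 90, 110, 130, 150, 170)
  cube1 <- makeCube(1, 1, 2000:2000, prec = prec)
  cube3 <- makeCube(1, 1, 2000:2000, prec = 3 * prec)
  b1 <- computeBioclim(horizonMean(cube1, 2000, 1))@values[1, "bio15"]
  b3 <- computeBioclim(horizonMean(cube3, 2000, 1))@values[1, "bio15"]
  expect_equal(unname(b1), unname(b3), tolerance = 0.01)
})

test_that("block-mean aggregation averages unmasked cells and conserves the grand mean", {
  g <- gridSpec(3, 3)
  mk <- function(vals) {
    v <- cbind(bio1 = vals, bio5 = vals + 10, bio6 = vals - 10,
               bio12 = abs(vals) * 100, bio15 = abs(vals))
    new("BioclimStack", values = v, grid = g, label = "t")
  }
  stack <- mk(as.numeric(1:9))
  agg <- aggregateGrid(stack, 3)
  expect_equal(unname(agg@values[1, "bio1"]), 5)  # mean of 1..9
  expect_equal(nCell(agg@grid), 1L)
  # a block with 8 masked cells keeps its single value
  vals <- c(NA, NA, NA, NA, 7, NA, NA, NA, NA)
  expect_equal(unname(aggregateGrid(mk(vals), 3)@values[1, "bio1"]), 7)
  # a fully masked block stays masked
  expect_true(is.na(aggregateGrid(mk(rep(NA_real_, 9)), 3)@values[1, "bio1"]))
  # factor 1 is the identity
  expect_identical(aggregateGrid(stack, 1), stack)
  # grand mean conserved when all blocks are fully unmasked
  g6 <- gridSpec(6, 6)
  big <- new("BioclimStack",
             values = {
               v <- matrix(rnorm(36 * 5, 50, 5), 36, 5,
                           dimnames = list(NULL, colnames(stack@values)))
               v[, "bio6"] <- v[, "bio1"] - 10; v[, "bio5"] <- v[, "bio1"] + 10
               v
             }, grid = g6, label = "t")
  expect_equal(colMeans(aggregateGrid(big, 3)@values), colMeans(big@values))
  # bad factors are parameter errors
  expect_error(aggregateGrid(stack, 0), "factor")
  expect_error(aggregateGrid(stack, 2), "divisible")
})
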