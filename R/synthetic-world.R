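#' Construct a scenario specification
#'
#' The control scenario (`RCP85`) carries only the secular warming trend.
#' Hosing scenarios `A`--`D` (0.11, 0.22, 0.34, 0.68 Sv of freshwater,
#' released 2020--2070) superimpose a regional anomaly: a winter-amplified
#' cooling and a fractional precipitation change inside `hosingRegion`,
#' ramping linearly over `forcingWindow` and persisting afterwards (the
#' overturning circulation does not recover within the century).
#'
#' The default anomaly amplitudes saturate quickly in the forcing,
#' `amplitude(f) = A_max * tanh(f / 0.05 Sv)`, so even the weakest hosing run
#' produces a near-maximal regional response — the tipping-point behaviour in
#' which impacts are largely insensitive to the amount of freshwater
#' released.  Defaults: `A_max = 6` degrees C cooling and a 35% precipitation
#' reduction.
#'
#' @param label scenario label, one of `RCP85`, `A`, `B`, `C`, `D`.
#' @param hosingRegion realm names receiving the hosing anomaly (ignored for
#'   `RCP85`).
#' @param warmingRate warming trend in degrees C per decade.
#' @param hosingCooling winter-peak cooling amplitude (degrees C); default is
#'   the saturating response above.
#' @param precipAnomaly fractional precipitation anomaly; default saturating.
#' @param forcingWindow freshwater release years.
#' @return a [ScenarioSpec-class].
#' @export
scenarioSpec <- function(label, hosingRegion = character(),
                         warmingRate = 0.55,
                         hosingCooling = NULL, precipAnomaly = NULL,
                         forcingWindow = c(2020L, 2070L)) {
  label <- match.arg(label, SCENARIO_LABELS)
  f <- unname(HOSING_FORCINGS[label])
  sat <- tanh(f / 0.05)
  if (f == 0) {
    hosingCooling <- 0; precipAnomaly <- 0; hosingRegion <- character()
  } else {
    hosingCooling <- hosingCooling %||% (6 * sat)
    precipAnomaly <- precipAnomaly %||% (-0.35 * sat)
  }
  new("ScenarioSpec", label = label, forcingSv = f,
      forcingWindow = as.integer(forcingWindow), warmingRate = warmingRate,
      hosingCooling = hosingCooling, hosingRegion = hosingRegion,
      precipAnomaly = precipAnomaly)
}

#' Default scenario set: control plus the four hosing runs
#' @param hosingRegion realm names receiving the hosing anomaly.
#' @param warmingRate warming trend, degrees C per decade.
#' @return list of five [ScenarioSpec-class] objects named by label.
#' @export
defaultScenarios <- function(hosingRegion, warmingRate = 0.55) {
  sc <- lapply(SCENARIO_LABELS, function(l)
    scenarioSpec(l, hosingRegion = hosingRegion, warmingRate = warmingRate))
  names(sc) <- SCENARIO_LABELS
  sc
}

#' Construct a world specification
#'
#' Defaults describe the study-scale synthetic world: a 30 x 60 grid of
#' 1/3-degree cells spanning two longitudinal realms, a 1970--2000 baseline,
#' scenario trajectories 2006--2100, horizons 2030/2050/2070, and the five
#' default scenarios with the hosing anomaly confined to the first realm.
#'
#' @param nrow,ncol,cellSize,xmin,ymax grid geometry.
#' @param nRealms number of contiguous longitudinal realm bands.
#' @param baselineYears,scenarioYears inclusive year ranges.
#' @param horizons horizon center years.
#' @param scenarios list of [ScenarioSpec-class]; default [defaultScenarios()]
#'   with the hosing region set to the first realm.
#' @param noiseSd named noise scales (`temp` degrees C, `prec` log-sd).
#' @param seed master seed (mandatory).
#' @return a validated [WorldSpec-class].
#' @export
worldSpec <- function(nrow = 30, ncol = 60, cellSize = 1 / 3,
                      xmin = 0, ymax = 62,
                      nRealms = 2, baselineYears = c(1970, 2000),
                      scenarioYears = c(2006, 2100),
                      horizons = c(2030, 2050, 2070),
                      scenarios = NULL,
                      noiseSd = c(temp = 0.8, prec = 0.15), seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(scenarios))
    scenarios <- defaultScenarios(hosingRegion = realmLevels(nRealms)[1])
  new("WorldSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      cellSize = cellSize, xmin = xmin, ymax = ymax,
      nRealms = as.integer(nRealms),
      baselineYears = as.integer(baselineYears),
      scenarioYears = as.integer(scenarioYears),
      horizons = as.integer(horizons), scenarios = scenarios,
      noiseSd = noiseSd, seed = as.integer(seed))
}

# Deterministic mean monthly fields (12 x nCell) for the synthetic world:
# temperature follows a steep latitudinal gradient (2 degrees C per degree of
# latitude, so the domain spans far more climate space than a century of
# warming) with a latitude-dependent seasonal cycle (northern-hemisphere
# phase, July warmest); precipitation follows a longitudinal wet-to-dry
# gradient with a winter-peak seasonal cycle.  Because the seasonal
# amplitude grows with latitude, the bio5 and bio6 isolines shift at
# different speeds under warming, so spatial analogues degrade gradually.
# Units: degrees C and mm/month.
baseMonthlyFields <- function(grid) {
  cc <- cellCenters(grid)
  m <- seq_len(12)
  seasT <- cos(2 * pi * (m - 7) / 12)       # +1 in July
  seasP <- 1 + 0.6 * cos(2 * pi * (m - 1) / 12)  # wetter in January
  tmean <- outer(seasT, pmax(2, 2 + 0.8 * (cc$lat - 45))) +
    matrix(25 - 2 * (cc$lat - 45), nrow = 12, ncol = nrow(cc), byrow = TRUE)
  lonSpan <- grid@ncol * grid@cellSize
  precBase <- 20 + 110 * (grid@xmin + lonSpan - cc$lon) / lonSpan
  prec <- outer(seasP, precBase)
  list(tmean = tmean, tmin = tmean - 5, tmax = tmean + 5, prec = prec)
}

# Smooth injected model-bias fields per variable (deterministic given seed).
biasFields <- function(grid, seed) {
  cc <- cellCenters(grid)
  withSeed(seed, {
    ph <- runif(4, 0, 2 * pi)
    amp <- runif(4, 0.8, 1.8)
  })
  wave <- function(k) sin(2 * pi * cc$col / grid@ncol + ph[k]) *
    cos(2 * pi * cc$row / grid@nrow + ph[(k %% 4) + 1])
  list(tmean = amp[1] * wave(1), tmin = amp[2] * wave(2),
       tmax = amp[3] * wave(3), prec = 8 * amp[4] * wave(4))
}

# One cube's worth of noise: additive N(0, sd) for temperatures (the tmin/tmax
# spreads use folded noise so ordering is preserved), multiplicative
# log-normal for precipitation.
noiseDraw <- function(nYear, nCellN, noiseSd, seed) {
  withSeed(seed, {
    dims <- c(nYear, 12, nCellN)
    nAll <- prod(dims)
    list(t0 = array(stats::rnorm(nAll, 0, noiseSd["temp"]), dims),
         dlo = array(abs(stats::rnorm(nAll, 0, noiseSd["temp"])), dims),
         dhi = array(abs(stats::rnorm(nAll, 0, noiseSd["temp"])), dims),
         pf = array(exp(stats::rnorm(nAll, -noiseSd["prec"]^2 / 2,
                                     noiseSd["prec"])), dims))
  })
}

# Assemble a ClimateCube from monthly-mean fields plus per-index anomalies
# and a noise draw.  `anomT` and `precFactor` are (year, 12, cell) arrays
# (or scalars) applied to all temperatures / to precipitation.
assembleCube <- function(fields, years, grid, scenario, noise,
                         biasMul = 0, bias = NULL, anomT = 0, precFactor = 1) {
  nY <- length(years); nC <- nCell(grid)
  expand <- function(mField, b) {
    a <- aperm(array(mField, c(12, nC, nY)), c(3, 1, 2))
    if (biasMul != 0) a <- a + biasMul * aperm(array(rep(b, each = 12),
                                                    c(12, nC, nY)), c(3, 1, 2))
    a
  }
  b <- bias %||% list(tmean = 0, tmin = 0, tmax = 0, prec = 0)
  tmean <- expand(fields$tmean, b$tmean) + anomT + noise$t0
  tmin <- expand(fields$tmin, b$tmin) + anomT + noise$t0 - noise$dlo
  tmax <- expand(fields$tmax, b$tmax) + anomT + noise$t0 + noise$dhi
  prec <- pmax(expand(fields$prec, b$prec), 0) * precFactor * noise$pf
  # bias can push the tmin/tmax envelopes through tmean; restore ordering
  tmin <- pmin(tmin, tmean)
  tmax <- pmax(tmax, tmean)
  new("ClimateCube", tmin = tmin, tmax = tmax, tmean = tmean, prec = prec,
      years = as.integer(years), grid = grid, scenario = scenario)
}

# Hosing ramp: zero before the forcing window, then a linear rise over a
# short response time (the overturning circulation collapses within about a
# decade of the freshwater release starting), saturating at 1 and persisting
# after the forcing stops (the circulation does not recover this century).
hosingRamp <- function(years, window, responseYears = 10) {
  tau <- min(responseYears, diff(window))
  pmin(pmax((years - window[1]) / tau, 0), 1)
}

#' Generate a synthetic climate world
#'
#' Produces an observed baseline cube (stationary in expectation), a model
#' baseline cube carrying a fixed smooth bias field (so delta bias correction
#' can be exercised and tested), one scenario cube per [ScenarioSpec-class],
#' and a realm mask.  All scenario cubes share one trajectory noise draw, so
#' cells outside the hosing region are bit-identical between the control and
#' the hosing runs, and differences between scenarios are purely the
#' deterministic anomalies.
#'
#' Scenario trajectories add the warming trend (degrees C per decade,
#' measured from the baseline end year) to all temperatures.  Hosing
#' scenarios additionally apply, within their region and forcing window
#' ramp, a cooling with winter-peaked seasonal weight `1 + cos(2 pi (m-1)/12)`
#' (mean 1 over the year: winters cool by twice the amplitude, summers are
#' untouched and keep warming) and a fractional precipitation anomaly.
#'
#' @param spec a [WorldSpec-class].
#' @return a [ClimateWorld-class].
#' @examples
#' w <- generateClimateWorld(worldSpec(nrow = 6, ncol = 12, nRealms = 2,
#'                                     scenarioYears = c(2006, 2090),
#'                                     seed = 1))
#' w@realms
#' @export
generateClimateWorld <- function(spec) {
  validObject(spec)
  grid <- gridSpec(spec@nrow, spec@ncol, spec@cellSize, spec@xmin, spec@ymax)
  realms <- makeRealmMask(grid, spec@nRealms)
  fields <- baseMonthlyFields(grid)
  bias <- biasFields(grid, deriveSeed(spec@seed, "bias"))
  baseYears <- seq(spec@baselineYears[1], spec@baselineYears[2])
  scenYears <- seq(spec@scenarioYears[1], spec@scenarioYears[2])
  nC <- nCell(grid)

  observed <- assembleCube(fields, baseYears, grid, "observed",
    noiseDraw(length(baseYears), nC, spec@noiseSd, deriveSeed(spec@seed, "obs")))
  modelBaseline <- assembleCube(fields, baseYears, grid, "model_baseline",
    noiseDraw(length(baseYears), nC, spec@noiseSd, deriveSeed(spec@seed, "modelbase")),
    biasMul = 1, bias = bias)

  trajNoise <- noiseDraw(length(scenYears), nC, spec@noiseSd,
                         deriveSeed(spec@seed, "trajectory"))
  winterW <- 1 + cos(2 * pi * (seq_len(12) - 1) / 12)

  cubes <- lapply(spec@scenarios, function(sc) {
    warm <- sc@warmingRate * (scenYears - spec@baselineYears[2]) / 10
    anomT <- array(warm, c(length(scenYears), 12, nC))
    precFactor <- 1
    if (sc@forcingSv > 0) {
      ramp <- hosingRamp(scenYears, sc@forcingWindow)
      inRegion <- realms@realm %in% match(sc@hosingRegion, realms@levels)
      regional <- outer(ramp, winterW)                 # (year, month)
      cool <- array(0, c(length(scenYears), 12, nC))
      cool[, , inRegion] <- -sc@hosingCooling * as.vector(regional)
      anomT <- anomT + cool
      pf <- array(1, c(length(scenYears), 12, nC))
      pf[, , inRegion] <- pmax(1 + sc@precipAnomaly *
                                 array(ramp, c(length(scenYears), 12, sum(inRegion))), 0)
      precFactor <- pf
    }
    assembleCube(fields, scenYears, grid, sc@label, trajNoise,
                 biasMul = 1, bias = bias, anomT = anomT,
                 precFactor = precFactor)
  })
  names(cubes) <- vapply(spec@scenarios, slot, "", "label")

  new("ClimateWorld", observed = observed, modelBaseline = modelBaseline,
      scenarios = cubes, realms = realms, spec = spec)
}

setMethod("show", "ClimateCube", function(object) {
  cat(sprintf("ClimateCube '%s': years %d-%d, %d x %d grid\n",
              object@scenario, min(object@years), max(object@years),
              object@grid@nrow, object@grid@ncol))
})

setMethod("show", "ClimateWorld", function(object) {
  cat(sprintf("ClimateWorld: %d x %d grid, %d realm(s), scenarios: %s\n",
              object@spec@nrow, object@spec@ncol, object@spec@nRealms,
              paste(names(object@scenarios), collapse = ", ")))
})
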