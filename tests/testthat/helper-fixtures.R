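# Shared fixtures built in code.

# Build a tiny ClimateCube directly from per-month values (recycled over
# years and cells) for arithmetic oracles.
makeCube <- function(nrow = 2, ncol = 2, years = 2000:2002,
                     tmean = rep(10, 12), spread = 5, prec = rep(100, 12),
                     yearTrend = 0, scenario = "test") {
  g <- gridSpec(nrow, ncol)
  nC <- nCell(g)
  nY <- length(years)
  mk <- function(monthVals) {
    a <- array(rep(monthVals, each = nY), c(nY, 12, nC))
    a + array(yearTrend * (years - years[1]), c(nY, 12, nC))
  }
  new("ClimateCube", tmean = mk(tmean), tmin = mk(tmean - spread),
      tmax = mk(tmean + spread), prec = pmax(mk(prec), 0),
      years = as.integer(years), grid = g, scenario = scenario)
}

# A fast, fully deterministic little world for structural tests.  The realm
# size (21 x 21 cells) still leaves room for >= 50-cell ranges plus 3:1
# realm-background pseudoabsences.
smallWorldSpec <- function(seed = 11, ...) {
  worldSpec(nrow = 21, ncol = 42, nRealms = 2, baselineYears = c(1981, 1990),
            scenarioYears = c(2006, 2086), horizons = c(2030, 2070),
            seed = seed, ...)
}

# Bioclim matrix helper for model tests: two well-separated Gaussian clouds
# in bioclim space (fixed seed).
separableCloud <- function(n = 120, seed = 99, gap = 6) {
  set.seed(seed)
  x1 <- cbind(rnorm(n, 10), rnorm(n, 25), rnorm(n, -5),
              rnorm(n, 900, 50), rnorm(n, 40, 3))
  x0 <- x1 + matrix(rep(c(gap, gap, gap, 200, 8), each = n), nrow = n)
  x <- rbind(x1, x0)
  colnames(x) <- c("bio1", "bio5", "bio6", "bio12", "bio15")
  list(x = x, y = rep(c(1L, 0L), each = n))
}

# The study-scale pipeline run shared by the acceptance tests: 30 x 60 grid
# of 1/3-degree cells, two realms, 36 virtual species, the control plus all
# four hosing scenarios, horizons 2030/2070, three algorithms, ten runs.
# Memoised: computed once per test session.
.acceptanceCache <- new.env(parent = emptyenv())
acceptanceRun <- function() {
  if (is.null(.acceptanceCache$res)) {
    ws <- worldSpec(seed = 42, scenarioYears = c(2006, 2090),
                    horizons = c(2030, 2070))
    cfg <- pipelineConfig(ws, nSpecies = 36, nRuns = 10, seed = 42)
    .acceptanceCache$res <- runPipeline(cfg)
  }
  .acceptanceCache$res
}
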