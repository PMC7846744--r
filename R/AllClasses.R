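#' @import methods
NULL

BIOCLIM_VARS <- c("bio1", "bio5", "bio6", "bio12", "bio15")
CLIM_VARS <- c("tmin", "tmax", "tmean", "prec")
THRESHOLD_CRITERIA <- c("MTP", "P10TP", "ESS", "MSS")
SCENARIO_LABELS <- c("RCP85", "A", "B", "C", "D")
HOSING_FORCINGS <- c(RCP85 = 0, A = 0.11, B = 0.22, C = 0.34, D = 0.68)
IUCN_STATUSES <- c("LC", "NT", "VU", "EN", "CR", "DD")
SIX_REALMS <- c("Afrotropical", "Australasian", "Indomalayan",
                "Nearctic", "Neotropical", "Palearctic")

#' Regular longitude--latitude grid
#'
#' Cells are indexed 1-based, row-major from the north-west corner: cell 1 is
#' the NW corner, cell `ncol` the NE corner, and row `r`, column `c` maps to
#' id `(r - 1) * ncol + c`.  Cell bounding boxes are half-open.
#'
#' @slot nrow,ncol grid dimensions (rows run north to south).
#' @slot cellSize cell edge length in degrees.
#' @slot xmin western edge longitude (degrees).
#' @slot ymax northern edge latitude (degrees).
#' @export
setClass("GridSpec",
  representation(nrow = "integer", ncol = "integer", cellSize = "numeric",
                 xmin = "numeric", ymax = "numeric"))

setValidity("GridSpec", function(object) {
  if (object@nrow < 1L || object@ncol < 1L) return("grid dimensions must be positive")
  if (object@cellSize <= 0) return("cellSize must be positive")
  TRUE
})

#' @param nrow,ncol,cellSize,xmin,ymax see slots of [GridSpec-class].
#' @rdname GridSpec-class
#' @export
gridSpec <- function(nrow, ncol, cellSize = 1, xmin = 0, ymax = nrow * cellSize) {
  new("GridSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      cellSize = as.numeric(cellSize), xmin = as.numeric(xmin),
      ymax = as.numeric(ymax))
}

#' Realm labels over a grid
#'
#' Assigns every cell of a grid to exactly one biogeographic realm.
#'
#' @slot realm integer realm index per cell (row-major order).
#' @slot levels realm names; `realm` indexes into this vector.
#' @slot grid the [GridSpec-class] the mask lives on.
#' @export
setClass("RealmMask",
  representation(realm = "integer", levels = "character", grid = "GridSpec"))

setValidity("RealmMask", function(object) {
  n <- object@grid@nrow * object@grid@ncol
  if (length(object@realm) != n) return("realm vector length must equal cell count")
  if (anyNA(object@realm)) return("realms must be collectively exhaustive (no NA)")
  if (any(object@realm < 1L | object@realm > length(object@levels)))
    return("realm indices out of range")
  TRUE
})

#' Monthly climate cube
#'
#' Monthly minimum/maximum/mean temperature (degrees C) and precipitation
#' (mm/month) fields per year on a regular grid, for one scenario.
#' Arrays are indexed `[year, month, cell]`.
#'
#' @slot tmin,tmax,tmean,prec numeric arrays of dimension
#'   `(n_years, 12, n_cells)`.
#' @slot years the calendar years covered (first array dimension).
#' @slot grid the [GridSpec-class].
#' @slot scenario scenario label (e.g. `"observed"`, `"RCP85"`, `"D"`).
#' @export
setClass("ClimateCube",
  representation(tmin = "array", tmax = "array", tmean = "array",
                 prec = "array", years = "integer", grid = "GridSpec",
                 scenario = "character"))

setValidity("ClimateCube", function(object) {
  d <- dim(object@tmean)
  n <- object@grid@nrow * object@grid@ncol
  for (v in CLIM_VARS) {
    dv <- dim(slot(object, v))
    if (length(dv) != 3L || dv[2] != 12L)
      return(sprintf("%s must be a (year, 12, cell) array", v))
    if (!identical(dv, d)) return("all variables must share one array shape")
  }
  if (d[1] != length(object@years)) return("years must match first array dimension")
  if (d[3] != n) return("third array dimension must equal the cell count")
  if (any(object@tmin > object@tmean + 1e-9) || any(object@tmean > object@tmax + 1e-9))
    return("tmin <= tmean <= tmax violated")
  if (any(object@prec < 0)) return("precipitation must be non-negative")
  TRUE
})

#' Scenario forcing description
#'
#' One climate trajectory: either the high-warming control (`RCP85`,
#' `forcingSv = 0`) or a hosing run that superimposes a freshwater-driven
#' regional cooling and precipitation anomaly on the control warming.
#'
#' @slot label one of `RCP85`, `A`, `B`, `C`, `D`.
#' @slot forcingSv freshwater forcing in Sverdrups (0, 0.11, 0.22, 0.34, 0.68).
#' @slot forcingWindow years over which freshwater is released (hosing only).
#' @slot warmingRate secular warming trend, degrees C per decade.
#' @slot hosingCooling winter-peak regional cooling amplitude, degrees C.
#' @slot hosingRegion realm names receiving the hosing anomaly.
#' @slot precipAnomaly fractional precipitation change in the hosing region.
#' @export
setClass("ScenarioSpec",
  representation(label = "character", forcingSv = "numeric",
                 forcingWindow = "integer", warmingRate = "numeric",
                 hosingCooling = "numeric", hosingRegion = "character",
                 precipAnomaly = "numeric"))

setValidity("ScenarioSpec", function(object) {
  if (!object@label %in% SCENARIO_LABELS)
    return(sprintf("label must be one of %s", paste(SCENARIO_LABELS, collapse = ", ")))
  if (!isTRUE(all.equal(object@forcingSv,
                        unname(HOSING_FORCINGS[object@label]))))
    return("forcingSv must match its scenario label (0 / 0.11 / 0.22 / 0.34 / 0.68)")
  if (object@forcingSv == 0 &&
      (object@hosingCooling != 0 || object@precipAnomaly != 0 ||
       length(object@hosingRegion) > 0))
    return("hosing terms must be zero/empty when forcingSv = 0")
  TRUE
})

#' World-generation parameters
#'
#' Everything needed to generate a deterministic synthetic world: grid shape,
#' realm partition, baseline and scenario year ranges, analysis horizons,
#' scenario forcings, and noise scales.
#'
#' @slot nrow,ncol,cellSize,xmin,ymax grid geometry (see [GridSpec-class]).
#' @slot nRealms number of contiguous longitudinal realm bands.
#' @slot baselineYears inclusive year range of the observed/model baseline.
#' @slot scenarioYears inclusive year range of scenario trajectories.
#' @slot horizons center years of the analysis horizons.
#' @slot scenarios list of [ScenarioSpec-class].
#' @slot noiseSd named noise scales: `temp` (degrees C, additive Gaussian) and
#'   `prec` (log-sd of the multiplicative log-normal factor).
#' @slot seed master seed for all stochastic components.
#' @export
setClass("WorldSpec",
  representation(nrow = "integer", ncol = "integer", cellSize = "numeric",
                 xmin = "numeric", ymax = "numeric", nRealms = "integer",
                 baselineYears = "integer", scenarioYears = "integer",
                 horizons = "integer", scenarios = "list",
                 noiseSd = "numeric", seed = "integer"))

setValidity("WorldSpec", function(object) {
  if (object@nrow < 1L || object@ncol < 1L) return("grid dimensions must be positive")
  if (object@nRealms < 1L) return("nRealms must be >= 1")
  if (object@nRealms > object@ncol) return("more realms than grid columns")
  if (length(object@baselineYears) != 2L || diff(object@baselineYears) < 0)
    return("baselineYears must be an inclusive (start, end) pair")
  if (length(object@scenarioYears) != 2L || diff(object@scenarioYears) < 0)
    return("scenarioYears must be an inclusive (start, end) pair")
  if (any(object@horizons < object@scenarioYears[1] |
          object@horizons > object@scenarioYears[2]))
    return("horizons must lie within the scenario year range")
  if (!all(c("temp", "prec") %in% names(object@noiseSd)))
    return("noiseSd must name 'temp' and 'prec'")
  realms <- realmLevels(object@nRealms)
  for (sc in object@scenarios) {
    if (!is(sc, "ScenarioSpec")) return("scenarios must be ScenarioSpec objects")
    bad <- setdiff(sc@hosingRegion, realms)
    if (length(bad))
      return(sprintf("hosingRegion names nonexistent realm(s): %s",
                     paste(bad, collapse = ", ")))
  }
  TRUE
})

#' A generated synthetic world
#'
#' @slot observed observed-baseline [ClimateCube-class] (stationary in
#'   expectation).
#' @slot modelBaseline model baseline cube carrying a fixed injected bias
#'   field, for bias-correction tests.
#' @slot scenarios named list of scenario [ClimateCube-class] objects.
#' @slot realms the [RealmMask-class].
#' @slot spec the generating [WorldSpec-class].
#' @export
setClass("ClimateWorld",
  representation(observed = "ClimateCube", modelBaseline = "ClimateCube",
                 scenarios = "list", realms = "RealmMask", spec = "WorldSpec"))

#' Monthly climatology for a stated period
#'
#' Per-calendar-month mean fields of the four climate variables over a year
#' window, as `12 x n_cells` matrices.
#'
#' @slot tmin,tmax,tmean,prec `12 x n_cells` matrices.
#' @slot grid the [GridSpec-class].
#' @slot centerYear,width window definition (half-open
#'   `[center - width/2, center + width/2)`).
#' @slot label free-form period label (e.g. `"2070 horizon, scenario D"`).
#' @export
setClass("PeriodClimatology",
  representation(tmin = "matrix", tmax = "matrix", tmean = "matrix",
                 prec = "matrix", grid = "GridSpec", centerYear = "numeric",
                 width = "numeric", label = "character"))

setValidity("PeriodClimatology", function(object) {
  n <- object@grid@nrow * object@grid@ncol
  for (v in CLIM_VARS) {
    m <- slot(object, v)
    if (nrow(m) != 12L) return(sprintf("%s must have 12 monthly rows", v))
    if (ncol(m) != n) return(sprintf("%s must have one column per cell", v))
  }
  TRUE
})

#' Bioclimatic variable stack
#'
#' Per-cell bio1 (annual mean temperature, degrees C), bio5 (max temperature
#' of the warmest month), bio6 (min temperature of the coldest month), bio12
#' (annual precipitation, mm) and bio15 (precipitation seasonality, percent)
#' for one period climatology.  Masked cells are `NA` across all variables.
#'
#' @slot values `n_cells x 5` matrix with columns
#'   `bio1, bio5, bio6, bio12, bio15`.
#' @slot grid the [GridSpec-class].
#' @slot label period label.
#' @export
setClass("BioclimStack",
  representation(values = "matrix", grid = "GridSpec", label = "character"))

setValidity("BioclimStack", function(object) {
  if (!identical(colnames(object@values), BIOCLIM_VARS))
    return("values must have columns bio1, bio5, bio6, bio12, bio15")
  if (nrow(object@values) != object@grid@nrow * object@grid@ncol)
    return("values must have one row per grid cell")
  ok <- stats::complete.cases(object@values)
  v <- object@values[ok, , drop = FALSE]
  if (any(v[, "bio6"] > v[, "bio1"] + 1e-9) || any(v[, "bio1"] > v[, "bio5"] + 1e-9))
    return("bio6 <= bio1 <= bio5 violated")
  if (any(v[, "bio12"] < 0) || any(v[, "bio15"] < 0))
    return("bio12 and bio15 must be non-negative")
  TRUE
})

#' A species with a rasterized presence range
#'
#' @slot speciesId species identifier.
#' @slot family taxonomic family label.
#' @slot status extinction-risk category (IUCN-style).
#' @slot realm the single realm containing the range.
#' @slot presenceCells integer cell ids of presence.
#' @export
setClass("SpeciesRecord",
  representation(speciesId = "character", family = "character",
                 status = "character", realm = "character",
                 presenceCells = "integer"))

setValidity("SpeciesRecord", function(object) {
  if (length(object@presenceCells) < 1L) return("presence set must be non-empty")
  if (anyDuplicated(object@presenceCells)) return("presence cells must be unique")
  TRUE
})

#' A virtual species with a known Gaussian niche
#'
#' Extends [SpeciesRecord-class] with the true suitability function
#' `s(x) = exp(-sum_v (x_v - mu_v)^2 / (2 sigma_v^2))` over the five
#' bioclimatic variables and the threshold `sStar` defining the realized
#' range (presence iff `s >= sStar` within the realm).
#'
#' @slot mu niche optimum per bioclim variable.
#' @slot sigma niche breadth per bioclim variable (all positive).
#' @slot sStar suitability threshold in (0, 1).
#' @export
setClass("VirtualSpecies", contains = "SpeciesRecord",
  representation(mu = "numeric", sigma = "numeric", sStar = "numeric"))

setValidity("VirtualSpecies", function(object) {
  if (!identical(names(object@mu), BIOCLIM_VARS) ||
      !identical(names(object@sigma), BIOCLIM_VARS))
    return("mu and sigma must be named by the five bioclim variables")
  if (any(object@sigma <= 0)) return("all sigma must be positive")
  if (object@sStar <= 0 || object@sStar >= 1) return("sStar must be in (0, 1)")
  TRUE
})

#' Presence/pseudoabsence modeling design for one species
#'
#' @slot speciesId species identifier.
#' @slot presence,pseudoabsence integer cell ids (disjoint).
#' @slot runs list of per-run splits, each
#'   `list(trainPresence, testPresence, trainAbsence, testAbsence)`.
#' @slot seed seed the design was drawn with.
#' @export
setClass("OccurrenceDesign",
  representation(speciesId = "character", presence = "integer",
                 pseudoabsence = "integer", runs = "list", seed = "integer"))

setValidity("OccurrenceDesign", function(object) {
  if (length(intersect(object@presence, object@pseudoabsence)))
    return("presence and pseudoabsence cells must be disjoint")
  for (r in object@runs) {
    if (length(intersect(r$trainPresence, r$testPresence)) ||
        length(intersect(r$trainAbsence, r$testAbsence)))
      return("train and test sets must be disjoint within each run")
    if (!setequal(c(r$trainPresence, r$testPresence), object@presence) ||
        !setequal(c(r$trainAbsence, r$testAbsence), object@pseudoabsence))
      return("each run must partition the presence and pseudoabsence sets")
  }
  TRUE
})

#' A fitted suitability model
#'
#' @slot algorithm one of the registered algorithm labels.
#' @slot fit the underlying fitted object.
#' @slot center,scale training-set standardization statistics.
#' @slot extras algorithm-specific fitted metadata (e.g. hinge knots).
#' @slot nTrain training-set size.
#' @slot seed fitting seed.
#' @export
setClass("SuitabilityModel",
  representation(algorithm = "character", fit = "ANY", center = "numeric",
                 scale = "numeric", extras = "list", nTrain = "integer",
                 seed = "integer"))

#' A binarization threshold
#'
#' @slot criterion one of `MTP`, `P10TP`, `ESS`, `MSS`.
#' @slot value the threshold, in suitability units in `[0, 1]`.
#' @export
setClass("ThresholdSpec",
  representation(criterion = "character", value = "numeric"))

setValidity("ThresholdSpec", function(object) {
  if (!object@criterion %in% THRESHOLD_CRITERIA)
    return(sprintf("criterion must be one of %s",
                   paste(THRESHOLD_CRITERIA, collapse = ", ")))
  if (object@value < 0 || object@value > 1) return("value must be in [0, 1]")
  TRUE
})

#' A binary presence/absence range map
#'
#' @slot speciesId species identifier.
#' @slot cells presence cell ids (subset of the realm background).
#' @slot grid the [GridSpec-class].
#' @slot scenario,horizon,algorithm,criterion provenance labels.
#' @export
setClass("BinaryRangeMap",
  representation(speciesId = "character", cells = "integer",
                 grid = "GridSpec", scenario = "character",
                 horizon = "integer", algorithm = "character",
                 criterion = "character"))

setValidity("BinaryRangeMap", function(object) {
  n <- object@grid@nrow * object@grid@ncol
  if (length(object@cells) && (min(object@cells) < 1L || max(object@cells) > n))
    return("cells out of grid range")
  if (anyDuplicated(object@cells)) return("cells must be unique")
  TRUE
})

#' Stacked species richness on a coarse grid
#'
#' @slot values species count per cell.
#' @slot grid coarse [GridSpec-class].
#' @slot scenario,horizon,algorithm,dispersal,criterion provenance labels.
#' @export
setClass("RichnessMap",
  representation(values = "numeric", grid = "GridSpec", scenario = "character",
                 horizon = "integer", algorithm = "character",
                 dispersal = "character", criterion = "character"))

#' Per-cell percentage species loss (diversity deficit)
#'
#' Values are `100 * (S_now - S_future) / S_now`, in `(-Inf, 100]`; cells
#' with zero current richness are `NA` (masked).
#'
#' @slot values percent species loss per cell (`NA` = masked).
#' @slot grid coarse [GridSpec-class].
#' @slot scenario,horizon,algorithm,dispersal provenance labels.
#' @export
setClass("DeficitMap",
  representation(values = "numeric", grid = "GridSpec", scenario = "character",
                 horizon = "integer", algorithm = "character",
                 dispersal = "character"))

setValidity("DeficitMap", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(v > 100 + 1e-9)) return("deficit cannot exceed 100%")
  TRUE
})
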