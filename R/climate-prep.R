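#' Horizon-window monthly climatology
#'
#' Per-calendar-month mean over the half-open year window
#' `[center - width/2, center + width/2)`, per cell (e.g. a 30-year average
#' centered in 2070).
#'
#' @param cube a [ClimateCube-class].
#' @param centerYear window center year.
#' @param width window width in years (default 30).
#' @return a [PeriodClimatology-class].
#' @export
horizonMean <- function(cube, centerYear, width = 30) {
  lo <- centerYear - width / 2
  hi <- centerYear + width / 2
  sel <- which(cube@years >= lo & cube@years < hi)
  firstNeeded <- ceiling(lo)
  lastNeeded <- if (hi == ceiling(hi)) hi - 1 else floor(hi)
  if (length(sel) == 0 || min(cube@years) > firstNeeded ||
      max(cube@years) < lastNeeded)
    stop(sprintf("window [%s, %s) exceeds cube years %d-%d",
                 format(lo), format(hi), min(cube@years), max(cube@years)))
  avg <- function(a) {
    out <- apply(a[sel, , , drop = FALSE], c(2, 3), mean)
    dimnames(out) <- NULL
    out
  }
  new("PeriodClimatology", tmin = avg(cube@tmin), tmax = avg(cube@tmax),
      tmean = avg(cube@tmean), prec = avg(cube@prec), grid = cube@grid,
      centerYear = centerYear, width = width,
      label = sprintf("%s horizon, scenario %s", format(centerYear),
                      cube@scenario))
}

#' Climatology over a cube's full year range
#' @param cube a [ClimateCube-class].
#' @return a [PeriodClimatology-class] averaging every year of the cube.
#' @export
baselineClimatology <- function(cube) {
  yrs <- range(cube@years)
  horizonMean(cube, centerYear = mean(yrs), width = diff(yrs) + 1)
}

#' Delta (mean-bias) correction of a model climatology
#'
#' Shifts a model target climatology by the mean bias between the modeled
#' and observed baseline climatology, per calendar month per cell:
#' `corrected = target - (model_baseline - observed_baseline)`.
#' Precipitation is clamped at zero after shifting.  Applying the correction
#' to the model baseline itself returns the observed baseline exactly
#' (before clamping).
#'
#' @param modelBaseline,obsBaseline,modelTarget [PeriodClimatology-class]
#'   objects on identical grids.
#' @return the corrected [PeriodClimatology-class] (target window/label kept).
#' @export
deltaBiasCorrect <- function(modelBaseline, obsBaseline, modelTarget) {
  if (!sameGrid(modelBaseline@grid, obsBaseline@grid) ||
      !sameGrid(modelBaseline@grid, modelTarget@grid))
    stop("climatologies are not on identical grids (alignment error)")
  corr <- modelTarget
  for (v in c("tmin", "tmax", "tmean"))
    slot(corr, v) <- slot(modelTarget, v) -
      (slot(modelBaseline, v) - slot(obsBaseline, v))
  slot(corr, "prec") <- pmax(modelTarget@prec -
                               (modelBaseline@prec - obsBaseline@prec), 0)
  corr@label <- paste0(modelTarget@label, " (bias-corrected)")
  corr
}

#' Compute the five bioclimatic variables
#'
#' From a 12-month climatology: bio1 = mean of monthly mean temperature;
#' bio5 = max of monthly maximum temperature; bio6 = min of monthly minimum
#' temperature; bio12 = sum of monthly precipitation; bio15 = precipitation
#' seasonality, `100 * sd(m + 1) / mean(m + 1)` over the 12 monthly
#' precipitation values (sample sd, n - 1; the +1 mm offset is the standard
#' ANUCLIM convention guarding against division by zero in arid cells).
#'
#' @param clim a [PeriodClimatology-class] with all 12 months.
#' @return a [BioclimStack-class].
#' @export
computeBioclim <- function(clim) {
  for (v in CLIM_VARS)
    if (nrow(slot(clim, v)) != 12L || anyNA(slot(clim, v)))
      stop("all 12 months of tmin/tmax/tmean/prec are required")
  p1 <- clim@prec + 1
  values <- cbind(
    bio1 = colMeans(clim@tmean),
    bio5 = apply(clim@tmax, 2, max),
    bio6 = apply(clim@tmin, 2, min),
    bio12 = colSums(clim@prec),
    bio15 = 100 * apply(p1, 2, stats::sd) / colMeans(p1))
  new("BioclimStack", values = values, grid = clim@grid, label = clim@label)
}

#' Block-mean aggregation of a bioclim stack to a coarser grid
#'
#' Each `factor x factor` block of fine cells becomes one coarse cell whose
#' value is the mean of the unmasked fine cells; a fully masked block stays
#' masked.  `factor = 1` is the identity.
#'
#' @param stack a [BioclimStack-class].
#' @param factor positive integer aggregation factor; grid dimensions must be
#'   divisible by it.
#' @return a [BioclimStack-class] on the coarsened grid.
#' @export
aggregateGrid <- function(stack, factor) {
  if (factor == 1) return(stack)
  idx <- coarseIndex(stack@grid, factor)
  cg <- coarsenGrid(stack@grid, factor)
  cols <- lapply(seq_len(ncol(stack@values)), function(j) {
    col <- stack@values[, j]
    s <- rowsum(ifelse(is.na(col), 0, col), idx)
    n <- rowsum(as.numeric(!is.na(col)), idx)
    out <- as.vector(s / n)
    out[n == 0] <- NA_real_
    out
  })
  values <- matrix(unlist(cols), ncol = length(BIOCLIM_VARS),
                   dimnames = list(NULL, BIOCLIM_VARS))
  new("BioclimStack", values = values, grid = cg, label = stack@label)
}

#' @describeIn computeBioclim accessor for the per-cell value matrix.
#' @param stack a [BioclimStack-class].
#' @export
bioclimValues <- function(stack) stack@values

setMethod("show", "PeriodClimatology", function(object) {
  cat(sprintf("PeriodClimatology '%s': center %s, width %s yr, %d x %d grid\n",
              object@label, format(object@centerYear), format(object@width),
              object@grid@nrow, object@grid@ncol))
})

setMethod("show", "BioclimStack", function(object) {
  cat(sprintf("BioclimStack '%s' on %d x %d grid\n", object@label,
              object@grid@nrow, object@grid@ncol))
  print(summary(object@values))
})
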