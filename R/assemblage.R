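#' Stack binary range maps into a coarse-grid richness map
#'
#' Aggregates each species' binary map from the analysis grid to a coarser
#' grid (e.g. 0.33 degree to 1 degree) by the any-subcell rule — a species
#' occupying any fine subcell of a coarse cell is present there — then counts
#' species per coarse cell.  All input maps must share the grid and the
#' threshold criterion (mixed criteria are a consistency error).
#'
#' @param maps list of [BinaryRangeMap-class] for one scenario/horizon/
#'   algorithm/dispersal combination.
#' @param factor integer aggregation factor from the analysis grid to the
#'   stacking grid (default 3, i.e. 0.33 degree to 1 degree).
#' @param scenario,horizon,algorithm,dispersal provenance labels (defaults
#'   taken from the first map).
#' @param grid analysis [GridSpec-class]; only needed when `maps` is empty
#'   (no species stacks to an all-zero map).
#' @return a [RichnessMap-class].
#' @export
stackRichness <- function(maps, factor = 3, scenario = NULL, horizon = NULL,
                          algorithm = NULL, dispersal = "full", grid = NULL) {
  if (length(maps) == 0) {
    if (is.null(grid)) stop("an empty stack needs an explicit grid")
    return(new("RichnessMap", values = numeric(nCell(coarsenGrid(grid, factor))),
               grid = coarsenGrid(grid, factor), scenario = scenario %||% "",
               horizon = as.integer(horizon %||% NA), algorithm = algorithm %||% "",
               dispersal = dispersal, criterion = ""))
  }
  g <- maps[[1]]@grid
  crit <- maps[[1]]@criterion
  for (m in maps) {
    if (!sameGrid(m@grid, g)) stop("maps are not on one grid")
    if (!identical(m@criterion, crit))
      stop("mixed threshold criteria among input maps (consistency error)")
  }
  idx <- coarseIndex(g, factor)
  cg <- coarsenGrid(g, factor)
  counts <- numeric(nCell(cg))
  for (m in maps) {
    coarse <- unique(idx[m@cells])
    counts[coarse] <- counts[coarse] + 1
  }
  new("RichnessMap", values = counts, grid = cg,
      scenario = scenario %||% maps[[1]]@scenario,
      horizon = as.integer(horizon %||% maps[[1]]@horizon),
      algorithm = algorithm %||% maps[[1]]@algorithm,
      dispersal = dispersal, criterion = crit)
}

#' Per-cell species diversity deficit (percentage species loss)
#'
#' `100 * (S_now - S_future) / S_now` per cell; cells with zero current
#' richness are masked (`NA`), never 0 or infinite.
#'
#' @param current,future [RichnessMap-class] objects on the same grid with
#'   the same criterion and dispersal assumption.
#' @return a [DeficitMap-class].
#' @export
deficitMap <- function(current, future) {
  if (!sameGrid(current@grid, future@grid))
    stop("richness maps are not on one grid (alignment error)")
  if (!identical(current@criterion, future@criterion) ||
      !identical(current@dispersal, future@dispersal))
    stop("richness maps differ in criterion or dispersal assumption")
  v <- 100 * (current@values - future@values) / current@values
  v[current@values == 0] <- NA_real_
  new("DeficitMap", values = v, grid = current@grid,
      scenario = future@scenario, horizon = future@horizon,
      algorithm = future@algorithm, dispersal = future@dispersal)
}

#' Average deficit maps across algorithms
#'
#' Cellwise mean over the unmasked values; a cell is masked in the average
#' only if it is masked in every input.
#'
#' @param maps list of aligned [DeficitMap-class] objects.
#' @return a [DeficitMap-class] with `algorithm = "ENSEMBLE"`.
#' @export
algorithmAverageMap <- function(maps) {
  if (length(maps) == 0) stop("no maps to average")
  g <- maps[[1]]@grid
  for (m in maps) if (!sameGrid(m@grid, g)) stop("maps are not aligned")
  vals <- vapply(maps, slot, numeric(nCell(g)), "values")
  v <- rowMeans(vals, na.rm = TRUE)
  v[rowSums(!is.na(vals)) == 0] <- NA_real_
  new("DeficitMap", values = v, grid = g, scenario = maps[[1]]@scenario,
      horizon = maps[[1]]@horizon, algorithm = "ENSEMBLE",
      dispersal = maps[[1]]@dispersal)
}

setMethod("show", "RichnessMap", function(object) {
  cat(sprintf("RichnessMap [%s/%s/%s/%s]: max richness %d on %d x %d grid\n",
              object@scenario, object@horizon, object@algorithm,
              object@dispersal, as.integer(max(object@values)), object@grid@nrow,
              object@grid@ncol))
})

setMethod("show", "DeficitMap", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf(
    "DeficitMap [%s/%s/%s/%s]: %d unmasked cells, median %.1f%% loss\n",
    object@scenario, object@horizon, object@algorithm, object@dispersal,
    length(v), if (length(v)) stats::median(v) else NA))
})
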