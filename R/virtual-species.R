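#' True Gaussian-niche suitability
#'
#' `s(x) = exp(-sum_v (x_v - mu_v)^2 / (2 sigma_v^2))` over the five
#' bioclimatic variables; `s = 1` exactly at the niche optimum.
#'
#' @param species a [VirtualSpecies-class].
#' @param bioclim a [BioclimStack-class] or a matrix with the five bioclim
#'   columns.
#' @param cells optional cell ids to evaluate (default all rows).
#' @return numeric suitability in `[0, 1]` per requested cell (`NA` where the
#'   bioclim values are masked).
#' @export
trueSuitability <- function(species, bioclim, cells = NULL) {
  x <- if (is(bioclim, "BioclimStack")) bioclim@values else bioclim
  if (!is.null(cells)) x <- x[cells, , drop = FALSE]
  z <- sweep(x[, BIOCLIM_VARS, drop = FALSE], 2, species@mu[BIOCLIM_VARS])
  z <- sweep(z, 2, species@sigma[BIOCLIM_VARS], "/")
  exp(-rowSums(z^2) / 2)
}

#' Generate virtual species with known niches
#'
#' For each species a realm is assigned (cycling through the realms), a niche
#' optimum `mu` is drawn as the bioclim vector of a random cell of that realm
#' (so the optimum is guaranteed to be realized), the breadth is
#' `sigma_v = breadth * sd(bioclim_v)` within the realm, and the suitability
#' threshold `sStar` is drawn uniformly from `sStarRange`.  The realized
#' range is the deterministic set of realm cells with `s >= sStar`; draws
#' yielding fewer than `minPresence` cells are resampled (bounded retries),
#' so every emitted species satisfies the minimum-range rule by
#' construction.  Family and extinction-risk status labels are sampled
#' metadata used for grouped summaries.
#'
#' @param world a [ClimateWorld-class].
#' @param nSpecies number of species to generate.
#' @param nicheSpec list with `breadth` (niche sd as a fraction of the realm
#'   sd of each variable, default 1), `sStarRange` (default `c(0.25, 0.5)`),
#'   `maxPresenceFrac` (largest realized range as a fraction of the realm,
#'   default 0.25 — realm endemics are restricted-range species, and the cap
#'   guarantees the realm background can supply three pseudoabsences per
#'   presence) and `maxTries` (default 200).
#' @param seed integer seed.
#' @param minPresence minimum realized range size in cells (default 50).
#' @param baselineBioclim optionally, the precomputed observed-baseline
#'   [BioclimStack-class] (recomputed from `world` if omitted).
#' @return list of [VirtualSpecies-class] objects.
#' @export
generateVirtualSpecies <- function(world, nSpecies, nicheSpec = list(),
                                   seed, minPresence = 50,
                                   baselineBioclim = NULL) {
  breadth <- nicheSpec$breadth %||% 1
  sStarRange <- nicheSpec$sStarRange %||% c(0.25, 0.5)
  maxPresenceFrac <- nicheSpec$maxPresenceFrac %||% 0.25
  maxTries <- nicheSpec$maxTries %||% 200
  bioc <- baselineBioclim %||% computeBioclim(baselineClimatology(world@observed))
  mask <- world@realms
  realms <- mask@levels
  realmIdx <- lapply(realms, function(r) realmCells(mask, r))
  realmSd <- lapply(realmIdx, function(ix)
    apply(bioc@values[ix, , drop = FALSE], 2, stats::sd))

  withSeed(seed, {
    assigned <- rep(seq_along(realms), length.out = nSpecies)
    out <- vector("list", nSpecies)
    for (i in seq_len(nSpecies)) {
      ri <- assigned[i]
      cellsR <- realmIdx[[ri]]
      xR <- bioc@values[cellsR, , drop = FALSE]
      sigma <- pmax(breadth * realmSd[[ri]], 1e-6)
      names(sigma) <- BIOCLIM_VARS
      done <- FALSE
      for (try in seq_len(maxTries)) {
        mu <- xR[sample.int(length(cellsR), 1), ]
        names(mu) <- BIOCLIM_VARS
        sStar <- stats::runif(1, sStarRange[1], sStarRange[2])
        z <- sweep(sweep(xR, 2, mu), 2, sigma, "/")
        s <- exp(-rowSums(z^2) / 2)
        pres <- cellsR[s >= sStar]
        if (length(pres) >= minPresence &&
            length(pres) <= maxPresenceFrac * length(cellsR)) {
          done <- TRUE; break
        }
      }
      if (!done)
        stop(sprintf(
          "could not place a species with >= %d presence cells in realm '%s' after %d tries",
          minPresence, realms[ri], maxTries))
      out[[i]] <- new("VirtualSpecies",
        speciesId = sprintf("vsp_%03d", i),
        family = sprintf("family_%02d", sample.int(8, 1)),
        status = sample(IUCN_STATUSES, 1,
                        prob = c(0.45, 0.12, 0.15, 0.12, 0.08, 0.08)),
        realm = realms[ri], presenceCells = as.integer(sort(pres)),
        mu = mu, sigma = sigma, sStar = sStar)
    }
    out
  })
}

#' True range change of a virtual species (oracle)
#'
#' Applies the species' true suitability function and threshold to a future
#' bioclim stack and returns the proportional range change
#' `q = (p1 - p2) / p1` against the true current range, where `p1` is the
#' current presence-cell count and `p2` the future one.  Under no dispersal
#' the future range is intersected with the current presence set.
#'
#' @param species a [VirtualSpecies-class].
#' @param futureBioclim a [BioclimStack-class] on the species' grid.
#' @param dispersal `"full"` or `"none"`.
#' @param realmMask the world's [RealmMask-class] (future presence is
#'   restricted to the species' realm).
#' @return a list with `q`, `p1`, `p2` and the future presence cell ids.
#' @export
trueRangeChange <- function(species, futureBioclim, dispersal = c("full", "none"),
                            realmMask) {
  dispersal <- match.arg(dispersal)
  p1cells <- species@presenceCells
  if (length(p1cells) == 0) stop("empty current range: q is undefined")
  cellsR <- realmCells(realmMask, species@realm)
  s <- trueSuitability(species, futureBioclim, cells = cellsR)
  fut <- cellsR[!is.na(s) & s >= species@sStar]
  if (dispersal == "none") fut <- intersect(fut, p1cells)
  p1 <- length(p1cells); p2 <- length(fut)
  list(q = (p1 - p2) / p1, p1 = p1, p2 = p2, futureCells = as.integer(fut))
}

setMethod("show", "SpeciesRecord", function(object) {
  cat(sprintf("%s '%s' (%s, %s): %d presence cells in %s\n",
              class(object), object@speciesId, object@family, object@status,
              length(object@presenceCells), object@realm))
})
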