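#' Rasterize presence input and apply the modeling filters
#'
#' Builds [SpeciesRecord-class] objects from per-species presence cell sets
#' (raster-style input: a named list of cell ids or logical vectors over the
#' grid, or [SpeciesRecord-class]/[VirtualSpecies-class] objects).  Species
#' are excluded — with a logged reason — when their range falls outside the
#' grid (`outside_grid`), spans more than one realm (`not_endemic`), or has
#' fewer than `minPresence` cells (`min_presence`).  The included set and
#' the exclusion log exactly partition the input list.
#'
#' @param ranges named list of presence inputs (see above).
#' @param meta optional data.frame with `species_id`, `family`, `status`
#'   columns (matched by name; defaults used when absent).
#' @param realmMask a [RealmMask-class] defining grid and realms.
#' @param minPresence minimum presence cell count (default 50).
#' @return list with `records` (list of [SpeciesRecord-class]) and
#'   `exclusions` (data.frame `species_id`, `reason`).
#' @export
rasterizeAndFilter <- function(ranges, meta = NULL, realmMask,
                               minPresence = 50) {
  n <- nCell(realmMask@grid)
  ids <- names(ranges) %||% vapply(ranges, function(r)
    if (is(r, "SpeciesRecord")) r@speciesId else NA_character_, "")
  if (anyNA(ids) || is.null(ids)) stop("ranges must be named by species id")
  records <- list()
  excl <- data.frame(species_id = character(), reason = character())
  for (i in seq_along(ranges)) {
    r <- ranges[[i]]
    fam <- "unknown"; status <- "DD"
    if (is(r, "SpeciesRecord")) {
      cells <- r@presenceCells; fam <- r@family; status <- r@status
    } else if (is.logical(r)) {
      if (length(r) != n) stop("logical presence vector must cover the grid")
      cells <- which(r)
    } else {
      cells <- as.integer(r)
    }
    if (!is.null(meta)) {
      mrow <- meta[meta$species_id == ids[i], , drop = FALSE]
      if (nrow(mrow)) {
        fam <- mrow$family[1] %||% fam
        status <- mrow$status[1] %||% status
      }
    }
    inGrid <- cells[cells >= 1L & cells <= n]
    if (length(inGrid) == 0) {
      excl <- rbind(excl, data.frame(species_id = ids[i], reason = "outside_grid"))
      next
    }
    spRealms <- unique(realmOf(realmMask, inGrid))
    if (length(spRealms) > 1L) {
      excl <- rbind(excl, data.frame(species_id = ids[i], reason = "not_endemic"))
      next
    }
    if (length(inGrid) < minPresence) {
      excl <- rbind(excl, data.frame(species_id = ids[i], reason = "min_presence"))
      next
    }
    rec <- if (is(r, "VirtualSpecies")) r else
      new("SpeciesRecord", speciesId = ids[i], family = fam, status = status,
          realm = spRealms, presenceCells = as.integer(sort(unique(inGrid))))
    records[[length(records) + 1L]] <- rec
  }
  list(records = records, exclusions = excl)
}

#' Sample realm-background pseudoabsences
#'
#' Draws `ratio` times the number of presences, uniformly without replacement
#' from the species' realm background (realm cells minus presences).
#' Deterministic given the seed.
#'
#' @param record a [SpeciesRecord-class].
#' @param realmMask a [RealmMask-class].
#' @param ratio pseudoabsence:presence ratio (default 3).
#' @param seed integer seed.
#' @return integer vector of pseudoabsence cell ids.
#' @export
samplePseudoabsences <- function(record, realmMask, ratio = 3, seed) {
  background <- setdiff(realmCells(realmMask, record@realm),
                        record@presenceCells)
  need <- ratio * length(record@presenceCells)
  if (length(background) < need)
    stop(sprintf(
      "species '%s': background (%d cells) smaller than %d pseudoabsences",
      record@speciesId, length(background), need))
  withSeed(seed, sort(sample(background, need)))
}

#' Repeated 70/30 calibration/validation splits
#'
#' Builds an [OccurrenceDesign-class] with `nRuns` independent random splits.
#' Within each run, `floor(trainFrac * n)` cells go to training (remainder to
#' validation), independently for presences and pseudoabsences, so every
#' train and test set keeps the presence:pseudoabsence ratio up to rounding.
#'
#' @param speciesId species identifier.
#' @param presence,pseudoabsence integer cell id vectors (disjoint, each of
#'   length >= 2).
#' @param trainFrac training fraction in (0, 1) (default 0.7).
#' @param nRuns number of random subsampling runs (default 10).
#' @param seed integer seed.
#' @return an [OccurrenceDesign-class].
#' @export
partitionRuns <- function(speciesId, presence, pseudoabsence,
                          trainFrac = 0.7, nRuns = 10, seed) {
  if (trainFrac <= 0 || trainFrac >= 1) stop("trainFrac must be in (0, 1)")
  if (length(presence) < 2 || length(pseudoabsence) < 2)
    stop("need at least 2 presences and 2 pseudoabsences")
  split70 <- function(cells) {
    k <- floor(trainFrac * length(cells))
    tr <- sort(sample(cells, k))
    list(train = tr, test = sort(setdiff(cells, tr)))
  }
  runs <- withSeed(seed, lapply(seq_len(nRuns), function(r) {
    p <- split70(presence); a <- split70(pseudoabsence)
    list(trainPresence = p$train, testPresence = p$test,
         trainAbsence = a$train, testAbsence = a$test)
  }))
  new("OccurrenceDesign", speciesId = speciesId,
      presence = as.integer(presence),
      pseudoabsence = as.integer(pseudoabsence), runs = runs,
      seed = as.integer(seed))
}

#' Build the full occurrence design for one species
#'
#' Convenience wrapper: realm-background pseudoabsences (drawn once and
#' shared across runs) plus the repeated 70/30 splits.
#'
#' @inheritParams samplePseudoabsences
#' @inheritParams partitionRuns
#' @return an [OccurrenceDesign-class].
#' @export
buildOccurrenceDesign <- function(record, realmMask, ratio = 3,
                                  trainFrac = 0.7, nRuns = 10, seed) {
  pa <- samplePseudoabsences(record, realmMask, ratio = ratio,
                             seed = deriveSeed(seed, "pa", record@speciesId))
  partitionRuns(record@speciesId, record@presenceCells, pa,
                trainFrac = trainFrac, nRuns = nRuns,
                seed = deriveSeed(seed, "runs", record@speciesId))
}

setMethod("show", "OccurrenceDesign", function(object) {
  cat(sprintf("OccurrenceDesign '%s': %d presences, %d pseudoabsences, %d runs\n",
              object@speciesId, length(object@presence),
              length(object@pseudoabsence), length(object@runs)))
})
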