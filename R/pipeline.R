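#' Pipeline configuration
#'
#' Bundles the synthetic-world specification with all modeling options.  The
#' master seed is mandatory; every stochastic stage derives its own seed from
#' it by stable hashing of the stage name and species id, so reruns with the
#' same configuration and seed reproduce all tables bit-identically.
#'
#' @slot world a [WorldSpec-class].
#' @slot nSpecies number of virtual species to generate.
#' @slot nicheSpec niche-generation options (see [generateVirtualSpecies()]).
#' @slot algorithms algorithm labels to fit.
#' @slot nRuns random-subsampling runs per species x algorithm.
#' @slot trainFrac calibration fraction of each split.
#' @slot paRatio pseudoabsence:presence ratio.
#' @slot tssMin TSS exclusion cutoff (mean TSS <= tssMin is dropped).
#' @slot criterion binarization threshold criterion.
#' @slot dispersal dispersal assumptions to evaluate.
#' @slot horizonWidth averaging window width in years.
#' @slot aggFactor aggregation factor from the analysis grid to the
#'   richness-stacking grid.
#' @slot minPresence minimum presence cells per species.
#' @slot seed master seed.
#' @export
setClass("PipelineConfig",
  representation(world = "WorldSpec", nSpecies = "integer",
                 nicheSpec = "list", algorithms = "character",
                 nRuns = "integer", trainFrac = "numeric",
                 paRatio = "numeric", tssMin = "numeric",
                 criterion = "character", dispersal = "character",
                 horizonWidth = "numeric", aggFactor = "integer",
                 minPresence = "integer", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a master seed is mandatory")
  if (!object@criterion %in% THRESHOLD_CRITERIA)
    return("unknown threshold criterion")
  if (!all(object@dispersal %in% c("full", "none")))
    return("dispersal must be 'full' and/or 'none'")
  bad <- setdiff(object@algorithms, availableAlgorithms())
  if (length(bad))
    return(sprintf("unregistered algorithm(s): %s", paste(bad, collapse = ", ")))
  TRUE
})

#' @param world,nSpecies,nicheSpec,algorithms,nRuns,trainFrac,paRatio,tssMin
#'   see slots.
#' @param criterion,dispersal,horizonWidth,aggFactor,minPresence,seed see
#'   slots; `seed` defaults to the world seed.
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(world, nSpecies = 40,
                           nicheSpec = list(),
                           algorithms = c("MAXENT", "BRT", "CART"),
                           nRuns = 10, trainFrac = 0.7, paRatio = 3,
                           tssMin = 0.4, criterion = "P10TP",
                           dispersal = c("full", "none"),
                           horizonWidth = 30, aggFactor = 3,
                           minPresence = 50, seed = world@seed) {
  new("PipelineConfig", world = world, nSpecies = as.integer(nSpecies),
      nicheSpec = nicheSpec, algorithms = algorithms,
      nRuns = as.integer(nRuns), trainFrac = trainFrac, paRatio = paRatio,
      tssMin = tssMin, criterion = criterion, dispersal = dispersal,
      horizonWidth = horizonWidth, aggFactor = as.integer(aggFactor),
      minPresence = as.integer(minPresence), seed = as.integer(seed))
}

futureKey <- function(scenario, horizon) paste(scenario, horizon, sep = "_")

#' Run the full assessment pipeline
#'
#' Executes, in order: synthetic-world generation, climate preparation
#' (baseline climatologies, delta bias correction, bioclim stacks per
#' scenario x horizon), species filtering and occurrence designs, per-run
#' suitability fitting and validation, TSS-based exclusion, threshold
#' binarization of the run-averaged suitability, per-species range change
#' under both dispersal assumptions (with the known-truth oracle alongside),
#' ensemble averaging, grouped contraction summaries, and stacked-richness
#' diversity-deficit maps.
#'
#' @param config a [PipelineConfig-class].
#' @param outDir optional output directory; when given, all tables are
#'   written as CSV, maps as ASCII grids, and a JSON run manifest recorded.
#' @param verbose print stage progress.
#' @return (invisibly) a list with elements `world`, `species`, `metrics`,
#'   `exclusions`, `thresholds`, `rangeChanges` (per-algorithm rows),
#'   `ensemble` (with the `q_true` oracle merged in), `summaries`,
#'   `richness`, `deficits` and `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL, verbose = FALSE) {
  validObject(config)
  seed <- config@seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating climate world")
  world <- generateClimateWorld(config@world)
  realms <- world@realms
  grid <- realms@grid

  say("preparing bioclim stacks")
  obsClim <- baselineClimatology(world@observed)
  modClim <- baselineClimatology(world@modelBaseline)
  currentStack <- computeBioclim(obsClim)
  scenLabels <- names(world@scenarios)
  horizons <- config@world@horizons
  futureStacks <- list()
  for (sc in scenLabels) for (h in horizons) {
    tgt <- horizonMean(world@scenarios[[sc]], h, width = config@horizonWidth)
    futureStacks[[futureKey(sc, h)]] <-
      computeBioclim(deltaBiasCorrect(modClim, obsClim, tgt))
  }

  say("generating %d virtual species", config@nSpecies)
  species <- generateVirtualSpecies(world, config@nSpecies,
    nicheSpec = config@nicheSpec, seed = deriveSeed(seed, "species"),
    minPresence = config@minPresence, baselineBioclim = currentStack)
  names(species) <- vapply(species, slot, "", "speciesId")
  flt <- rasterizeAndFilter(species, realmMask = realms,
                            minPresence = config@minPresence)
  records <- flt$records
  exclusions <- flt$exclusions

  say("fitting %d species x %d algorithms x %d runs",
      length(records), length(config@algorithms), config@nRuns)
  metricsRows <- list()
  avgSuit <- list()       # [speciesId][algorithm] -> list(current=, futures=)
  backgrounds <- list()
  designs <- list()
  for (rec in records) {
    id <- rec@speciesId
    des <- buildOccurrenceDesign(rec, realms, ratio = config@paRatio,
                                 trainFrac = config@trainFrac,
                                 nRuns = config@nRuns,
                                 seed = deriveSeed(seed, "design", id))
    designs[[id]] <- des
    bg <- realmCells(realms, rec@realm)
    backgrounds[[id]] <- bg
    xAll <- currentStack@values
    avgSuit[[id]] <- list()
    for (alg in config@algorithms) {
      curSum <- numeric(length(bg))
      futSum <- lapply(futureStacks, function(fs) numeric(length(bg)))
      for (ri in seq_len(config@nRuns)) {
        run <- des@runs[[ri]]
        m <- fitSuitability(alg,
          xAll[c(run$trainPresence, run$trainAbsence), , drop = FALSE],
          rep(c(1L, 0L), c(length(run$trainPresence), length(run$trainAbsence))),
          seed = deriveSeed(seed, "fit", id, alg, ri))
        metricsRows[[length(metricsRows) + 1L]] <- cbind(
          species_id = id, algorithm = alg, run = ri,
          evaluateModel(m, xAll[run$trainPresence, , drop = FALSE],
                        xAll[run$testPresence, , drop = FALSE],
                        xAll[run$testAbsence, , drop = FALSE],
                        criterion = config@criterion))
        curSum <- curSum + predictSuitability(m, xAll[bg, , drop = FALSE])
        for (k in names(futureStacks))
          futSum[[k]] <- futSum[[k]] +
            predictSuitability(m, futureStacks[[k]]@values[bg, , drop = FALSE])
      }
      avgSuit[[id]][[alg]] <- list(current = curSum / config@nRuns,
        futures = lapply(futSum, function(v) v / config@nRuns))
    }
  }
  metrics <- do.call(rbind, metricsRows)
  rownames(metrics) <- NULL

  say("applying TSS exclusion rule")
  tssFilter <- excludePoorModels(metrics, tssMin = config@tssMin)
  retainedKeys <- unique(paste(tssFilter$retained$species_id,
                               tssFilter$retained$algorithm))
  modelExclusions <- tssFilter$excluded

  say("binarizing and computing range changes")
  thresholdRows <- list()
  changeRows <- list()
  emptyP1 <- data.frame(species_id = character(), algorithm = character(),
                        reason = character())
  binMaps <- list()       # [key][algorithm] -> list(speciesId -> cells)
  curMaps <- list()
  for (rec in records) {
    id <- rec@speciesId
    bg <- backgrounds[[id]]
    for (alg in config@algorithms) {
      if (!paste(id, alg) %in% retainedKeys) next
      su <- avgSuit[[id]][[alg]]
      presIdx <- match(rec@presenceCells, bg)
      paIdx <- match(designs[[id]]@pseudoabsence, bg)
      thr <- computeThreshold(su$current[presIdx],
        scores = su$current[c(presIdx, paIdx)],
        labels = rep(c(1L, 0L), c(length(presIdx), length(paIdx))),
        criterion = config@criterion)
      thresholdRows[[length(thresholdRows) + 1L]] <-
        data.frame(species_id = id, algorithm = alg,
                   criterion = thr@criterion, threshold = thr@value)
      cur <- applyThreshold(su$current, bg, thr, grid, speciesId = id,
                            scenario = "current", algorithm = alg)
      if (length(cur@cells) == 0) {
        emptyP1 <- rbind(emptyP1, data.frame(species_id = id, algorithm = alg,
                                             reason = "empty_p1"))
        next
      }
      curMaps[[alg]] <- c(curMaps[[alg]], stats::setNames(list(cur@cells), id))
      for (sc in scenLabels) for (h in horizons) {
        k <- futureKey(sc, h)
        fut <- applyThreshold(su$futures[[k]], bg, thr, grid, speciesId = id,
                              scenario = sc, horizon = h, algorithm = alg)
        if (is.null(binMaps[[k]])) binMaps[[k]] <- list()
        binMaps[[k]][[alg]] <- c(binMaps[[k]][[alg]],
                                 stats::setNames(list(fut@cells), id))
        for (disp in config@dispersal) {
          cur2 <- cur; cur2@scenario <- sc; cur2@horizon <- as.integer(h)
          fut2 <- fut
          changeRows[[length(changeRows) + 1L]] <-
            rangeChange(cur2, fut2, dispersal = disp, realm = rec@realm,
                        family = rec@family, status = rec@status)
        }
      }
    }
  }
  rangeChanges <- do.call(rbind, changeRows)
  thresholds <- do.call(rbind, thresholdRows)

  say("ensembling and summarizing")
  ensemble <- ensembleRangeChange(rangeChanges)
  # known-truth oracle for virtual species
  truth <- NULL
  if (all(vapply(records, is, TRUE, "VirtualSpecies"))) {
    truthRows <- list()
    for (rec in records) for (sc in scenLabels) for (h in horizons)
      for (disp in config@dispersal) {
        tr <- trueRangeChange(rec, futureStacks[[futureKey(sc, h)]],
                              dispersal = disp, realmMask = realms)
        truthRows[[length(truthRows) + 1L]] <-
          data.frame(species_id = rec@speciesId, scenario = sc, horizon = h,
                     dispersal = disp, q_true = tr$q)
      }
    truth <- do.call(rbind, truthRows)
    ensemble <- merge(ensemble, truth,
                      by = c("species_id", "scenario", "horizon", "dispersal"),
                      all.x = TRUE, sort = FALSE)
    ensemble <- ensemble[order(ensemble$species_id, ensemble$scenario,
                               ensemble$horizon, ensemble$dispersal), ,
                         drop = FALSE]
    rownames(ensemble) <- NULL
  }
  summaries <- summarizeContractions(ensemble, seed = deriveSeed(seed, "boot"))
  summariesByRealm <- summarizeContractions(ensemble,
    grouping = c("realm", "scenario", "horizon", "dispersal"),
    seed = deriveSeed(seed, "boot_realm"))

  say("stacking richness and deficits")
  richness <- list()
  deficits <- list()
  mkMap <- function(cellsList, sc, h, alg) lapply(names(cellsList), function(id)
    new("BinaryRangeMap", speciesId = id, cells = cellsList[[id]], grid = grid,
        scenario = sc, horizon = as.integer(h), algorithm = alg,
        criterion = config@criterion))
  for (disp in config@dispersal) {
    for (alg in config@algorithms) {
      if (is.null(curMaps[[alg]]) || length(curMaps[[alg]]) == 0) next
      curR <- stackRichness(mkMap(curMaps[[alg]], "current", NA, alg),
                            factor = config@aggFactor, dispersal = disp)
      richness[[paste("current", alg, disp, sep = "_")]] <- curR
      for (sc in scenLabels) for (h in horizons) {
        k <- futureKey(sc, h)
        cl <- binMaps[[k]][[alg]]
        if (disp == "none")
          cl <- stats::setNames(lapply(names(cl), function(id)
            intersect(cl[[id]], curMaps[[alg]][[id]])), names(cl))
        futR <- stackRichness(mkMap(cl, sc, h, alg),
                              factor = config@aggFactor, dispersal = disp)
        richness[[paste(k, alg, disp, sep = "_")]] <- futR
        deficits[[paste(k, alg, disp, sep = "_")]] <- deficitMap(curR, futR)
      }
    }
    for (sc in scenLabels) for (h in horizons) {
      k <- futureKey(sc, h)
      perAlg <- deficits[paste(k, config@algorithms, disp, sep = "_")]
      perAlg <- perAlg[!vapply(perAlg, is.null, TRUE)]
      if (length(perAlg))
        deficits[[paste(k, "ENSEMBLE", disp, sep = "_")]] <-
          algorithmAverageMap(perAlg)
    }
  }

  manifest <- list(
    config_hash = stableHash(list(config@world@seed, config@nSpecies,
      config@algorithms, config@nRuns, config@trainFrac, config@paRatio,
      config@tssMin, config@criterion, config@dispersal, config@seed)),
    seed = seed,
    package_version = as.character(utils::packageVersion("rangecast")),
    n_species_input = config@nSpecies,
    n_species_modeled = length(records),
    n_species_excluded = nrow(exclusions),
    n_model_exclusions = nrow(modelExclusions),
    n_empty_current_range = nrow(emptyP1),
    n_range_change_rows = if (is.null(rangeChanges)) 0L else nrow(rangeChanges),
    scenarios = scenLabels, horizons = horizons)

  out <- list(world = world, species = records, metrics = metrics,
              exclusions = exclusions, modelExclusions = modelExclusions,
              emptyP1 = emptyP1, thresholds = thresholds,
              rangeChanges = rangeChanges, ensemble = ensemble,
              truth = truth, summaries = summaries,
              summariesByRealm = summariesByRealm, richness = richness,
              deficits = deficits, manifest = manifest)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  invisible(out)
}

#' Write pipeline outputs to a directory
#'
#' Tables as CSV, richness/deficit maps as ASCII grids
#' (`deficit_<scenario>_<horizon>_<algorithm>_<dispersal>.asc`), and the run
#' manifest as JSON.
#'
#' @param result the list returned by [runPipeline()].
#' @param outDir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$metrics, "model_metrics.csv")
  wr(result$exclusions, "species_exclusions.csv")
  wr(result$modelExclusions, "model_exclusions.csv")
  wr(result$thresholds, "thresholds.csv")
  wr(result$rangeChanges, "range_changes.csv")
  wr(result$ensemble, "range_changes_ensemble.csv")
  wr(result$summaries, "contraction_summaries.csv")
  wr(result$summariesByRealm, "contraction_summaries_by_realm.csv")
  spMeta <- do.call(rbind, lapply(result$species, function(s)
    data.frame(species_id = s@speciesId, realm = s@realm, family = s@family,
               status = s@status, n_presence = length(s@presenceCells))))
  wr(spMeta, "species_metadata.csv")
  for (k in names(result$deficits)) {
    m <- result$deficits[[k]]
    p <- file.path(outDir, sprintf("deficit_%s.asc", k))
    writeAsciiGrid(m@values, m@grid, p)
    paths <- c(paths, p)
  }
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}

#' Read a flat key=value pipeline configuration file
#'
#' Recognized keys (all optional except `seed`): `nrow`, `ncol`,
#' `cell_size`, `n_realms`, `n_species`, `horizons` (comma-separated),
#' `scenario_labels` (comma-separated subset of RCP85,A,B,C,D),
#' `algorithms`, `n_runs`, `train_frac`, `pa_ratio`, `tss_min`, `criterion`,
#' `dispersal`, `agg_factor`, `seed`.
#'
#' @param path config file path.
#' @param seed optional seed overriding the file's.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  conf <- stats::setNames(lapply(kv, function(x) trimws(x[2])),
                          trimws(vapply(kv, `[`, "", 1)))
  num <- function(k, d) if (is.null(conf[[k]])) d else as.numeric(conf[[k]])
  chr <- function(k, d) if (is.null(conf[[k]])) d else
    trimws(strsplit(conf[[k]], ",")[[1]])
  seed <- seed %||% conf$seed
  if (is.null(seed)) stop("seed is mandatory (in the config file or --seed)")
  seed <- as.integer(seed)
  labels <- chr("scenario_labels", SCENARIO_LABELS)
  nRealms <- num("n_realms", 2)
  ws <- worldSpec(nrow = num("nrow", 30), ncol = num("ncol", 60),
                  cellSize = num("cell_size", 1 / 3), nRealms = nRealms,
                  horizons = as.integer(chr("horizons", c(2030, 2050, 2070))),
                  scenarios = defaultScenarios(
                    hosingRegion = realmLevels(nRealms)[1])[labels],
                  seed = seed)
  pipelineConfig(ws, nSpecies = num("n_species", 40),
                 algorithms = chr("algorithms", c("MAXENT", "BRT", "CART")),
                 nRuns = num("n_runs", 10), trainFrac = num("train_frac", 0.7),
                 paRatio = num("pa_ratio", 3), tssMin = num("tss_min", 0.4),
                 criterion = chr("criterion", "P10TP"),
                 dispersal = chr("dispersal", c("full", "none")),
                 aggFactor = num("agg_factor", 3), seed = seed)
}
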