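#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The fraction of (presence, background) score pairs in which the presence
#' scores higher, with ties counted one half.  Computed via midranks, which
#' is exactly the exhaustive pair count.
#'
#' @param scoresPresence,scoresBackground non-empty numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scoresPresence, scoresBackground) {
  nP <- length(scoresPresence); nB <- length(scoresBackground)
  if (nP == 0 || nB == 0) stop("both score sets must be non-empty")
  r <- rank(c(scoresPresence, scoresBackground))
  (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nB)
}

#' Confusion-matrix validation metrics
#'
#' Sensitivity, specificity, the true skill statistic
#' (TSS = sensitivity + specificity - 1), Cohen's kappa (chance-corrected
#' agreement) and the omission rate (fraction of presences predicted absent).
#'
#' @param tp,fn,tn,fp confusion counts (presences predicted present/absent,
#'   absences predicted absent/present); `tp + fn > 0` and `tn + fp > 0`.
#' @return named numeric vector
#'   `(sensitivity, specificity, tss, kappa, omission)`.
#' @export
confusionMetrics <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be non-negative")
  if (tp + fn == 0 || tn + fp == 0) stop("zero marginal: metrics undefined")
  n <- tp + fn + tn + fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  c(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
    kappa = kappa, omission = fn / (tp + fn))
}

#' Evaluate one fitted model on a held-out split
#'
#' AUC from the raw scores; the confusion-based metrics (TSS, kappa,
#' omission) at the threshold obtained by applying `criterion` to the
#' *training*-presence scores — the same threshold criterion used for
#' downstream binarization (default the 10th-percentile training presence).
#'
#' @param model a [SuitabilityModel-class].
#' @param xTrainPresence training-presence feature matrix (threshold source).
#' @param xTestPresence,xTestAbsence held-out feature matrices.
#' @param criterion threshold criterion label (default `"P10TP"`).
#' @return one-row data.frame with `auc`, `tss`, `kappa`, `omission`,
#'   `sensitivity`, `specificity`, `threshold`.
#' @export
evaluateModel <- function(model, xTrainPresence, xTestPresence, xTestAbsence,
                          criterion = "P10TP") {
  sTrainP <- predictSuitability(model, xTrainPresence)
  sP <- predictSuitability(model, xTestPresence)
  sA <- predictSuitability(model, xTestAbsence)
  thr <- computeThreshold(sTrainP, criterion = criterion)
  cm <- confusionMetrics(tp = sum(sP >= thr@value), fn = sum(sP < thr@value),
                         tn = sum(sA < thr@value), fp = sum(sA >= thr@value))
  data.frame(auc = rocAuc(sP, sA), tss = cm[["tss"]], kappa = cm[["kappa"]],
             omission = cm[["omission"]], sensitivity = cm[["sensitivity"]],
             specificity = cm[["specificity"]], threshold = thr@value)
}

#' Screen candidate algorithms on a random species sample
#'
#' Samples up to `nPerRealm` species per realm, fits every requested
#' registered learner with `nRuns` subsampling runs each, and tabulates mean
#' validation metrics per algorithm.  The table is ordered by mean TSS
#' descending; picking the retained set is a reported decision, not
#' automatic.  Individual fit failures are logged as warnings, not fatal.
#'
#' @param records list of [SpeciesRecord-class].
#' @param bioclim current-climate [BioclimStack-class].
#' @param realmMask a [RealmMask-class].
#' @param algorithms algorithm labels (default all registered).
#' @param nPerRealm species sampled per realm (default 15).
#' @param nRuns subsampling runs per species (default 3 for screening).
#' @param seed integer seed.
#' @param ... passed to [buildOccurrenceDesign()] (`ratio`, `trainFrac`).
#' @return data.frame, one row per algorithm, ordered by `tss` descending.
#' @export
screenAlgorithms <- function(records, bioclim, realmMask,
                             algorithms = availableAlgorithms(),
                             nPerRealm = 15, nRuns = 3, seed, ...) {
  if (length(algorithms) == 0) stop("algorithm registry selection is empty")
  byRealm <- split(records, vapply(records, slot, "", "realm"))
  sampled <- withSeed(deriveSeed(seed, "screen"), unlist(lapply(byRealm,
    function(rs) sample(rs, min(nPerRealm, length(rs)))), use.names = FALSE))
  rows <- list()
  for (rec in sampled) {
    des <- buildOccurrenceDesign(rec, realmMask, nRuns = nRuns,
                                 seed = deriveSeed(seed, "screen_design"), ...)
    for (alg in algorithms) for (ri in seq_len(nRuns)) {
      run <- des@runs[[ri]]
      res <- tryCatch({
        m <- fitSuitability(alg,
          bioclim@values[c(run$trainPresence, run$trainAbsence), , drop = FALSE],
          rep(c(1L, 0L), c(length(run$trainPresence), length(run$trainAbsence))),
          seed = deriveSeed(seed, "screen_fit", rec@speciesId, alg, ri))
        cbind(species_id = rec@speciesId, algorithm = alg, run = ri,
              evaluateModel(m,
                bioclim@values[run$trainPresence, , drop = FALSE],
                bioclim@values[run$testPresence, , drop = FALSE],
                bioclim@values[run$testAbsence, , drop = FALSE]))
      }, error = function(e) {
        warning(sprintf("screening fit failed (%s, %s, run %d): %s",
                        rec@speciesId, alg, ri, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab[c("auc", "tss", "kappa", "omission")],
                          by = list(algorithm = tab$algorithm), FUN = mean)
  agg[order(-agg$tss), , drop = FALSE]
}

#' Exclude species-algorithm combinations with poor validation skill
#'
#' Removes entries whose mean cross-run TSS is less than or equal to
#' `tssMin` (the rule is inclusive: TSS exactly at the cutoff is excluded)
#' and logs them.
#'
#' @param metrics data.frame with `species_id`, `algorithm`, `tss` (one row
#'   per run).
#' @param tssMin exclusion cutoff (default 0.4).
#' @return list with `retained` (subset of `metrics`) and `excluded`
#'   (data.frame `species_id`, `algorithm`, `mean_tss`, `reason`).
#' @export
excludePoorModels <- function(metrics, tssMin = 0.4) {
  agg <- stats::aggregate(list(mean_tss = metrics$tss),
    by = list(species_id = metrics$species_id, algorithm = metrics$algorithm),
    FUN = mean)
  bad <- agg[agg$mean_tss <= tssMin, , drop = FALSE]
  key <- paste(metrics$species_id, metrics$algorithm)
  badKey <- paste(bad$species_id, bad$algorithm)
  list(retained = metrics[!key %in% badKey, , drop = FALSE],
       excluded = if (nrow(bad)) cbind(bad, reason = "TSS")
                  else data.frame(species_id = character(),
                                  algorithm = character(),
                                  mean_tss = numeric(), reason = character()))
}
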