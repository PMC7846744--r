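#' Compute a binarization threshold
#'
#' Four criteria convert continuous suitability to presence/absence (presence
#' is inclusive: a cell is presence iff suitability `>= value`):
#'
#' * `MTP` — minimum training presence: the smallest training-presence
#'   score, giving zero training omission.
#' * `P10TP` — 10th-percentile training presence by the nearest-rank rule
#'   (the `ceiling(0.1 n)`-th smallest presence score), omitting at most the
#'   lowest ~10% of training presences.
#' * `ESS` — equal sensitivity and specificity: the candidate threshold
#'   minimizing `|sensitivity - specificity|`.
#' * `MSS` — maximum sensitivity plus specificity (equivalently maximum TSS).
#'
#' ESS/MSS candidates are the unique observed scores of both classes; ties
#' resolve to the lower threshold.
#'
#' @param presenceScores training-presence suitability scores (non-empty).
#' @param scores,labels for `ESS`/`MSS`: all training scores with 0/1 labels
#'   (both classes required).
#' @param criterion one of `MTP`, `P10TP`, `ESS`, `MSS`.
#' @return a [ThresholdSpec-class].
#' @export
computeThreshold <- function(presenceScores, scores = NULL, labels = NULL,
                             criterion = c("P10TP", "MTP", "ESS", "MSS")) {
  criterion <- match.arg(criterion)
  if (length(presenceScores) == 0) stop("presence scores must be non-empty")
  value <- switch(criterion,
    MTP = min(presenceScores),
    P10TP = {
      s <- sort(presenceScores)
      s[max(1L, ceiling(0.1 * length(s)))]
    },
    ESS = , MSS = {
      if (is.null(scores) || is.null(labels))
        stop(sprintf("%s requires labeled scores for both classes", criterion))
      labels <- as.integer(labels)
      if (length(unique(labels)) < 2L)
        stop(sprintf("%s requires scores from both classes", criterion))
      cand <- sort(unique(scores))
      sens <- vapply(cand, function(t) mean(scores[labels == 1] >= t), 0)
      spec <- vapply(cand, function(t) mean(scores[labels == 0] < t), 0)
      obj <- if (criterion == "ESS") -abs(sens - spec) else sens + spec
      cand[which.max(obj)]   # which.max takes the first (lowest) on ties
    })
  new("ThresholdSpec", criterion = criterion,
      value = min(max(value, 0), 1))
}

#' Apply a threshold to a suitability map
#'
#' Presence iff suitability `>= value`, restricted to the species' realm
#' background; cells outside the background are always absent.
#'
#' @param suitability numeric suitability for each background cell.
#' @param backgroundCells integer cell ids the suitabilities refer to.
#' @param threshold a [ThresholdSpec-class].
#' @param grid the [GridSpec-class].
#' @param speciesId,scenario,horizon,algorithm provenance labels.
#' @return a [BinaryRangeMap-class].
#' @export
applyThreshold <- function(suitability, backgroundCells, threshold, grid,
                           speciesId = "", scenario = "", horizon = NA_integer_,
                           algorithm = "") {
  if (length(suitability) != length(backgroundCells))
    stop("suitability and background cells are not aligned")
  new("BinaryRangeMap", speciesId = speciesId,
      cells = as.integer(sort(backgroundCells[suitability >= threshold@value])),
      grid = grid, scenario = scenario, horizon = as.integer(horizon),
      algorithm = algorithm, criterion = threshold@criterion)
}

setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec %s = %.4f\n", object@criterion, object@value))
})

setMethod("show", "BinaryRangeMap", function(object) {
  cat(sprintf("BinaryRangeMap '%s' [%s/%s/%s/%s]: %d presence cells\n",
              object@speciesId, object@scenario, object@horizon,
              object@algorithm, object@criterion, length(object@cells)))
})
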