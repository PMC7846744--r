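#' Proportional range change between two binary maps
#'
#' `q = (p1 - p2) / p1`, where `p1` is the current and `p2` the future
#' predicted presence-cell count.  Under full dispersal `p2` counts future
#' presence anywhere in the realm background; under no dispersal only future
#' presence inside the current range (`q >= 0` follows).  `q = 1` is total
#' loss, negative `q` is expansion.
#'
#' @param current,future [BinaryRangeMap-class] objects for the same
#'   species, grid and algorithm.
#' @param dispersal `"full"` or `"none"`.
#' @param realm,family,status optional species metadata carried through.
#' @return one-row data.frame: `species_id`, `realm`, `family`, `status`,
#'   `scenario`, `horizon`, `dispersal`, `algorithm`, `p1`, `p2`, `q`.
#' @export
rangeChange <- function(current, future, dispersal = c("full", "none"),
                        realm = NA_character_, family = NA_character_,
                        status = NA_character_) {
  dispersal <- match.arg(dispersal)
  if (current@speciesId != future@speciesId ||
      current@algorithm != future@algorithm ||
      !sameGrid(current@grid, future@grid))
    stop("current and future maps must share species, grid and algorithm")
  p1 <- length(current@cells)
  if (p1 == 0)
    stop(sprintf("species '%s': empty current predicted range, q undefined",
                 current@speciesId))
  p2 <- if (dispersal == "none")
    length(intersect(future@cells, current@cells)) else length(future@cells)
  data.frame(species_id = current@speciesId, realm = realm, family = family,
             status = status, scenario = future@scenario,
             horizon = future@horizon, dispersal = dispersal,
             algorithm = current@algorithm, p1 = p1, p2 = p2,
             q = (p1 - p2) / p1)
}

#' Ensemble range change across algorithms
#'
#' Averages per-algorithm `q` for each species x scenario x horizon x
#' dispersal cell (arithmetic mean over retained algorithms), recording the
#' contributing algorithms.  Species with no retained algorithm are absent
#' from the result (dropped upstream with a log entry).
#'
#' @param records data.frame of per-algorithm range-change rows as produced
#'   by [rangeChange()].
#' @return data.frame with `algorithm = "ENSEMBLE"`, the averaged `q`, and a
#'   `contributors` column listing the averaged algorithms.
#' @export
ensembleRangeChange <- function(records) {
  if (nrow(records) == 0) return(records)
  keys <- c("species_id", "realm", "family", "status", "scenario", "horizon",
            "dispersal")
  agg <- stats::aggregate(list(q = records$q),
                          by = records[keys], FUN = mean)
  contrib <- stats::aggregate(list(contributors = records$algorithm),
    by = records[keys],
    FUN = function(a) paste(sort(unique(a)), collapse = "+"))
  out <- merge(agg, contrib, by = keys, sort = FALSE)
  out$algorithm <- "ENSEMBLE"
  out[order(out$species_id, out$scenario, out$horizon, out$dispersal), ,
      drop = FALSE]
}

#' Grouped contraction summaries with bootstrap confidence intervals
#'
#' Median `q` per group with a seeded percentile-bootstrap 95% confidence
#' interval of the median.  With `contractingOnly = TRUE` (the reporting
#' convention for contraction figures) only species with `q > 0` enter, per
#' group; groups emptied by the filter are omitted.
#'
#' @param records data.frame of range-change rows (typically the ensemble).
#' @param grouping character vector of grouping columns (default
#'   scenario/horizon/dispersal).
#' @param contractingOnly keep only `q > 0` rows (default TRUE).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @return data.frame: grouping columns, `n`, `median_q`, `ci_lower`,
#'   `ci_upper`, `contracting_only`.
#' @export
summarizeContractions <- function(records,
                                  grouping = c("scenario", "horizon", "dispersal"),
                                  contractingOnly = TRUE, nBoot = 1000, seed,
                                  level = 0.95) {
  df <- if (contractingOnly) records[records$q > 0, , drop = FALSE] else records
  if (nrow(df) == 0)
    return(data.frame())
  groups <- split(df$q, df[grouping], drop = TRUE, sep = "|;|")
  alpha <- (1 - level) / 2
  rows <- withSeed(seed, lapply(names(groups), function(g) {
    q <- groups[[g]]
    boots <- vapply(seq_len(nBoot), function(b)
      stats::median(sample(q, replace = TRUE)), 0)
    keyVals <- strsplit(g, "|;|", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(keyVals), stringsAsFactors = FALSE)
    names(row) <- grouping
    row <- utils::type.convert(row, as.is = TRUE)
    cbind(row, n = length(q), median_q = stats::median(q),
          ci_lower = unname(stats::quantile(boots, alpha)),
          ci_upper = unname(stats::quantile(boots, 1 - alpha)),
          contracting_only = contractingOnly)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
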