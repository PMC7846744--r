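#' @importFrom stats predict quantile
NULL

# ---- algorithm registry -----------------------------------------------------

.algorithms <- new.env(parent = emptyenv())

#' Register / list suitability algorithms
#'
#' The registry ships `MAXENT` (l1-penalized logistic regression on an
#' expanded feature set: linear, quadratic, pairwise-product and hinge
#' features — the well-known GLM realization of the MaxEnt model), `BRT`
#' (gradient-boosted classification trees) and `CART` (a single
#' cost-complexity-pruned classification tree).  Additional learners can be
#' registered; `fitSuitability` rejects unknown labels.
#'
#' @param label algorithm label.
#' @param fit function `(x, y, hyperparams, seed) -> list(fit, extras)`;
#'   `x` is the standardized feature matrix, `y` a 0/1 vector.
#' @param predict function `(fitted, extras, x) -> suitability in [0, 1]`.
#' @return `availableAlgorithms()` returns the registered labels.
#' @export
registerAlgorithm <- function(label, fit, predict) {
  assign(label, list(fit = fit, predict = predict), envir = .algorithms)
  invisible(label)
}

#' @rdname registerAlgorithm
#' @export
availableAlgorithms <- function() sort(ls(.algorithms))

# ---- MAXENT: penalized logistic on expanded features ------------------------

# Hinge knots at the training deciles of each (standardized) variable.
hingeKnots <- function(x) {
  apply(x, 2, stats::quantile, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
}

maxentFeatures <- function(x, knots) {
  p <- ncol(x)
  prods <- list()
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p))
    prods[[length(prods) + 1L]] <- x[, i] * x[, j]
  hinges <- lapply(seq_len(p), function(j)
    sapply(knots[, j], function(k) pmax(x[, j] - k, 0)))
  cbind(x, x^2, do.call(cbind, prods), do.call(cbind, hinges))
}

fitMaxent <- function(x, y, hyperparams, seed) {
  knots <- hingeKnots(x)
  f <- maxentFeatures(x, knots)
  foldid <- withSeed(seed, sample(rep_len(seq_len(4), length(y))))
  fit <- glmnet::cv.glmnet(f, y, family = "binomial", alpha = 1,
                           foldid = foldid, standardize = TRUE)
  list(fit = fit, extras = list(knots = knots))
}

predictMaxent <- function(fitted, extras, x) {
  f <- maxentFeatures(x, extras$knots)
  as.numeric(stats::predict(fitted, newx = f, s = "lambda.min",
                            type = "response"))
}

# ---- BRT: gradient-boosted classification trees -----------------------------

fitBrt <- function(x, y, hyperparams, seed) {
  eta <- hyperparams$eta %||% 0.05
  depth <- hyperparams$maxDepth %||% 3
  nroundsMax <- hyperparams$nroundsMax %||% 500
  # internal 20% holdout for early stopping
  hold <- withSeed(seed, sample.int(length(y), max(2, round(0.2 * length(y)))))
  dtrain <- xgboost::xgb.DMatrix(x[-hold, , drop = FALSE], label = y[-hold])
  dvalid <- xgboost::xgb.DMatrix(x[hold, , drop = FALSE], label = y[hold])
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta, max_depth = depth,
                  nthread = 1, eval_metric = "logloss"),
    data = dtrain, nrounds = nroundsMax,
    evals = list(valid = dvalid),
    early_stopping_rounds = 20, verbose = 0)
  list(fit = fit, extras = list())
}

predictBrt <- function(fitted, extras, x) {
  as.numeric(stats::predict(fitted, xgboost::xgb.DMatrix(x)))
}

# ---- CART: single pruned classification tree --------------------------------

fitCart <- function(x, y, hyperparams, seed) {
  df <- data.frame(y = factor(y, levels = c(0, 1)), x)
  fit <- withSeed(seed,
    rpart::rpart(y ~ ., data = df, method = "class",
                 control = rpart::rpart.control(cp = 0.001, xval = 10)))
  cptab <- fit$cptable
  best <- cptab[which.min(cptab[, "xerror"]), "CP"]
  list(fit = rpart::prune(fit, cp = best), extras = list())
}

predictCart <- function(fitted, extras, x) {
  as.numeric(stats::predict(fitted, newdata = data.frame(x),
                            type = "prob")[, "1"])
}

registerAlgorithm("MAXENT", fitMaxent, predictMaxent)
registerAlgorithm("BRT", fitBrt, predictBrt)
registerAlgorithm("CART", fitCart, predictCart)

# ---- fitting and prediction -------------------------------------------------

#' Fit a suitability model
#'
#' Features (the five bioclim variables) are standardized per species using
#' training statistics; the fitted predictor is pure (same input, same
#' output) and returns suitabilities in `[0, 1]`.
#'
#' @param algorithm registered algorithm label (`MAXENT`, `BRT`, `CART`).
#' @param x numeric training feature matrix (rows = cells, columns = bioclim
#'   variables, raw units).
#' @param y 0/1 labels (1 = presence, 0 = pseudoabsence).
#' @param hyperparams optional named list of algorithm hyperparameters.
#' @param seed integer seed (all algorithm stochasticity is derived from it).
#' @return a [SuitabilityModel-class].
#' @export
fitSuitability <- function(algorithm, x, y, hyperparams = list(), seed) {
  if (!exists(algorithm, envir = .algorithms))
    stop(sprintf("unknown algorithm '%s'; registered: %s", algorithm,
                 paste(availableAlgorithms(), collapse = ", ")))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("degenerate training set: a single class cannot be fitted")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  alg <- get(algorithm, envir = .algorithms)
  fitted <- alg$fit(xs, y, hyperparams, seed)
  new("SuitabilityModel", algorithm = algorithm, fit = fitted$fit,
      center = ctr, scale = scl, extras = fitted$extras,
      nTrain = length(y), seed = as.integer(seed))
}

#' Predict suitability from a fitted model
#'
#' @param model a [SuitabilityModel-class].
#' @param x feature matrix in raw bioclim units.
#' @return numeric suitabilities clamped to `[0, 1]`.
#' @export
predictSuitability <- function(model, x) {
  if (!is.null(colnames(x)) && !is.null(names(model@center)))
    x <- x[, names(model@center), drop = FALSE]
  xs <- scale(x, center = model@center, scale = model@scale)
  alg <- get(model@algorithm, envir = .algorithms)
  pmin(pmax(alg$predict(model@fit, model@extras, xs), 0), 1)
}

setMethod("show", "SuitabilityModel", function(object) {
  cat(sprintf("SuitabilityModel (%s), n_train = %d, seed = %d\n",
              object@algorithm, object@nTrain, object@seed))
})
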