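#' Derive a reproducible child seed from a master seed
#'
#' Stage- and species-level seeds are derived from one master seed by hashing
#' the master seed together with a string key (stage name, species id, ...).
#' The hash is a simple polynomial rolling hash modulo 2^31 - 1, so derived
#' seeds are valid 32-bit integers and stable across platforms and sessions.
#'
#' @param master integer master seed.
#' @param ... character or numeric key components identifying the consumer.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, ...) {
  stopifnot(length(master) == 1L, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Polynomial rolling hash of a deparsed R object, for run manifests.
stableHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 257 + ch) %% 4294967291
  sprintf("%010.0f", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
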