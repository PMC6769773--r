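# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after.
#'
#' All generators route their randomness through this so that they behave as
#' pure functions of (config, seed) and never disturb the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Geometric mean with the count zero-handling rule: zeros are replaced by 1
#' before log-averaging. Counts are integers, so this is deterministic and
#' avoids -Inf without a pseudo-count on positive values.
#' @noRd
geo_mean <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("geometric mean undefined for negative values")
  x[x == 0] <- 1
  exp(mean(log(x)))
}

#' Derive a child seed from a root seed and a stage label, keeping results
#' within 32-bit integer range. Deterministic and stage-separated so that
#' toggling one pipeline stage does not shift another stage's stream.
#' @noRd
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
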