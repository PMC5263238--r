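#' @importFrom withr with_seed
NULL

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state; seed = NULL means "use the current RNG stream".
.withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    eval.parent(substitute(expr))
  } else {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
    withr::with_seed(seed, eval.parent(substitute(expr)))
  }
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

## Rec.601 luma of an RGB array (values on the 0..255 scale), rounded to the
## integer gray levels used for histogram entropy.
.luma <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  pmin(pmax(round(g), 0), 255)
}

## Row z-score with the n-1 (sample SD) convention, matching the classic
## zscore() used for expression heatmaps; zero-variance rows map to 0.
.zscoreRow <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}
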