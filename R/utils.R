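# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' Geometric mean of strictly positive values, the aggregation geNorm uses to
#' build normalization factors.
#'
#' @param x numeric vector, all values > 0.
#' @param na.rm drop missing values first.
#' @return a single number.
#' @keywords internal
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

stop_refstab <- function(fmt, ..., module) {
  stop(sprintf("[%s] %s", module, sprintf(fmt, ...)), call. = FALSE)
}

warn_refstab <- function(fmt, ..., module) {
  warning(sprintf("[%s] %s", module, sprintf(fmt, ...)), call. = FALSE)
}

# Run an expression under a fixed RNG state, restoring the caller's stream.
with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Full-precision numeric formatting so CSV round-trips are bit-exact.
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
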