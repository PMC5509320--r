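#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans prcomp rnorm runif sd var quantile setNames
#' @importFrom utils read.csv write.csv head tail
NULL

## Condition constructors -----------------------------------------------------

bspim_error <- function(msg, class) {
  stop(structure(
    class = c(class, "bspim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

geometry_error  <- function(msg) bspim_error(msg, "bspim_geometry_error")
config_error    <- function(msg) bspim_error(msg, "bspim_config_error")
validation_error <- function(msg) bspim_error(msg, "bspim_validation_error")
parameter_error <- function(msg) bspim_error(msg, "bspim_parameter_error")
schema_error    <- function(msg) bspim_error(msg, "bspim_schema_error")
stimulus_error  <- function(msg) bspim_error(msg, "bspim_stimulus_error")
range_error     <- function(msg) bspim_error(msg, "bspim_range_error")

## Seeded evaluation ----------------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Small vector helpers -------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) geometry_error("cannot normalize a zero vector")
  v / n
}

rownorms <- function(m) sqrt(rowSums(m * m))

## cross product of rows of two n x 3 matrices
rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
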