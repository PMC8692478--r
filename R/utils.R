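#' @import stats
#' @import utils
#' @useDynLib glucotcn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Glycemic category boundaries (mg/dL), used by loss weighting, QC and metrics.
HYPO_MGDL <- 70
HYPER_MGDL <- 180
SENSOR_MIN_MGDL <- 20
SENSOR_MAX_MGDL <- 600
STEP_MIN <- 5L # CGM sampling interval, minutes

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

#' Classify glucose values into glycemic categories
#'
#' @param bg numeric vector of glucose values in mg/dL.
#' @return character vector with values `"hypo"` (< 70), `"normo"`
#'   (70--179.99) or `"hyper"` (>= 180).
#' @export
glycemic_category <- function(bg) {
  out <- rep("normo", length(bg))
  out[bg < HYPO_MGDL] <- "hypo"
  out[bg >= HYPER_MGDL] <- "hyper"
  out
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
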