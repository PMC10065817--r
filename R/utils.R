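#' @keywords internal
"_PACKAGE"

# Geometric mean of strictly positive values; zero/negative input is the
# caller's responsibility (normalization factors are undefined there).
geomean <- function(x) {
  if (any(x < 0)) stop("geometric mean requires nonnegative values")
  exp(mean(log(x)))
}

# Sample standard deviation (n - 1 denominator), kept as an explicit alias so
# the QC/background rules read like their definitions.
sample_sd <- function(x) stats::sd(x)

#' Derive a reproducible per-stage seed from a global seed
#'
#' Each pipeline stage draws its random numbers from a seed derived
#' deterministically from the run's global seed and the stage name, so a
#' stage can be rerun in isolation with the identical stream.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
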