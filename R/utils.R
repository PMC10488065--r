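#' @keywords internal
"_PACKAGE"

# logistic link helpers used across modules
expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive reproducible per-stage seeds from one master seed
#'
#' The pipeline runs several stochastic stages (cohort simulation is the only
#' one by default, but callers may want independent streams). Deriving stage
#' seeds from a single master seed keeps each stage individually
#' reproducible while the whole run is controlled by one integer.
#'
#' @param seed master integer seed.
#' @param n number of stage seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
stage_seeds <- function(seed, n = 4L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# stable short hash of an R object (FNV-1a over its serialized bytes);
# used for the run-manifest config fingerprint only, not for security
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
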