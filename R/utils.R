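# Internal helpers shared across modules.

# Maximum attainable age; death is forced at the cap.
AGE_CAP <- 120L

SEVERITIES <- c("mild", "moderate", "severe")
LOCATIONS <- c("community", "nursing_home")
LABELS <- c("TP", "FP", "TN", "FN")

#' Derive a reproducible substream seed
#'
#' Every stochastic stage of the pipeline (cohort build, AD-course paths,
#' screening classification, treatment course, trial resampling, ...) seeds
#' R's RNG with a distinct substream derived from the run seed, so adding or
#' removing a stage never perturbs the draws of another stage and compared
#' strategies share identical cohort histories (common random numbers).
#'
#' @param seed integer run seed.
#' @param k integer substream index (>= 0).
#' @return an integer in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  # all intermediates stay below 2^53 so double arithmetic is exact
  s <- (abs(seed) %% 2147483647) * 65539
  as.integer((s + k * 262144 + 11) %% 2147483646 + 1)
}

# First-success year index (0-based) of an annual Bernoulli(p) sequence,
# sampled by inverting one uniform per individual. Distributionally identical
# to drawing year by year; comonotone in p, which keeps paired-seed
# sensitivity curves pathwise monotone. Returns Inf when p <= 0.
geometric_year <- function(u, p) {
  if (p <= 0) return(rep(Inf, length(u)))
  if (p >= 1) return(rep(0, length(u)))
  floor(log1p(-u) / log1p(-p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
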