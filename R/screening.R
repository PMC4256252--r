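# Screening: classify individuals against the 20-year conversion horizon.

#' Horizon-converter status
#'
#' An individual is a horizon converter when their assigned AD onset falls
#' within `horizon` years of the base age (inclusive). By default the
#' comparison uses the assigned (pre-test) onset destiny regardless of
#' whether the individual survives to express it, matching a screen defined
#' by the population-average pre-test probability of conversion; set
#' `count_censored = FALSE` to count only onsets expressed before untreated
#' death.
#'
#' @param cohort an `ad_cohort`.
#' @param horizon horizon in years (base case 20).
#' @param count_censored include conversions censored by prior death.
#' @return logical vector.
#' @export
is_horizon_converter <- function(cohort, horizon = 20,
                                 count_censored = TRUE) {
  base_age <- attr(cohort, "base_age")
  conv <- !is.na(cohort$ad_onset_age) &
    (cohort$ad_onset_age - base_age) <= horizon
  if (!count_censored) conv <- conv & effective_converter(cohort)
  conv
}

#' Classify a cohort into diagnostic categories
#'
#' Horizon converters screen positive with probability `sensitivity` (true
#' positives, otherwise false negatives); non-converters screen positive
#' with probability `1 - specificity` (false positives, otherwise true
#' negatives). One uniform draw per individual, from the substream derived
#' from `seed`.
#'
#' @param cohort an `ad_cohort`.
#' @param s_params a [screening_params()].
#' @param seed run seed (substream 3 is used).
#' @param count_censored see [is_horizon_converter()].
#' @return the cohort with a `diagnostic_label` column
#'   (`"TP"`/`"FP"`/`"TN"`/`"FN"`).
#' @export
classify_cohort <- function(cohort, s_params = screening_params(),
                            seed = attr(cohort, "seed"),
                            count_censored = TRUE) {
  conv <- is_horizon_converter(cohort, s_params$horizon_years,
                               count_censored = count_censored)
  set.seed(derive_seed(seed, 3L))
  u <- stats::runif(nrow(cohort))
  positive <- ifelse(conv, u < s_params$sensitivity,
                     u < (1 - s_params$specificity))
  cohort$diagnostic_label <- ifelse(
    conv, ifelse(positive, "TP", "FN"),
    ifelse(positive, "FP", "TN"))
  cohort
}
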