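# Monte Carlo trial engine: repeated trial populations, strategy
# evaluation with common random numbers, Table-style aggregation.

#' Prepare both worlds for a cohort
#'
#' Runs classification, the untreated world and the treated-world course
#' once for every individual, so any strategy can afterwards be evaluated as
#' a pure masking of the per-individual net utilities (common random
#' numbers: the untreated world is bit-identical across strategies under one
#' seed).
#'
#' @param cohort an `ad_cohort`.
#' @param p_params,t_params,s_params model parameter objects.
#' @param seed run seed (substreams 2-4 and 8 are used).
#' @param count_censored see [is_horizon_converter()].
#' @param benefit_model see [simulate_treatment_course()].
#' @param untreated optional precomputed [untreated_life_histories()]
#'   output (reused by the sensitivity grids when progression parameters do
#'   not change).
#' @return list of class `sim_world`: `cohort` (with labels), `untreated`,
#'   `course`, `net` (per-individual net utility if treated), `params`.
#' @export
prepare_worlds <- function(cohort,
                           p_params = progression_params(quiet = TRUE),
                           t_params = treatment_params(),
                           s_params = screening_params(),
                           seed = attr(cohort, "seed"),
                           count_censored = TRUE,
                           benefit_model = "masked",
                           untreated = NULL) {
  cohort <- classify_cohort(cohort, s_params, seed = seed,
                            count_censored = count_censored)
  if (is.null(untreated)) {
    untreated <- untreated_life_histories(cohort, p_params, seed = seed)
  }
  course <- simulate_treatment_course(cohort, untreated, t_params, p_params,
                                      seed = seed,
                                      benefit_model = benefit_model)
  net <- net_individual_utility(untreated, course)
  structure(list(cohort = cohort, untreated = untreated, course = course,
                 net = net,
                 params = list(progression = p_params, treatment = t_params,
                               screening = s_params)),
            class = "sim_world")
}

# Which individuals a strategy treats.
treated_mask <- function(world, strategy) {
  switch(strategy,
         screen_and_treat = world$cohort$diagnostic_label %in% c("TP", "FP"),
         treat_all = rep(TRUE, nrow(world$cohort)),
         none = rep(FALSE, nrow(world$cohort)),
         stop("unknown strategy: ", strategy))
}

#' Run one trial
#'
#' Samples `trial_size` individuals without replacement from the cohort and
#' sums the per-individual net utilities of those the strategy treats.
#'
#' @param world a `sim_world` from [prepare_worlds()].
#' @param strategy `"screen_and_treat"`, `"treat_all"` or `"none"`.
#' @param trial_size number of individuals per trial.
#' @param idx optional pre-drawn index vector (used by [run_simulation()]);
#'   when `NULL` a fresh sample is drawn from the current RNG state.
#' @return list: `net` (summed net QALYs), `n_treated`, `n_false_positive`,
#'   `fp_net` (net QALYs in false positives).
#' @export
run_trial <- function(world, strategy, trial_size, idx = NULL) {
  n <- nrow(world$cohort)
  if (trial_size > n) stop("trial_size exceeds cohort size")
  if (is.null(idx)) idx <- sample.int(n, trial_size)
  treated <- treated_mask(world, strategy)[idx]
  net_i <- world$net[idx] * treated
  fp <- world$cohort$diagnostic_label[idx] == "FP" & treated
  list(net = sum(net_i), n_treated = sum(treated),
       n_false_positive = sum(fp), fp_net = sum(net_i[fp]))
}

#' Run the full Monte Carlo simulation for one strategy
#'
#' Builds (or reuses) the cohort, prepares both worlds, runs `n_trials`
#' trials of `trial_size` individuals and aggregates outcomes per 1000
#' screened and per 1000 treated.
#'
#' @param config a [default_config()].
#' @param fixtures calibration fixtures; defaults to [default_fixtures()].
#' @param cohort optional prebuilt `ad_cohort` (must match `config`'s base
#'   age); used by the sensitivity module to avoid rebuilding.
#' @param world optional prebuilt `sim_world`.
#' @return list of class `trial_summary` with fields `base_age`, `strategy`,
#'   `net_qaly_per_1000_screened`, `net_qaly_per_1000_treated`,
#'   `n_treated_per_1000`, `n_false_positive_per_1000`,
#'   `fp_net_qaly_per_1000_screened`, `sd_across_trials`, and the per-trial
#'   table in `trials`.
#' @export
run_simulation <- function(config, fixtures = NULL, cohort = NULL,
                           world = NULL) {
  if (is.null(fixtures)) fixtures <- default_fixtures()
  if (is.null(world)) {
    if (is.null(cohort)) {
      cohort <- build_cohort(config$population_size, config$base_age,
                             fixtures, seed = config$seed,
                             risk_set = config$risk_set)
    }
    world <- prepare_worlds(cohort, config$progression, config$treatment,
                            config$screening, seed = config$seed,
                            count_censored = config$count_censored,
                            benefit_model = config$benefit_model)
  }
  n <- nrow(world$cohort)
  set.seed(derive_seed(config$seed, 5L))
  trials <- vector("list", config$n_trials)
  for (t in seq_len(config$n_trials)) {
    trials[[t]] <- run_trial(world, config$strategy, config$trial_size)
  }
  net <- vapply(trials, `[[`, numeric(1), "net")
  n_treated <- vapply(trials, `[[`, numeric(1), "n_treated")
  n_fp <- vapply(trials, `[[`, numeric(1), "n_false_positive")
  fp_net <- vapply(trials, `[[`, numeric(1), "fp_net")
  scale <- 1000 / config$trial_size
  per_screened <- mean(net) * scale
  treated_per_1000 <- mean(n_treated) * scale
  per_treated <- if (treated_per_1000 > 0) {
    per_screened * 1000 / treated_per_1000
  } else 0
  structure(list(
    base_age = config$base_age, strategy = config$strategy,
    net_qaly_per_1000_screened = per_screened,
    net_qaly_per_1000_treated = per_treated,
    n_treated_per_1000 = treated_per_1000,
    n_false_positive_per_1000 = mean(n_fp) * scale,
    fp_net_qaly_per_1000_screened = mean(fp_net) * scale,
    sd_across_trials = stats::sd(net * scale),
    n_trials = config$n_trials, trial_size = config$trial_size,
    trials = data.frame(net = net * scale, n_treated = n_treated * scale,
                        n_false_positive = n_fp * scale,
                        fp_net = fp_net * scale)),
    class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("strategy %s, base age %d (%d trials x %d):\n", x$strategy,
              x$base_age, x$n_trials, x$trial_size))
  cat(sprintf("  net QALYs per 1000 screened: %.1f (sd across trials %.1f)\n",
              x$net_qaly_per_1000_screened, x$sd_across_trials))
  cat(sprintf("  net QALYs per 1000 treated:  %.1f\n",
              x$net_qaly_per_1000_treated))
  cat(sprintf("  treated per 1000 screened: %.1f;  false positives: %.1f (net %.2f)\n",
              x$n_treated_per_1000, x$n_false_positive_per_1000,
              x$fp_net_qaly_per_1000_screened))
  invisible(x)
}

#' AD prevalence among survivors, with and without a flat treatment effect
#'
#' Treat-all scenario with no harm, no discontinuation and a constant
#' (lead-time-independent) relative risk reduction: each expressed onset is
#' cancelled with probability `flat_rrr`. Returns, per age, the proportion
#' of the surviving population living with AD in the untreated and treated
#' worlds.
#'
#' @param cohort an `ad_cohort`.
#' @param flat_rrr constant RRR in `[0, 1]`.
#' @param p_params a [progression_params()].
#' @param seed run seed.
#' @return data.frame with columns `age`, `prev_untreated`, `prev_treated`.
#' @export
prevalence_curve <- function(cohort, flat_rrr,
                             p_params = progression_params(quiet = TRUE),
                             seed = attr(cohort, "seed")) {
  stopifnot(flat_rrr >= 0, flat_rrr <= 1)
  base_age <- attr(cohort, "base_age")
  untreated <- untreated_life_histories(cohort, p_params, seed = seed)
  set.seed(derive_seed(seed, 7L))
  prevented <- untreated$effective & stats::runif(nrow(cohort)) < flat_rrr
  onset <- cohort$ad_onset_age
  ages <- base_age:(AGE_CAP - 1L)
  prev_for <- function(death_age, has_ad_from) {
    vapply(ages, function(a) {
      alive <- death_age > a
      with_ad <- alive & !is.na(has_ad_from) & has_ad_from <= a
      if (!any(alive)) return(NA_real_)
      sum(with_ad) / sum(alive)
    }, numeric(1))
  }
  onset_expr <- ifelse(untreated$effective, onset, NA_integer_)
  death_treated <- ifelse(prevented, cohort$death_age_no_ad,
                          untreated$death_age)
  onset_treated <- ifelse(prevented, NA_integer_, onset_expr)
  data.frame(age = ages,
             prev_untreated = prev_for(untreated$death_age, onset_expr),
             prev_treated = prev_for(death_treated, onset_treated))
}
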