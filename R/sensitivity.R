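# One-way, two-way and probabilistic (3rd-order Monte Carlo) sensitivity
# analyses over the published parameter ranges.

ONE_WAY_PARAMS <- c("rrr_slope", "rrr_ceiling", "harm_prob",
                    "harm_magnitude", "discontinuation_rate",
                    "sensitivity", "specificity", "discount_rate",
                    "base_age")

# Return a copy of `config` with one named parameter replaced.
set_config_param <- function(config, param, value) {
  if (param %in% names(config$treatment)) {
    config$treatment[[param]] <- value
    config$treatment <- do.call(treatment_params, unclass(config$treatment))
  } else if (param %in% c("sensitivity", "specificity")) {
    config$screening[[param]] <- value
    config$screening <- do.call(screening_params, unclass(config$screening))
  } else if (param == "discount_rate") {
    config$progression$discount_rate <- value
  } else if (param == "base_age") {
    config$base_age <- as.integer(value)
  } else {
    stop("unknown parameter: ", param)
  }
  config
}

#' One-way sensitivity analysis
#'
#' Evaluates net benefit on a grid of values of one parameter, all other
#' parameters at their configured (base-case) values, with the same seed at
#' every grid point so curves are paired.
#'
#' @param config a [default_config()].
#' @param param one of `rrr_slope`, `rrr_ceiling`, `harm_prob`,
#'   `harm_magnitude`, `discontinuation_rate`, `sensitivity`,
#'   `specificity`, `discount_rate`, `base_age`.
#' @param grid numeric grid of parameter values.
#' @param fixtures calibration fixtures (default packaged).
#' @param cohort optional prebuilt cohort, reused whenever `param` does not
#'   change the population.
#' @return data.frame with columns `param`, `value`,
#'   `net_qaly_per_1000_screened`, `net_qaly_per_1000_treated`,
#'   `n_treated_per_1000`.
#' @export
one_way_sensitivity <- function(config, param, grid, fixtures = NULL,
                                cohort = NULL) {
  if (!param %in% ONE_WAY_PARAMS) stop("unknown parameter: ", param)
  if (is.null(fixtures)) fixtures <- default_fixtures()
  if (param != "base_age" && is.null(cohort)) {
    cohort <- build_cohort(config$population_size, config$base_age,
                           fixtures, seed = config$seed,
                           risk_set = config$risk_set)
  }
  rows <- lapply(grid, function(v) {
    cfg <- set_config_param(config, param, v)
    s <- run_simulation(cfg, fixtures,
                        cohort = if (param == "base_age") NULL else cohort)
    data.frame(param = param, value = v,
               net_qaly_per_1000_screened = s$net_qaly_per_1000_screened,
               net_qaly_per_1000_treated = s$net_qaly_per_1000_treated,
               n_treated_per_1000 = s$n_treated_per_1000)
  })
  do.call(rbind, rows)
}

#' Two-way sensitivity analysis over harm probability and magnitude
#'
#' Net QALYs per 1000 screened on the grid
#' `prob_grid` x `magnitude_grid`, everything else at base case, with
#' shared random draws across cells (paired seeds).
#'
#' @param config a [default_config()].
#' @param prob_grid annual harm probabilities.
#' @param magnitude_grid harm magnitudes (QALYs per event).
#' @param fixtures calibration fixtures.
#' @param cohort optional prebuilt cohort.
#' @return long-format data.frame (`harm_prob`, `harm_magnitude`,
#'   `net_qaly_per_1000_screened`) with the value matrix (rows = probability
#'   grid, columns = magnitude grid) as attribute `"matrix"`.
#' @export
two_way_harm <- function(config, prob_grid, magnitude_grid, fixtures = NULL,
                         cohort = NULL) {
  if (is.null(fixtures)) fixtures <- default_fixtures()
  if (is.null(cohort)) {
    cohort <- build_cohort(config$population_size, config$base_age,
                           fixtures, seed = config$seed,
                           risk_set = config$risk_set)
  }
  m <- matrix(NA_real_, length(prob_grid), length(magnitude_grid),
              dimnames = list(prob_grid, magnitude_grid))
  rows <- list()
  for (i in seq_along(prob_grid)) {
    for (j in seq_along(magnitude_grid)) {
      cfg <- set_config_param(config, "harm_prob", prob_grid[i])
      cfg <- set_config_param(cfg, "harm_magnitude", magnitude_grid[j])
      s <- run_simulation(cfg, fixtures, cohort = cohort)
      m[i, j] <- s$net_qaly_per_1000_screened
      rows[[length(rows) + 1L]] <- data.frame(
        harm_prob = prob_grid[i], harm_magnitude = magnitude_grid[j],
        net_qaly_per_1000_screened = m[i, j])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "matrix") <- m
  out
}

#' Sampling specification for the probabilistic sensitivity analysis
#'
#' Intervention and diagnostic parameters are uniform over their one-way
#' ranges; non-AD utilities are uniform over their published ranges; AD
#' utilities are perturbed additively by +/-0.1 (clamped to `[0, 1]`);
#' initial-severity, transition and nursing-home probabilities are perturbed
#' by +/-10% relative (rows renormalized).
#'
#' @param n_iterations number of PSA iterations (published analysis:
#'   10,000).
#' @return list of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 10000L) {
  structure(list(
    n_iterations = as.integer(n_iterations),
    base_age = 55L,
    ranges = list(
      rrr_slope = c(0, 0.06), rrr_ceiling = c(0, 1),
      harm_prob = c(0, 0.1), harm_magnitude = c(0, 6),
      discontinuation_rate = c(0, 0.2),
      sensitivity = c(0.5, 1), specificity = c(0.5, 1),
      discount_rate = c(0, 0.25)),
    no_ad_utility_ranges = list(c(0.85, 0.90), c(0.81, 0.86),
                                c(0.77, 0.85), c(0.72, 0.83)),
    ad_utility_delta = 0.1,
    relative_delta = 0.1),
    class = "psa_spec")
}

# Draw one parameter set from the spec given a row of uniforms in [0,1].
draw_psa_params <- function(spec, u) {
  k <- 0L
  nxt <- function(n = 1L) {
    v <- u[(k + 1L):(k + n)]
    k <<- k + n
    v
  }
  unif <- function(range) range[1] + nxt() * (range[2] - range[1])
  tp <- treatment_params(
    rrr_slope = unif(spec$ranges$rrr_slope),
    rrr_ceiling = unif(spec$ranges$rrr_ceiling),
    harm_prob = unif(spec$ranges$harm_prob),
    harm_magnitude = unif(spec$ranges$harm_magnitude),
    discontinuation_rate = unif(spec$ranges$discontinuation_rate))
  sp <- screening_params(
    sensitivity = unif(spec$ranges$sensitivity),
    specificity = unif(spec$ranges$specificity))
  d <- spec$relative_delta
  rel <- function(x, n) x * (1 - d + 2 * d * nxt(n))
  init <- c(mild = 0.6, moderate = 0.4, severe = 0)
  init[1:2] <- rel(init[1:2], 2L)
  trans <- default_transitions()
  nz <- which(t(trans) > 0)  # row-major order over nonzero entries
  tt <- t(trans)
  tt[nz] <- rel(tt[nz], length(nz))
  trans <- t(tt)
  nh <- pmin(pmax(rel(c(0.038, 0.110, 0.259), 3L), 0), 1)
  adu <- default_ad_utilities()
  adu[] <- pmin(pmax(adu + (2 * nxt(6L) - 1) * spec$ad_utility_delta, 0), 1)
  noadu <- vapply(spec$no_ad_utility_ranges,
                  function(rg) rg[1] + nxt() * (rg[2] - rg[1]), numeric(1))
  pp <- progression_params(
    initial_severity = init, transitions = trans,
    nh_entry = stats::setNames(nh, SEVERITIES), ad_utilities = adu,
    no_ad_utilities = noadu,
    discount_rate = unif(spec$ranges$discount_rate), quiet = TRUE)
  list(progression = pp, treatment = tp, screening = sp, n_uniforms = k)
}

N_PSA_UNIFORMS <- 32L

#' Probabilistic (3rd-order Monte Carlo) sensitivity analysis
#'
#' Repeats the screen-and-treat simulation with all parameters drawn from
#' the distributions in [psa_spec()]. The per-iteration design defaults to
#' a reduced budget (a 20,000-person cohort, 100 trials of 1000) which is
#' ample for the sign decision behind the beneficial flag; full-size runs
#' are available by raising `population_size`/`n_trials`.
#'
#' @param spec a [psa_spec()].
#' @param fixtures calibration fixtures (default packaged).
#' @param seed run seed.
#' @param n_iterations number of iterations (defaults to the spec's).
#' @param population_size cohort size per iteration (shared cohort; the
#'   life-history layer has no sampled uncertainty, so it is built once).
#' @param n_trials,trial_size trial design per iteration.
#' @return data.frame of class `psa_result`: one row per iteration with the
#'   drawn intervention/diagnostic parameters, `total_harm`
#'   (`harm_prob * harm_magnitude`), `net_qaly_per_1000_screened`,
#'   `beneficial`, `realized_mean_rrr` (mean RRR across treated individuals
#'   with an assigned onset), `slope_x_mean_lead` and `n_treated_per_1000`.
#' @export
run_psa <- function(spec = psa_spec(), fixtures = NULL, seed = 1L,
                    n_iterations = spec$n_iterations,
                    population_size = 20000L, n_trials = 100L,
                    trial_size = 1000L) {
  if (is.null(fixtures)) fixtures <- default_fixtures()
  base_cfg <- default_config(base_age = spec$base_age,
                             population_size = population_size,
                             n_trials = n_trials, trial_size = trial_size,
                             seed = seed)
  cohort <- build_cohort(population_size, spec$base_age, fixtures,
                         seed = seed)
  base_age <- spec$base_age
  lead <- ifelse(is.na(cohort$ad_onset_age), NA_real_,
                 cohort$ad_onset_age - base_age)
  set.seed(derive_seed(seed, 6L))
  U <- matrix(stats::runif(n_iterations * N_PSA_UNIFORMS), n_iterations)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    par <- draw_psa_params(spec, U[i, ])
    cfg <- base_cfg
    cfg$progression <- par$progression
    cfg$treatment <- par$treatment
    cfg$screening <- par$screening
    cfg$seed <- derive_seed(seed, 1000L + i)
    s <- run_simulation(cfg, fixtures, cohort = cohort)
    # realized RRR among treated individuals destined to convert
    labels <- classify_cohort(cohort, par$screening, seed = cfg$seed,
                              count_censored = cfg$count_censored)$diagnostic_label
    treated_conv <- labels %in% c("TP", "FP") & !is.na(lead)
    rl <- lead[treated_conv]
    realized <- if (length(rl)) {
      mean(relative_risk_reduction(rl, par$treatment))
    } else NA_real_
    slope_lead <- if (length(rl)) {
      min(par$treatment$rrr_slope * mean(rl), par$treatment$rrr_ceiling)
    } else NA_real_
    rows[[i]] <- data.frame(
      iteration = i,
      rrr_slope = par$treatment$rrr_slope,
      rrr_ceiling = par$treatment$rrr_ceiling,
      harm_prob = par$treatment$harm_prob,
      harm_magnitude = par$treatment$harm_magnitude,
      discontinuation_rate = par$treatment$discontinuation_rate,
      sensitivity = par$screening$sensitivity,
      specificity = par$screening$specificity,
      discount_rate = par$progression$discount_rate,
      total_harm = par$treatment$harm_prob * par$treatment$harm_magnitude,
      net_qaly_per_1000_screened = s$net_qaly_per_1000_screened,
      n_treated_per_1000 = s$n_treated_per_1000,
      realized_mean_rrr = realized,
      slope_x_mean_lead = slope_lead)
  }
  out <- do.call(rbind, rows)
  out$beneficial <- out$net_qaly_per_1000_screened > 0
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Summarize a probabilistic sensitivity analysis
#'
#' @param result a `psa_result` from [run_psa()].
#' @param n_quintiles number of benefit groups for the benefit-by-harm
#'   table (quintiles by default).
#' @return list: `n_iterations`, `n_beneficial`, `beneficial_fraction`,
#'   `group_means` (per-parameter means by beneficial flag),
#'   `harm_quantiles_beneficial` (50/75/95th percentiles of total harm
#'   among beneficial iterations), `benefit_quintiles` (per quintile of
#'   realized mean RRR: RRR range, iteration counts and total-harm
#'   quartiles among beneficial iterations), and `empty_beneficial`.
#' @export
summarize_psa <- function(result, n_quintiles = 5L) {
  stopifnot(nrow(result) > 0)
  ben <- result$beneficial
  params <- c("rrr_slope", "rrr_ceiling", "realized_mean_rrr",
              "harm_prob", "harm_magnitude", "total_harm",
              "discontinuation_rate", "sensitivity", "specificity",
              "discount_rate")
  group_means <- data.frame(
    param = params,
    beneficial = vapply(params, function(p) mean(result[[p]][ben], na.rm = TRUE),
                        numeric(1)),
    non_beneficial = vapply(params, function(p) mean(result[[p]][!ben], na.rm = TRUE),
                            numeric(1)))
  rownames(group_means) <- NULL
  harm_q <- if (any(ben)) {
    stats::quantile(result$total_harm[ben], c(0.5, 0.75, 0.95), names = TRUE)
  } else c(`50%` = NA_real_, `75%` = NA_real_, `95%` = NA_real_)
  rk <- rank(result$realized_mean_rrr, ties.method = "first",
             na.last = "keep")
  qt <- ceiling(rk / (sum(!is.na(rk)) / n_quintiles))
  qt <- pmin(qt, n_quintiles)
  quint <- lapply(seq_len(n_quintiles), function(g) {
    in_g <- !is.na(qt) & qt == g
    bg <- in_g & ben
    th <- result$total_harm[bg]
    data.frame(quintile = g,
               rrr_lo = suppressWarnings(min(result$realized_mean_rrr[in_g])),
               rrr_hi = suppressWarnings(max(result$realized_mean_rrr[in_g])),
               mean_rrr = mean(result$realized_mean_rrr[in_g]),
               n = sum(in_g), n_beneficial = sum(bg),
               harm_q25 = if (length(th)) stats::quantile(th, 0.25) else NA_real_,
               harm_median = if (length(th)) stats::median(th) else NA_real_,
               harm_q75 = if (length(th)) stats::quantile(th, 0.75) else NA_real_)
  })
  list(n_iterations = nrow(result), n_beneficial = sum(ben),
       beneficial_fraction = mean(ben),
       group_means = group_means,
       harm_quantiles_beneficial = harm_q,
       benefit_quintiles = do.call(rbind, quint),
       empty_beneficial = !any(ben))
}
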