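# Model parameter containers and the run configuration.

#' Markov progression parameters
#'
#' Container for the AD course model: initial severity distribution, annual
#' severity/death transition probabilities, community-to-nursing-home entry
#' probabilities, utilities for AD years (severity x location) and non-AD
#' years (age band), and the annual discount rate. Defaults are the
#' published base-case values.
#'
#' Transition rows that do not sum to 1 (the printed moderate row sums to
#' 0.957) are renormalized proportionally, with a message.
#'
#' @param initial_severity named numeric `c(mild=, moderate=, severe=)`,
#'   proportions summing to 1.
#' @param transitions 3x4 matrix, rows `mild`/`moderate`/`severe`, columns
#'   `mild`/`moderate`/`severe`/`dead`; severity never improves, so entries
#'   below the diagonal must be zero.
#' @param nh_entry named numeric: annual community-to-nursing-home entry
#'   probability per severity.
#' @param ad_utilities 3x2 matrix (severity x `community`/`nursing_home`).
#' @param no_ad_utilities utilities for the age bands 55-64, 65-74, 75-84
#'   and 85+.
#' @param discount_rate annual discount rate in `[0, 1)`; utilities `t`
#'   years after the base age are weighted by `(1 - rate)^t`.
#' @param quiet suppress the renormalization message.
#' @return list of class `progression_params`.
#' @export
progression_params <- function(
    initial_severity = c(mild = 0.6, moderate = 0.4, severe = 0),
    transitions = default_transitions(),
    nh_entry = c(mild = 0.038, moderate = 0.110, severe = 0.259),
    ad_utilities = default_ad_utilities(),
    no_ad_utilities = c(0.872, 0.836, 0.809, 0.775),
    discount_rate = 0.03,
    quiet = FALSE) {
  stopifnot(length(initial_severity) == 3L, all(initial_severity >= 0),
            sum(initial_severity) > 0)
  initial_severity <- initial_severity / sum(initial_severity)
  transitions <- as.matrix(transitions)
  stopifnot(identical(dim(transitions), c(3L, 4L)))
  dimnames(transitions) <- list(SEVERITIES, c(SEVERITIES, "dead"))
  if (transitions[2, 1] != 0 || any(transitions[3, 1:2] != 0)) {
    stop("severity never improves: backward transition probabilities must be 0")
  }
  if (any(transitions < 0)) stop("transition probabilities must be >= 0")
  rs <- rowSums(transitions)
  if (any(abs(rs - 1) > 1e-12)) {
    if (!quiet) {
      message("renormalizing transition row(s) ",
              paste(SEVERITIES[abs(rs - 1) > 1e-12], collapse = ", "),
              " to sum to 1")
    }
    transitions <- transitions / rs
  }
  stopifnot(length(nh_entry) == 3L, all(nh_entry >= 0 & nh_entry <= 1))
  ad_utilities <- as.matrix(ad_utilities)
  stopifnot(identical(dim(ad_utilities), c(3L, 2L)),
            all(ad_utilities >= 0 & ad_utilities <= 1))
  dimnames(ad_utilities) <- list(SEVERITIES, LOCATIONS)
  stopifnot(length(no_ad_utilities) == 4L,
            all(no_ad_utilities >= 0 & no_ad_utilities <= 1))
  stopifnot(discount_rate >= 0, discount_rate < 1)
  structure(list(initial_severity = initial_severity,
                 transitions = transitions,
                 nh_entry = stats::setNames(as.numeric(nh_entry), SEVERITIES),
                 ad_utilities = ad_utilities,
                 no_ad_utilities = as.numeric(no_ad_utilities),
                 discount_rate = discount_rate),
            class = "progression_params")
}

#' Base-case annual severity transition matrix
#' @return 3x4 matrix (rows: current severity; columns: next state).
#' @export
default_transitions <- function() {
  m <- rbind(mild     = c(0.614, 0.322, 0.042, 0.021),
             moderate = c(0,     0.565, 0.339, 0.053),
             severe   = c(0,     0,     0.847, 0.153))
  colnames(m) <- c(SEVERITIES, "dead")
  m
}

#' Base-case AD utilities by severity and living location
#' @return 3x2 matrix.
#' @export
default_ad_utilities <- function() {
  m <- rbind(mild = c(0.37, 0.52), moderate = c(0.18, 0.21),
             severe = c(0.02, 0))
  colnames(m) <- LOCATIONS
  m
}

# Age-band utility for non-AD years: 55-64, 65-74, 75-84, 85+.
no_ad_utility_at <- function(age, params) {
  band <- findInterval(age, c(55, 65, 75, 85), rightmost.closed = FALSE)
  band[band < 1L] <- 1L
  params$no_ad_utilities[band]
}

#' Treatment-effect parameters
#'
#' @param rrr_slope increase in relative risk reduction (RRR) per year of
#'   lead time between treatment initiation and destined AD onset.
#' @param rrr_ceiling maximum RRR regardless of lead time.
#' @param harm_prob annual probability of a treatment-related harm event
#'   while on treatment.
#' @param harm_magnitude one-time QALY decrement of a harm event
#'   (discounted at the year it occurs); harm stops treatment permanently.
#' @param discontinuation_rate annual probability of stopping treatment for
#'   non-harm reasons (no decrement, no further benefit).
#' @return list of class `treatment_params`.
#' @export
treatment_params <- function(rrr_slope = 0.03, rrr_ceiling = 0.5,
                             harm_prob = 0.001, harm_magnitude = 0.06,
                             discontinuation_rate = 0.05) {
  stopifnot(rrr_slope >= 0, rrr_slope <= 1,
            rrr_ceiling >= 0, rrr_ceiling <= 1,
            harm_prob >= 0, harm_prob <= 1, harm_magnitude >= 0,
            discontinuation_rate >= 0, discontinuation_rate <= 1)
  structure(list(rrr_slope = rrr_slope, rrr_ceiling = rrr_ceiling,
                 harm_prob = harm_prob, harm_magnitude = harm_magnitude,
                 discontinuation_rate = discontinuation_rate),
            class = "treatment_params")
}

#' Screening-test parameters
#'
#' @param sensitivity probability a horizon converter screens positive.
#' @param specificity probability a non-converter screens negative.
#' @param horizon_years the conversion horizon the screen predicts
#'   (inclusive: onset exactly `horizon_years` after the base age counts).
#' @return list of class `screening_params`.
#' @export
screening_params <- function(sensitivity = 0.65, specificity = 0.95,
                             horizon_years = 20) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, horizon_years > 0)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 horizon_years = horizon_years),
            class = "screening_params")
}

#' Default run configuration
#'
#' Fully enumerates the base-case parameter set so that a run is reproducible
#' from the configuration plus a seed alone.
#'
#' @param base_age screening/treatment initiation age (55, 60, 65, 70 or 75
#'   for replication runs; other ages are accepted).
#' @param population_size size of the life-history cohort.
#' @param n_trials number of Monte Carlo trials.
#' @param trial_size individuals sampled (without replacement) per trial.
#' @param seed run seed.
#' @param strategy one of `"screen_and_treat"`, `"treat_all"`, `"none"`.
#' @param risk_set denominator for annual conversion quotas: `"original"`
#'   (the full original cohort regardless of vital status) or `"alive"`.
#' @param count_censored whether conversions assigned after untreated death
#'   still count as converters for screening classification.
#' @param benefit_model persistence of a suppressed onset: `"masked"`
#'   (disease expression averted while on treatment, course and mortality
#'   underneath unchanged), `"on_treatment"` (disease prevented while on
#'   treatment; stopping lapses into a delayed onset) or `"permanent"`
#'   (suppression at the destined onset year is for good). See
#'   [simulate_treatment_course()].
#' @param incidence an [incidence_model()].
#' @param progression a [progression_params()].
#' @param treatment a [treatment_params()].
#' @param screening a [screening_params()].
#' @return list of class `run_config`.
#' @export
default_config <- function(base_age = 55L, population_size = 1e6,
                           n_trials = 1000L, trial_size = 1000L, seed = 1L,
                           strategy = c("screen_and_treat", "treat_all", "none"),
                           risk_set = c("original", "alive"),
                           count_censored = TRUE,
                           benefit_model = c("masked", "on_treatment",
                                             "permanent"),
                           incidence = incidence_model(),
                           progression = progression_params(quiet = TRUE),
                           treatment = treatment_params(),
                           screening = screening_params()) {
  strategy <- match.arg(strategy)
  risk_set <- match.arg(risk_set)
  benefit_model <- match.arg(benefit_model)
  stopifnot(population_size >= 1, n_trials >= 1, trial_size >= 1)
  structure(list(base_age = as.integer(base_age),
                 population_size = as.integer(population_size),
                 n_trials = as.integer(n_trials),
                 trial_size = as.integer(trial_size),
                 seed = as.integer(seed), strategy = strategy,
                 risk_set = risk_set, count_censored = count_censored,
                 benefit_model = benefit_model,
                 incidence = incidence, progression = progression,
                 treatment = treatment, screening = screening),
            class = "run_config")
}

#' Write a run configuration to a YAML file
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$progression
  x <- list(
    base_age = config$base_age, population_size = config$population_size,
    n_trials = config$n_trials, trial_size = config$trial_size,
    seed = config$seed, strategy = config$strategy,
    risk_set = config$risk_set, count_censored = config$count_censored,
    benefit_model = config$benefit_model,
    incidence = unclass(config$incidence),
    progression = list(
      initial_severity = as.list(p$initial_severity),
      transitions = lapply(SEVERITIES, function(s) as.list(p$transitions[s, ])),
      nh_entry = as.list(p$nh_entry),
      ad_utilities = lapply(SEVERITIES, function(s) as.list(p$ad_utilities[s, ])),
      no_ad_utilities = as.list(stats::setNames(
        p$no_ad_utilities, c("age_55_64", "age_65_74", "age_75_84", "age_85_plus"))),
      discount_rate = p$discount_rate),
    treatment = unclass(config$treatment),
    screening = unclass(config$screening))
  names(x$progression$transitions) <- SEVERITIES
  names(x$progression$ad_utilities) <- SEVERITIES
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path YAML path written by [write_config()] (or hand-authored with
#'   the same structure; missing fields fall back to base-case defaults).
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pr <- x$progression %||% list()
  trans <- default_transitions()
  if (!is.null(pr$transitions)) {
    for (s in SEVERITIES) {
      for (col in colnames(trans)) {
        v <- pr$transitions[[s]][[col]]
        if (!is.null(v)) trans[s, col] <- v
      }
    }
  }
  adu <- default_ad_utilities()
  if (!is.null(pr$ad_utilities)) {
    for (s in SEVERITIES) {
      for (col in LOCATIONS) {
        v <- pr$ad_utilities[[s]][[col]]
        if (!is.null(v)) adu[s, col] <- v
      }
    }
  }
  progression <- progression_params(
    initial_severity = unlist(pr$initial_severity %||%
                                list(mild = 0.6, moderate = 0.4, severe = 0)),
    transitions = trans,
    nh_entry = unlist(pr$nh_entry %||%
                        list(mild = 0.038, moderate = 0.110, severe = 0.259)),
    ad_utilities = adu,
    no_ad_utilities = unlist(pr$no_ad_utilities %||%
                               list(0.872, 0.836, 0.809, 0.775)),
    discount_rate = pr$discount_rate %||% 0.03,
    quiet = TRUE)
  inc <- x$incidence %||% list()
  tr <- x$treatment %||% list()
  sc <- x$screening %||% list()
  default_config(
    base_age = x$base_age %||% 55L,
    population_size = x$population_size %||% 1e6,
    n_trials = x$n_trials %||% 1000L,
    trial_size = x$trial_size %||% 1000L,
    seed = x$seed %||% 1L,
    strategy = x$strategy %||% "screen_and_treat",
    risk_set = x$risk_set %||% "original",
    count_censored = x$count_censored %||% TRUE,
    benefit_model = x$benefit_model %||% "masked",
    incidence = incidence_model(
      lambda60 = inc$lambda60 %||% 0.00117,
      doubling_time = inc$doubling_time %||% (log(2) / 0.126),
      sub60_halving_interval = inc$sub60_halving_interval %||% 5),
    progression = progression,
    treatment = treatment_params(
      rrr_slope = tr$rrr_slope %||% 0.03,
      rrr_ceiling = tr$rrr_ceiling %||% 0.5,
      harm_prob = tr$harm_prob %||% 0.001,
      harm_magnitude = tr$harm_magnitude %||% 0.06,
      discontinuation_rate = tr$discontinuation_rate %||% 0.05),
    screening = screening_params(
      sensitivity = sc$sensitivity %||% 0.65,
      specificity = sc$specificity %||% 0.95,
      horizon_years = sc$horizon_years %||% 20))
}
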