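# Untreated-world life-history cohort: sex, non-AD death age, AD onset age.

#' Assign sex by base-age census proportions
#'
#' @param n number of individuals.
#' @param base_age cohort base age; must be present in `sex_props`.
#' @param sex_props a [sex_proportions()] table.
#' @return character vector of `"female"`/`"male"`; each entry is an
#'   independent Bernoulli(prop_female) draw.
#' @export
assign_sex <- function(n, base_age, sex_props) {
  stopifnot(n >= 1)
  i <- match(as.integer(base_age), sex_props$base_age)
  if (is.na(i)) stop("base age ", base_age, " not present in sex proportion table")
  ifelse(stats::runif(n) < sex_props$prop_female[i], "female", "male")
}

#' Sample non-AD death ages from the life table
#'
#' For each individual, one uniform draw is made per year of possible life
#' from the base age upward; the individual dies in the first year whose
#' draw falls below the life-table annual death probability for their age
#' and sex. Survivors of every draw die at the age cap (120). The draw
#' protocol is fixed: for each age in turn, a vector of `length(sex)`
#' uniforms is drawn (one per individual, dead or alive, so the stream
#' position is independent of outcomes), stopping early only once the whole
#' cohort is dead.
#'
#' @param sex character vector (`"male"`/`"female"`), one entry per
#'   individual.
#' @param base_age first year of possible death.
#' @param life_tab a [life_table()] covering `base_age` up to its terminal
#'   age; ages beyond the terminal age have death probability 1.
#' @return integer death ages, in `[base_age, 120]`.
#' @export
sample_death_age_no_ad <- function(sex, base_age, life_tab) {
  n <- length(sex)
  lk <- lt_lookup(life_tab)
  is_f <- sex == "female"
  death <- rep(AGE_CAP, n)
  alive <- rep(TRUE, n)
  for (a in base_age:(AGE_CAP - 1L)) {
    qm <- lk$male[a + 1L]
    qf <- lk$female[a + 1L]
    if (is.na(qm) || is.na(qf)) {
      stop("life table has no coverage at age ", a)
    }
    u <- stats::runif(n)
    q <- ifelse(is_f, qf, qm)
    dies <- alive & u < q
    death[dies] <- a
    alive <- alive & !dies
    if (!any(alive)) break
  }
  as.integer(death)
}

#' Annual AD incidence
#'
#' Exponential incidence anchored at age 60, doubling every
#' `model$doubling_time` years above 60 and halving every
#' `model$sub60_halving_interval` years below 60; clamped to `[0, 1]`.
#'
#' @param age numeric vector of ages.
#' @param model an [incidence_model()].
#' @return annual conversion probabilities.
#' @export
incidence_rate <- function(age, model) {
  stopifnot(all(age >= 0))
  r <- ifelse(age >= 60,
              model$lambda60 * 2^((age - 60) / model$doubling_time),
              model$lambda60 * 2^(-(60 - age) / model$sub60_halving_interval))
  pmin(pmax(r, 0), 1)
}

#' Annual conversion quotas implied by the incidence curve
#'
#' For each year of age, the number of new converters is the incidence rate
#' times the count of not-yet-converted members of the original cohort,
#' rounded to the nearest integer with the fractional remainder carried to
#' the next year so long-run totals are unbiased.
#'
#' @param n cohort size.
#' @param base_age first year of possible conversion.
#' @param model an [incidence_model()].
#' @return data.frame with columns `age` and `quota`.
#' @export
incidence_quotas <- function(n, base_age, model) {
  ages <- base_age:(AGE_CAP - 1L)
  quota <- integer(length(ages))
  remaining <- n
  carry <- 0
  for (i in seq_along(ages)) {
    x <- incidence_rate(ages[i], model) * remaining + carry
    k <- min(round(x), remaining)
    carry <- x - k
    quota[i] <- k
    remaining <- remaining - k
    if (remaining == 0L) break
  }
  data.frame(age = ages, quota = quota)
}

#' Assign AD onset ages by the risk-rank quota mechanism
#'
#' Each individual carries a uniform risk score; each year the
#' incidence-implied quota of new converters is taken from the
#' not-yet-converted individuals with the highest risk scores (ties broken
#' by id). Under the default `risk_set = "original"` the quota denominator
#' is the original cohort and conversions may be assigned to individuals
#' already dead in the untreated world; such censored conversions are
#' recorded but contribute nothing to outcomes. Under `risk_set = "alive"`
#' both the denominator and the eligible pool are restricted to individuals
#' alive (and unconverted) at that age.
#'
#' @param cohort an `ad_cohort` with `risk` and `death_age_no_ad` filled.
#' @param model an [incidence_model()].
#' @param risk_set `"original"` or `"alive"`.
#' @return the cohort with `ad_onset_age` filled (NA for never-converters).
#' @export
assign_ad_onsets <- function(cohort, model,
                             risk_set = c("original", "alive")) {
  risk_set <- match.arg(risk_set)
  n <- nrow(cohort)
  base_age <- attr(cohort, "base_age")
  onset <- rep(NA_integer_, n)
  if (risk_set == "original") {
    q <- incidence_quotas(n, base_age, model)
    ord <- order(-cohort$risk, cohort$id)
    total <- cumsum(q$quota)
    upto <- 0L
    for (i in seq_len(nrow(q))) {
      if (q$quota[i] > 0L) {
        onset[ord[(upto + 1L):total[i]]] <- q$age[i]
      }
      upto <- total[i]
      if (upto >= n) break
    }
  } else {
    unconverted <- rep(TRUE, n)
    carry <- 0
    for (a in base_age:(AGE_CAP - 1L)) {
      pool <- which(unconverted & cohort$death_age_no_ad > a)
      if (!length(pool)) break
      x <- incidence_rate(a, model) * length(pool) + carry
      k <- min(round(x), length(pool))
      carry <- x - k
      if (k > 0L) {
        sel <- pool[order(-cohort$risk[pool], cohort$id[pool])[seq_len(k)]]
        onset[sel] <- a
        unconverted[sel] <- FALSE
      }
    }
  }
  cohort$ad_onset_age <- onset
  cohort
}

#' Build an untreated-world life-history cohort
#'
#' Draw order (all from one RNG substream derived from `seed`): sex
#' (`n` uniforms), risk scores (`n` uniforms), then the year-by-year death
#' draws of [sample_death_age_no_ad()]. Onset assignment is deterministic
#' given the risk scores. Within a year, the death check precedes the onset
#' check: an onset assigned at the death age or later is censored.
#'
#' @param n cohort size.
#' @param base_age cohort base age.
#' @param fixtures list with `life_table`, `sex_props`, `incidence`
#'   (see [default_fixtures()] / [make_toy_fixtures()]).
#' @param seed integer seed.
#' @param risk_set see [assign_ad_onsets()].
#' @return data.frame of class `ad_cohort` with columns `id`, `sex`, `risk`,
#'   `death_age_no_ad`, `ad_onset_age`, and attributes `base_age`, `seed`,
#'   `risk_set`.
#' @export
build_cohort <- function(n, base_age, fixtures, seed = 1L,
                         risk_set = c("original", "alive")) {
  risk_set <- match.arg(risk_set)
  n <- as.integer(n)
  base_age <- as.integer(base_age)
  set.seed(derive_seed(seed, 1L))
  sex <- assign_sex(n, base_age, fixtures$sex_props)
  risk <- stats::runif(n)
  death <- sample_death_age_no_ad(sex, base_age, fixtures$life_table)
  cohort <- data.frame(id = seq_len(n), sex = sex, risk = risk,
                       death_age_no_ad = death,
                       ad_onset_age = NA_integer_)
  attr(cohort, "base_age") <- base_age
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "risk_set") <- risk_set
  class(cohort) <- c("ad_cohort", "data.frame")
  assign_ad_onsets(cohort, fixtures$incidence, risk_set = risk_set)
}

#' @export
print.ad_cohort <- function(x, ...) {
  eff <- effective_converter(x)
  cat("ad_cohort:", nrow(x), "individuals, base age",
      attr(x, "base_age"), "\n")
  cat(sprintf("  assigned AD onsets: %d (%.1f%%); expressed before death: %d (%.1f%%)\n",
              sum(!is.na(x$ad_onset_age)),
              100 * mean(!is.na(x$ad_onset_age)),
              sum(eff), 100 * mean(eff)))
  invisible(x)
}

# Converters whose onset precedes their untreated (no-AD) death age; only
# these express disease in the untreated world.
effective_converter <- function(cohort) {
  !is.na(cohort$ad_onset_age) & cohort$ad_onset_age < cohort$death_age_no_ad
}

#' Validate a cohort against its calibration fixtures
#'
#' Compares simulated no-AD survival with the life-table product-limit
#' survival (mixed over sexes by the cohort's realized sex split) and the
#' realized annual conversion counts with the incidence-implied quotas.
#'
#' @param cohort an `ad_cohort`.
#' @param fixtures the fixtures the cohort was built from.
#' @return list with `survival` (age, actual, predicted, deviation),
#'   `incidence` (age, conversions, quota, cumulative actual/expected
#'   proportions), `max_survival_deviation`, `max_quota_deviation`.
#' @export
validate_population <- function(cohort, fixtures) {
  base_age <- attr(cohort, "base_age")
  n <- nrow(cohort)
  ages <- base_age:AGE_CAP
  lk <- lt_lookup(fixtures$life_table)
  pf <- mean(cohort$sex == "female")
  # predicted S(a) = P(alive at start of year a) = prod_{y<a} (1-q(y))
  surv_m <- c(1, cumprod(1 - lk$male[(base_age:(AGE_CAP - 1L)) + 1L]))
  surv_f <- c(1, cumprod(1 - lk$female[(base_age:(AGE_CAP - 1L)) + 1L]))
  predicted <- pf * surv_f + (1 - pf) * surv_m
  actual <- vapply(ages, function(a) mean(cohort$death_age_no_ad >= a),
                   numeric(1))
  survival <- data.frame(age = ages, actual = actual, predicted = predicted,
                         deviation = actual - predicted)
  q <- incidence_quotas(n, base_age, fixtures$incidence)
  conv <- table(factor(cohort$ad_onset_age, levels = q$age))
  incidence <- data.frame(
    age = q$age, conversions = as.integer(conv), quota = q$quota)
  incidence$cum_actual <- cumsum(incidence$conversions) / n
  lam <- incidence_rate(q$age, fixtures$incidence)
  incidence$cum_expected <- 1 - cumprod(1 - lam)
  list(survival = survival, incidence = incidence,
       max_survival_deviation = max(abs(survival$deviation)),
       max_quota_deviation = max(abs(incidence$conversions - incidence$quota)))
}
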