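# Treatment-effect model: lead-time-dependent relative risk reduction with
# a ceiling, annual harm, annual non-harm discontinuation.

#' Relative risk reduction as a function of lead time
#'
#' RRR grows linearly with the number of years between treatment initiation
#' and the destined AD onset, at `rrr_slope` per year, capped at
#' `rrr_ceiling`.
#'
#' @param years_to_onset non-negative lead time(s) in years.
#' @param params a [treatment_params()].
#' @return RRR value(s) in `[0, rrr_ceiling]`.
#' @export
relative_risk_reduction <- function(years_to_onset, params = treatment_params()) {
  stopifnot(all(years_to_onset >= 0))
  pmin(params$rrr_slope * years_to_onset, params$rrr_ceiling)
}

#' Untreated-world outcomes for every individual
#'
#' Simulates the untreated world once per cohort: AD courses (Markov model,
#' substream 2 of `seed`) for every converter whose onset precedes the
#' life-table death age, plus the closed-form discounted QALYs of the
#' counterfactual never-AD life course used when an onset is prevented.
#'
#' @param cohort an `ad_cohort`.
#' @param p_params a [progression_params()].
#' @param seed run seed.
#' @return data.frame with per-individual columns `effective` (expresses AD
#'   untreated), `death_age` (untreated world), `qaly_untreated`,
#'   `qaly_no_ad_full` (discounted QALYs of the full non-AD life course).
#' @export
untreated_life_histories <- function(cohort,
                                     p_params = progression_params(quiet = TRUE),
                                     seed = attr(cohort, "seed")) {
  base_age <- attr(cohort, "base_age")
  cumtab <- nonad_qaly_cum(base_age, p_params)
  qaly_full <- nonad_qaly_segment(cumtab, base_age, base_age,
                                  cohort$death_age_no_ad)
  eff <- effective_converter(cohort)
  death <- cohort$death_age_no_ad
  qaly <- qaly_full
  if (any(eff)) {
    set.seed(derive_seed(seed, 2L))
    idx <- which(eff)
    ad <- sim_ad_batch(cohort$ad_onset_age[idx], base_age, p_params)
    death[idx] <- ad$death_age
    qaly[idx] <- nonad_qaly_segment(cumtab, base_age, base_age,
                                    cohort$ad_onset_age[idx]) + ad$qaly
  }
  data.frame(effective = eff, death_age = death, qaly_untreated = qaly,
             qaly_no_ad_full = qaly_full)
}

#' Simulate the treated-world course for every individual
#'
#' Treatment starts at the base age. Each treated year carries independent
#' harm (checked first) and discontinuation draws; a harm event imposes a
#' one-time QALY decrement, discounted at the year it occurs, and stops
#' treatment permanently, while discontinuation stops treatment with no
#' decrement. An individual still on treatment at their destined onset has
#' the onset suppressed with probability equal to the RRR at their lead
#' time. Onsets censored by prior death cannot be suppressed and confer no
#' benefit.
#'
#' What suppression means afterwards is governed by `benefit_model`:
#' \describe{
#'   \item{`"masked"` (default)}{disease expression is averted only while
#'     treatment continues: every AD year before the treatment stop accrues
#'     the non-AD (age-band) utility instead of the AD utility, while the
#'     disease course underneath — including its Markov mortality — is
#'     unchanged. Stopping treatment (harm or discontinuation) drops the
#'     individual back into their own AD course; population survival is
#'     therefore identical across strategies.}
#'   \item{`"on_treatment"`}{suppression prevents the disease outright
#'     while treatment continues: the individual follows the non-AD life
#'     course (life-table mortality), and if treatment stops while they are
#'     alive the suppressed onset lapses and AD begins at that age (a
#'     delayed onset with a fresh Markov course). Dying on treatment means
#'     dying AD-free.}
#'   \item{`"permanent"`}{suppression at the destined onset year cancels
#'     the onset for good; the individual follows their untreated non-AD
#'     life course (pre-drawn life-table death age) and treatment-year
#'     draws end at the destined onset year.}
#' }
#'
#' The course is computed for every individual (whether or not a strategy
#' treats them) so that strategies compared under one seed share identical
#' treated-world draws (common random numbers). Annual
#' harm/discontinuation Bernoulli sequences are realized by inverse-CDF
#' geometric sampling from one uniform per individual, which is
#' distributionally identical to year-by-year draws and comonotone in the
#' rates.
#'
#' @param cohort an `ad_cohort`.
#' @param untreated output of [untreated_life_histories()].
#' @param t_params a [treatment_params()].
#' @param p_params a [progression_params()] (delayed-onset courses and
#'   discounting).
#' @param seed run seed (substreams 4 and 8 are used).
#' @param benefit_model `"masked"`, `"on_treatment"` or `"permanent"`.
#' @return data.frame with columns `harm_time`, `disc_time` (years from
#'   base age to the first success of each annual draw sequence, `Inf` if
#'   never), `harmed` (harm realized while treated and alive), `harm_year`,
#'   `on_treatment_at_onset`, `prevented` (onset suppressed at the destined
#'   year), `treated_onset_age` (actual onset age in the treated world, NA
#'   if none) and `qaly_treated` (discounted treated-world QALYs, before
#'   netting against the untreated world).
#' @export
simulate_treatment_course <- function(cohort, untreated,
                                      t_params = treatment_params(),
                                      p_params = progression_params(quiet = TRUE),
                                      seed = attr(cohort, "seed"),
                                      benefit_model = c("masked",
                                                        "on_treatment",
                                                        "permanent")) {
  benefit_model <- match.arg(benefit_model)
  base_age <- attr(cohort, "base_age")
  n <- nrow(cohort)
  r <- p_params$discount_rate
  set.seed(derive_seed(seed, 4L))
  u_harm <- stats::runif(n)
  u_disc <- stats::runif(n)
  u_prev <- stats::runif(n)
  harm_time <- geometric_year(u_harm, t_params$harm_prob)
  disc_time <- geometric_year(u_disc, t_params$discontinuation_rate)
  stop_time <- pmin(harm_time, disc_time)

  lead <- ifelse(is.na(cohort$ad_onset_age), Inf,
                 cohort$ad_onset_age - base_age)
  death_years <- cohort$death_age_no_ad - base_age
  on_trt <- untreated$effective & stop_time >= lead
  rrr <- relative_risk_reduction(pmin(pmax(lead, 0), AGE_CAP), t_params)
  prevented <- on_trt & u_prev < rrr

  # Years open to a harm draw: treatment runs until harm, discontinuation,
  # expressed (unsuppressed) onset, or death, whichever is first. The
  # death/onset year itself is closed (death and onset checks precede it).
  # For suppressed onsets the span on treatment depends on the benefit
  # model: until the (non-AD) life-table death under "on_treatment", until
  # the AD-world death under "masked", until the destined onset year under
  # "permanent".
  harm_window <- ifelse(untreated$effective & !prevented,
                        pmin(lead, death_years), death_years)
  if (any(prevented)) {
    harm_window[prevented] <- switch(
      benefit_model,
      on_treatment = death_years[prevented],
      masked = untreated$death_age[prevented] - base_age,
      permanent = lead[prevented])
  }
  harmed <- harm_time < harm_window & harm_time <= disc_time
  harm_year <- ifelse(harmed, base_age + harm_time, NA_real_)
  harm_dec <- ifelse(harmed, t_params$harm_magnitude * (1 - r)^harm_time, 0)

  qaly_treated <- untreated$qaly_untreated - harm_dec
  treated_onset <- ifelse(untreated$effective, cohort$ad_onset_age,
                          NA_real_)
  if (any(prevented)) {
    cumtab <- nonad_qaly_cum(base_age, p_params)
    idx <- which(prevented)
    if (benefit_model == "permanent") {
      qaly_treated[idx] <- untreated$qaly_no_ad_full[idx] - harm_dec[idx]
      treated_onset[idx] <- NA_real_
    } else if (benefit_model == "masked") {
      # Disease expression is averted only while treatment continues: AD
      # years before the treatment stop accrue non-AD (age-band) utility
      # instead of AD utility; the disease course underneath, including
      # its mortality, is unchanged, so stopping treatment drops the
      # individual back into their own AD course.
      eff_idx <- which(untreated$effective)
      cutoff <- rep(-Inf, length(eff_idx))
      sel <- match(idx, eff_idx)
      cutoff[sel] <- base_age + stop_time[idx]
      set.seed(derive_seed(seed, 2L))
      ad <- sim_ad_batch(cohort$ad_onset_age[eff_idx], base_age, p_params,
                         cutoff_age = cutoff)
      masked_end <- pmin(base_age + stop_time[idx],
                         untreated$death_age[idx])
      qaly_treated[idx] <- untreated$qaly_untreated[idx] -
        ad$qaly_cut[sel] +
        nonad_qaly_segment(cumtab, base_age, cohort$ad_onset_age[idx],
                           masked_end) - harm_dec[idx]
      treated_onset[idx] <- ifelse(
        base_age + stop_time[idx] < untreated$death_age[idx],
        base_age + stop_time[idx], NA_real_)
    } else {
      # Suppression lasts while treatment does: a stop (harm or
      # discontinuation) before the life-table death age lapses into a
      # delayed onset at that age; dying on treatment means dying AD-free.
      lapse <- stop_time[idx] < death_years[idx]
      free <- idx[!lapse]
      qaly_treated[free] <- untreated$qaly_no_ad_full[free] - harm_dec[free]
      treated_onset[free] <- NA_real_
      rel <- idx[lapse]
      if (length(rel)) {
        onset2 <- base_age + stop_time[rel]
        set.seed(derive_seed(seed, 8L))
        ad2 <- sim_ad_batch(onset2, base_age, p_params)
        qaly_treated[rel] <- nonad_qaly_segment(cumtab, base_age, base_age,
                                                onset2) +
          ad2$qaly - harm_dec[rel]
        treated_onset[rel] <- onset2
      }
    }
  }
  data.frame(harm_time = harm_time, disc_time = disc_time, harmed = harmed,
             harm_year = harm_year, on_treatment_at_onset = on_trt,
             prevented = prevented, treated_onset_age = treated_onset,
             qaly_treated = qaly_treated)
}

#' Per-individual net utility of treatment
#'
#' Discounted treated-world QALYs minus untreated-world QALYs, computed
#' with common random numbers: everything not altered by treatment cancels
#' exactly, so a never-converter without a harm event nets exactly zero.
#'
#' @param untreated output of [untreated_life_histories()].
#' @param course output of [simulate_treatment_course()].
#' @return numeric vector: QALY difference if the individual is treated
#'   (zero contribution when a strategy leaves them untreated).
#' @export
net_individual_utility <- function(untreated, course) {
  course$qaly_treated - untreated$qaly_untreated
}
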