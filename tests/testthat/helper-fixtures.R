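# Shared test fixtures, all generated in code.

toy_fx <- make_toy_fixtures(seed = 1L)

# Life table with constant annual death probability q from age_from, forced
# to 1 at the terminal age, for both sexes.
flat_life_table <- function(q, age_from = 60L, age_to = 110L) {
  ages <- age_from:age_to
  qs <- c(rep(q, length(ages) - 1L), 1)
  life_table(rbind(data.frame(age = ages, sex = "male", q = qs),
                   data.frame(age = ages, sex = "female", q = qs)))
}

flat_sex_props <- sex_proportions(
  data.frame(base_age = seq(55L, 75L, 5L), prop_female = 0.5))

# Hand-built cohort with fully specified life histories, for screening and
# treatment unit tests that need exact control over onsets and deaths.
synthetic_cohort <- function(n, base_age, death_age, onset_age = NA_integer_,
                             seed = 1L) {
  co <- data.frame(id = seq_len(n),
                   sex = rep_len(c("female", "male"), n),
                   risk = rev(seq_len(n)) / n,
                   death_age_no_ad = as.integer(rep_len(death_age, n)),
                   ad_onset_age = as.integer(rep_len(onset_age, n)))
  attr(co, "base_age") <- as.integer(base_age)
  attr(co, "seed") <- as.integer(seed)
  attr(co, "risk_set") <- "original"
  class(co) <- c("ad_cohort", "data.frame")
  co
}

# Progression parameters with a frozen disease course: mild in the
# community forever (no transitions, no nursing-home entry), so QALYs are
# closed-form computable.
frozen_progression <- function(discount_rate = 0.03) {
  progression_params(
    initial_severity = c(mild = 1, moderate = 0, severe = 0),
    transitions = rbind(mild = c(1, 0, 0, 0), moderate = c(0, 1, 0, 0),
                        severe = c(0, 0, 1, 0)),
    nh_entry = c(mild = 0, moderate = 0, severe = 0),
    discount_rate = discount_rate, quiet = TRUE)
}

# Independent year-by-year discounted QALY sum for a non-AD life course,
# written without the package's cumulative-table machinery.
brute_nonad_qalys <- function(base_age, from, to, rate = 0.03) {
  u_at <- function(a) {
    if (a < 65) 0.872 else if (a < 75) 0.836 else if (a < 85) 0.809 else 0.775
  }
  total <- 0
  if (to > from) {
    for (y in from:(to - 1L)) total <- total + u_at(y) * (1 - rate)^(y - base_age)
  }
  total
}
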