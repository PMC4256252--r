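test_that("relative risk reduction is linear in lead time with a ceiling", {
  tp <- treatment_params(rrr_slope = 0.03, rrr_ceiling = 0.5)
  expect_equal(relative_risk_reduction(10, tp), 0.3)
  expect_equal(relative_risk_reduction(30, tp), 0.5)
  expect_equal(relative_risk_reduction(0, tp), 0)
  expect_equal(relative_risk_reduction(c(5, 16, 17, 40), tp),
               c(0.15, 0.48, 0.5, 0.5))
  expect_error(relative_risk_reduction(-1, tp))
})

test_that("null treatment leaves the treated world identical", {
  co <- build_cohort(3000L, 60L, toy_fx, seed = 4L)
  p <- progression_params(quiet = TRUE)
  un <- untreated_life_histories(co, p, seed = 4L)
  null_tp <- treatment_params(rrr_ceiling = 0, harm_prob = 0,
                              discontinuation_rate = 0)
  for (bm in c("masked", "on_treatment", "permanent")) {
    course <- simulate_treatment_course(co, un, null_tp, p, seed = 4L,
                                        benefit_model = bm)
    expect_equal(course$qaly_treated, un$qaly_untreated)
    expect_true(all(net_individual_utility(un, course) == 0))
    expect_false(any(course$harmed))
  }
})

test_that("certain harm imposes exactly one decrement at year zero", {
  co <- synthetic_cohort(500, 60L, death_age = 90L, onset_age = NA)
  p <- progression_params(quiet = TRUE)
  un <- untreated_life_histories(co, p, seed = 1L)
  tp <- treatment_params(harm_prob = 1, harm_magnitude = 0.3,
                         discontinuation_rate = 0)
  course <- simulate_treatment_course(co, un, tp, p, seed = 1L)
  expect_true(all(course$harmed))
  expect_true(all(course$harm_time == 0))
  expect_equal(net_individual_utility(un, course), rep(-0.3, 500))
})

test_that("harmed never-converters lose the discounted decrement only", {
  co <- synthetic_cohort(2e4, 55L, death_age = 95L, onset_age = NA)
  p <- progression_params(quiet = TRUE)
  un <- untreated_life_histories(co, p, seed = 2L)
  tp <- treatment_params()  # base case: 0.1%/year risk of a 0.06 QALY loss
  course <- simulate_treatment_course(co, un, tp, p, seed = 2L)
  net <- net_individual_utility(un, course)
  h <- course$harmed
  expect_true(any(h))
  expect_equal(net[h], -0.06 * 0.97^course$harm_time[h])
  expect_true(all(net[!h] == 0))
})

test_that("suppression probability equals the RRR at the lead time", {
  n <- 1e5
  co <- synthetic_cohort(n, 55L, death_age = 95L, onset_age = 65L)
  p <- progression_params(quiet = TRUE)
  un <- untreated_life_histories(co, p, seed = 3L)
  tp <- treatment_params(rrr_slope = 0.03, rrr_ceiling = 0.5,
                         harm_prob = 0, discontinuation_rate = 0)
  course <- simulate_treatment_course(co, un, tp, p, seed = 3L)
  expect_true(all(course$on_treatment_at_onset))
  expect_lt(abs(mean(course$prevented) - 0.3), 0.005)
})

test_that("a discontinuation before onset forfeits suppression", {
  co <- synthetic_cohort(5000, 55L, death_age = 95L, onset_age = 70L)
  p <- progression_params(quiet = TRUE)
  un <- untreated_life_histories(co, p, seed = 5L)
  tp <- treatment_params(discontinuation_rate = 0.3)
  course <- simulate_treatment_course(co, un, tp, p, seed = 5L)
  early <- course$disc_time < 15
  expect_true(any(early))
  expect_false(any(course$prevented[early]))
})

test_that("masked benefit equals the utility-gap oracle over treated years", {
  frozen <- frozen_progression()  # AD course: mild, community, to the cap
  co <- synthetic_cohort(400, 55L, death_age = 85L, onset_age = 70L)
  un <- untreated_life_histories(co, frozen, seed = 6L)
  tp <- treatment_params(rrr_slope = 0.06, rrr_ceiling = 1, harm_prob = 0,
                         discontinuation_rate = 0.1)
  course <- simulate_treatment_course(co, un, tp, frozen, seed = 6L,
                                      benefit_model = "masked")
  net <- net_individual_utility(un, course)
  idx <- which(course$prevented)
  expect_gt(length(idx), 5)
  for (i in idx[1:5]) {
    stop_age <- min(55 + course$disc_time[i], 120)
    want <- 0
    for (y in seq_len(stop_age - 70) + 69) {
      want <- want + (0.836 * (y < 75) + 0.809 * (y >= 75 & y < 85) +
                        0.775 * (y >= 85) - 0.37) * 0.97^(y - 55)
    }
    expect_equal(net[i], want, tolerance = 1e-10)
  }
  expect_true(all(net[!course$prevented] == 0))
})

test_that("net benefit is pathwise monotone in harm and efficacy", {
  co <- build_cohort(5000L, 60L, toy_fx, seed = 7L)
  p <- progression_params(quiet = TRUE)
  un <- untreated_life_histories(co, p, seed = 7L)
  net_for <- function(tp) {
    net_individual_utility(
      un, simulate_treatment_course(co, un, tp, p, seed = 7L))
  }
  lo <- net_for(treatment_params(harm_prob = 0.001))
  hi <- net_for(treatment_params(harm_prob = 0.05))
  expect_true(all(hi <= lo + 1e-12))

  mag_lo <- net_for(treatment_params(harm_prob = 0.02, harm_magnitude = 0.06))
  mag_hi <- net_for(treatment_params(harm_prob = 0.02, harm_magnitude = 1))
  expect_true(all(mag_hi <= mag_lo + 1e-12))

  ceil_lo <- net_for(treatment_params(rrr_ceiling = 0.2))
  ceil_hi <- net_for(treatment_params(rrr_ceiling = 0.8))
  expect_true(all(ceil_hi >= ceil_lo - 1e-12))
})
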