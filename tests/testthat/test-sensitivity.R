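base_cfg <- function(pop = 20000L, trials = 50L, seed = 14L) {
  default_config(base_age = 60L, population_size = pop, n_trials = trials,
                 trial_size = 1000L, seed = seed)
}

test_that("a one-point grid reproduces the plain simulation exactly", {
  cfg <- base_cfg(pop = 5000L, trials = 20L)
  res <- one_way_sensitivity(cfg, "rrr_ceiling", 0.5, toy_fx)
  ref <- run_simulation(cfg, toy_fx)
  expect_equal(res$net_qaly_per_1000_screened, ref$net_qaly_per_1000_screened)
  expect_equal(res$n_treated_per_1000, ref$n_treated_per_1000)
  expect_error(one_way_sensitivity(cfg, "no_such_param", 1, toy_fx),
               "unknown parameter")
})

test_that("one-way curves have the expected signs and monotonicity", {
  cfg <- base_cfg()
  co <- build_cohort(cfg$population_size, cfg$base_age, toy_fx,
                     seed = cfg$seed)
  ceil <- one_way_sensitivity(cfg, "rrr_ceiling", c(0, 0.5), toy_fx,
                              cohort = co)
  expect_lte(ceil$net_qaly_per_1000_screened[1], 0)
  expect_gt(ceil$net_qaly_per_1000_screened[2], 0)

  mag <- one_way_sensitivity(cfg, "harm_magnitude", c(0, 0.5, 2, 6), toy_fx,
                             cohort = co)
  expect_true(all(diff(mag$net_qaly_per_1000_screened) <= 1e-9))

  disc <- one_way_sensitivity(cfg, "discontinuation_rate", c(0, 0.1, 0.2),
                              toy_fx, cohort = co)
  expect_true(all(diff(disc$net_qaly_per_1000_screened) <= 0.25))
})

test_that("the two-way harm grid nests the base case and is monotone", {
  cfg <- base_cfg()
  co <- build_cohort(cfg$population_size, cfg$base_age, toy_fx,
                     seed = cfg$seed)
  tw <- two_way_harm(cfg, c(0, 0.02, 0.1), c(0, 0.5, 6), toy_fx, cohort = co)
  m <- attr(tw, "matrix")
  cfg0 <- cfg
  cfg0$treatment <- treatment_params(harm_prob = 0, harm_magnitude = 0)
  ref <- run_simulation(cfg0, toy_fx, cohort = co)
  expect_equal(m[1, 1], ref$net_qaly_per_1000_screened)
  expect_true(all(apply(m, 2, function(col) all(diff(col) <= 1e-9))))
  expect_true(all(apply(m, 1, function(row) all(diff(row) <= 1e-9))))
})

test_that("a degenerate PSA spec collapses to the base case", {
  spec <- psa_spec(20L)
  spec$ranges <- list(rrr_slope = c(0.03, 0.03), rrr_ceiling = c(0.5, 0.5),
                      harm_prob = c(0.001, 0.001),
                      harm_magnitude = c(0.06, 0.06),
                      discontinuation_rate = c(0.05, 0.05),
                      sensitivity = c(0.65, 0.65),
                      specificity = c(0.95, 0.95),
                      discount_rate = c(0.03, 0.03))
  spec$no_ad_utility_ranges <- lapply(c(0.872, 0.836, 0.809, 0.775),
                                      function(u) c(u, u))
  spec$ad_utility_delta <- 0
  spec$relative_delta <- 0
  res <- run_psa(spec, toy_fx, seed = 15L, population_size = 10000L,
                 n_trials = 20L)
  expect_equal(nrow(res), 20L)
  expect_true(all(res$rrr_ceiling == 0.5))
  expect_gte(mean(res$beneficial), 0.9)
})

test_that("overwhelming harm makes essentially no iteration beneficial", {
  spec <- psa_spec(15L)
  spec$ranges$harm_prob <- c(0.1, 0.1)
  spec$ranges$harm_magnitude <- c(6, 6)
  res <- run_psa(spec, toy_fx, seed = 16L, population_size = 5000L,
                 n_trials = 10L)
  expect_equal(mean(res$beneficial), 0)
})

test_that("the PSA is reproducible under a fixed seed", {
  spec <- psa_spec(8L)
  a <- run_psa(spec, toy_fx, seed = 17L, population_size = 3000L,
               n_trials = 5L)
  b <- run_psa(spec, toy_fx, seed = 17L, population_size = 3000L,
               n_trials = 5L)
  expect_identical(a$net_qaly_per_1000_screened, b$net_qaly_per_1000_screened)
  expect_identical(sum(a$beneficial), sum(b$beneficial))
  expect_true(all(c("rrr_slope", "rrr_ceiling", "realized_mean_rrr",
                    "slope_x_mean_lead") %in% names(a)))
})

test_that("PSA summaries match hand-computed quantiles on a known table", {
  res <- data.frame(
    iteration = 1:10, rrr_slope = 0.03, rrr_ceiling = seq(0.1, 1, 0.1),
    harm_prob = 0.01, harm_magnitude = seq(0.1, 1, 0.1),
    discontinuation_rate = 0.05, sensitivity = 0.65, specificity = 0.95,
    discount_rate = 0.03, total_harm = 0.01 * seq(0.1, 1, 0.1),
    net_qaly_per_1000_screened = c(-5, -4, -3, -2, -1, 1, 2, 3, 4, 5),
    n_treated_per_1000 = 100,
    realized_mean_rrr = seq(0.05, 0.95, 0.1),
    slope_x_mean_lead = 0.3,
    beneficial = c(rep(FALSE, 5), rep(TRUE, 5)))
  class(res) <- c("psa_result", "data.frame")
  s <- summarize_psa(res)
  expect_equal(s$n_beneficial, 5L)
  expect_equal(s$beneficial_fraction, 0.5)
  gm <- s$group_means
  expect_equal(gm$beneficial[gm$param == "total_harm"],
               mean(0.01 * seq(0.6, 1, 0.1)))
  expect_equal(unname(s$harm_quantiles_beneficial["75%"]),
               unname(quantile(0.01 * seq(0.6, 1, 0.1), 0.75)))
  expect_equal(nrow(s$benefit_quintiles), 5L)
  expect_equal(s$benefit_quintiles$n, rep(2L, 5))
  expect_false(s$empty_beneficial)

  one <- res[10, ]
  class(one) <- c("psa_result", "data.frame")
  s1 <- summarize_psa(one)
  expect_equal(unname(s1$harm_quantiles_beneficial), rep(0.01, 3))

  none <- res; none$beneficial <- FALSE
  class(none) <- c("psa_result", "data.frame")
  expect_true(summarize_psa(none)$empty_beneficial)
})
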