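# Calibration fixtures: life table, sex proportions, incidence model.

#' Load and validate a sex-specific annual life table
#'
#' The life table gives, per integer age and sex, the annual probability `q`
#' of dying at that age. The table must be contiguous in age within each sex
#' and end in a terminal age with `q = 1`, which forces death at or before
#' the model's age cap of 120. Ages past the terminal age are treated as
#' having `q = 1`.
#'
#' @param path path to a CSV file with columns `age`, `sex`
#'   (`"male"`/`"female"`) and `q`.
#' @param require_span if `TRUE`, additionally require coverage from age 55
#'   (or lower) through 110 (or higher) per sex, as needed for full
#'   population runs. Toy tables used in unit tests may be shorter.
#' @return a `data.frame` of class `life_table` with columns
#'   `age`, `sex`, `q`.
#' @export
load_life_table <- function(path, require_span = FALSE) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  life_table(df, require_span = require_span)
}

#' Construct a validated life table from a data frame
#'
#' @param df data.frame with columns `age`, `sex`, `q`.
#' @inheritParams load_life_table
#' @return a validated `life_table`.
#' @export
life_table <- function(df, require_span = FALSE) {
  need <- c("age", "sex", "q")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("life table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[need]
  df$age <- as.integer(df$age)
  if (!all(df$sex %in% c("male", "female"))) {
    stop("life table 'sex' must be 'male' or 'female'")
  }
  if (any(!is.finite(df$q)) || any(df$q < 0 | df$q > 1)) {
    stop("life table 'q' values must lie in [0, 1]")
  }
  for (s in unique(df$sex)) {
    a <- sort(df$age[df$sex == s])
    if (any(diff(a) != 1L)) {
      stop("life table ages are not contiguous for sex '", s, "'")
    }
    qterm <- df$q[df$sex == s & df$age == max(a)]
    if (qterm != 1) {
      stop("life table terminal q must be 1 for sex '", s,
           "' (death must be forced by the age cap)")
    }
    if (require_span && (min(a) > 55L || max(a) < 110L)) {
      stop("life table for sex '", s, "' must span ages 55 through 110")
    }
  }
  df <- df[order(df$sex, df$age), ]
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

# Per-sex q lookup over ages 0..AGE_CAP; ages beyond the terminal age get 1,
# ages below the table start get NA (coverage errors are raised at use).
lt_lookup <- function(lt) {
  out <- list()
  for (s in c("male", "female")) {
    sub <- lt[lt$sex == s, ]
    if (!nrow(sub)) stop("life table lacks rows for sex '", s, "'")
    q <- rep(NA_real_, AGE_CAP + 1L)
    q[sub$age + 1L] <- sub$q
    if (max(sub$age) < AGE_CAP) q[(max(sub$age) + 2L):(AGE_CAP + 1L)] <- 1
    out[[s]] <- q
  }
  out
}

#' Load base-age to sex-proportion table
#'
#' @param path CSV with columns `base_age` and `prop_female`.
#' @return data.frame of class `sex_proportions`.
#' @export
load_sex_proportions <- function(path) {
  if (!file.exists(path)) stop("sex proportion file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sex_proportions(df)
}

#' Construct a validated sex-proportion table
#'
#' @param df data.frame with columns `base_age`, `prop_female`.
#' @return data.frame of class `sex_proportions`.
#' @export
sex_proportions <- function(df) {
  need <- c("base_age", "prop_female")
  if (!all(need %in% names(df))) {
    stop("sex proportion table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$base_age <- as.integer(df$base_age)
  if (any(df$prop_female < 0 | df$prop_female > 1)) {
    stop("prop_female must lie in [0, 1]")
  }
  class(df) <- c("sex_proportions", "data.frame")
  df
}

#' Age-specific AD incidence model
#'
#' Exponential (Brookmeyer-type) annual incidence anchored at age 60:
#' above 60 the rate doubles every `doubling_time` years; below 60 it halves
#' for every `sub60_halving_interval` (fixed at 5) years of age, the
#' extrapolation rule used for populations younger than the fitted range.
#'
#' @param lambda60 annual incidence probability at age 60.
#' @param doubling_time years per doubling of incidence above age 60.
#' @param sub60_halving_interval years per halving below age 60.
#' @return list of class `incidence_model`.
#' @export
incidence_model <- function(lambda60 = 0.00117, doubling_time = log(2) / 0.126,
                            sub60_halving_interval = 5) {
  stopifnot(lambda60 > 0, doubling_time > 0, sub60_halving_interval > 0)
  structure(list(lambda60 = lambda60, doubling_time = doubling_time,
                 sub60_halving_interval = sub60_halving_interval),
            class = "incidence_model")
}

#' Packaged default calibration fixtures
#'
#' Returns the life table, sex proportions and incidence model shipped with
#' the package. The life table and sex proportions are synthetic
#' approximations to US data: the life table is a per-sex Gompertz hazard
#' calibrated to published US annual death probabilities at ages 55 and 85,
#' with a terminal age of 110; sex proportions are census-like female shares
#' by base age. The incidence model defaults are the exponential-curve
#' coefficients from the epidemiological literature (incidence 0.00117/year
#' at age 60, doubling every ~5.5 years).
#'
#' @return list with elements `life_table`, `sex_props`, `incidence`.
#' @export
default_fixtures <- function() {
  lt <- load_life_table(
    system.file("extdata", "life_table_us_synthetic.csv",
                package = "adscreensim", mustWork = TRUE),
    require_span = TRUE)
  sp <- load_sex_proportions(
    system.file("extdata", "sex_proportions_us_synthetic.csv",
                package = "adscreensim", mustWork = TRUE))
  list(life_table = lt, sex_props = sp, incidence = incidence_model())
}

#' Generate internally consistent toy fixtures
#'
#' Produces a small synthetic life table (Gompertz-like `q` rising with age,
#' terminal `q = 1`), sex proportions for the supported base ages, and an
#' incidence model, all drawn reproducibly from `seed`. Intended for tests
#' and examples that must not depend on the packaged calibration files.
#'
#' @param seed integer seed.
#' @param age_from,age_to life-table age span.
#' @return list with elements `life_table`, `sex_props`, `incidence`.
#' @export
make_toy_fixtures <- function(seed = 1L, age_from = 55L, age_to = 110L) {
  set.seed(derive_seed(seed, 97L))
  ages <- age_from:age_to
  out <- list()
  rows <- NULL
  for (s in c("male", "female")) {
    a0 <- stats::runif(1, 0.004, 0.009)
    b <- stats::runif(1, 0.075, 0.095)
    q <- pmin(a0 * exp(b * (ages - age_from)), 1)
    q[length(q)] <- 1
    rows <- rbind(rows, data.frame(age = ages, sex = s, q = q))
  }
  out$life_table <- life_table(rows)
  out$sex_props <- sex_proportions(data.frame(
    base_age = seq(55L, 75L, by = 5L),
    prop_female = round(stats::runif(5, 0.50, 0.60), 3)))
  out$incidence <- incidence_model(
    lambda60 = stats::runif(1, 5e-4, 2e-3),
    doubling_time = stats::runif(1, 4.5, 6.5))
  out
}

#' Write strategy summaries to CSV
#'
#' One row per (base age, strategy) with the aggregate outcome columns of a
#' [run_simulation()] summary.
#'
#' @param results a `trial_summary`, or a list of them.
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_summary <- function(results, path) {
  if (inherits(results, "trial_summary")) results <- list(results)
  cols <- c("base_age", "strategy", "net_qaly_per_1000_screened",
            "net_qaly_per_1000_treated", "n_treated_per_1000",
            "n_false_positive_per_1000", "fp_net_qaly_per_1000_screened",
            "sd_across_trials")
  if (length(results)) {
    df <- do.call(rbind, lapply(results, function(r) {
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
  } else {
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    df$strategy <- character(0)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a summary CSV written by [write_summary()]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_summary <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
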