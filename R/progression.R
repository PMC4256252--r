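# Markov AD course model: severity, location, mortality, utilities, QALYs.
#
# Conventions (annual cycle, integer ages): the onset year accrues utility
# at the initial severity, in the community. Each subsequent year applies
# the severity transition first; if the transition is to death the year
# accrues nothing and the path ends. Survivors then take the location
# transition (nursing home is absorbing) and accrue utility at the NEW
# severity/location. Death is forced at age 120. Severity never improves.

#' Discount factor
#'
#' The model's discounting convention is `(1 - rate)^years` from the base
#' age (not `1/(1+r)^t`).
#'
#' @param years_since_base non-negative years since the base age.
#' @param rate annual discount rate in `[0, 1)`.
#' @return numeric discount weights.
#' @export
discount_factor <- function(years_since_base, rate) {
  stopifnot(all(years_since_base >= 0), rate >= 0)
  if (rate >= 1) stop("discount rate must be < 1")
  (1 - rate)^years_since_base
}

#' Draw initial AD severity at onset
#'
#' @param params a [progression_params()].
#' @param n number of draws.
#' @return character vector of severities (base case: mild with probability
#'   0.6, moderate 0.4).
#' @export
draw_initial_severity <- function(params, n = 1L) {
  p <- params$initial_severity
  u <- stats::runif(n)
  SEVERITIES[1L + (u > p[1]) + (u > p[1] + p[2])]
}

#' One annual severity transition
#'
#' @param severity current severity (vector of `"mild"`/`"moderate"`/
#'   `"severe"`).
#' @param params a [progression_params()].
#' @return next state: a severity, or `"dead"`. Severity never improves.
#' @export
step_severity <- function(severity, params) {
  i <- match(severity, SEVERITIES)
  if (anyNA(i)) stop("invalid severity")
  cm <- t(apply(params$transitions, 1, cumsum))
  u <- stats::runif(length(i))
  nxt <- 1L + (u > cm[i, 1]) + (u > cm[i, 2]) + (u > cm[i, 3])
  c(SEVERITIES, "dead")[nxt]
}

#' One annual living-location transition
#'
#' Community residents enter a nursing home with the severity-specific
#' annual probability; the nursing home is absorbing.
#'
#' @param severity current severity vector.
#' @param location current location vector (`"community"`/`"nursing_home"`).
#' @param params a [progression_params()].
#' @return next location vector.
#' @export
step_location <- function(severity, location, params) {
  i <- match(severity, SEVERITIES)
  if (anyNA(i) || !all(location %in% LOCATIONS)) stop("invalid state")
  u <- stats::runif(length(i))
  moved <- location == "community" & u < params$nh_entry[i]
  ifelse(location == "nursing_home" | moved, "nursing_home", "community")
}

#' Simulate one individual's AD course
#'
#' @param onset_age AD onset age.
#' @param params a [progression_params()].
#' @return list of class `ad_path`: `onset_age`, `death_age` and `path`, a
#'   data.frame of (age, severity, location) for each year lived with AD.
#' @export
simulate_ad_course <- function(onset_age, params) {
  stopifnot(onset_age >= 0)
  sev <- draw_initial_severity(params)
  loc <- "community"
  age <- as.integer(onset_age)
  rows <- list(data.frame(age = age, severity = sev, location = loc))
  repeat {
    age <- age + 1L
    if (age >= AGE_CAP) break
    sev_next <- step_severity(sev, params)
    if (sev_next == "dead") break
    sev <- sev_next
    loc <- step_location(sev, loc, params)
    rows[[length(rows) + 1L]] <- data.frame(age = age, severity = sev,
                                            location = loc)
  }
  path <- do.call(rbind, rows)
  structure(list(onset_age = as.integer(onset_age), death_age = age,
                 path = path), class = "ad_path")
}

# Vectorized AD-course engine: simulates courses for a batch of onset ages
# and returns death ages plus discounted AD-year QALYs (discounted from
# base_age). Same conventions and per-year draw semantics as
# simulate_ad_course, with draws made per surviving individual per year.
# When cutoff_age is supplied (same length as onset_ages), qaly_cut
# additionally accumulates the utility of AD years strictly below the
# cutoff; the draw stream is identical whether or not a cutoff is given.
sim_ad_batch <- function(onset_ages, base_age, params, cutoff_age = NULL) {
  n <- length(onset_ages)
  if (!n) {
    return(list(death_age = integer(0), qaly = numeric(0),
                qaly_cut = numeric(0)))
  }
  if (is.null(cutoff_age)) cutoff_age <- rep(-Inf, n)
  r <- params$discount_rate
  u0 <- stats::runif(n)
  p <- params$initial_severity
  sev <- 1L + (u0 > p[1]) + (u0 > p[1] + p[2])
  loc <- rep(1L, n)  # 1 = community, 2 = nursing home
  age <- as.integer(onset_ages)
  um <- params$ad_utilities
  qaly <- um[cbind(sev, loc)] * (1 - r)^(age - base_age)
  qaly_cut <- qaly * (age < cutoff_age)
  death <- rep(AGE_CAP, n)
  alive <- age < AGE_CAP
  cm <- t(apply(params$transitions, 1, cumsum))
  while (any(alive)) {
    idx <- which(alive)
    age[idx] <- age[idx] + 1L
    at_cap <- age[idx] >= AGE_CAP
    if (any(at_cap)) {
      alive[idx[at_cap]] <- FALSE
      idx <- idx[!at_cap]
      if (!length(idx)) break
    }
    s <- sev[idx]
    u <- stats::runif(length(idx))
    nxt <- 1L + (u > cm[s, 1]) + (u > cm[s, 2]) + (u > cm[s, 3])
    died <- nxt == 4L
    if (any(died)) {
      dd <- idx[died]
      death[dd] <- age[dd]
      alive[dd] <- FALSE
    }
    live <- idx[!died]
    if (length(live)) {
      sev[live] <- nxt[!died]
      ul <- stats::runif(length(live))
      moved <- loc[live] == 1L & ul < params$nh_entry[sev[live]]
      loc[live][moved] <- 2L
      acc <- um[cbind(sev[live], loc[live])] * (1 - r)^(age[live] - base_age)
      qaly[live] <- qaly[live] + acc
      qaly_cut[live] <- qaly_cut[live] + acc * (age[live] < cutoff_age[live])
    }
  }
  death[death > AGE_CAP] <- AGE_CAP
  list(death_age = as.integer(pmin(death, AGE_CAP)), qaly = qaly,
       qaly_cut = qaly_cut)
}

# Cumulative discounted non-AD QALY table for a base age.
# C[k+1] = sum over the first k years (ages base..base+k-1) of
# u(age) * (1-r)^(age-base); nonad segment [from, to) = C[to-base+1] -
# C[from-base+1].
nonad_qaly_cum <- function(base_age, params) {
  ages <- base_age:(AGE_CAP - 1L)
  u <- no_ad_utility_at(ages, params)
  w <- (1 - params$discount_rate)^(ages - base_age)
  c(0, cumsum(u * w))
}

nonad_qaly_segment <- function(cumtab, base_age, from, to) {
  from <- pmax(from, base_age)
  to <- pmin(pmax(to, from), AGE_CAP)
  cumtab[to - base_age + 1L] - cumtab[from - base_age + 1L]
}

#' Discounted lifetime QALYs for one life history
#'
#' Sums, over every year lived from the base age to death, the year's
#' utility times the discount factor. Non-AD years use the age-band utility
#' table; AD years use the severity-by-location table; the death year and
#' any later year contribute nothing.
#'
#' @param base_age base (screening) age discounting is anchored to.
#' @param death_age_no_ad untreated death age from the life table, used when
#'   the individual never expresses AD.
#' @param ad_path an `ad_path` from [simulate_ad_course()], or `NULL` for a
#'   non-AD life course. When a path is supplied it governs mortality from
#'   onset and `death_age_no_ad` is ignored past the onset year.
#' @param params a [progression_params()].
#' @return discounted QALY total.
#' @export
life_course_qalys <- function(base_age, death_age_no_ad, ad_path = NULL,
                              params = progression_params(quiet = TRUE)) {
  r <- params$discount_rate
  end_no_ad <- if (is.null(ad_path)) death_age_no_ad else ad_path$onset_age
  total <- 0
  if (end_no_ad > base_age) {
    for (y in base_age:(end_no_ad - 1L)) {
      total <- total + no_ad_utility_at(y, params) * (1 - r)^(y - base_age)
    }
  }
  if (!is.null(ad_path)) {
    p <- ad_path$path
    i <- match(p$severity, SEVERITIES)
    j <- match(p$location, LOCATIONS)
    total <- total +
      sum(params$ad_utilities[cbind(i, j)] * (1 - r)^(p$age - base_age))
  }
  total
}
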