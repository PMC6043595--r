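#' Regime parameters for synthetic RSL curves
#'
#' Shape parameters for the three glacio-isostatic regimes seen across Great
#' Britain. Near-field sites (close to the former ice-sheet center) fall from
#' high early-Holocene levels, rise to a mid-Holocene highstand above present,
#' then fall to present. Margin sites show the same pattern with a small or
#' absent highstand. Far-field sites rise monotonically toward present at a
#' decelerating rate.
#'
#' @param regime one of `"near_field"`, `"margin"`, `"far_field"`.
#' @param highstand_m highstand amplitude, metres above present
#'   (near-field/margin; default 2.8 / 0.7).
#' @param highstand_age highstand timing, cal yr BP (default 4000 / 3000).
#' @param early_rate_cap cap on the early-Holocene rate magnitude, mm/yr
#'   (far-field default 10, must lie in (3.1, 15.2]; near-field default 6,
#'   magnitude at most 7.7).
#' @param present_rate present-day rate, mm/yr (far-field default 0.2).
#' @return a `regime_params` list.
#' @export
regime_params <- function(regime = c("near_field", "margin", "far_field"),
                          highstand_m = NULL, highstand_age = NULL,
                          early_rate_cap = NULL, present_rate = NULL) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    near_field = list(highstand_m = 2.8, highstand_age = 4000,
                      early_rate_cap = 6, present_rate = -0.6),
    margin = list(highstand_m = 0.7, highstand_age = 3000,
                  early_rate_cap = 4, present_rate = -0.2),
    far_field = list(highstand_m = 0, highstand_age = NA,
                     early_rate_cap = 10, present_rate = 0.2))
  p <- list(regime = regime,
            highstand_m = highstand_m %||% defaults$highstand_m,
            highstand_age = highstand_age %||% defaults$highstand_age,
            early_rate_cap = early_rate_cap %||% defaults$early_rate_cap,
            present_rate = present_rate %||% defaults$present_rate)
  if (regime == "far_field" &&
      (p$early_rate_cap <= 3.1 || p$early_rate_cap > 15.2))
    stop("far-field early-Holocene rate cap must lie in (3.1, 15.2] mm/yr")
  if (regime != "far_field" && abs(p$early_rate_cap) > 7.7)
    stop("near-field/margin early-Holocene rate magnitude must be <= 7.7 mm/yr")
  structure(p, class = "regime_params")
}

# Regime envelopes on the emitted 1000-yr segment rates (mm/yr):
# near-field/margin within [-7.7, 6.0]; far-field non-negative with
# early-Holocene segments in (3.1, 15.2] and late-Holocene in [0, 4.6].
check_regime_envelope <- function(regime, mids, rates) {
  if (regime == "far_field") {
    if (any(rates < -1e-9) || max(rates) > 15.2)
      stop("far-field curve violates its rate envelope [0, 15.2] mm/yr")
    early <- rates[mids >= 8000]
    if (length(early) && (any(early <= 3.1) || any(early > 15.2)))
      stop("far-field early-Holocene rates must lie in (3.1, 15.2] mm/yr")
    late <- rates[mids <= 4000]
    if (length(late) && any(late > 4.6))
      stop("far-field late-Holocene rates must lie in [0, 4.6] mm/yr")
  } else {
    if (any(rates < -7.7) || any(rates > 6.0))
      stop(regime, " curve violates its rate envelope [-7.7, 6.0] mm/yr")
  }
  invisible(TRUE)
}

#' Generate a synthetic GIA-style relative sea-level curve
#'
#' Builds a 1000-yr-resolution curve over 0--12,000 cal yr BP whose
#' piecewise-linear rates follow the regime's characteristic pattern, with a
#' small seeded multiplicative jitter per segment. The per-segment rates used
#' internally are attached as `attr(curve, "segment_rates")` (mm/yr, at
#' segment midpoints) so they can be recovered exactly by [compute_rate()].
#'
#' @param params a [regime_params()] (or a regime name).
#' @param seed RNG seed (generators are seed-deterministic).
#' @param site_id site identifier for the curve.
#' @param jitter multiplicative jitter half-width on segment rates
#'   (default 0.08).
#' @return an [rsl_curve()] with `segment_rates` and `segment_mid` attributes.
#' @export
gen_rsl_curve <- function(params = regime_params("far_field"), seed = 1,
                          site_id = NULL, jitter = 0.08) {
  if (is.character(params)) params <- regime_params(params)
  stopifnot(inherits(params, "regime_params"))
  set.seed(seed)
  t_nodes <- seq(0, 12000, by = 1000)
  mids <- seq(500, 11500, by = 1000)

  base <- switch(params$regime,
    far_field = {
      tau <- 4000
      params$present_rate + (params$early_rate_cap - params$present_rate) *
        (exp(mids / tau) - 1) / (exp(12000 / tau) - 1)
    },
    near_field = {
      th <- params$highstand_age
      # rate anchors: late fall, ramp to mid-Holocene rise, early fall
      r_late <- -params$highstand_m * 1000 / th
      anchors_t <- c(0, th - 500, th + 2500, 8500, 11000, 12000)
      anchors_r <- c(r_late, r_late, params$early_rate_cap * 0.75,
                     params$early_rate_cap * 0.5,
                     -params$early_rate_cap, -params$early_rate_cap)
      approx(anchors_t, anchors_r, xout = mids)$y
    },
    margin = {
      th <- params$highstand_age
      r_late <- -params$highstand_m * 1000 / th
      anchors_t <- c(0, th - 500, th + 2500, 9000, 12000)
      anchors_r <- c(r_late, r_late, params$early_rate_cap * 0.75,
                     params$early_rate_cap * 0.3, params$early_rate_cap * 0.15)
      approx(anchors_t, anchors_r, xout = mids)$y
    })
  rates <- base * runif(length(base), 1 - jitter, 1 + jitter)
  check_regime_envelope(params$regime, mids, rates)

  # 1 mm/yr sustained over a 1000-yr segment is 1 m of RSL change;
  # positive rate means RSL was lower at older ages
  rsl <- c(0, -cumsum(rates))  # metres; node spacing 1000 yr
  if (params$regime == "near_field") {
    interior <- rsl[2:(length(rsl) - 1)]
    n_max <- sum(diff(sign(diff(rsl))) < 0)
    if (n_max != 1 || max(interior) <= 0)
      stop("near-field curve must contain exactly one mid-Holocene highstand above present")
  }
  if (is.null(site_id)) site_id <- paste0("SYN-", params$regime, "-", seed)
  cv <- rsl_curve(site_id, t_nodes, rsl, resolution = 1000)
  attr(cv, "segment_rates") <- rates
  attr(cv, "segment_mid") <- mids
  attr(cv, "regime") <- params$regime
  cv
}

#' Truth curve for synthetic tendencies
#'
#' The monotone probability-of-retreat curve that synthetic tendencies are
#' drawn from; logistic in the rate by default, with intercept -1.5 and slope
#' 0.5 per mm/yr, so p is about 0.9 near 7 mm/yr and about 0.1 near -2 mm/yr.
#'
#' @param intercept logit-scale intercept.
#' @param slope logit-scale slope per mm/yr (must be >= 0).
#' @return a `truth_curve` with elements `p(rate)` and `inverse(p)`.
#' @export
truth_curve <- function(intercept = -1.5, slope = 0.5) {
  if (slope < 0) stop("truth curve must be monotone non-decreasing in rate")
  structure(list(
    form = "logistic", intercept = intercept, slope = slope,
    p = function(rate) plogis(intercept + slope * rate),
    inverse = function(p) (qlogis(p) - intercept) / slope),
    class = "truth_curve")
}

#' Generate a synthetic index-point database
#'
#' Samples ages with mid-Holocene concentration (most points between 3000 and
#' 8000 cal yr BP), assigns each point to a curve, computes its rate by the
#' 200-yr centered rule, and draws its tendency Bernoulli from the truth
#' curve (positive vs negative). A `frac_none` share is relabelled
#' no-tendency and a `frac_erosional` share is marked as erosional contacts.
#' The generating rate and probability are kept in columns `rate_true` and
#' `p_true` for recovery tests; [write_index_points()] emits only the
#' canonical fields.
#'
#' @param curves list of [rsl_curve()] objects (points are spread uniformly
#'   across them).
#' @param truth a [truth_curve()].
#' @param n number of points (default 1097, the size of the compiled Great
#'   British database).
#' @param frac_none share relabelled no-tendency (default 19/1097).
#' @param frac_erosional share marked erosional (default 316/1097, so the
#'   gradual subset is about 781 points).
#' @param seed RNG seed.
#' @return an `index_point_db` whose points carry `rate_true`, `p_true`,
#'   `y_true` columns.
#' @export
gen_index_points <- function(curves, truth = truth_curve(), n = 1097,
                             frac_none = 19 / 1097,
                             frac_erosional = 316 / 1097, seed = 1) {
  if (inherits(curves, "rsl_curve")) curves <- list(curves)
  if (length(curves) == 0) stop("curves must be non-empty")
  stopifnot(n > 0, frac_none >= 0, frac_none < 1,
            frac_erosional >= 0, frac_erosional < 1)
  set.seed(seed)
  mid <- runif(n) < 0.7
  age <- ifelse(mid, runif(n, 3000, 8000), runif(n, 150, 11850))
  which_curve <- sample.int(length(curves), n, replace = TRUE)
  rate <- vapply(seq_len(n), function(i)
    compute_rate(curves[[which_curve[i]]], age[i]), 0)
  p <- truth$p(rate)
  y <- rbinom(n, 1, p)
  tendency <- ifelse(y == 1, "positive", "negative")
  tendency[runif(n) < frac_none] <- "none"
  contact <- ifelse(runif(n) < frac_erosional, "erosional", "gradual")
  region <- vapply(curves, function(cv) cv$site_id, "")[which_curve]
  k <- match(region, unique(region))
  points <- data.frame(
    point_id = sprintf("SYN-%05d", seq_len(n)),
    region_id = region,
    lat = 50 + 0.15 * k + rnorm(n, 0, 0.02),
    lon = -5 + 0.1 * k + rnorm(n, 0, 0.02),
    age = age, tendency = tendency, contact = contact,
    rate_true = rate, p_true = p, y_true = y,
    stringsAsFactors = FALSE)
  new_index_point_db(points, source = "synthetic")
}

#' Scenario parameters for synthetic projection ensembles
#'
#' A stylized two-term projection model: deterministic background land motion
#' plus a stochastic climate term with linear and quadratic (accelerating)
#' components, calibrated so the 5th--95th percentile of the rise at 2100
#' matches a target range.
#'
#' @param target_rise_cm length-2 vector, the 5th and 95th percentile of the
#'   2000--2100 rise in cm (default `c(23, 123)`, the high-emission Thames
#'   estuary benchmark).
#' @param background_rate deterministic land-motion rate, mm/yr (positive =
#'   relative rise; default 0).
#' @param accel_frac share of the climate-term variance (and mean) carried by
#'   the quadratic component, in \[0, 1) (default 0.6).
#' @param n_samples Monte Carlo sample count (default 1000).
#' @param years decadal calendar-year grid (default 2000--2300).
#' @param scenario scenario label.
#' @param site_id site identifier.
#' @param seed RNG seed (mandatory).
#' @param constant_rate_mm if set, a zero-variance ensemble rising at exactly
#'   this rate (mm/yr); all stochastic parameters are ignored.
#' @return a `scenario_params` list.
#' @export
scenario_params <- function(target_rise_cm = c(23, 123), background_rate = 0,
                            accel_frac = 0.6, n_samples = 1000,
                            years = seq(2000, 2300, by = 10),
                            scenario = "RCP8.5", site_id = "SYN-SITE",
                            seed = 1, constant_rate_mm = NULL) {
  if (is.null(seed)) stop("seed is mandatory for ensemble generation")
  if (is.null(constant_rate_mm)) {
    if (length(target_rise_cm) != 2 || target_rise_cm[1] >= target_rise_cm[2])
      stop("target_rise_cm must be an increasing (5%, 95%) pair")
    if (accel_frac < 0 || accel_frac >= 1) stop("accel_frac must be in [0, 1)")
  }
  structure(list(target_rise_cm = target_rise_cm,
                 background_rate = background_rate, accel_frac = accel_frac,
                 n_samples = n_samples, years = years, scenario = scenario,
                 site_id = site_id, seed = seed,
                 constant_rate_mm = constant_rate_mm),
            class = "scenario_params")
}

#' Generate a synthetic projection ensemble
#'
#' Each sample's trajectory is `background + a * u + b * u^2` (u = centuries
#' since 2000, values in cm), with `a` and `b` drawn Normal so that the rise
#' at 2100 has the target 5th--95th percentile range. The realized range is
#' verified against the target; a mismatch beyond 10% of the target width is
#' a calibration error.
#'
#' @param params a [scenario_params()].
#' @return a [projection_ensemble()] with a `realized_2100_range` attribute.
#' @export
gen_projection_ensemble <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  years <- params$years
  u <- (years - years[1]) / 100
  bg_cm <- params$background_rate * (years - years[1]) / 10
  if (!is.null(params$constant_rate_mm)) {
    traj <- params$constant_rate_mm * (years - years[1]) / 10
    samples <- matrix(rep(traj, params$n_samples),
                      nrow = params$n_samples, byrow = TRUE)
    return(projection_ensemble(params$site_id, params$scenario, years, samples))
  }
  set.seed(params$seed)
  q5 <- params$target_rise_cm[1]; q95 <- params$target_rise_cm[2]
  mu <- (q5 + q95) / 2 - params$background_rate * 10
  sd_tot <- (q95 - q5) / 2 / qnorm(0.95)
  f <- params$accel_frac
  a <- rnorm(params$n_samples, (1 - f) * mu, sd_tot * sqrt(1 - f))
  b <- rnorm(params$n_samples, f * mu, sd_tot * sqrt(f))
  samples <- outer(a, u) + outer(b, u^2) +
    matrix(bg_cm, params$n_samples, length(years), byrow = TRUE)
  at2100 <- samples[, which(u == 1)]
  realized <- quantile(at2100, c(0.05, 0.95), names = FALSE)
  # 10% of the target width, widened by the Monte Carlo error of a sample
  # quantile at this sample count (asymptotic normal-quantile variance)
  se_q <- sd_tot * sqrt(0.05 * 0.95 / params$n_samples) /
    dnorm(qnorm(0.95))
  tol <- 0.1 * (q95 - q5) + 3 * se_q
  if (abs(realized[1] - q5) > tol || abs(realized[2] - q95) > tol)
    stop(sprintf(
      "ensemble calibration failed: realized 5-95%% range [%.1f, %.1f] cm vs target [%g, %g]",
      realized[1], realized[2], q5, q95))
  ens <- projection_ensemble(params$site_id, params$scenario, years, samples)
  attr(ens, "realized_2100_range") <- realized
  ens
}

#' @importFrom stats qnorm dnorm sd
NULL
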