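#' Construct a sea-level projection ensemble
#'
#' Monte Carlo samples of future relative sea level at one site under one
#' emission scenario, on a decadal calendar-year grid, in cm relative to the
#' year-2000 baseline.
#'
#' @param site_id site identifier.
#' @param scenario scenario label, e.g. `"RCP8.5"`.
#' @param years strictly increasing calendar years CE with a constant 10-yr
#'   step.
#' @param samples numeric matrix, one row per Monte Carlo sample, one column
#'   per year; RSL in cm relative to 2000.
#' @return a `projection_ensemble`.
#' @export
projection_ensemble <- function(site_id, scenario, years, samples) {
  years <- as.numeric(years)
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (ncol(samples) != length(years))
    stop("samples must have one column per year")
  if (length(years) < 2 || any(diff(years) != 10))
    stop("years must be a decadal grid with constant 10-yr step")
  structure(list(site_id = as.character(site_id),
                 scenario = as.character(scenario),
                 years = years, samples = samples,
                 n_samples = nrow(samples)),
            class = "projection_ensemble")
}

#' @export
print.projection_ensemble <- function(x, ...) {
  cat(sprintf("projection_ensemble '%s' (%s): %d samples, %g-%g CE\n",
              x$site_id, x$scenario, x$n_samples,
              min(x$years), max(x$years)))
  invisible(x)
}

#' Trailing 20-year average rates of sea-level rise
#'
#' For each year `t` on the decadal grid with `t - 20` also on the grid, the
#' average rate over the preceding 20 years: `(RSL(t) - RSL(t - 20)) / 20`,
#' converted from cm to mm/yr. The first two decades carry no value.
#'
#' @param sample one RSL trajectory in cm, parallel to `years`.
#' @param years decadal calendar-year grid.
#' @return named vector of rates in mm/yr for `years[-(1:2)]`.
#' @export
twenty_year_rates <- function(sample, years) {
  years <- as.numeric(years)
  if (length(years) < 3) stop("need at least 3 decadal points")
  if (any(diff(years) != 10)) stop("years must be a decadal (10-yr step) grid")
  if (length(sample) != length(years)) stop("sample not parallel to years")
  idx <- 3:length(years)
  rates <- (sample[idx] - sample[idx - 2]) / 20 * 10   # cm over 20 yr -> mm/yr
  names(rates) <- years[idx]
  rates
}

#' Running maximum of a series
#'
#' `out[i] = max(series[1..i])`. Applied to 20-year rates it gives the
#' fastest sustained rise a marsh has experienced up to each year, the
#' quantity the retreat probability is conditioned on.
#'
#' @param series numeric vector.
#' @return vector of prefix maxima.
#' @export
cumulative_max <- function(series) {
  if (length(series) == 0) stop("series must be non-empty")
  cummax(series)
}

#' Retreat-probability timeline for a projection ensemble
#'
#' For every Monte Carlo sample: trailing 20-year rates, their running
#' maximum, then the posterior-mean retreat probability at that running
#' maximum (flat beyond the fitted support). The timeline is the arithmetic
#' mean of these probabilities across samples, and the threshold year is the
#' first year whose probability strictly exceeds the threshold.
#'
#' @param post_curve a [probability_curve()].
#' @param ens a [projection_ensemble()].
#' @param threshold probability threshold, default 0.8.
#' @return a `retreat_timeline`: list with `years` (evaluable years),
#'   `probability`, `threshold`, `threshold_year` (`NA` when never exceeded).
#' @export
retreat_timeline <- function(post_curve, ens, threshold = 0.8) {
  stopifnot(inherits(post_curve, "probability_curve"),
            inherits(ens, "projection_ensemble"))
  if (ens$n_samples == 0) stop("ensemble has no samples")
  years <- ens$years[-(1:2)]
  probs <- matrix(NA_real_, ens$n_samples, length(years))
  for (s in seq_len(ens$n_samples)) {
    r <- twenty_year_rates(ens$samples[s, ], ens$years)
    probs[s, ] <- curve_lookup(post_curve, cumulative_max(r))
  }
  p <- colMeans(probs)
  cross <- which(p > threshold)
  structure(list(site_id = ens$site_id, scenario = ens$scenario,
                 years = years, probability = p, threshold = threshold,
                 threshold_year = if (length(cross)) years[cross[1]] else NA_real_),
            class = "retreat_timeline")
}

#' @export
print.retreat_timeline <- function(x, ...) {
  cat(sprintf("retreat_timeline '%s' (%s): %g-%g CE\n",
              x$site_id, x$scenario, min(x$years), max(x$years)))
  yr <- if (is.na(x$threshold_year)) "not reached" else
    sprintf("%g", x$threshold_year)
  cat(sprintf("  first year with P > %.2f: %s\n", x$threshold, yr))
  invisible(x)
}

#' Threshold-crossing years across sites and scenarios
#'
#' @param timelines list of [retreat_timeline()] objects sharing a threshold.
#' @return data frame with `site_id`, `scenario`, `threshold`, `year`
#'   (`"not reached"` kept as a distinct value; column is character).
#' @export
threshold_year_table <- function(timelines) {
  if (inherits(timelines, "retreat_timeline")) timelines <- list(timelines)
  th <- unique(vapply(timelines, function(t) t$threshold, 0))
  if (length(th) != 1)
    stop("timelines use mixed thresholds: ", paste(th, collapse = ", "))
  data.frame(
    site_id = vapply(timelines, function(t) t$site_id, ""),
    scenario = vapply(timelines, function(t) t$scenario, ""),
    threshold = th,
    year = vapply(timelines, function(t)
      if (is.na(t$threshold_year)) "not reached"
      else sprintf("%g", t$threshold_year), ""),
    stringsAsFactors = FALSE)
}

#' Read projection ensembles from a delimited file
#'
#' Expects columns `site_id,scenario,sample_id,year,rsl_cm`.
#'
#' @param path file path.
#' @return list of [projection_ensemble()] objects, one per site x scenario.
#' @export
read_projection_ensembles <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "scenario", "sample_id", "year", "rsl_cm")
  if (!all(need %in% names(raw)))
    stop("ensemble file must have columns: ", paste(need, collapse = ", "))
  groups <- split(raw, list(raw$site_id, raw$scenario), drop = TRUE)
  lapply(unname(groups), function(d) {
    years <- sort(unique(d$year))
    ids <- unique(d$sample_id)
    m <- matrix(NA_real_, length(ids), length(years))
    d <- d[order(match(d$sample_id, ids), d$year), ]
    m[cbind(match(d$sample_id, ids), match(d$year, years))] <- d$rsl_cm
    projection_ensemble(d$site_id[1], d$scenario[1], years, m)
  })
}

#' Write projection ensembles in the canonical file format
#'
#' @param ensembles list of [projection_ensemble()] objects (or one).
#' @param path output path.
#' @export
write_projection_ensembles <- function(ensembles, path) {
  if (inherits(ensembles, "projection_ensemble")) ensembles <- list(ensembles)
  rows <- do.call(rbind, lapply(ensembles, function(e) {
    data.frame(site_id = e$site_id, scenario = e$scenario,
               sample_id = rep(seq_len(e$n_samples), each = length(e$years)),
               year = rep(e$years, e$n_samples),
               rsl_cm = as.vector(t(e$samples)))
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write retreat timelines as delimited text
#'
#' Long format `site_id,scenario,year,probability`.
#'
#' @param timelines list of [retreat_timeline()] objects (or one).
#' @param path output path.
#' @export
write_timelines <- function(timelines, path) {
  if (inherits(timelines, "retreat_timeline")) timelines <- list(timelines)
  rows <- do.call(rbind, lapply(timelines, function(t)
    data.frame(site_id = t$site_id, scenario = t$scenario,
               year = t$years, probability = t$probability)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
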