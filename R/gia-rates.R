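#' Construct a relative sea-level curve
#'
#' A per-site (or per-region) series of relative sea level against age,
#' typically the output of a glacial-isostatic-adjustment model at coarse
#' (1000-yr) resolution. Values between nodes are obtained by linear
#' interpolation; no smoothing is applied.
#'
#' @param site_id site or region identifier.
#' @param t ages in cal yr BP, strictly increasing, at least 2 nodes.
#' @param rsl relative sea level in metres relative to present, parallel to `t`.
#' @param resolution native node spacing in years (metadata only).
#' @return an `rsl_curve`.
#' @export
rsl_curve <- function(site_id, t, rsl, resolution = 1000) {
  t <- as.numeric(t); rsl <- as.numeric(rsl)
  if (length(t) < 2) stop("rsl_curve needs at least 2 nodes")
  if (length(t) != length(rsl)) stop("t and rsl must be parallel")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(!is.finite(rsl)) || any(!is.finite(t)))
    stop("t and rsl must be finite")
  structure(list(site_id = as.character(site_id), t = t, rsl = rsl,
                 resolution = resolution),
            class = "rsl_curve")
}

#' @export
print.rsl_curve <- function(x, ...) {
  cat(sprintf("rsl_curve '%s': %d nodes, %g-%g cal yr BP, RSL %.2f to %.2f m\n",
              x$site_id, length(x$t), min(x$t), max(x$t),
              min(x$rsl), max(x$rsl)))
  invisible(x)
}

#' Interpolate relative sea level at an age
#'
#' Piecewise-linear interpolation between curve nodes; exact at nodes.
#' Extrapolation beyond the curve support is refused.
#'
#' @param curve an [rsl_curve()].
#' @param age age(s) in cal yr BP, each within the curve support.
#' @return RSL in metres relative to present.
#' @export
interpolate_rsl <- function(curve, age) {
  stopifnot(inherits(curve, "rsl_curve"))
  out_of_range <- age < min(curve$t) | age > max(curve$t)
  if (any(out_of_range))
    stop(sprintf("age %s outside curve support [%g, %g]",
                 paste(age[out_of_range], collapse = ", "),
                 min(curve$t), max(curve$t)))
  approx(curve$t, curve$rsl, xout = age, method = "linear")$y
}

#' Rate of relative sea-level rise at an age
#'
#' The rate assigned to an index point is the centered finite difference of
#' the interpolated curve over a window of `2 * half_width` years (default
#' 200 yr, i.e. +/-100 yr). Positive rates mean sea level rising toward the
#' present (RSL higher at younger ages).
#'
#' @param curve an [rsl_curve()].
#' @param age age(s) in cal yr BP.
#' @param half_width half the differencing window, years (default 100).
#' @return rate(s) in mm/yr.
#' @export
compute_rate <- function(curve, age, half_width = 100) {
  stopifnot(inherits(curve, "rsl_curve"), half_width > 0)
  lo <- age - half_width; hi <- age + half_width
  if (any(lo < min(curve$t)))
    stop(sprintf("rate window lower bound %g before curve support start %g",
                 min(lo), min(curve$t)))
  if (any(hi > max(curve$t)))
    stop(sprintf("rate window upper bound %g beyond curve support end %g",
                 max(hi), max(curve$t)))
  # metres per year -> mm/yr; RSL at the younger edge minus the older edge
  (interpolate_rsl(curve, lo) - interpolate_rsl(curve, hi)) /
    (2 * half_width) * 1000
}

#' Assign a rate of sea-level rise to every index point
#'
#' Looks up each point's region curve and applies [compute_rate()] at the
#' point's median calibrated age. Points whose differencing window extends
#' beyond the curve support are flagged rather than one-sided differenced.
#'
#' @param db an `index_point_db`.
#' @param curves named list of [rsl_curve()] objects, names = region ids
#'   (a single unnamed curve is applied to all points).
#' @param half_width rate window half-width, years.
#' @return data frame with `point_id`, `rate` (mm/yr, `NA` where the window
#'   leaves the curve support), `in_support` flag; rows in database order.
#' @export
assign_rates <- function(db, curves, half_width = 100) {
  stopifnot(inherits(db, "index_point_db"))
  if (inherits(curves, "rsl_curve")) curves <- list(curves)
  pts <- db$points
  if (nrow(pts) == 0)
    return(data.frame(point_id = character(), rate = numeric(),
                      in_support = logical()))
  if (is.null(names(curves)) && length(curves) == 1) {
    idx <- rep(1L, nrow(pts))
  } else {
    idx <- match(pts$region_id, names(curves))
    if (any(is.na(idx)))
      stop("no RSL curve for region(s): ",
           paste(unique(pts$region_id[is.na(idx)]), collapse = ", "))
  }
  rate <- numeric(nrow(pts)); in_support <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cv <- curves[[idx[i]]]
    ok <- pts$age[i] - half_width >= min(cv$t) &&
      pts$age[i] + half_width <= max(cv$t)
    in_support[i] <- ok
    rate[i] <- if (ok) compute_rate(cv, pts$age[i], half_width) else NA_real_
  }
  data.frame(point_id = pts$point_id, rate = rate, in_support = in_support,
             stringsAsFactors = FALSE)
}

#' Read relative sea-level curves from a delimited file
#'
#' Expects columns `site_id,age_cal_bp,rsl_m`; multiple sites per file are
#' allowed, rows grouped per site.
#'
#' @param path file path.
#' @param resolution native node spacing metadata, years.
#' @return named list of [rsl_curve()] objects.
#' @export
read_rsl_curves <- function(path, resolution = 1000) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "age_cal_bp", "rsl_m")
  if (!all(need %in% names(raw)))
    stop("curve file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(raw, raw$site_id), function(d) {
    d <- d[order(d$age_cal_bp), ]
    rsl_curve(d$site_id[1], d$age_cal_bp, d$rsl_m, resolution)
  })
  out
}

#' Write relative sea-level curves in the canonical file format
#'
#' @param curves list of [rsl_curve()] objects.
#' @param path output path.
#' @export
write_rsl_curves <- function(curves, path) {
  if (inherits(curves, "rsl_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv)
    data.frame(site_id = cv$site_id, age_cal_bp = cv$t, rsl_m = cv$rsl)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
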