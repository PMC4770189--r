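#' Interval relative growth rate on the thermal-time axis
#'
#' Classical growth analysis computes the mean relative rate over an
#' interval as the difference of natural-log sizes divided by the elapsed
#' thermal time: (ln x2 - ln x1) / (g2 - g1). Called RER when the size is
#' a length and RGR when it is a dry mass. Invariant under a common
#' rescaling of the sizes, so the unit of measurement cancels.
#'
#' @param x1,x2 sizes at the interval start and end (positive; any common
#'   unit).
#' @param g1,g2 cumulative GDD at the interval start and end (`g2 > g1`).
#' @return relative rate per degree-day (vectorised).
#' @export
interval_relative_rate <- function(x1, x2, g1, g2) {
  if (any(x1 <= 0) || any(x2 <= 0)) stop("sizes must be positive")
  if (any(g2 <= g1)) stop("interval must have positive thermal-time width")
  (log(x2) - log(x1)) / (g2 - g1)
}

#' Interval rate series for one organ trajectory
#'
#' One rate per successive observation pair, assigned to the interval's
#' GDD midpoint. Lengths give RER, dry masses RGR. Negative rates are
#' retained (fruit dry weight can decline near harvest).
#'
#' @param traj data.frame with a `gdd` column (strictly increasing) and the
#'   requested size column.
#' @param variable which size to differentiate: `"length"` (column
#'   `length_cm`) or `"dry_mass"` (column `dry_mass_g`). A bare `length` /
#'   `dry_mass` column is also accepted.
#' @return data.frame of class `growth_rate_series` with columns
#'   `gdd_mid`, `rate`, `gdd_start`, `gdd_end`; attribute `rate_kind` is
#'   `"RER"` or `"RGR"`. Fewer than two usable observations yield an empty
#'   series with a warning.
#' @export
trajectory_rates <- function(traj, variable = c("length", "dry_mass")) {
  variable <- match.arg(variable)
  col <- switch(variable, length = intersect(c("length_cm", "length"), names(traj))[1],
                dry_mass = intersect(c("dry_mass_g", "dry_mass"), names(traj))[1])
  if (is.na(col)) stop("trajectory has no '", variable, "' column")
  keep <- !is.na(traj[[col]]) & !is.na(traj$gdd)
  g <- traj$gdd[keep]
  x <- traj[[col]][keep]
  kind <- if (variable == "length") "RER" else "RGR"
  if (length(g) < 2L) {
    warning("fewer than two usable observations; empty rate series")
    out <- data.frame(gdd_mid = numeric(0), rate = numeric(0),
                      gdd_start = numeric(0), gdd_end = numeric(0))
    attr(out, "rate_kind") <- kind
    class(out) <- c("growth_rate_series", "data.frame")
    return(out)
  }
  if (is.unsorted(g, strictly = TRUE)) stop("gdd must be strictly increasing")
  n <- length(g)
  out <- data.frame(
    gdd_mid = (g[-n] + g[-1L]) / 2,
    rate = interval_relative_rate(x[-n], x[-1L], g[-n], g[-1L]),
    gdd_start = g[-n], gdd_end = g[-1L])
  attr(out, "rate_kind") <- kind
  class(out) <- c("growth_rate_series", "data.frame")
  out
}

#' Mean and SD of rate series across organs
#'
#' Averages a set of rate series interval by interval. All series must
#' share the measurement schedule: interval midpoints are matched by index
#' and must agree within `tol` degree-days.
#'
#' @param series_list list of `growth_rate_series` (equal length).
#' @param tol maximum allowed spread of matched interval midpoints
#'   (degree-days, default 1e-6; raise for field schedules where organs
#'   were measured on slightly different dates).
#' @return data.frame with `gdd_mid`, `mean_rate`, `sd_rate`, `n`.
#' @export
mean_rate_curve <- function(series_list, tol = 1e-6) {
  series_list <- Filter(function(s) nrow(s) > 0L, series_list)
  if (length(series_list) == 0L) {
    warning("no non-empty rate series")
    return(data.frame(gdd_mid = numeric(0), mean_rate = numeric(0),
                      sd_rate = numeric(0), n = integer(0)))
  }
  len <- vapply(series_list, nrow, integer(1))
  if (length(unique(len)) > 1L)
    stop("rate series have different numbers of intervals: ",
         paste(unique(len), collapse = ", "))
  mids <- vapply(series_list, function(s) s$gdd_mid, numeric(len[1L]))
  mids <- matrix(mids, nrow = len[1L])
  spread <- apply(mids, 1L, function(v) diff(range(v)))
  if (any(spread > tol))
    stop("misaligned measurement schedules at interval(s) ",
         paste(which(spread > tol), collapse = ", "),
         " (midpoint spread up to ", signif(max(spread), 3), " GDD)")
  rates <- matrix(vapply(series_list, function(s) s$rate, numeric(len[1L])),
                  nrow = len[1L])
  data.frame(gdd_mid = rowMeans(mids),
             mean_rate = rowMeans(rates),
             sd_rate = if (length(series_list) == 1L) rep(0, len[1L])
                       else apply(rates, 1L, stats::sd),
             n = rep(length(series_list), len[1L]))
}

#' Log-linear RGR fit for woody biomass
#'
#' Fits an ordinary least-squares line through ln(biomass) vs cumulative
#' GDD; the slope is the relative growth rate of the above-ground woody
#' biomass over the fitted window.
#'
#' @param gdd cumulative GDD values (at least two distinct).
#' @param biomass_g biomass (g, positive), or set `log_biomass` instead.
#' @param log_biomass optional pre-logged biomass (overrides `biomass_g`).
#' @return list of class `log_linear_fit`: `slope` (RGR per degree-day),
#'   `intercept` (ln g), `r_squared`, `n_points`.
#' @export
fit_log_linear_rgr <- function(gdd, biomass_g = NULL, log_biomass = NULL) {
  if (is.null(log_biomass)) {
    if (any(biomass_g <= 0)) stop("biomass must be positive")
    log_biomass <- log(biomass_g)
  }
  keep <- !is.na(gdd) & !is.na(log_biomass)
  gdd <- gdd[keep]; log_biomass <- log_biomass[keep]
  if (length(unique(gdd)) < 2L) stop("need at least two distinct GDD values")
  fit <- stats::lm(log_biomass ~ gdd)
  # noiseless exponential growth gives a perfect fit; silence summary.lm
  r2 <- if (stats::var(log_biomass) == 0) 1
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_points = length(gdd)),
            class = "log_linear_fit")
}

#' @export
print.log_linear_fit <- function(x, ...) {
  cat(sprintf("log-linear RGR fit: slope %.5g per degree-day (r2 = %.3f, n = %d)\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Normalize a trunk circumference trajectory to its first observation
#'
#' @param traj data.frame with `gdd` and `circumference_mm` columns.
#' @return data.frame `gdd`, `normalized` (first value exactly 1) and
#'   `relative_increment` (`normalized - 1`).
#' @export
normalized_circumference <- function(traj) {
  if (!"circumference_mm" %in% names(traj))
    stop("trajectory has no 'circumference_mm' column")
  keep <- !is.na(traj$circumference_mm)
  if (!any(keep)) stop("no circumference observations")
  g <- traj$gdd[keep]; circ <- traj$circumference_mm[keep]
  if (any(circ <= 0)) stop("circumferences must be positive")
  data.frame(gdd = g, normalized = circ / circ[1L],
             relative_increment = circ / circ[1L] - 1)
}

#' Detect sustained cessation of shoot elongation
#'
#' Shoot elongation is considered ceased from the first interval at which
#' the RER drops below `threshold` and stays below it for every remaining
#' interval; a single dip followed by a rebound does not count.
#'
#' @param series a `growth_rate_series` with `rate_kind = "RER"`.
#' @param threshold RER threshold per degree-day (default 1e-2).
#' @return the GDD midpoint at cessation onset, or `NA` if elongation
#'   never ceases (or the series is empty, with a warning).
#' @export
detect_elongation_cessation <- function(series, threshold = 1e-2) {
  if (!is.null(attr(series, "rate_kind")) && attr(series, "rate_kind") != "RER")
    stop("cessation detection applies to RER series")
  if (nrow(series) == 0L) {
    warning("empty rate series")
    return(NA_real_)
  }
  below <- series$rate < threshold
  sustained <- rev(cumprod(rev(below))) == 1
  if (!any(sustained)) return(NA_real_)
  series$gdd_mid[which.max(sustained)]
}
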