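#' Aggregate sub-hourly temperature records to hourly means
#'
#' Weather stations in orchard studies typically log every 10--30 minutes;
#' degree-day accumulation is defined on hourly mean temperatures, so
#' sub-hourly records are averaged within each clock hour first.
#'
#' @param weather data.frame with columns `timestamp` (POSIXct or ISO 8601
#'   character) and `temp_c` (air temperature, degrees C).
#' @return data.frame with one row per hour present in the input:
#'   `timestamp` (hour start, POSIXct, UTC) and `temp_c` (hourly mean).
#'   Hours with no record are simply absent; downstream daily aggregation
#'   decides whether enough hours survive.
#' @export
hourly_means <- function(weather) {
  weather <- validate_weather(weather)
  hour <- as.POSIXct(trunc(weather$timestamp, units = "hours"))
  agg <- stats::aggregate(weather$temp_c, by = list(hour = hour), FUN = mean)
  out <- data.frame(timestamp = agg$hour, temp_c = agg$x)
  out[order(out$timestamp), , drop = FALSE]
}

validate_weather <- function(weather) {
  if (!is.data.frame(weather) || !all(c("timestamp", "temp_c") %in% names(weather)))
    stop("weather must be a data.frame with columns 'timestamp' and 'temp_c'")
  if (nrow(weather) == 0L) stop("empty temperature series")
  if (is.character(weather$timestamp) || is.factor(weather$timestamp))
    weather$timestamp <- as.POSIXct(as.character(weather$timestamp), tz = "UTC",
                                    tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                   "%Y-%m-%d %H:%M:%S",
                                                   "%Y-%m-%d %H:%M",
                                                   "%Y-%m-%d"))
  if (anyNA(weather$timestamp)) stop("unparseable timestamps in weather series")
  if (!all(is.finite(weather$temp_c))) stop("non-finite temperatures in weather series")
  if (is.unsorted(weather$timestamp, strictly = FALSE))
    weather <- weather[order(weather$timestamp), , drop = FALSE]
  if (anyDuplicated(weather$timestamp))
    stop("duplicated timestamps in weather series")
  weather
}

#' Daily growing degree days from hourly temperatures
#'
#' Each hourly value is clamped (default) into `[base_temp, upper_cutoff]`;
#' the day's GDD is the mean of the clamped values minus `base_temp`, hence
#' bounded in `[0, upper_cutoff - base_temp]`. With
#' `cutoff_mode = "discard"` out-of-range hours are dropped instead of
#' saturated (not recommended: discarding biases cold days upward).
#'
#' @param hourly_temps numeric vector of hourly mean temperatures for one
#'   day (degrees C); `NA` marks missing hours.
#' @param base_temp base temperature, degrees C (default 4.5).
#' @param upper_cutoff upper cutoff, degrees C (default 35).
#' @param cutoff_mode `"clamp"` (default) or `"discard"`.
#' @param min_hours minimum non-missing hours required (default 18).
#' @param date optional label used in error messages.
#' @return daily GDD in degree-days (a single non-negative number).
#' @export
daily_gdd <- function(hourly_temps, base_temp = 4.5, upper_cutoff = 35,
                      cutoff_mode = c("clamp", "discard"), min_hours = 18L,
                      date = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  stopifnot(base_temp < upper_cutoff)
  x <- hourly_temps[!is.na(hourly_temps)]
  lab <- if (is.null(date)) "" else paste0(" on ", date)
  if (length(x) == 0L) stop("no hourly temperatures available", lab)
  if (length(hourly_temps) >= 24L && length(x) < min_hours)
    stop(sprintf("only %d of %d hours present%s (need >= %d)",
                 length(x), length(hourly_temps), lab, min_hours))
  if (cutoff_mode == "clamp") {
    x <- pmin(pmax(x, base_temp), upper_cutoff)
  } else {
    inside <- x >= base_temp & x <= upper_cutoff
    if (!any(inside)) return(0)
    x <- x[inside]
  }
  mean(x) - base_temp
}

#' Accumulate growing degree days from full bloom
#'
#' Builds the thermal-time axis used by all downstream growth analysis:
#' daily GDD for every day covered by the weather series and cumulative GDD
#' starting at the full-bloom date (days before bloom contribute zero).
#' Daily GDD is credited at the end of its day, so a measurement taken on
#' day d maps to the cumulative sum through d.
#'
#' @param weather data.frame of temperature records (sub-hourly accepted;
#'   aggregated with [hourly_means()] first).
#' @param bloom_date full-bloom date (`Date` or `"YYYY-MM-DD"`).
#' @inheritParams daily_gdd
#' @return object of class `thermal_time_axis`: data.frame with columns
#'   `date`, `daily_gdd`, `cumulative_gdd` and attributes `bloom_date`,
#'   `base_temp`, `upper_cutoff`.
#' @export
accumulate_gdd <- function(weather, bloom_date, base_temp = 4.5,
                           upper_cutoff = 35,
                           cutoff_mode = c("clamp", "discard"),
                           min_hours = 18L) {
  cutoff_mode <- match.arg(cutoff_mode)
  bloom_date <- as.Date(bloom_date)
  hw <- hourly_means(weather)
  day <- as.Date(hw$timestamp, tz = "UTC")
  days <- sort(unique(day))
  if (bloom_date < days[1L] || bloom_date > days[length(days)])
    stop(sprintf("bloom date %s outside weather coverage (%s to %s)",
                 bloom_date, days[1L], days[length(days)]))
  dg <- vapply(seq_along(days), function(i) {
    daily_gdd(hw$temp_c[day == days[i]], base_temp, upper_cutoff,
              cutoff_mode, min_hours, date = days[i])
  }, numeric(1))
  contrib <- ifelse(days >= bloom_date, dg, 0)
  out <- data.frame(date = days, daily_gdd = dg,
                    cumulative_gdd = cumsum(contrib))
  attr(out, "bloom_date") <- bloom_date
  attr(out, "base_temp") <- base_temp
  attr(out, "upper_cutoff") <- upper_cutoff
  class(out) <- c("thermal_time_axis", "data.frame")
  out
}

#' Cumulative GDD at the end of a calendar day
#'
#' @param axis a `thermal_time_axis` from [accumulate_gdd()].
#' @param date one or more dates (`Date` or `"YYYY-MM-DD"`).
#' @return cumulative GDD (degree-days) at the end of each requested day.
#' @export
gdd_at <- function(axis, date) {
  stopifnot(inherits(axis, "thermal_time_axis"))
  date <- as.Date(date)
  idx <- match(date, axis$date)
  if (anyNA(idx))
    stop("date(s) outside thermal-time axis: ",
         paste(format(date[is.na(idx)]), collapse = ", "))
  axis$cumulative_gdd[idx]
}
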