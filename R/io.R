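#' Run configuration for the growth-analysis pipeline
#'
#' Collects the tunable constants in one place. Defaults are the study
#' values: GDD base 4.5 C with a 35 C upper cutoff (hourly values clamped
#' into range), spur threshold 4 cm (strict), five Max shoots per class,
#' significance stars at 0.001 / 0.01 / 0.05 on Bonferroni-adjusted
#' p-values, and one-sided alternatives "defruited shoot RER greater than
#' fruited" and "thinned fruit RGR greater than fruited".
#'
#' @param base_temp GDD base temperature, degrees C.
#' @param upper_cutoff GDD upper cutoff, degrees C.
#' @param cutoff_mode `"clamp"` or `"discard"` out-of-range hours.
#' @param min_final_length spur threshold, cm.
#' @param k_max_shoots shoots per class in the Max selection.
#' @param star_thresholds cuts for `***`, `**`, `*`.
#' @param shoot_alternative,fruit_alternative one-sided direction of the
#'   treatment comparisons (first-named group relative to control).
#' @param shoot_family,fruit_family dry-weight model family per organ,
#'   `"gaussian"` (identity link) or `"gamma"` (log link). The shoot
#'   default is gaussian (the calibration relation is close to linear in
#'   the chosen terms); the fruit default is gamma-log, which keeps
#'   predictions strictly positive across the three-orders-of-magnitude
#'   seasonal mass range.
#' @param schedule_tol GDD tolerance when aligning measurement schedules.
#' @return list of class `run_config`.
#' @export
run_config <- function(base_temp = 4.5, upper_cutoff = 35,
                       cutoff_mode = "clamp", min_final_length = 4,
                       k_max_shoots = 5L,
                       star_thresholds = c(0.001, 0.01, 0.05),
                       shoot_alternative = "greater",
                       fruit_alternative = "greater",
                       shoot_family = "gaussian", fruit_family = "gamma",
                       schedule_tol = 1e-6) {
  structure(list(base_temp = base_temp, upper_cutoff = upper_cutoff,
                 cutoff_mode = cutoff_mode,
                 min_final_length = min_final_length,
                 k_max_shoots = as.integer(k_max_shoots),
                 star_thresholds = star_thresholds,
                 shoot_alternative = shoot_alternative,
                 fruit_alternative = fruit_alternative,
                 shoot_family = shoot_family, fruit_family = fruit_family,
                 schedule_tol = schedule_tol),
            class = "run_config")
}

measurement_columns <- c(
  "organ_id", "tree_id", "treatment", "organ_type", "shoot_class_hint",
  "canopy_level", "pruning_trace", "pest_damaged", "date", "length_cm",
  "basal_diam_mm", "d1_mm", "d2_mm", "d3_mm", "circumference_mm",
  "dry_mass_g")

#' Read and validate a long-format measurement table
#'
#' The schema carries one row per organ and measurement date, with the
#' size columns appropriate to the organ type (shoot length, fruit
#' orthogonal diameters, trunk circumference). Validation checks column
#' presence, treatment labels, date parseability, per-organ-date
#' uniqueness, and that each row carries at least one size field.
#'
#' @param path CSV file, or a data.frame to validate in place.
#' @return validated data.frame with `date` as `Date`.
#' @export
read_measurements <- function(path) {
  tab <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(measurement_columns, "gdd"), names(tab))
  if (length(missing_cols))
    stop("measurement table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$date <- as.Date(tab$date)
  if (anyNA(tab$date)) {
    bad <- which(is.na(tab$date))
    stop("unparseable date(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad_trt <- setdiff(unique(tab$treatment), c("FRU", "DEF", "THI"))
  if (length(bad_trt))
    stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "))
  key <- paste(tab$organ_id, tab$date)
  if (anyDuplicated(key))
    stop("duplicated (organ_id, date) pair(s), e.g. ",
         key[anyDuplicated(key)])
  size_cols <- c("length_cm", "d1_mm", "d2_mm", "d3_mm", "circumference_mm",
                 "dry_mass_g")
  has_size <- rowSums(!is.na(tab[size_cols])) > 0
  if (!all(has_size))
    stop("row(s) without any size measurement: ",
         paste(utils::head(which(!has_size), 5L), collapse = ", "))
  tab
}

#' Read an hourly weather CSV
#'
#' @param path CSV with columns `timestamp` (ISO 8601) and `temp_c`.
#' @return validated data.frame (see [hourly_means()] for aggregation).
#' @export
read_weather <- function(path) {
  validate_weather(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write measurement / weather tables to CSV
#'
#' Plain `write.csv` without row names, so write-then-read is the
#' identity for the standard schemas.
#'
#' @param tab data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path) {
  if ("timestamp" %in% names(tab))
    tab$timestamp <- format(tab$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
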