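#' Per-organ rate series from a long measurement table
#'
#' Splits a long table by organ and computes the interval rate series for
#' the requested variable, preserving organ order.
#'
#' @param tab long data.frame with `organ_id`, `gdd` and the size column.
#' @param variable `"length"` or `"dry_mass"`.
#' @return named list of `growth_rate_series`.
#' @export
rate_series_by_organ <- function(tab, variable = c("length", "dry_mass")) {
  variable <- match.arg(variable)
  lapply(split(tab, factor(tab$organ_id, levels = unique(tab$organ_id))),
         trajectory_rates, variable = variable)
}

organ_final <- function(tab, col) {
  vapply(split(tab, tab$organ_id), function(d) {
    d <- d[!is.na(d[[col]]), , drop = FALSE]
    if (nrow(d) == 0L) return(NA_real_)
    d[[col]][which.max(d$gdd)]
  }, numeric(1))
}

#' Run the full growth-analysis pipeline
#'
#' Chains every stage on validated input tables: thermal-time axis;
#' calibration of the shoot and fruit dry-weight models; spur filtering
#' and shoot classification; organ rate series (shoot RER and RGR, fruit
#' RGR, trunk woody-biomass RGR); per-date treatment comparisons with
#' Bonferroni correction; the maximum-potential extraction (top-k shoots
#' per class from the defruited population, the Max trunk tree, the
#' thinned-fruit mean curve and its variability diagnostics); and the
#' trunk treatment-and-GDD linear model with per-treatment log-linear RGR
#' fits. Counts after every filtering step are reported with `message()`.
#'
#' @param measurements long measurement table ([read_measurements()]
#'   schema; a path or data.frame).
#' @param weather hourly weather table (path or data.frame).
#' @param bloom_date full-bloom date.
#' @param calibration destructive calibration table (shoots and fruits
#'   with oven-dry masses; see [fit_dry_weight_model()]).
#' @param config a [run_config()].
#' @return list of class `growth_report` with elements `axis`, `models`,
#'   `shoots` (series, mean curves, cessation, comparison), `fruits`
#'   (series, mean curves, comparison, potential, variability), `trunk`
#'   (normalized trajectories, treatment model, RGR fits, max tree), and
#'   `max_shoots`.
#' @export
run_report <- function(measurements, weather, bloom_date, calibration,
                       config = run_config()) {
  meas <- read_measurements(measurements)
  weather <- if (is.data.frame(weather)) validate_weather(weather)
             else read_weather(weather)
  axis <- accumulate_gdd(weather, bloom_date,
                         base_temp = config$base_temp,
                         upper_cutoff = config$upper_cutoff,
                         cutoff_mode = config$cutoff_mode)
  meas$gdd <- gdd_at(axis, meas$date)

  ## calibration models (shoot model fitted on FRU samples only; applied
  ## to DEF shoots as a lower-bound estimate)
  cal_shoot <- calibration[calibration$organ_type == "shoot" &
                             calibration$treatment == "FRU", , drop = FALSE]
  cal_fruit <- calibration[calibration$organ_type == "fruit", , drop = FALSE]
  shoot_model <- fit_dry_weight_model(cal_shoot, organ = "shoot",
                                      family = config$shoot_family)
  fruit_model <- fit_dry_weight_model(cal_fruit, organ = "fruit",
                                      family = config$fruit_family)

  ## ---- shoots ----
  shoots <- meas[meas$organ_type == "shoot", , drop = FALSE]
  shoots <- filter_spurs(shoots, config$min_final_length)
  pred <- predict_dry_weight(shoot_model, shoots)
  shoots$dry_mass_g <- pmax(pred, 1e-3)
  if (any(pred <= 0))
    message(sum(pred <= 0), " shoot mass prediction(s) at or below zero ",
            "floored to 1 mg (smallest shoots early in the season)")
  rer <- rate_series_by_organ(shoots, "length")
  rgr_sh <- rate_series_by_organ(shoots, "dry_mass")
  by_trt <- function(series, tab) split(series, tab$treatment[match(names(series), tab$organ_id)])
  shoot_idx <- shoots[!duplicated(shoots$organ_id), ]
  rer_trt <- by_trt(rer, shoot_idx)
  rgr_sh_trt <- by_trt(rgr_sh, shoot_idx)
  shoot_cmp <- compare_series(rer_trt$DEF, rer_trt$FRU,
                              test_kind = "mann_whitney",
                              alternative = config$shoot_alternative,
                              tol = config$schedule_tol)
  shoot_mean <- lapply(rer_trt, mean_rate_curve, tol = config$schedule_tol)
  shoot_rgr_mean <- lapply(rgr_sh_trt, mean_rate_curve, tol = config$schedule_tol)
  cessation <- vapply(shoot_mean, function(cv) {
    s <- cv; names(s)[names(s) == "mean_rate"] <- "rate"
    attr(s, "rate_kind") <- "RER"
    detect_elongation_cessation(s)
  }, numeric(1))

  ## ---- max shoots (defruited population only: pruning traces were
  ##      recorded there) ----
  def_shoots <- shoots[shoots$treatment == "DEF", , drop = FALSE]
  def_idx <- def_shoots[!duplicated(def_shoots$organ_id), ]
  summary_df <- data.frame(
    organ_id = def_idx$organ_id,
    shoot_class = classify_shoot_type(def_idx$pruning_trace),
    final_mass_g = organ_final(def_shoots, "dry_mass_g")[def_idx$organ_id],
    final_length_cm = organ_final(def_shoots, "length_cm")[def_idx$organ_id])
  max_shoots <- select_max_shoots(summary_df, k = config$k_max_shoots)
  max_curves <- lapply(max_shoots, function(sel) {
    if (length(sel$member_ids) == 0L) return(NULL)
    list(RER = mean_rate_curve(rer[sel$member_ids], tol = config$schedule_tol),
         RGR = mean_rate_curve(rgr_sh[sel$member_ids], tol = config$schedule_tol))
  })

  ## ---- fruits ----
  fruits <- meas[meas$organ_type == "fruit", , drop = FALSE]
  n_before <- length(unique(fruits$organ_id))
  fruits <- fruits[!isTRUE_vec(fruits$pest_damaged), , drop = FALSE]
  message(sprintf("pest filter: removed %d of %d fruits",
                  n_before - length(unique(fruits$organ_id)), n_before))
  fruits$dry_mass_g <- predict_dry_weight(fruit_model, fruits)
  rgr_fr <- rate_series_by_organ(fruits, "dry_mass")
  fruit_idx <- fruits[!duplicated(fruits$organ_id), ]
  rgr_fr_trt <- by_trt(rgr_fr, fruit_idx)
  fruit_cmp <- compare_series(rgr_fr_trt$THI, rgr_fr_trt$FRU,
                              test_kind = "t_test",
                              alternative = config$fruit_alternative,
                              tol = config$schedule_tol)
  fruit_mean <- lapply(rgr_fr_trt, mean_rate_curve, tol = config$schedule_tol)
  thi <- fruits[fruits$treatment == "THI", , drop = FALSE]
  fruit_potential <- fruit_potential_curve(thi, tol = config$schedule_tol)
  fruit_var <- fruit_variability_analysis(thi)

  ## ---- trunk ----
  trunks <- meas[meas$organ_type == "trunk", , drop = FALSE]
  norm_circ <- do.call(rbind, lapply(split(trunks, trunks$tree_id), function(d) {
    d <- d[order(d$gdd), , drop = FALSE]
    nc <- normalized_circumference(d)
    cbind(tree_id = d$tree_id[1L], treatment = d$treatment[1L], nc)
  }))
  rownames(norm_circ) <- NULL
  trunk_model <- trunk_treatment_model(norm_circ)
  trunks$agb_g <- wood_agb(trunks$circumference_mm / 10)
  trunk_rgr <- lapply(split(trunks, trunks$treatment), function(d) {
    by_date <- stats::aggregate(log(d$agb_g), by = list(gdd = d$gdd), FUN = mean)
    fit_log_linear_rgr(by_date$gdd, log_biomass = by_date$x)
  })
  max_trunk <- select_max_trunk(trunks[trunks$treatment == "DEF", , drop = FALSE])

  structure(list(
    axis = axis,
    models = list(shoot = shoot_model, fruit = fruit_model),
    shoots = list(rer = rer, rgr = rgr_sh, mean_rer = shoot_mean,
                  mean_rgr = shoot_rgr_mean, comparison = shoot_cmp,
                  cessation = cessation, summary = summary_df),
    max_shoots = list(selection = max_shoots, curves = max_curves),
    fruits = list(rgr = rgr_fr, mean_rgr = fruit_mean,
                  comparison = fruit_cmp, potential = fruit_potential,
                  variability = fruit_var),
    trunk = list(normalized = norm_circ, model = trunk_model,
                 rgr = trunk_rgr, max = max_trunk),
    config = config), class = "growth_report")
}

#' Write the report bundle to a directory
#'
#' Emits the comparison tables, rate-curve means, Max selections and
#' model summaries as CSV/JSON files under `dir`.
#'
#' @param report a `growth_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "growth_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$shoots$comparison,
                   file.path(dir, "shoot_rer_comparison.csv"), row.names = FALSE)
  utils::write.csv(report$fruits$comparison,
                   file.path(dir, "fruit_rgr_comparison.csv"), row.names = FALSE)
  sel <- do.call(rbind, lapply(names(report$max_shoots$selection), function(cls) {
    s <- report$max_shoots$selection[[cls]]
    if (length(s$member_ids) == 0L) return(NULL)
    data.frame(category = cls, organ_id = s$member_ids,
               final_mass_g = s$selection_metric)
  }))
  utils::write.csv(sel, file.path(dir, "max_shoot_selection.csv"),
                   row.names = FALSE)
  trunk_tab <- data.frame(
    group = c(names(report$trunk$rgr), paste0("Max_", report$trunk$max$tree_id)),
    slope = c(vapply(report$trunk$rgr, `[[`, numeric(1), "slope"),
              report$trunk$max$rgr_fit$slope),
    r2 = c(vapply(report$trunk$rgr, `[[`, numeric(1), "r_squared"),
           report$trunk$max$rgr_fit$r_squared))
  utils::write.csv(trunk_tab, file.path(dir, "trunk_rgr.csv"), row.names = FALSE)
  fv <- report$fruits$variability
  jsonlite::write_json(
    list(harvest_vs_initial = fv$harvest_vs_initial,
         initial_vs_early_rgr = fv$initial_vs_early_rgr),
    file.path(dir, "fruit_variability.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
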