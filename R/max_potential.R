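#' Remove probable spurs from the tagged shoot population
#'
#' Shoots whose final-season length never exceeds `min_final_length` are
#' treated as spurs and dropped before growth analysis.
#'
#' @param shoots long-format measurement data.frame with columns
#'   `organ_id`, `gdd`, `length_cm`.
#' @param min_final_length retention threshold in cm (default 4, strict:
#'   a shoot is kept only if its final length is strictly greater).
#' @return the rows of `shoots` belonging to retained organs; the number
#'   of removed shoots is reported via `message()`.
#' @export
filter_spurs <- function(shoots, min_final_length = 4) {
  stopifnot(all(c("organ_id", "gdd", "length_cm") %in% names(shoots)))
  sp <- split(shoots, shoots$organ_id)
  final_len <- vapply(sp, function(d) {
    d <- d[!is.na(d$length_cm), , drop = FALSE]
    if (nrow(d) == 0L) stop("shoot ", d$organ_id[1L], " has no length observations")
    d$length_cm[which.max(d$gdd)]
  }, numeric(1))
  keep_ids <- names(final_len)[final_len > min_final_length]
  removed <- length(final_len) - length(keep_ids)
  message(sprintf("spur filter: removed %d of %d shoots (final length <= %g cm)",
                  removed, length(final_len), min_final_length))
  if (length(keep_ids) == 0L) warning("no shoots left after spur filtering")
  shoots[shoots$organ_id %in% keep_ids, , drop = FALSE]
}

#' Classify shoots as proleptic or epicormic from pruning traces
#'
#' Epicormic shoots most commonly arise after severe pruning, so shoots on
#' branches bearing pruning traces are classified as potentially epicormic
#' and all others as proleptic. A missing flag yields `"unknown"` (with a
#' warning) and excludes the shoot from maximum-potential selection.
#'
#' @param pruning_trace logical vector (NA allowed).
#' @return character vector: `"epicormic"`, `"proleptic"` or `"unknown"`.
#' @export
classify_shoot_type <- function(pruning_trace) {
  out <- ifelse(is.na(pruning_trace), "unknown",
                ifelse(pruning_trace, "epicormic", "proleptic"))
  if (any(out == "unknown"))
    warning(sum(out == "unknown"),
            " shoot(s) without pruning-trace flag classified 'unknown'")
  out
}

#' Select the top-k shoots by final dry mass per shoot class
#'
#' The maximum potential RER/RGR of each shoot class is represented by the
#' k shoots that reached the highest dry masses by the end of the season.
#' Ties on mass are broken by final length, then by organ id, so the
#' selection is deterministic.
#'
#' @param shoot_summary data.frame with one row per shoot: `organ_id`,
#'   `shoot_class` (`"proleptic"`/`"epicormic"`/`"unknown"`),
#'   `final_mass_g`, `final_length_cm`.
#' @param k number of shoots to select per class (default 5).
#' @return object of class `max_selection`: a list with one element per
#'   class (excluding `"unknown"`) holding `member_ids`,
#'   `selection_metric` (final dry mass, g) and the selected sub-table.
#' @export
select_max_shoots <- function(shoot_summary, k = 5L) {
  req <- c("organ_id", "shoot_class", "final_mass_g", "final_length_cm")
  stopifnot(all(req %in% names(shoot_summary)))
  known <- shoot_summary[shoot_summary$shoot_class %in% c("proleptic", "epicormic"), ,
                         drop = FALSE]
  out <- lapply(split(known, factor(known$shoot_class,
                                    levels = c("proleptic", "epicormic"))),
                function(d) {
    if (nrow(d) == 0L) {
      warning("empty shoot class; empty selection")
      return(list(member_ids = character(0), selection_metric = numeric(0),
                  table = d))
    }
    if (nrow(d) < k)
      warning(sprintf("class '%s' has only %d shoots (< k = %d); keeping all",
                      d$shoot_class[1L], nrow(d), k))
    ord <- order(-d$final_mass_g, -d$final_length_cm, d$organ_id)
    sel <- d[ord[seq_len(min(k, nrow(d)))], , drop = FALSE]
    list(member_ids = sel$organ_id, selection_metric = sel$final_mass_g,
         table = sel)
  })
  structure(out, class = "max_selection", k = k)
}

#' Select the maximum-growth tree from trunk trajectories
#'
#' The Max tree is the one with the highest increment in normalized trunk
#' circumference over the season. Its woody-biomass RGR (the slope of the
#' log-linear fit of the wood allometry applied to its circumference
#' record) is attached.
#'
#' @param trunks long-format data.frame with `tree_id`, `gdd`,
#'   `circumference_mm` (>= 2 observations per tree).
#' @param a,b wood allometry coefficients passed to [wood_agb()].
#' @return list: `tree_id`, `final_increment`, `rgr_fit`
#'   (a `log_linear_fit`), and `increments` (per-tree final normalized
#'   increments).
#' @export
select_max_trunk <- function(trunks, a = 202.9379, b = 1.6115) {
  stopifnot(all(c("tree_id", "gdd", "circumference_mm") %in% names(trunks)))
  sp <- split(trunks, trunks$tree_id)
  sp <- Filter(function(d) sum(!is.na(d$circumference_mm)) >= 2L, sp)
  if (length(sp) == 0L) stop("no tree with >= 2 circumference observations")
  incr <- vapply(sp, function(d) {
    nc <- normalized_circumference(d[order(d$gdd), , drop = FALSE])
    nc$relative_increment[nrow(nc)]
  }, numeric(1))
  best <- names(incr)[order(-incr, names(incr))][1L]
  d <- sp[[best]][order(sp[[best]]$gdd), , drop = FALSE]
  d <- d[!is.na(d$circumference_mm), , drop = FALSE]
  fit <- fit_log_linear_rgr(d$gdd, wood_agb(d$circumference_mm / 10, a = a, b = b))
  list(tree_id = best, final_increment = unname(incr[best]),
       rgr_fit = fit, increments = incr)
}

#' Mean RGR curve of thinned-tree fruits (maximum fruit potential)
#'
#' For fruit the maximum potential growth is represented by the simple
#' mean over all non-pest-damaged fruits on heavily thinned trees, rather
#' than a top-k subset: much of the within-treatment spread reflects
#' differential fruit-set timing, not resource limitation.
#'
#' @param fruits long-format data.frame with `organ_id`, `gdd`,
#'   `dry_mass_g` and optionally `pest_damaged` (damaged fruits dropped).
#' @param tol schedule-alignment tolerance passed to [mean_rate_curve()].
#' @return mean ± SD RGR curve (see [mean_rate_curve()]); empty with a
#'   warning when no undamaged fruit remains.
#' @export
fruit_potential_curve <- function(fruits, tol = 1e-6) {
  stopifnot(all(c("organ_id", "gdd", "dry_mass_g") %in% names(fruits)))
  if ("pest_damaged" %in% names(fruits))
    fruits <- fruits[!isTRUE_vec(fruits$pest_damaged), , drop = FALSE]
  if (nrow(fruits) == 0L) {
    warning("no undamaged fruits; empty potential curve")
    return(data.frame(gdd_mid = numeric(0), mean_rate = numeric(0),
                      sd_rate = numeric(0), n = integer(0)))
  }
  series <- lapply(split(fruits, fruits$organ_id), trajectory_rates,
                   variable = "dry_mass")
  mean_rate_curve(series, tol = tol)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Diagnose fruit-to-fruit variability in final dry weight
#'
#' Two ordinary least-squares regressions over the fruit cohort:
#' (A) harvest dry mass on first-date dry mass, and (B) first-date dry
#' mass on early-season RGR (the first measured interval's RGR). A
#' positive slope in A together with a negative slope in B indicates that
#' the spread in final fruit weight traces back to differential fruit-set
#' timing rather than to resource limitation.
#'
#' @param fruits long-format data.frame with `organ_id`, `gdd`,
#'   `dry_mass_g` (>= 3 fruits with >= 2 observations each); pest-damaged
#'   fruits should already be excluded.
#' @return object of class `fruit_variability_report`: lists
#'   `harvest_vs_initial` and `initial_vs_early_rgr`, each with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
fruit_variability_analysis <- function(fruits) {
  stopifnot(all(c("organ_id", "gdd", "dry_mass_g") %in% names(fruits)))
  sp <- split(fruits, fruits$organ_id)
  rows <- lapply(sp, function(d) {
    d <- d[!is.na(d$dry_mass_g), , drop = FALSE]
    d <- d[order(d$gdd), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    data.frame(initial = d$dry_mass_g[1L],
               harvest = d$dry_mass_g[nrow(d)],
               early_rgr = interval_relative_rate(d$dry_mass_g[1L], d$dry_mass_g[2L],
                                                  d$gdd[1L], d$gdd[2L]))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3L)
    stop("need >= 3 fruits with first-date and harvest masses")
  ols_report <- function(y, x) {
    if (stats::var(x) == 0) stop("degenerate (constant) predictor")
    fit <- stats::lm(y ~ x)
    s <- suppressWarnings(summary(fit))  # exact cohorts fit perfectly
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = s$r.squared,
         p_value = unname(s$coefficients[2L, 4L]),
         n = length(y))
  }
  structure(list(harvest_vs_initial = ols_report(tab$harvest, tab$initial),
                 initial_vs_early_rgr = ols_report(tab$initial, tab$early_rgr)),
            class = "fruit_variability_report")
}

#' @export
print.fruit_variability_report <- function(x, ...) {
  a <- x$harvest_vs_initial; b <- x$initial_vs_early_rgr
  cat("Fruit variability diagnostics\n")
  cat(sprintf("  harvest ~ initial mass : slope %+.3f, r2 %.3f, p %.3g (n=%d)\n",
              a$slope, a$r_squared, a$p_value, a$n))
  cat(sprintf("  initial ~ early RGR    : slope %+.3g, r2 %.3f, p %.3g (n=%d)\n",
              b$slope, b$r_squared, b$p_value, b$n))
  invisible(x)
}
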