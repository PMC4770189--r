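#' Volume of a rotational spheroid from three orthogonal diameters
#'
#' Fruit volume is approximated from three orthogonal caliper diameters as
#' an ellipsoid: V = 4/3 * pi * r1 * r2 * r3 = pi/6 * d1 * d2 * d3.
#' Symmetric in its arguments and cubic under a common rescaling.
#'
#' @param d1,d2,d3 orthogonal diameters (mm); vectors recycle as usual.
#' @return volume in mm^3.
#' @export
spheroid_volume <- function(d1, d2, d3) {
  if (any(c(d1, d2, d3) <= 0)) stop("all diameters must be positive")
  (pi / 6) * d1 * d2 * d3
}

#' Above-ground woody biomass from trunk circumference
#'
#' Power-law allometry for the dry weight of the woody structure (trunk,
#' scaffold branches; current-year shoots excluded): a * (c / pi)^b where
#' c is the trunk circumference, so c/pi is the diameter. The default
#' coefficients were established for mature apple trees on a dwarfing
#' rootstock in the orchard the law was calibrated for; circumference in
#' cm yields grams.
#'
#' @param circumference_cm trunk circumference (cm), positive.
#' @param a scaling coefficient in grams (default 202.9379).
#' @param b allometric exponent (default 1.6115).
#' @return above-ground woody dry biomass (g).
#' @export
wood_agb <- function(circumference_cm, a = 202.9379, b = 1.6115) {
  if (any(circumference_cm <= 0)) stop("circumference must be positive")
  stopifnot(a > 0, b > 0)
  a * (circumference_cm / pi)^b
}

#' Invert the wood allometry: circumference from biomass
#'
#' @param agb_g above-ground woody dry biomass (g), positive.
#' @inheritParams wood_agb
#' @return trunk circumference (cm).
#' @export
wood_circumference <- function(agb_g, a = 202.9379, b = 1.6115) {
  if (any(agb_g <= 0)) stop("biomass must be positive")
  pi * (agb_g / a)^(1 / b)
}

#' Default candidate term sets for dry-weight model selection
#'
#' For shoots the full candidate is length plus log(length) crossed with
#' GDD; for fruits log(volume) plus treatment crossed with GDD. Nested
#' reductions are included so AIC has a genuine choice. The `*` operator
#' follows model-formula convention (main effects plus interaction); set
#' `interaction_only = TRUE` to restrict the crossed term to the pure
#' product.
#'
#' @param organ `"shoot"` or `"fruit"`.
#' @param interaction_only logical; use only the product term for the
#'   crossed pair rather than expanding to main effects + interaction.
#' @return named list of one-sided formulas.
#' @export
dry_weight_candidates <- function(organ = c("shoot", "fruit"),
                                  interaction_only = FALSE) {
  organ <- match.arg(organ)
  if (organ == "shoot") {
    full <- if (interaction_only) ~ length + I(log_length * gdd)
            else ~ length + log_length * gdd
    list(length_only   = ~ length,
         length_gdd    = ~ length + gdd,
         length_loglen = ~ length + log_length + gdd,
         full          = full)
  } else {
    full <- if (interaction_only) ~ log_volume + I(as.numeric(treatment != levels(treatment)[1]) * gdd)
            else ~ log_volume + treatment * gdd
    list(volume_only   = ~ log_volume,
         volume_gdd    = ~ log_volume + gdd,
         volume_trt    = ~ log_volume + treatment + gdd,
         full          = full)
  }
}

prepare_calibration <- function(records, organ) {
  req <- c("gdd", "dry_mass_g")
  if (!all(req %in% names(records)))
    stop("calibration records need columns: ", paste(req, collapse = ", "))
  if (any(records$dry_mass_g <= 0)) stop("dry masses must be positive")
  if (any(records$gdd < 0)) stop("gdd must be non-negative")
  df <- data.frame(dry_mass = records$dry_mass_g, gdd = records$gdd)
  if (organ == "shoot") {
    if (!"length_cm" %in% names(records))
      stop("shoot calibration records need column 'length_cm'")
    if (any(records$length_cm <= 0))
      stop("shoot lengths must be positive (log term requested)")
    df$length <- records$length_cm
    df$log_length <- log(records$length_cm)
  } else {
    if ("volume_mm3" %in% names(records)) {
      vol <- records$volume_mm3
    } else if (all(c("d1_mm", "d2_mm", "d3_mm") %in% names(records))) {
      vol <- spheroid_volume(records$d1_mm, records$d2_mm, records$d3_mm)
    } else {
      stop("fruit calibration records need 'volume_mm3' or 'd1_mm','d2_mm','d3_mm'")
    }
    if (any(vol <= 0)) stop("fruit volumes must be positive (log term requested)")
    df$log_volume <- log(vol)
    if (!"treatment" %in% names(records))
      stop("fruit calibration records need column 'treatment'")
    df$treatment <- factor(records$treatment)
  }
  df
}

#' Fit an organ dry-weight model with AIC term selection
#'
#' Fits every candidate term set by maximum likelihood (ordinary least
#' squares under the gaussian-identity family; Gamma GLM with log link as
#' an alternative for right-skewed dry weights) and returns the AIC-minimal
#' model together with its training RMSE, adjusted R-squared and the full
#' AIC table.
#'
#' @param records calibration data.frame. Shoots: `length_cm`, `gdd`,
#'   `dry_mass_g`. Fruits: `d1_mm`,`d2_mm`,`d3_mm` (or `volume_mm3`),
#'   `treatment`, `gdd`, `dry_mass_g`.
#' @param organ `"shoot"` or `"fruit"`.
#' @param candidates named list of one-sided formulas over the derived
#'   predictors (`length`, `log_length`, `log_volume`, `gdd`, `treatment`);
#'   default [dry_weight_candidates()].
#' @param family `"gaussian"` (identity link, default) or `"gamma"`
#'   (log link).
#' @return object of class `allometric_model`.
#' @export
fit_dry_weight_model <- function(records, organ = c("shoot", "fruit"),
                                 candidates = NULL,
                                 family = c("gaussian", "gamma")) {
  organ <- match.arg(organ)
  family <- match.arg(family)
  if (is.null(candidates)) candidates <- dry_weight_candidates(organ)
  if (!is.list(candidates)) candidates <- list(candidate = candidates)
  df <- prepare_calibration(records, organ)
  max_terms <- max(vapply(candidates, function(f)
    ncol(stats::model.matrix(f, df)), numeric(1)))
  if (nrow(df) < max_terms + 5L)
    stop(sprintf("need at least %d calibration records for %d model terms",
                 max_terms + 5L, max_terms))
  fits <- lapply(candidates, function(f) {
    form <- stats::update(f, dry_mass ~ .)
    fit <- if (family == "gaussian") stats::lm(form, data = df)
           else stats::glm(form, data = df, family = stats::Gamma(link = "log"))
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient design; collinear terms: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
    fit
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  best_i <- which.min(aics)
  fit <- fits[[best_i]]
  pred <- as.numeric(stats::predict(fit, type = "response"))
  resid <- df$dry_mass - pred
  rmse <- sqrt(mean(resid^2))
  adj_r2 <- if (family == "gaussian")
    suppressWarnings(summary(fit)$adj.r.squared) else {
    r2 <- 1 - sum(resid^2) / sum((df$dry_mass - mean(df$dry_mass))^2)
    n <- nrow(df); p <- length(stats::coef(fit)) - 1L
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  if (any(pred <= 0))
    warning(sprintf("%d non-positive fitted dry masses on the training data",
                    sum(pred <= 0)))
  structure(list(organ = organ, family = family,
                 term_set = names(candidates)[best_i],
                 formula = stats::formula(fit), fit = fit,
                 coefficients = stats::coef(fit),
                 rmse = rmse, adj_r2 = adj_r2, aic = unname(aics[best_i]),
                 aic_table = sort(aics),
                 treatment_levels = if (organ == "fruit") levels(df$treatment) else NULL),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("Allometric dry-weight model (%s, %s family)\n", x$organ, x$family))
  cat("  terms:", x$term_set, " ", deparse(x$formula), "\n")
  cat(sprintf("  RMSE = %.3f g, adj R2 = %.3f, AIC = %.1f\n",
              x$rmse, x$adj_r2, x$aic))
  invisible(x)
}

#' Predict organ dry weight from field measurements
#'
#' @param model an `allometric_model` from [fit_dry_weight_model()].
#' @param newdata data.frame in the calibration schema (sizes, `gdd`, and
#'   `treatment` for fruits). Predictions under the gamma-log family are
#'   strictly positive by construction.
#' @return predicted dry mass (g), one value per row.
#' @export
predict_dry_weight <- function(model, newdata) {
  stopifnot(inherits(model, "allometric_model"))
  nd <- as.data.frame(newdata)
  nd$dry_mass_g <- 1   # placeholder; the response is not used in prediction
  df <- prepare_calibration(nd, model$organ)
  if (model$organ == "fruit") {
    unknown <- setdiff(levels(df$treatment), model$treatment_levels)
    if (length(unknown))
      stop("unknown treatment level(s): ", paste(unknown, collapse = ", "))
    df$treatment <- factor(df$treatment, levels = model$treatment_levels)
  }
  as.numeric(stats::predict(model$fit, newdata = df, type = "response"))
}

#' Export / import an allometric model as JSON
#'
#' Stores the term set, coefficient vector, family and units so a fitted
#' calibration model can be archived next to the measurement tables.
#'
#' @param model an `allometric_model`.
#' @param path file to write (JSON).
#' @return `write_allometric_model` returns `path` invisibly;
#'   `read_allometric_model` returns the stored description as a list
#'   (coefficients, formula text, family, organ, diagnostics).
#' @export
write_allometric_model <- function(model, path) {
  stopifnot(inherits(model, "allometric_model"))
  doc <- list(organ = model$organ, family = model$family,
              term_set = model$term_set,
              formula = paste(deparse(model$formula), collapse = " "),
              coefficients = as.list(model$coefficients),
              rmse = model$rmse, adj_r2 = model$adj_r2, aic = model$aic,
              treatment_levels = model$treatment_levels,
              units = list(length = "cm", diameter = "mm", mass = "g",
                           time = "GDD (degree-days, base 4.5C)"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_allometric_model
#' @export
read_allometric_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$coefficients <- unlist(doc$coefficients)
  doc
}
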