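#' One-sided unpaired Mann-Whitney test
#'
#' Wraps [stats::wilcox.test()] with the contract made explicit: the exact
#' distribution of U is used when `n_a + n_b <= 16` and there are no ties
#' (the exact p then equals the full permutation-enumeration p); otherwise
#' the tie-corrected normal approximation with continuity correction is
#' used. `alternative = "greater"` tests whether `a` is stochastically
#' greater than `b`.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative `"greater"` or `"less"` (of `a` relative to `b`).
#' @return list: `statistic` (U for `a`), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#' @export
mann_whitney_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 16L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx",
       n_a = length(a), n_b = length(b))
}

#' One-sided unpaired Welch t-test
#'
#' Welch's unequal-variance t-test; when both groups are constant and
#' equal the test is undefined and p = 0.5 is returned by convention with
#' a warning (no evidence either way).
#'
#' @inheritParams mann_whitney_one_sided
#' @return list: `statistic` (t), `p_value`, `df`, `n_a`, `n_b`.
#' @export
t_test_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means; p = 0.5 by convention")
      return(list(statistic = 0, p_value = 0.5, df = NA_real_,
                  n_a = length(a), n_b = length(b)))
    }
    diff_ok <- if (alternative == "greater") mean(a) > mean(b) else mean(a) < mean(b)
    return(list(statistic = if (diff_ok) Inf else -Inf,
                p_value = if (diff_ok) 0 else 1, df = NA_real_,
                n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_a = length(a), n_b = length(b))
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the family size (the length of the
#' vector) and capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Significance stars for adjusted p-values
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05 (the
#' single-star cut is the conventional completion of the two documented
#' thresholds), empty otherwise.
#'
#' @param adjusted_p numeric vector in `[0, 1]`.
#' @param thresholds named or unnamed length-3 numeric, cuts for
#'   `***`, `**`, `*`.
#' @return character vector of stars.
#' @export
stars <- function(adjusted_p, thresholds = c(0.001, 0.01, 0.05)) {
  if (any(adjusted_p < 0 | adjusted_p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep("", length(adjusted_p))
  out[adjusted_p <= thresholds[3L]] <- "*"
  out[adjusted_p <= thresholds[2L]] <- "**"
  out[adjusted_p <= thresholds[1L]] <- "***"
  out
}

#' Per-interval treatment comparison of rate series
#'
#' Runs one two-sample test per shared measurement interval between two
#' groups of organs (e.g. shoot RER in defruited vs fruited trees), with
#' Bonferroni adjustment over the number of intervals in the series and
#' significance stars on the adjusted p-values. Intervals are matched by
#' index; their GDD midpoints must agree within `tol`.
#'
#' @param series_A,series_B lists of `growth_rate_series` (one per organ);
#'   the alternative is stated for group A relative to group B.
#' @param test_kind `"mann_whitney"` or `"t_test"`.
#' @param alternative `"greater"` or `"less"` (A vs B).
#' @param tol GDD alignment tolerance between the two groups' interval
#'   midpoints (default 1e-6).
#' @return data.frame of class `comparison_table`: `gdd_mid`, `n_A`,
#'   `n_B`, `statistic`, `raw_p`, `adj_p`, `stars`; attributes `test_kind`
#'   and `alternative`.
#' @export
compare_series <- function(series_A, series_B,
                           test_kind = c("mann_whitney", "t_test"),
                           alternative = c("greater", "less"), tol = 1e-6) {
  test_kind <- match.arg(test_kind)
  alternative <- match.arg(alternative)
  series_A <- Filter(function(s) nrow(s) > 0L, series_A)
  series_B <- Filter(function(s) nrow(s) > 0L, series_B)
  if (length(series_A) == 0L || length(series_B) == 0L)
    stop("both groups need at least one non-empty rate series")
  nA <- unique(vapply(series_A, nrow, integer(1)))
  nB <- unique(vapply(series_B, nrow, integer(1)))
  if (length(nA) > 1L || length(nB) > 1L || nA != nB)
    stop("groups do not share a common interval schedule")
  m <- nA
  if (m == 0L) stop("no shared intervals")
  midsA <- rowMeans(matrix(vapply(series_A, function(s) s$gdd_mid, numeric(m)), nrow = m))
  midsB <- rowMeans(matrix(vapply(series_B, function(s) s$gdd_mid, numeric(m)), nrow = m))
  if (any(abs(midsA - midsB) > tol))
    stop("interval midpoints differ between groups beyond tolerance")
  ratesA <- matrix(vapply(series_A, function(s) s$rate, numeric(m)), nrow = m)
  ratesB <- matrix(vapply(series_B, function(s) s$rate, numeric(m)), nrow = m)
  res <- lapply(seq_len(m), function(i) {
    if (test_kind == "mann_whitney")
      mann_whitney_one_sided(ratesA[i, ], ratesB[i, ], alternative)
    else t_test_one_sided(ratesA[i, ], ratesB[i, ], alternative)
  })
  raw_p <- vapply(res, `[[`, numeric(1), "p_value")
  adj_p <- bonferroni(raw_p)
  out <- data.frame(gdd_mid = (midsA + midsB) / 2,
                    n_A = length(series_A), n_B = length(series_B),
                    statistic = vapply(res, `[[`, numeric(1), "statistic"),
                    raw_p = raw_p, adj_p = adj_p, stars = stars(adj_p),
                    stringsAsFactors = FALSE)
  attr(out, "test_kind") <- test_kind
  attr(out, "alternative") <- alternative
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Linear model for treatment and GDD effects on trunk growth
#'
#' Ordinary least-squares fit of the relative increment in trunk
#' circumference on treatment (categorical) and cumulative GDD, used to
#' establish that both factors matter before fitting per-treatment
#' log-linear RGR lines.
#'
#' @param data data.frame with columns `relative_increment`, `treatment`,
#'   `gdd` (one row per tree and date).
#' @param interaction include a treatment:gdd interaction (default FALSE).
#' @return list of class `linear_model_report`: `coefficients` (estimate,
#'   std error, t, p per term), `r_squared`, `n`, and the underlying `fit`.
#' @export
trunk_treatment_model <- function(data, interaction = FALSE) {
  stopifnot(all(c("relative_increment", "treatment", "gdd") %in% names(data)))
  data$treatment <- factor(data$treatment)
  if (nlevels(data$treatment) < 2L) stop("need >= 2 treatment levels")
  if (length(unique(data$gdd)) < 3L) stop("need >= 3 distinct GDD values")
  form <- if (interaction) relative_increment ~ treatment * gdd
          else relative_increment ~ treatment + gdd
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  s <- summary(fit)
  structure(list(coefficients = as.data.frame(s$coefficients),
                 r_squared = s$r.squared, n = nrow(data), fit = fit),
            class = "linear_model_report")
}

#' One-sided comparison of shoot wood density between treatments
#'
#' Welch one-sided t-test with alternative "group A denser than group B";
#' used to check that defruited shoots are not significantly denser than
#' fruited ones (so a shared length-to-mass allometry is a lower-bound
#' approximation for defruited shoots).
#'
#' @param densities_A,densities_B shoot densities (g/cm^3), n >= 2 each.
#' @return as [t_test_one_sided()].
#' @export
density_comparison <- function(densities_A, densities_B) {
  t_test_one_sided(densities_A, densities_B, alternative = "greater")
}
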