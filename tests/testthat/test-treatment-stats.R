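test_that("one-sided Mann-Whitney exact path matches enumeration", {
  # complete separation of 3 vs 3: 1 arrangement in choose(6,3) = 20
  res <- mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(res$p_value, 1 / 20)
  expect_equal(res$method, "exact")
  # same comparison phrased from the other side
  expect_equal(mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6), "less")$p_value,
               1 / 20)
  # spot-check random no-tie samples against the enumeration oracle
  set.seed(10)
  for (i in 1:10) {
    a <- round(runif(4, 0, 100), 3)
    b <- round(runif(3, 0, 100), 3)
    expect_equal(mann_whitney_one_sided(a, b, "greater")$p_value,
                 mw_enum_oracle(a, b))
  }
  expect_error(mann_whitney_one_sided(numeric(0), 1:3), "non-empty")
})

test_that("identical groups give no one-sided evidence", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  expect_gte(mann_whitney_one_sided(x, x, "greater")$p_value, 0.5)
  tt <- t_test_one_sided(x, x, "greater")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 0.5)
})

test_that("Mann-Whitney p-values are valid under the null", {
  set.seed(19)
  ps <- replicate(400, mann_whitney_one_sided(rnorm(5), rnorm(5),
                                              "greater")$p_value)
  # discrete exact p: P(p <= alpha) <= alpha at every alpha, and the mean
  # sits at 1/2 (up to the discreteness half-atom)
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 400))
  }
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("Welch one-sided t-test detects shifts and holds its size", {
  set.seed(23)
  a <- rnorm(20, 5, 1)
  b <- rnorm(20, 0, 1)
  expect_lt(t_test_one_sided(a, b, "greater")$p_value, 0.001)

  rejections <- sum(replicate(300, {
    t_test_one_sided(rnorm(8), rnorm(8), "greater")$p_value <= 0.05
  }))
  # binomial 99% band around alpha = 0.05 at 300 draws
  expect_lt(abs(rejections / 300 - 0.05), 2.58 * sqrt(0.05 * 0.95 / 300))

  expect_warning(res <- t_test_one_sided(c(2, 2, 2), c(2, 2, 2)), "convention")
  expect_equal(res$p_value, 0.5)
  expect_error(t_test_one_sided(1, 1:3), "n >= 2")
})

test_that("Bonferroni multiplies by the family size and caps at one", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.2, 0.5)), c(0.03, 0.6, 1.0))
  set.seed(2)
  p <- runif(9)
  expect_true(all(bonferroni(p) >= p))
  expect_equal(bonferroni(rep(0.02, 7)), rep(min(1, 7 * 0.02), 7))
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("significance stars follow the documented thresholds", {
  expect_equal(stars(c(0.0005, 0.009, 0.03, 0.2)),
               c("***", "**", "*", ""))
  expect_equal(stars(c(0.001, 0.01, 0.05)), c("***", "**", "*"))
})

test_that("per-date series comparison adjusts over its own family", {
  g <- seq(200, 1600, by = 200)
  mk_group <- function(n, shift = 0, seed) {
    set.seed(seed)
    lapply(1:n, function(i)
      make_rate_series(g, rnorm(length(g), 0.004 + shift, 0.0005)))
  }
  # identical groups: no stars anywhere
  A <- mk_group(6, seed = 31)
  tab <- compare_series(A, A, "t_test", "greater")
  expect_equal(tab$stars, rep("", length(g)))
  expect_equal(tab$adj_p, pmin(1, length(g) * tab$raw_p))

  # strong shift: every date flagged after adjustment
  B <- mk_group(6, shift = 0.005, seed = 32)
  tab2 <- compare_series(B, A, "t_test", "greater")
  expect_true(all(tab2$adj_p < 0.001))
  expect_true(all(tab2$stars == "***"))

  misaligned <- lapply(1:4, function(i) make_rate_series(g + 50, rnorm(8)))
  expect_error(compare_series(A, misaligned, "t_test"), "midpoints")
})

test_that("a difference appearing mid-season flags a suffix of dates", {
  g <- seq(200, 1600, by = 200)
  hits <- 0L
  for (s in 1:20) {
    set.seed(600 + s)
    A <- lapply(1:8, function(i)
      make_rate_series(g, rnorm(8, 0.004 + ifelse(g >= 800, 0.002, 0),
                                0.0006)))
    B <- lapply(1:8, function(i) make_rate_series(g, rnorm(8, 0.004, 0.0006)))
    tab <- compare_series(A, B, "mann_whitney", "greater")
    sig <- tab$adj_p <= 0.05
    suffix_ok <- all(sig[g >= 800]) && !any(sig[g < 600])
    if (suffix_ok) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("trunk model matches the normal equations and finds real effects", {
  fix <- data.frame(
    treatment = rep(c("DEF", "FRU"), each = 6),
    gdd = rep(c(300, 600, 900, 1200, 1500, 1800), 2),
    relative_increment = c(0.01, 0.03, 0.05, 0.08, 0.10, 0.12,
                           0.005, 0.012, 0.02, 0.03, 0.04, 0.045))
  rep <- trunk_treatment_model(fix)
  # oracle: explicit normal equations on the dummy-coded design
  X <- cbind(1, as.numeric(fix$treatment == "FRU"), fix$gdd)
  beta <- solve(t(X) %*% X, t(X) %*% fix$relative_increment)
  expect_equal(unname(rep$coefficients[, "Estimate"]), as.numeric(beta),
               tolerance = 1e-12)
  expect_lt(rep$coefficients["treatmentFRU", 4], 0.001)
  expect_lt(rep$coefficients["gdd", 4], 0.001)

  # null treatment effect: p approximately uniform
  ps <- vapply(1:100, function(s) {
    set.seed(700 + s)
    d <- data.frame(treatment = rep(c("DEF", "FRU"), each = 8),
                    gdd = rep(seq(200, 1600, by = 200), 2),
                    relative_increment = rnorm(16, 0.05, 0.01))
    trunk_treatment_model(d)$coefficients["treatmentFRU", 4]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  expect_error(trunk_treatment_model(
    data.frame(treatment = "DEF", gdd = c(1, 2, 3),
               relative_increment = c(1, 2, 3))), "levels")
})

test_that("density comparison is the one-sided Welch test, A greater", {
  set.seed(41)
  a <- rnorm(20, 0.45, 0.05)
  b <- rnorm(20, 0.45, 0.05)
  expect_equal(density_comparison(a, b),
               t_test_one_sided(a, b, "greater"))
  expect_lt(density_comparison(a + 0.5, b)$p_value, 1e-6)
  expect_equal(density_comparison(a, a)$p_value, 0.5)
})
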