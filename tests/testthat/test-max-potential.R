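make_shoot_table <- function(final_lengths, dates_gdd = c(100, 2000)) {
  do.call(rbind, lapply(seq_along(final_lengths), function(i) {
    data.frame(organ_id = sprintf("S%02d", i), gdd = dates_gdd,
               length_cm = c(final_lengths[i] / 4, final_lengths[i]))
  }))
}

test_that("spur filter keeps only shoots strictly longer than the cut", {
  tab <- make_shoot_table(c(3.9, 4.0, 4.1))
  expect_message(kept <- filter_spurs(tab), "removed 2 of 3")
  expect_equal(unique(kept$organ_id), "S03")

  tab2 <- make_shoot_table(c(10, 25, 60))
  expect_message(kept2 <- filter_spurs(tab2), "removed 0 of 3")
  expect_equal(nrow(kept2), nrow(tab2))

  set.seed(4)
  lens <- c(runif(4, 1, 4), runif(6, 5, 80))
  tab3 <- make_shoot_table(lens)
  expect_message(kept3 <- filter_spurs(tab3), "removed 4 of 10")
  expect_equal(length(unique(kept3$organ_id)), 6)
})

test_that("pruning traces classify shoots, missing flags become unknown", {
  expect_equal(classify_shoot_type(c(TRUE, FALSE)),
               c("epicormic", "proleptic"))
  expect_warning(out <- classify_shoot_type(c(TRUE, NA, FALSE)), "unknown")
  expect_equal(out, c("epicormic", "unknown", "proleptic"))
})

test_that("top-k shoot selection is a deterministic sort with tie-breaks", {
  df <- data.frame(
    organ_id = sprintf("S%02d", 1:7),
    shoot_class = "proleptic",
    final_mass_g = c(5, 9, 3, 7, 8, 6, 4),
    final_length_cm = seq(10, 70, by = 10))
  sel <- suppressWarnings(select_max_shoots(df, k = 5))
  # sort oracle: top five masses are 9,8,7,6,5
  expect_equal(sel$proleptic$selection_metric, c(9, 8, 7, 6, 5))
  expect_equal(sel$proleptic$member_ids, c("S02", "S05", "S04", "S06", "S01"))

  # k larger than the population keeps everyone, with a warning
  expect_warning(sel2 <- select_max_shoots(df[1:3, ], k = 5), "only 3")
  expect_equal(length(sel2$proleptic$member_ids), 3)

  # exact tie at rank 5: the longer shoot wins
  df3 <- df
  df3$final_mass_g <- c(5, 9, 5, 7, 8, 6, 4)
  df3$final_length_cm <- c(10, 10, 30, 10, 10, 10, 10)
  sel3 <- suppressWarnings(select_max_shoots(df3, k = 5))
  expect_true("S03" %in% sel3$proleptic$member_ids)
  expect_false("S01" %in% sel3$proleptic$member_ids)

  # idempotence: re-selecting from the selection returns the same set
  again <- suppressWarnings(select_max_shoots(sel$proleptic$table, k = 5))
  expect_equal(again$proleptic$member_ids, sel$proleptic$member_ids)

  # selection mean dominates the population mean by construction
  expect_gte(mean(sel$proleptic$selection_metric), mean(df$final_mass_g))

  # unknown-class shoots are never selected
  df4 <- rbind(df, data.frame(organ_id = "S99", shoot_class = "unknown",
                              final_mass_g = 100, final_length_cm = 100))
  sel4 <- suppressWarnings(select_max_shoots(df4, k = 5))
  expect_false("S99" %in% sel4$proleptic$member_ids)
})

test_that("max-trunk selection maximises the normalized increment", {
  mk <- function(id, circs) data.frame(tree_id = id, gdd = c(300, 900, 1800),
                                       circumference_mm = circs)
  trunks <- rbind(mk("T1", c(100, 104, 108)),
                  mk("T2", c(120, 128, 134.4)),
                  mk("T3", c(110, 116, 121)))
  out <- select_max_trunk(trunks)
  expect_equal(out$tree_id, "T2")
  expect_equal(out$final_increment, 0.12)
  expect_s3_class(out$rgr_fit, "log_linear_fit")
  expect_equal(select_max_trunk(mk("T9", c(90, 95, 99)))$tree_id, "T9")
  expect_error(select_max_trunk(mk("T1", c(100, NA, NA))), "observations")
})

test_that("max-trunk recovery under noise identifies the fastest grower", {
  hits <- 0L
  g <- seq(300, 2100, by = 300)
  for (s in 1:20) {
    set.seed(400 + s)
    r <- c(4e-5, 5e-5, 9e-5, 6e-5, 3e-5)   # tree 3 grows fastest
    trunks <- do.call(rbind, lapply(1:5, function(i) {
      agb <- 4000 * exp(r[i] * g)
      data.frame(tree_id = paste0("T", i), gdd = g,
                 circumference_mm = 10 * wood_circumference(agb) *
                   exp(rnorm(length(g), 0, 0.002)))
    }))
    if (select_max_trunk(trunks)$tree_id == "T3") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("fruit potential curve averages undamaged thinned fruits", {
  g <- c(300, 600, 900, 1200)
  mk <- function(id, r, damaged = FALSE) data.frame(
    organ_id = id, gdd = g, dry_mass_g = 0.5 * exp(r * g),
    pest_damaged = damaged)
  one <- fruit_potential_curve(mk("F1", 0.004))
  expect_equal(one$mean_rate, rep(0.004, 3), tolerance = 1e-12)
  expect_equal(one$n, rep(1L, 3))

  expect_warning(empty <- fruit_potential_curve(mk("F1", 0.004, TRUE)),
                 "no undamaged")
  expect_equal(nrow(empty), 0)

  set.seed(6)
  cohort <- do.call(rbind, lapply(1:25, function(i)
    mk(paste0("F", i), rnorm(1, 0.004, 0.0005))))
  cv <- fruit_potential_curve(cohort)
  se <- 0.0005 / sqrt(25)
  expect_true(all(abs(cv$mean_rate - 0.004) < 3 * se))
})

simulate_thi_cohort <- function(n, seed) {
  # expolinear fruits with set-time jitter measured on a shared schedule
  set.seed(seed)
  g <- seq(250, 2250, by = 250)
  do.call(rbind, lapply(seq_len(n), function(i) {
    g_set <- runif(1, 40, 180)
    s <- 0.035 * exp(rnorm(1, 0, 0.03))
    data.frame(organ_id = sprintf("F%03d", i), gdd = g,
               dry_mass_g = latent_fruit_mass(0.021, s, 150, g_set, g))
  }))
}

test_that("variability regressions expose fruit-set timing", {
  # exact proportionality: slope and fit are exact
  g <- c(300, 600, 2100)
  exact <- do.call(rbind, lapply(1:6, function(i) data.frame(
    organ_id = paste0("F", i), gdd = g,
    dry_mass_g = c(i, 1.5 * i^1.1, 10 * i))))
  rep <- fruit_variability_analysis(exact)
  expect_equal(rep$harvest_vs_initial$slope, 10, tolerance = 1e-10)
  expect_equal(rep$harvest_vs_initial$r_squared, 1, tolerance = 1e-10)

  # set-time jitter: later set means lighter first record but faster
  # early growth, so initial ~ early RGR comes out negative
  cohort <- simulate_thi_cohort(40, seed = 77)
  rep2 <- fruit_variability_analysis(cohort)
  expect_lt(rep2$initial_vs_early_rgr$slope, 0)
  expect_lt(rep2$initial_vs_early_rgr$p_value, 0.01)
  expect_gt(rep2$harvest_vs_initial$slope, 0)

  # degenerate predictor is rejected
  const <- do.call(rbind, lapply(1:4, function(i) data.frame(
    organ_id = paste0("F", i), gdd = c(100, 500, 900),
    dry_mass_g = c(2, 4, 6))))
  expect_error(fruit_variability_analysis(const), "degenerate")
  expect_error(fruit_variability_analysis(exact[exact$organ_id == "F1", ]),
               ">= 3 fruits")
})

test_that("null pairing yields approximately uniform regression p-values", {
  ps <- vapply(1:100, function(s) {
    set.seed(900 + s)
    tab <- do.call(rbind, lapply(1:15, function(i) data.frame(
      organ_id = paste0("F", i), gdd = c(200, 600, 2000),
      dry_mass_g = c(exp(rnorm(1, 0, 0.3)), 2, 8 * exp(rnorm(1, 0, 0.3))))))
    fruit_variability_analysis(tab)$harvest_vs_initial$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
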