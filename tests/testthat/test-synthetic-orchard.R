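zero_noise_config <- function(...) {
  orchard_config(noise = list(length = 0, diameter = 0, circumference = 0,
                              mass = 0, fruit_shape = 0, weather_sd = 0,
                              pest_rate = 0), ...)
}

test_that("weather generation is seeded, bounded and exact at zero noise", {
  w1 <- generate_weather("2014-04-02", 30, seed = 5)
  w2 <- generate_weather("2014-04-02", 30, seed = 5)
  expect_identical(w1, w2)
  expect_false(identical(w1$temp_c,
                         generate_weather("2014-04-02", 30, seed = 6)$temp_c))

  w0 <- generate_weather("2014-04-02", 10, noise_sd = 0)
  pars <- orchard_config()$weather
  d <- as.numeric(difftime(w0$timestamp, w0$timestamp[1], units = "days"))
  h <- as.numeric(format(w0$timestamp, "%H"))
  expect_equal(w0$temp_c,
               pars$t_base_mean + pars$t_amp * sin(pi * (d + pars$phase_days) /
                                                     pars$period_days) -
                 pars$diurnal_amp * cos(2 * pi * (h - 2) / 24))

  wd <- generate_weather("2014-04-02", 190, seed = 1)
  expect_true(all(wd$temp_c > -20 & wd$temp_c < 45))
})

test_that("generated orchards honour the design structure", {
  orch <- generate_orchard(orchard_config(), seed = 3)
  expect_identical(generate_orchard(orchard_config(), seed = 3)$shoots,
                   orch$shoots)
  # treatments and organ placement
  expect_setequal(unique(orch$shoots$treatment), c("FRU", "DEF"))
  expect_setequal(unique(orch$fruits$treatment), c("FRU", "THI"))
  expect_setequal(unique(orch$trunks$treatment), c("FRU", "DEF"))
  expect_equal(nrow(orch$trunks), 10)
  # epicormics exist only on pruned branches of defruited trees
  epi <- orch$shoots$shoot_class == "epicormic"
  expect_true(all(orch$shoots$treatment[epi] == "DEF"))
  expect_true(all(orch$shoots$pruning_trace[epi]))
  expect_true(all(is.na(orch$shoots$pruning_trace[orch$shoots$treatment == "FRU"])))

  # latent shoot trajectories are positive and non-decreasing
  g <- seq(0, 2400, by = 50)
  for (i in sample(nrow(orch$shoots), 10)) {
    p <- orch$shoots[i, ]
    L <- latent_shoot_length(p$Lmax, p$A, p$k, g)
    expect_true(all(L > 0))
    expect_true(all(diff(L) >= 0))
    W <- latent_shoot_mass(p$Lmax, p$A, p$k, g[g > 0], 0.08, 4e-4)
    expect_true(all(W > 0))
  }

  # trunk ground truth: defruited trees outgrow fruited ones on average
  r_mean <- tapply(orch$trunks$r, orch$trunks$treatment, mean)
  expect_gt(r_mean[["DEF"]], r_mean[["FRU"]])
})

test_that("fruit-set jitter induces the negative initial-mass/early-RGR link", {
  orch <- generate_orchard(orchard_config(), seed = 8)
  thi <- orch$fruits[orch$fruits$treatment == "THI", ]
  g1 <- 280; g2 <- 420
  w1 <- latent_fruit_mass(thi$rm, thi$s, thi$tb, thi$g_set, g1)
  w2 <- latent_fruit_mass(thi$rm, thi$s, thi$tb, thi$g_set, g2)
  early_rgr <- (log(w2) - log(w1)) / (g2 - g1)
  expect_lt(cor(w1, early_rgr), 0)
})

test_that("zero-noise measurements reproduce latent values exactly", {
  sim <- simulate_orchard(zero_noise_config(), seed = 2)
  meas <- sim$measurements
  orch <- sim$orchard

  sh <- meas[meas$organ_type == "shoot", ]
  p <- orch$shoots[match(sh$organ_id, orch$shoots$organ_id), ]
  expect_equal(sh$length_cm, latent_shoot_length(p$Lmax, p$A, p$k, sh$gdd),
               tolerance = 1e-12)

  fr <- meas[meas$organ_type == "fruit", ]
  pf <- orch$fruits[match(fr$organ_id, orch$fruits$organ_id), ]
  v_lat <- latent_fruit_volume(pf$rm, pf$s, pf$tb, pf$g_set, fr$gdd,
                               orch$config$fruit$rho0, orch$config$fruit$rho_g)
  expect_equal(spheroid_volume(fr$d1_mm, fr$d2_mm, fr$d3_mm), v_lat,
               tolerance = 1e-9)

  tr <- meas[meas$organ_type == "trunk", ]
  pt <- orch$trunks[match(tr$tree_id, orch$trunks$tree_id), ]
  expect_equal(tr$circumference_mm,
               10 * wood_circumference(latent_trunk_agb(pt$agb0, pt$r, tr$gdd)),
               tolerance = 1e-12)
  expect_false(any(fr$pest_damaged))
})

test_that("fruit diameter shape jitter preserves the latent volume", {
  cfg <- orchard_config(noise = list(diameter = 0))  # keep shape jitter
  sim <- simulate_orchard(cfg, seed = 4)
  fr <- sim$measurements[sim$measurements$organ_type == "fruit", ]
  pf <- sim$orchard$fruits[match(fr$organ_id, sim$orchard$fruits$organ_id), ]
  v_lat <- latent_fruit_volume(pf$rm, pf$s, pf$tb, pf$g_set, fr$gdd,
                               cfg$fruit$rho0, cfg$fruit$rho_g)
  expect_equal(spheroid_volume(fr$d1_mm, fr$d2_mm, fr$d3_mm), v_lat,
               tolerance = 1e-9)
  # the three diameters do differ (shape jitter is on)
  expect_gt(sd(c(fr$d1_mm[1] / fr$d2_mm[1], fr$d2_mm[1] / fr$d3_mm[1])), 0)
})

test_that("measurement sampling is reproducible and schedule-bound", {
  orch <- generate_orchard(orchard_config(), seed = 6)
  m1 <- sample_measurements(orch, seed = 99)
  m2 <- sample_measurements(orch, seed = 99)
  expect_identical(m1$measurements, m2$measurements)
  expect_identical(m1$calibration, m2$calibration)
  expect_false(identical(
    m1$measurements$length_cm,
    sample_measurements(orch, seed = 100)$measurements$length_cm))
  # fruit schedule starts only after every fruit has set
  first_fruit_gdd <- min(m1$measurements$gdd[
    m1$measurements$organ_type == "fruit"])
  expect_gte(first_fruit_gdd, max(orch$fruits$g_set))
})

test_that("ground truth is complete, noise-invariant and serialisable", {
  orch <- generate_orchard(orchard_config(), seed = 12)
  gt <- ground_truth(orch)
  expect_equal(nrow(gt$trunks), 10)
  expect_true(all(c("rm", "s", "tb", "g_set") %in% names(gt$fruits)))
  expect_equal(gt$max_trunk_tree[["DEF"]],
               gt$trunks$tree_id[which.max(gt$trunks$r *
                                             (gt$trunks$treatment == "DEF"))])
  # truth does not depend on how noisily we later measure
  sample_measurements(orch, seed = 1)
  expect_identical(ground_truth(orch), gt)
  # JSON round-trip of the trunk truth table
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(gt$trunks, path, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$r, gt$trunks$r)
  expect_equal(back$tree_id, gt$trunks$tree_id)
})

test_that("zero-noise pipeline recovery returns exact rates and labels", {
  sim <- simulate_orchard(zero_noise_config(), seed = 5)
  meas <- sim$measurements
  orch <- sim$orchard

  # (a) interval RER equals the analytic log-difference of the latent curve
  sh <- meas[meas$organ_type == "shoot" & meas$organ_id == meas$organ_id[1], ]
  p <- orch$shoots[orch$shoots$organ_id == sh$organ_id[1], ]
  rs <- trajectory_rates(sh, "length")
  lat <- latent_shoot_length(p$Lmax, p$A, p$k, sh$gdd)
  expect_equal(rs$rate, diff(log(lat)) / diff(sh$gdd), tolerance = 1e-12)

  # (b) the measured max-increment tree is the true fastest grower
  tr <- meas[meas$organ_type == "trunk" & meas$treatment == "DEF", ]
  expect_equal(select_max_trunk(tr)$tree_id,
               ground_truth(orch)$max_trunk_tree[["DEF"]])

  # (c) classification from emitted flags reproduces the generating labels
  def <- orch$shoots[orch$shoots$treatment == "DEF", ]
  expect_equal(classify_shoot_type(def$pruning_trace), def$shoot_class)
})

test_that("per-treatment trunk RGR estimates stay near truth under noise", {
  ok <- 0L
  n_rep <- 25L
  for (s in 1:n_rep) {
    sim <- simulate_orchard(orchard_config(), seed = 2000 + s)
    tr <- sim$measurements[sim$measurements$organ_type == "trunk", ]
    tr$agb <- wood_agb(tr$circumference_mm / 10)
    truth <- tapply(sim$orchard$trunks$r, sim$orchard$trunks$treatment, mean)
    est <- vapply(split(tr, tr$treatment), function(d) {
      by_date <- aggregate(log(d$agb), by = list(gdd = d$gdd), FUN = mean)
      fit_log_linear_rgr(by_date$gdd, log_biomass = by_date$x)$slope
    }, numeric(1))
    if (all(abs(est[names(truth)] / truth - 1) < 0.10)) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})
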