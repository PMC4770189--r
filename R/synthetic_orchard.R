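#' Configuration for the synthetic orchard generator
#'
#' Defaults emulate the study conditions of the field experiment the
#' pipeline is designed for: five trees per treatment (fruited control
#' FRU, defruited DEF, heavily thinned THI), tagged shoots on FRU and DEF
#' trees, nine tagged fruits per FRU and THI tree (THI carrying at most
#' one fruit per bourse shoot or spur, FRU about 0.47 fruits per shoot),
#' trunk collars on FRU and DEF trees, a biweekly measurement schedule
#' from spring that relaxes to monthly in late summer, and an early-April
#' full bloom in a temperate alpine-valley climate (annual mean near
#' 12 degrees C).
#'
#' Latent growth shapes (all in thermal time after full bloom):
#' * shoot length: Gompertz, `L(g) = Lmax * exp(-A * exp(-k g))`, whose
#'   RER `A k exp(-k g)` declines smoothly from bloom -- proleptic shoots
#'   cease elongation early, epicormic shoots (on pruned branches of DEF
#'   trees) keep elongating into late summer;
#' * shoot dry mass from length by the fixed rule
#'   `W = c1 * L + c2 * log1p(L) * g` (strictly positive; known ground
#'   truth for calibration model fitting, close to but deliberately not
#'   identical to the log-length term set the calibration model uses);
#' * fruit dry mass: expolinear in fruit age `u = g - g_set`,
#'   `W(u) = (s / r_m) * log(1 + exp(r_m (u - t_b)))` -- exponential at
#'   maximum RGR `r_m`, transitioning to linear accumulation at slope `s`
#'   around age `t_b`; fruit-set jitter `g_set` makes early RGR decline
#'   with fruit age, inducing the negative initial-mass ~ early-RGR
#'   correlation seen in thinned cohorts;
#' * fruit volume from mass through a slowly densifying dry density
#'   `rho(g) = rho0 * exp(rho_g * g)`;
#' * trunk woody biomass: exponential, `AGB(g) = AGB0 * exp(r g)` with
#'   treatment-specific `r` (defruited trees grow faster), circumference
#'   obtained by inverting the wood power law.
#'
#' @param n_trees trees per treatment (default 5).
#' @param shoots_per_tree tagged shoots per FRU/DEF tree (default 20).
#' @param fruits_per_tree tagged fruits per FRU/THI tree (default 9).
#' @param epicormic_fraction fraction of DEF shoots on pruned branches
#'   (default 0.3).
#' @param spur_fraction fraction of tagged shoots that are actually spurs
#'   (final length around or below 4 cm; default 0.15).
#' @param bloom_date full-bloom date (default "2014-04-02").
#' @param season_days length of the monitored season (default 190 days,
#'   bloom through early-October harvest).
#' @param fruit_set_range GDD window over which individual fruits set
#'   (default c(40, 150)).
#' @param fruit_decline logical: impose a late-season decline in fruit dry
#'   mass (default FALSE; the pure expolinear form has none).
#' @param noise list of measurement coefficients of variation:
#'   `length`, `diameter`, `circumference`, `mass` (calibration dry mass),
#'   `fruit_shape` (spread of the three orthogonal diameters around the
#'   equivalent sphere; volume-preserving), `weather_sd` (hourly
#'   temperature noise, degrees C), and `pest_rate`.
#' @return list of class `orchard_config`.
#' @export
orchard_config <- function(n_trees = 5L, shoots_per_tree = 20L,
                           fruits_per_tree = 9L,
                           epicormic_fraction = 0.3, spur_fraction = 0.15,
                           bloom_date = "2014-04-02", season_days = 190L,
                           fruit_set_range = c(40, 180),
                           fruit_decline = FALSE,
                           noise = list()) {
  noise_def <- list(length = 0.03, diameter = 0.02, circumference = 0.002,
                    mass = 0.05, fruit_shape = 0.03, weather_sd = 1.5,
                    pest_rate = 0.08)
  noise <- utils::modifyList(noise_def, noise)
  stopifnot(n_trees >= 1, shoots_per_tree >= 1, fruits_per_tree >= 1,
            epicormic_fraction >= 0, epicormic_fraction <= 1,
            spur_fraction >= 0, spur_fraction <= 1, season_days >= 1,
            all(unlist(noise) >= 0))
  structure(list(
    n_trees = as.integer(n_trees),
    shoots_per_tree = as.integer(shoots_per_tree),
    fruits_per_tree = as.integer(fruits_per_tree),
    epicormic_fraction = epicormic_fraction,
    spur_fraction = spur_fraction,
    bloom_date = as.Date(bloom_date),
    season_days = as.integer(season_days),
    fruit_set_range = fruit_set_range,
    fruit_decline = fruit_decline,
    noise = noise,
    # latent growth parameters (class/treatment means; jittered per organ)
    shoot = list(
      FRU_proleptic = list(Lmax = 25, A = 5.5, k = 0.0045),
      DEF_proleptic = list(Lmax = 32, A = 7.0, k = 0.0030),
      DEF_epicormic = list(Lmax = 160, A = 8.0, k = 0.0011),
      cv_Lmax = 0.25, cv_k = 0.10,
      mass_c1 = 0.08,    # g per cm of length
      mass_c2 = 4e-4),   # g per unit log1p(length) per degree-day
    fruit = list(
      rm = c(FRU = 0.015, THI = 0.021),   # max RGR, per degree-day
      s  = c(FRU = 0.022, THI = 0.035),   # linear-phase slope, g per degree-day
      tb = 150,                            # transition age, degree-days
      cv_rm = 0.05, cv_s = 0.03,
      rho0 = 0.08, rho_g = 2e-4,           # dry density g/cm^3 and its GDD trend
      decline_start = 1900, decline_frac = 0.08),
    trunk = list(
      r = c(FRU = 2e-5, DEF = 7.4e-5),    # woody-biomass RGR per degree-day
      cv_r = 0.4,    # lognormal tree effect; expected max of 5 sits ~55-60%
                     # above the treatment mean, matching the field contrast
      circ0_cm = 25, cv_circ0 = 0.10),
    weather = list(t_base_mean = 10, t_amp = 10, phase_days = 5,
                   period_days = 230, diurnal_amp = 5.5)
  ), class = "orchard_config")
}

## ---- latent trajectory evaluators (exact ground truth) ----

#' Latent organ trajectories of the synthetic orchard
#'
#' Exact (noise-free) latent values used by the generator; exposed so
#' recovery tests can compare estimates against analytic truth.
#'
#' `latent_shoot_length` is Gompertz in GDD; `latent_shoot_mass` applies
#' the fixed length-to-mass rule; `latent_fruit_mass` is expolinear in
#' fruit age; `latent_fruit_volume` divides mass by the drifting dry
#' density; `latent_trunk_agb` is exponential in GDD.
#'
#' @param Lmax,A,k Gompertz parameters (asymptote cm, shape, rate per
#'   degree-day).
#' @param gdd cumulative GDD after bloom (vectorised).
#' @return numeric vector of latent values.
#' @export
latent_shoot_length <- function(Lmax, A, k, gdd) {
  Lmax * exp(-A * exp(-k * gdd))
}

#' @rdname latent_shoot_length
#' @param c1,c2 length-to-mass rule coefficients.
#' @export
latent_shoot_mass <- function(Lmax, A, k, gdd, c1, c2) {
  L <- latent_shoot_length(Lmax, A, k, gdd)
  c1 * L + c2 * log1p(L) * gdd
}

#' @rdname latent_shoot_length
#' @param rm maximum (exponential-phase) RGR per degree-day.
#' @param s linear-phase slope, g per degree-day.
#' @param tb exponential-to-linear transition age, degree-days.
#' @param g_set fruit-set GDD offset.
#' @param decline optional list(start, frac, season_end) for a late-season
#'   mass decline; NULL for the pure expolinear form.
#' @export
latent_fruit_mass <- function(rm, s, tb, g_set, gdd, decline = NULL) {
  age <- pmax(gdd - g_set, 0)
  w <- (s / rm) * log1p(exp(rm * (age - tb)))
  if (!is.null(decline)) {
    over <- pmax(gdd - decline$start, 0) / max(decline$season_end - decline$start, 1)
    w <- w * (1 - decline$frac * pmin(over, 1))
  }
  w
}

#' @rdname latent_shoot_length
#' @param rho0,rho_g dry-density intercept (g/cm^3) and GDD trend.
#' @return `latent_fruit_volume`: volume in mm^3.
#' @export
latent_fruit_volume <- function(rm, s, tb, g_set, gdd, rho0, rho_g,
                                decline = NULL) {
  w <- latent_fruit_mass(rm, s, tb, g_set, gdd, decline)
  1000 * w / (rho0 * exp(rho_g * gdd))
}

#' @rdname latent_shoot_length
#' @param agb0 woody biomass at bloom (g).
#' @param r trunk RGR per degree-day.
#' @export
latent_trunk_agb <- function(agb0, r, gdd) {
  agb0 * exp(r * gdd)
}

## ---- weather ----

#' Generate synthetic hourly orchard weather
#'
#' Seasonal sinusoidal trend plus a diurnal cycle (peak mid-afternoon)
#' plus seeded Gaussian noise, at hourly cadence. With `noise_sd = 0` the
#' series is an exact deterministic sinusoid.
#'
#' @param bloom_date first day of the series.
#' @param season_days number of days.
#' @param noise_sd hourly noise SD, degrees C.
#' @param seed integer seed.
#' @param pars weather shape parameters (see [orchard_config()]).
#' @return data.frame `timestamp`, `temp_c` (one row per hour).
#' @export
generate_weather <- function(bloom_date, season_days, noise_sd = 1.5,
                             seed = 1L,
                             pars = orchard_config()$weather) {
  bloom_date <- as.Date(bloom_date)
  set.seed(seed)
  hours <- seq(from = as.POSIXct(paste(bloom_date, "00:00:00"), tz = "UTC"),
               by = "1 hour", length.out = 24L * season_days)
  d <- as.numeric(difftime(hours, hours[1L], units = "days"))
  h <- as.numeric(format(hours, "%H"))
  seasonal <- pars$t_base_mean +
    pars$t_amp * sin(pi * (d + pars$phase_days) / pars$period_days)
  diurnal <- -pars$diurnal_amp * cos(2 * pi * (h - 2) / 24)
  noise <- if (noise_sd > 0) {
    stats::rnorm(season_days, sd = noise_sd)[floor(d) + 1L] +
      stats::rnorm(length(hours), sd = noise_sd / 2)
  } else 0
  data.frame(timestamp = hours, temp_c = seasonal + diurnal + noise)
}

## ---- orchard generation ----

new_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate a synthetic orchard with known ground truth
#'
#' Draws per-organ latent growth parameters for every tree, shoot, fruit
#' and trunk under `config`, together with a seeded weather series and its
#' thermal-time axis. All randomness flows from `seed` through named
#' substreams (weather, trees, later measurement noise), so the same seed
#' reproduces the same orchard.
#'
#' @param config an [orchard_config()].
#' @param seed integer root seed.
#' @return object of class `synthetic_orchard`: `config`, `weather`,
#'   `axis` (thermal-time axis), and parameter tables `shoots`, `fruits`,
#'   `trunks`.
#' @export
generate_orchard <- function(config = orchard_config(), seed = 1L) {
  stopifnot(inherits(config, "orchard_config"))
  seed <- as.integer(seed)
  weather <- generate_weather(config$bloom_date, config$season_days,
                              noise_sd = config$noise$weather_sd,
                              seed = (seed * 7L + 1L) %% 2147483647L,
                              pars = config$weather)
  axis <- accumulate_gdd(weather, config$bloom_date)
  set.seed((seed * 7L + 2L) %% 2147483647L)

  trt_trees <- function(trt) new_ids(paste0(trt, "_T"), config$n_trees)

  ## shoots: tagged on FRU and DEF trees
  sh <- do.call(rbind, lapply(c("FRU", "DEF"), function(trt) {
    do.call(rbind, lapply(trt_trees(trt), function(tree) {
      n <- config$shoots_per_tree
      is_spur <- stats::runif(n) < config$spur_fraction
      cls <- if (trt == "DEF")
        ifelse(stats::runif(n) < config$epicormic_fraction, "epicormic", "proleptic")
      else rep("proleptic", n)
      base <- lapply(seq_len(n), function(i) {
        key <- if (trt == "DEF" && cls[i] == "epicormic") "DEF_epicormic"
               else paste0(trt, "_proleptic")
        p <- config$shoot[[key]]
        Lmax <- if (is_spur[i]) stats::runif(1, 1.5, 4.5)
                else p$Lmax * exp(stats::rnorm(1, 0, config$shoot$cv_Lmax))
        data.frame(
          tree_id = tree, treatment = trt, shoot_class = cls[i],
          is_spur = is_spur[i],
          pruning_trace = if (trt == "DEF") cls[i] == "epicormic" else NA,
          canopy_level = sample(c("low", "medium", "high"), 1),
          Lmax = Lmax, A = p$A,
          k = p$k * exp(stats::rnorm(1, 0, config$shoot$cv_k)))
      })
      do.call(rbind, base)
    }))
  }))
  sh$organ_id <- new_ids("SH", nrow(sh))
  sh <- sh[c("organ_id", setdiff(names(sh), "organ_id"))]

  ## fruits: tagged on FRU and THI trees
  fr <- do.call(rbind, lapply(c("FRU", "THI"), function(trt) {
    do.call(rbind, lapply(trt_trees(trt), function(tree) {
      n <- config$fruits_per_tree
      data.frame(
        tree_id = tree, treatment = trt,
        canopy_level = sample(c("low", "medium", "high"), n, replace = TRUE),
        pest_damaged = stats::runif(n) < config$noise$pest_rate,
        g_set = stats::runif(n, config$fruit_set_range[1L],
                             config$fruit_set_range[2L]),
        rm = config$fruit$rm[[trt]] * exp(stats::rnorm(n, 0, config$fruit$cv_rm)),
        s = config$fruit$s[[trt]] * exp(stats::rnorm(n, 0, config$fruit$cv_s)),
        tb = config$fruit$tb)
    }))
  }))
  fr$organ_id <- new_ids("FR", nrow(fr))
  fr <- fr[c("organ_id", setdiff(names(fr), "organ_id"))]

  ## trunks: collars on FRU and DEF trees
  tr <- do.call(rbind, lapply(c("FRU", "DEF"), function(trt) {
    circ0 <- config$trunk$circ0_cm *
      exp(stats::rnorm(config$n_trees, 0, config$trunk$cv_circ0))
    data.frame(
      tree_id = trt_trees(trt), treatment = trt,
      agb0 = wood_agb(circ0),
      r = config$trunk$r[[trt]] *
        exp(stats::rnorm(config$n_trees, 0, config$trunk$cv_r)))
  }))

  structure(list(config = config, seed = seed, weather = weather,
                 axis = axis, shoots = sh, fruits = fr, trunks = tr),
            class = "synthetic_orchard")
}

#' Ground truth of a synthetic orchard
#'
#' Complete generating-parameter record for recovery tests: per-organ
#' latent parameters, the shoot mass rule, and derived truths (the true
#' maximum-RGR tree per treatment).
#'
#' @param orchard a `synthetic_orchard`.
#' @return list: `shoots`, `fruits`, `trunks` parameter tables,
#'   `shoot_mass_rule` (c1, c2), `fruit_density` (rho0, rho_g),
#'   `max_trunk_tree` (per treatment, the tree id with the largest
#'   generating trunk RGR).
#' @export
ground_truth <- function(orchard) {
  stopifnot(inherits(orchard, "synthetic_orchard"))
  tr <- orchard$trunks
  max_tree <- vapply(split(tr, tr$treatment), function(d)
    d$tree_id[which.max(d$r)], character(1))
  list(shoots = orchard$shoots, fruits = orchard$fruits,
       trunks = orchard$trunks,
       shoot_mass_rule = c(c1 = orchard$config$shoot$mass_c1,
                           c2 = orchard$config$shoot$mass_c2),
       fruit_density = c(rho0 = orchard$config$fruit$rho0,
                         rho_g = orchard$config$fruit$rho_g),
       max_trunk_tree = as.list(max_tree))   # named list: JSON-stable
}

#' Measurement schedule of the synthetic orchard
#'
#' Biweekly dates from two weeks after bloom through July, monthly in
#' August and September, plus a harvest date at season end; trunk collars
#' are read biweekly starting about seven weeks after bloom; fruits are
#' measured from the first date at which every fruit has set (latest
#' fruit-set GDD plus a 30 degree-day buffer).
#'
#' @param config an [orchard_config()].
#' @param axis optional thermal-time axis; when supplied, the fruit
#'   schedule starts at the first date past the fruit-set window.
#' @return list of `Date` vectors: `shoot`, `fruit`, `trunk`.
#' @export
measurement_schedule <- function(config, axis = NULL) {
  bloom <- config$bloom_date
  end <- bloom + config$season_days - 1L
  jul31 <- as.Date(paste0(format(bloom, "%Y"), "-07-31"))
  biweekly <- seq(bloom + 14L, min(jul31, end), by = 14L)
  monthly <- seq(max(biweekly) + 28L, end, by = 28L)
  dates <- sort(unique(c(biweekly, monthly, end)))
  fruit <- if (is.null(axis)) dates[dates >= bloom + 28L]
           else dates[gdd_at(axis, dates) >= config$fruit_set_range[2L] + 30]
  list(shoot = dates, fruit = fruit,
       trunk = dates[dates >= bloom + 49L])
}

#' Sample measurement tables from a synthetic orchard
#'
#' Evaluates every organ's latent trajectory at the schedule dates, adds
#' multiplicative log-normal measurement noise at the configured CVs, and
#' assembles (i) the long-format measurement table in the standard schema,
#' (ii) a destructive calibration table (shoots and fruits sampled from
#' the same latent populations with oven-dry masses), and (iii) a winter
#' shoot-density table. Fruit diameters are emitted as three
#' volume-preserving jittered orthogonal diameters, so the spheroid volume
#' of the emitted diameters reproduces the latent volume exactly when the
#' diameter measurement CV is zero.
#'
#' @param orchard a `synthetic_orchard`.
#' @param seed integer seed for the measurement-noise substream (default:
#'   derived from the orchard's root seed).
#' @return list: `measurements` (long data.frame), `calibration`,
#'   `densities`, `schedule`.
#' @export
sample_measurements <- function(orchard, seed = NULL) {
  stopifnot(inherits(orchard, "synthetic_orchard"))
  cfg <- orchard$config
  if (is.null(seed)) seed <- (orchard$seed * 7L + 3L) %% 2147483647L
  set.seed(as.integer(seed))
  sched <- measurement_schedule(cfg, orchard$axis)
  nz <- function(n, cv) if (cv > 0) exp(stats::rnorm(n, 0, cv)) else rep(1, n)
  decline <- if (cfg$fruit_decline)
    list(start = cfg$fruit$decline_start, frac = cfg$fruit$decline_frac,
         season_end = max(orchard$axis$cumulative_gdd)) else NULL

  blank_row <- function(n) data.frame(
    length_cm = rep(NA_real_, n), basal_diam_mm = NA_real_, d1_mm = NA_real_,
    d2_mm = NA_real_, d3_mm = NA_real_, circumference_mm = NA_real_,
    dry_mass_g = NA_real_)

  ## shoots
  g_sh <- gdd_at(orchard$axis, sched$shoot)
  sh_rows <- do.call(rbind, lapply(seq_len(nrow(orchard$shoots)), function(i) {
    p <- orchard$shoots[i, ]
    L <- latent_shoot_length(p$Lmax, p$A, p$k, g_sh)
    obs <- blank_row(length(g_sh))
    obs$length_cm <- L * nz(length(L), cfg$noise$length)
    obs$basal_diam_mm <- (1.1 + 0.21 * sqrt(L) * ifelse(p$treatment == "DEF", 1.08, 1)) *
      nz(length(L), cfg$noise$diameter)
    cbind(data.frame(organ_id = p$organ_id, tree_id = p$tree_id,
                     treatment = p$treatment, organ_type = "shoot",
                     shoot_class_hint = p$shoot_class,
                     canopy_level = p$canopy_level,
                     pruning_trace = p$pruning_trace, pest_damaged = FALSE,
                     date = sched$shoot, gdd = g_sh), obs)
  }))

  ## fruits
  g_fr <- gdd_at(orchard$axis, sched$fruit)
  fr_rows <- do.call(rbind, lapply(seq_len(nrow(orchard$fruits)), function(i) {
    p <- orchard$fruits[i, ]
    V <- latent_fruit_volume(p$rm, p$s, p$tb, p$g_set, g_fr,
                             cfg$fruit$rho0, cfg$fruit$rho_g, decline)
    d_eq <- (6 * V / pi)^(1 / 3)
    e1 <- stats::rnorm(length(V), 0, cfg$noise$fruit_shape)
    e2 <- stats::rnorm(length(V), 0, cfg$noise$fruit_shape)
    obs <- blank_row(length(V))
    obs$d1_mm <- d_eq * exp(e1) * nz(length(V), cfg$noise$diameter)
    obs$d2_mm <- d_eq * exp(e2) * nz(length(V), cfg$noise$diameter)
    obs$d3_mm <- d_eq * exp(-e1 - e2) * nz(length(V), cfg$noise$diameter)
    cbind(data.frame(organ_id = p$organ_id, tree_id = p$tree_id,
                     treatment = p$treatment, organ_type = "fruit",
                     shoot_class_hint = NA_character_,
                     canopy_level = p$canopy_level, pruning_trace = NA,
                     pest_damaged = p$pest_damaged,
                     date = sched$fruit, gdd = g_fr), obs)
  }))

  ## trunks
  g_tr <- gdd_at(orchard$axis, sched$trunk)
  tr_rows <- do.call(rbind, lapply(seq_len(nrow(orchard$trunks)), function(i) {
    p <- orchard$trunks[i, ]
    circ_mm <- 10 * wood_circumference(latent_trunk_agb(p$agb0, p$r, g_tr))
    obs <- blank_row(length(g_tr))
    obs$circumference_mm <- circ_mm * nz(length(g_tr), cfg$noise$circumference)
    cbind(data.frame(organ_id = paste0("TRK_", p$tree_id), tree_id = p$tree_id,
                     treatment = p$treatment, organ_type = "trunk",
                     shoot_class_hint = NA_character_,
                     canopy_level = NA_character_, pruning_trace = NA,
                     pest_damaged = FALSE, date = sched$trunk, gdd = g_tr), obs)
  }))

  measurements <- rbind(sh_rows, fr_rows, tr_rows)
  rownames(measurements) <- NULL

  calibration <- simulate_calibration(orchard, nz)
  densities <- data.frame(
    treatment = rep(c("FRU", "DEF", "THI"), each = 20L),
    density_g_cm3 = stats::rnorm(60L, 0.45, 0.05))

  list(measurements = measurements, calibration = calibration,
       densities = densities, schedule = sched)
}

# destructive calibration samples drawn from the same latent populations
simulate_calibration <- function(orchard, nz) {
  cfg <- orchard$config
  axis <- orchard$axis
  end <- max(axis$date)
  shoot_dates <- axis$date[pmin(round(seq(12, nrow(axis) - 1, length.out = 8)),
                                nrow(axis))]
  sh <- do.call(rbind, lapply(shoot_dates, function(dt) {
    g <- gdd_at(axis, dt)
    n <- 30L
    p <- cfg$shoot$FRU_proleptic
    Lmax <- p$Lmax * exp(stats::rnorm(n, 0, cfg$shoot$cv_Lmax))
    k <- p$k * exp(stats::rnorm(n, 0, cfg$shoot$cv_k))
    L <- latent_shoot_length(Lmax, p$A, k, g)
    keep <- L > 0.5
    data.frame(organ_type = "shoot", treatment = "FRU", date = dt, gdd = g,
               length_cm = L[keep],
               d1_mm = NA_real_, d2_mm = NA_real_, d3_mm = NA_real_,
               dry_mass_g = latent_shoot_mass(Lmax[keep], p$A, k[keep], g,
                                              cfg$shoot$mass_c1,
                                              cfg$shoot$mass_c2) *
                 nz(sum(keep), cfg$noise$mass))
  }))
  fruit_dates <- axis$date[pmin(round(seq(30, nrow(axis) - 1, length.out = 8)),
                                nrow(axis))]
  frt <- do.call(rbind, lapply(fruit_dates, function(dt) {
    g <- gdd_at(axis, dt)
    do.call(rbind, lapply(c("FRU", "THI"), function(trt) {
      n <- 15L
      g_set <- stats::runif(n, cfg$fruit_set_range[1L], cfg$fruit_set_range[2L])
      rm <- cfg$fruit$rm[[trt]] * exp(stats::rnorm(n, 0, cfg$fruit$cv_rm))
      s <- cfg$fruit$s[[trt]] * exp(stats::rnorm(n, 0, cfg$fruit$cv_s))
      V <- latent_fruit_volume(rm, s, cfg$fruit$tb, g_set, g,
                               cfg$fruit$rho0, cfg$fruit$rho_g)
      d_eq <- (6 * V / pi)^(1 / 3)
      W <- latent_fruit_mass(rm, s, cfg$fruit$tb, g_set, g)
      data.frame(organ_type = "fruit", treatment = trt, date = dt, gdd = g,
                 length_cm = NA_real_,
                 d1_mm = d_eq, d2_mm = d_eq, d3_mm = d_eq,
                 dry_mass_g = W * nz(n, cfg$noise$mass))
    }))
  }))
  out <- rbind(sh, frt)
  rownames(out) <- NULL
  out
}

#' Generate an orchard and sample its measurements in one call
#'
#' @param config an [orchard_config()].
#' @param seed integer root seed.
#' @return list combining [generate_orchard()] output (`orchard`) with the
#'   [sample_measurements()] tables.
#' @export
simulate_orchard <- function(config = orchard_config(), seed = 1L) {
  orchard <- generate_orchard(config, seed)
  c(list(orchard = orchard), sample_measurements(orchard))
}
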