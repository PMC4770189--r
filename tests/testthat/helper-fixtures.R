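# shared fixtures and independent oracles, all built in code

# constant-temperature weather: one row per hour
constant_weather <- function(temp, days, start = "2014-04-02") {
  hours <- seq(from = as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
               by = "1 hour", length.out = 24 * days)
  data.frame(timestamp = hours, temp_c = rep(temp, length(hours)))
}

# brute-force daily GDD: explicit loop, clamp then average
daily_gdd_oracle <- function(temps, base = 4.5, upper = 35) {
  tot <- 0
  n <- 0
  for (t in temps) {
    if (is.na(t)) next
    if (t < base) t <- base
    if (t > upper) t <- upper
    tot <- tot + t
    n <- n + 1
  }
  tot / n - base
}

# closed-form simple OLS via normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# one-sided Mann-Whitney p by full enumeration of group assignments:
# probability, over all splits of the pooled sample, of a U statistic for
# group a at least as extreme as observed (alternative: a greater)
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) # no ties assumed
  obs <- u_stat(a, b)
  splits <- utils::combn(n, na)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    ga <- pooled[splits[, j]]
    gb <- pooled[-splits[, j]]
    if (u_stat(ga, gb) >= obs) hits <- hits + 1
  }
  hits / ncol(splits)
}

# exponential-in-GDD trajectory sampled at given thermal times
exp_trajectory <- function(x0, rate, gdd) {
  data.frame(gdd = gdd, dry_mass_g = x0 * exp(rate * gdd),
             length_cm = x0 * exp(rate * gdd))
}

# minimal growth_rate_series built directly from vectors
make_rate_series <- function(gdd_mid, rate, kind = "RER") {
  out <- data.frame(gdd_mid = gdd_mid, rate = rate,
                    gdd_start = gdd_mid - 1, gdd_end = gdd_mid + 1)
  attr(out, "rate_kind") <- kind
  class(out) <- c("growth_rate_series", "data.frame")
  out
}

# scan-based cessation oracle: last run of sub-threshold values reaching
# the series end; returns its first index or NA
cessation_oracle <- function(rates, threshold) {
  n <- length(rates)
  if (n == 0) return(NA_integer_)
  idx <- NA_integer_
  for (i in n:1) {
    if (rates[i] < threshold) idx <- i else break
  }
  idx
}
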