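# Independent oracle implementations used to cross-check the package.
# Each one is a separate transcription of the underlying method, written
# against the published algorithm rather than the package source.

# FLH as peak height above the straight baseline: interpolate the radiance
# at the three band centres with stats::approx, draw the line between the
# flanking bands and subtract its value at the peak band.
flh_oracle <- function(wavelengths, lw, bands = c(667, 678, 748)) {
  l <- stats::approx(wavelengths, lw, xout = bands)$y
  baseline_at_peak <- l[1] +
    (l[3] - l[1]) * (bands[2] - bands[1]) / (bands[3] - bands[1])
  l[2] - baseline_at_peak
}

# Ranged-major-axis slope via eigen decomposition: range both variables to
# [0, 1], take the first principal axis of the 2x2 covariance matrix, and
# back-transform the axis direction by the ratio of ranges.
rma_oracle <- function(x, y) {
  u <- (x - min(x)) / diff(range(x))
  v <- (y - min(y)) / diff(range(y))
  ev <- eigen(stats::cov(cbind(u, v)))
  d <- ev$vectors[, 1]  # axis of largest variance
  (d[2] / d[1]) * diff(range(y)) / diff(range(x))
}

# Solar zenith angle from the Meeus low-precision solar ephemeris
# (mean longitude / mean anomaly -> ecliptic longitude -> declination),
# with the hour angle taken from local apparent solar time.
solar_zenith_meeus <- function(lat, date, local_solar_time) {
  jd <- as.numeric(as.Date(date)) + 2440587.5 + local_solar_time / 24
  n <- jd - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 0.0000004 * n) * pi / 180
  dec <- asin(sin(eps) * sin(lambda))
  phi <- lat * pi / 180
  h <- (local_solar_time - 12) * 15 * pi / 180
  cosz <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(h)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

# Textbook one-way ANOVA from sums of squares.
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  k <- length(groups)
  n <- length(all_v)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Textbook Welch two-sample statistic and Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# random rough test spectrum on an irregular grid covering the FLH bands
random_spectrum <- function() {
  wl <- sort(unique(c(seq(340, 940, by = runif(1, 2, 6)),
                      runif(10, 600, 800))))
  lw <- runif(1, 0.5, 2) + 0.3 * sin(wl / runif(1, 15, 60)) +
    runif(length(wl), -0.05, 0.05)
  list(wavelengths = wl, lw = lw)
}
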