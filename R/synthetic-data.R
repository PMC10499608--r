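# Synthetic-data generators emulating every input the pipeline consumes:
# ENSO-forced satellite fields, model limitation terms, shipboard
# hyperspectral transects, bioassay tables and diel active-fluorometry
# series. All generators are pure functions of (config, seed).

#' Configuration for the synthetic satellite/model scene
#'
#' Describes an equatorial-Pacific-like box (defaults: the Nino3 region at
#' 1-degree resolution), an ENSO-like AR(1) SST anomaly with one spatial
#' mode, and the couplings the analysis assumes: a true Fe-limitation series
#' affine in the SST anomaly with prescribed sensitivity `s_true`,
#' chlorophyll responding linearly (and negatively) to the anomaly, and a
#' fluorescence yield affine in limitation — the exact inverse of the
#' analysis-side [scaling_spec()], so recovery is well-posed.
#'
#' @param lat,lon Grid cell-centre axes in degrees.
#' @param months Record length (>= 24 for anomaly work).
#' @param seed Integer seed; every random draw derives from it.
#' @param start First composite mid-point date.
#' @param sst_clim Climatological SST (degC).
#' @param enso_amp Stationary standard deviation of the ENSO SST anomaly
#'   (degC).
#' @param enso_ar1 Month-to-month AR(1) persistence, in \[0, 1).
#' @param s_true Prescribed limitation-SST sensitivity (limitation units
#'   per degC).
#' @param l0 Baseline Fe limitation at zero anomaly.
#' @param chl_clim Climatological chlorophyll a (mg m^-3).
#' @param chl_sst_slope Chlorophyll response to the SST anomaly
#'   (mg m^-3 per degC, negative).
#' @param scaling [scaling_spec()] whose inverse maps limitation to yield in
#'   the generator.
#' @param overpass_local_time Local solar time of the emulated overpass
#'   (hours).
#' @param noise Per-variable observational noise: `nflh_cv` and `chl_cv`
#'   are multiplicative coefficients of variation, `sst_sd` an additive
#'   standard deviation (degC).
#' @param missing_frac Fraction of pixels masked (shared across variables).
#' @return An object of class `"scene_config"`.
#' @export
scene_config <- function(lat = seq(-4.5, 4.5, by = 1),
                         lon = seq(-149.5, -90.5, by = 1),
                         months = 220L, seed = 1L,
                         start = as.Date("2003-01-15"),
                         sst_clim = 26, enso_amp = 0.9, enso_ar1 = 0.9,
                         s_true = 0.03, l0 = 0.39,
                         chl_clim = 0.25, chl_sst_slope = -0.03,
                         scaling = scaling_spec(),
                         overpass_local_time = 13.5,
                         noise = list(nflh_cv = 0.05, chl_cv = 0.05,
                                      sst_sd = 0.05),
                         missing_frac = 0.02) {
  stopifnot(months >= 24, enso_ar1 >= 0, enso_ar1 < 1, enso_amp >= 0,
            inherits(scaling, "scaling_spec"),
            missing_frac >= 0, missing_frac < 1)
  noise <- utils::modifyList(list(nflh_cv = 0, chl_cv = 0, sst_sd = 0),
                             noise)
  stopifnot(all(unlist(noise) >= 0))
  structure(
    list(lat = lat, lon = lon, months = as.integer(months),
         seed = as.integer(seed), start = as.Date(start),
         sst_clim = sst_clim, enso_amp = enso_amp, enso_ar1 = enso_ar1,
         s_true = s_true, l0 = l0, chl_clim = chl_clim,
         chl_sst_slope = chl_sst_slope, scaling = scaling,
         overpass_local_time = overpass_local_time,
         noise = noise, missing_frac = missing_frac),
    class = "scene_config"
  )
}

# shared ENSO AR(1) anomaly: one realization per config seed, so the
# observation and model records of a scene see the same physical forcing
.gen_enso <- function(cfg) {
  .with_seed(cfg$seed, {
    burn <- 60L
    n <- cfg$months + burn
    innov_sd <- cfg$enso_amp * sqrt(1 - cfg$enso_ar1^2)
    e <- numeric(n)
    z <- stats::rnorm(n, sd = innov_sd)
    for (t in 2:n) e[t] <- cfg$enso_ar1 * e[t - 1] + z[t]
    e[(burn + 1):n]
  })
}

.scene_time <- function(cfg) {
  seq(cfg$start, by = "month", length.out = cfg$months)
}

#' Generate a synthetic satellite record (nFLH, chlorophyll, SST)
#'
#' SST is climatology plus a spatially coherent AR(1) ENSO anomaly. The
#' true limitation is `clip(l0 + s_true * anomaly, 0, lim_max)`; the true
#' yield is its inverse-scaled image; chlorophyll responds linearly to the
#' anomaly; and `nFLH = yield * chl / cos(SZA)` at the configured overpass
#' time, so that the analysis-side denormalization inverts the geometry
#' exactly. Observational noise and a shared missing-value mask are applied
#' last. A warning is raised if the limitation clip saturates more than 20%
#' of months (regression attenuation).
#'
#' @param cfg A [scene_config()].
#' @return List with `nflh`, `chl`, `sst` ([gridded_field()]s sharing one
#'   mask) and `truth` (the ENSO anomaly, limitation, yield and chlorophyll
#'   series plus the clipped fraction).
#' @export
gen_satellite_record <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  e <- .gen_enso(cfg)
  time <- .scene_time(cfg)
  nlat <- length(cfg$lat)
  nlon <- length(cfg$lon)
  nt <- cfg$months
  sp <- cfg$scaling

  lim_raw <- cfg$l0 + cfg$s_true * e
  lim <- pmin(pmax(lim_raw, 0), sp$lim_max)
  clip_frac <- mean(lim != lim_raw)
  if (clip_frac > 0.2) {
    warning(sprintf(
      "limitation clip saturates %.0f%% of months: regression attenuation",
      100 * clip_frac), call. = FALSE)
  }
  fchl_true <- sp$fchl_lower +
    lim * (sp$fchl_upper - sp$fchl_lower) / sp$lim_max
  chl_true <- pmax(cfg$chl_clim + cfg$chl_sst_slope * e, 1e-3)

  cosz <- cos(outer(seq_len(nt), seq_len(nlat), function(t, i) {
    solar_zenith(cfg$lat[i], time[t], cfg$overpass_local_time)
  }) * pi / 180)

  expand_t <- function(v) array(rep(v, times = nlat * nlon),
                                dim = c(nt, nlat, nlon))
  expand_ti <- function(m) array(rep(m, times = nlon),
                                 dim = c(nt, nlat, nlon))

  sst_true <- expand_t(cfg$sst_clim + e)
  nflh_true <- expand_t(fchl_true * chl_true) / expand_ti(cosz)
  chl_arr <- expand_t(chl_true)

  ncell <- nt * nlat * nlon
  fields <- .with_seed(cfg$seed + 7919L, {
    nflh_obs <- nflh_true * (1 + stats::rnorm(ncell, sd = cfg$noise$nflh_cv))
    chl_obs <- chl_arr * (1 + stats::rnorm(ncell, sd = cfg$noise$chl_cv))
    sst_obs <- sst_true + stats::rnorm(ncell, sd = cfg$noise$sst_sd)
    miss <- stats::runif(ncell) < cfg$missing_frac
    nflh_obs[miss] <- NA_real_
    chl_obs[miss] <- NA_real_
    sst_obs[miss] <- NA_real_
    list(nflh = nflh_obs, chl = chl_obs, sst = sst_obs)
  })

  list(
    nflh = gridded_field(fields$nflh, time, cfg$lat, cfg$lon, "nflh",
                         "W m-2 sr-1 um-1"),
    chl = gridded_field(fields$chl, time, cfg$lat, cfg$lon, "chl",
                        "mg m-3"),
    sst = gridded_field(fields$sst, time, cfg$lat, cfg$lon, "sst",
                        "degC"),
    truth = list(enso = e, limitation = lim, fchl = fchl_true,
                 chl = chl_true, clip_frac = clip_frac)
  )
}

#' Generate synthetic model limitation fields for two phytoplankton groups
#'
#' Emulates monthly surface growth-limitation terms for diatoms and
#' nanophytoplankton whose carbon-biomass-weighted Fe-limitation index
#' (`1 - weighted mean l_fe`) tracks the scene's shared ENSO SST anomaly
#' with sensitivity `s_model`. The groups sit symmetrically (in the
#' biomass-weighted sense) around the target, offset by `group_offset`, so
#' the weighted term is exact before pixel noise.
#'
#' @param cfg The same [scene_config()] used for the satellite record; the
#'   model shares its ENSO realization (paired forcing).
#' @param s_model Model limitation-SST sensitivity (per degC).
#' @param group_offset Diatom limitation offset below the community mean.
#' @param biomass Named carbon-biomass weights `c(diatom = , nano = )`.
#' @param noise_sd Per-pixel Gaussian noise on each group's term.
#' @return List of [gridded_field()]s `l_fe_diatom`, `l_fe_nano`,
#'   `biomass_diatom`, `biomass_nano`, `sst`, plus `truth` (ENSO anomaly
#'   and target Fe-limitation series).
#' @export
gen_model_limitation <- function(cfg, s_model = 0.06, group_offset = 0.06,
                                 biomass = c(diatom = 1, nano = 3),
                                 noise_sd = 0.01) {
  stopifnot(inherits(cfg, "scene_config"), all(biomass >= 0),
            sum(biomass) > 0)
  e <- .gen_enso(cfg)
  time <- .scene_time(cfg)
  nlat <- length(cfg$lat)
  nlon <- length(cfg$lon)
  nt <- cfg$months

  fe_lim_target <- pmin(pmax(cfg$l0 + s_model * e, 0), 1)
  lbar <- 1 - fe_lim_target
  d_off <- group_offset
  n_off <- group_offset * biomass[["diatom"]] / max(biomass[["nano"]],
                                                    .Machine$double.eps)
  expand_t <- function(v) array(rep(v, times = nlat * nlon),
                                dim = c(nt, nlat, nlon))
  l_d <- expand_t(lbar - d_off)
  l_n <- expand_t(lbar + n_off)
  if (noise_sd > 0) {
    ncell <- nt * nlat * nlon
    noise <- .with_seed(cfg$seed + 104729L, {
      list(d = stats::rnorm(ncell, sd = noise_sd),
           n = stats::rnorm(ncell, sd = noise_sd))
    })
    l_d <- l_d + noise$d
    l_n <- l_n + noise$n
  }
  l_d <- pmin(pmax(l_d, 0), 1)
  l_n <- pmin(pmax(l_n, 0), 1)

  gf <- function(v, var, units) {
    gridded_field(v, time, cfg$lat, cfg$lon, var, units)
  }
  list(
    l_fe_diatom = gf(l_d, "l_fe_diatom", "1"),
    l_fe_nano = gf(l_n, "l_fe_nano", "1"),
    biomass_diatom = gf(expand_t(rep(biomass[["diatom"]], nt)),
                        "biomass_diatom", "carbon"),
    biomass_nano = gf(expand_t(rep(biomass[["nano"]], nt)),
                      "biomass_nano", "carbon"),
    sst = gf(expand_t(cfg$sst_clim + e), "sst", "degC"),
    truth = list(enso = e, fe_lim = fe_lim_target)
  )
}

#' Configuration for the synthetic shipboard hyperspectral transect
#'
#' @param wavelengths Spectral grid (nm), covering 320-950.
#' @param cadence_min Sampling cadence (minutes).
#' @param days Transect duration (days).
#' @param start First timestamp (UTC).
#' @param lat Transect latitude (degrees).
#' @param lon_start,lon_end Transect longitude span (degrees).
#' @param changepoint_lon Longitude of the Fe-to-N regime switch; records
#'   west of it are Fe-limited.
#' @param peak_center,peak_sigma Gaussian fluorescence emission peak centre
#'   and width (nm); the sun-induced emission peak sits near 680 nm.
#' @param yield_n Light-saturated F/Chl plateau of the N-limited regime
#'   (W m^-2 sr^-1 um^-1 \[mg Chl m^-3\]^-1).
#' @param yield_ratio Fe-limited over N-limited plateau ratio.
#' @param b_slope Light-limited initial slope of the yield-PAR response.
#' @param chl Chlorophyll a along the transect (mg m^-3).
#' @param par_max Clear-sky noon PAR (umol photons m^-2 s^-1).
#' @param baseline_amp Amplitude of the smooth non-fluorescence radiance
#'   baseline.
#' @param noise_cv Multiplicative radiance noise.
#' @param seed Integer seed.
#' @return An object of class `"ship_sim_config"`.
#' @export
ship_sim_config <- function(wavelengths = seq(320, 950, by = 1),
                            cadence_min = 5, days = 6,
                            start = as.POSIXct("2019-02-01 00:00:00",
                                               tz = "UTC"),
                            lat = 0, lon_start = -160, lon_end = -110,
                            changepoint_lon = -135,
                            peak_center = 683, peak_sigma = 10,
                            yield_n = 0.16, yield_ratio = 3.5,
                            b_slope = 0.002, chl = 0.2, par_max = 2000,
                            baseline_amp = 0.3, noise_cv = 0.05,
                            seed = 1L) {
  stopifnot(peak_center > min(wavelengths), peak_center < max(wavelengths),
            yield_ratio > 0, yield_n > 0, chl > 0, b_slope > 0)
  structure(
    list(wavelengths = as.numeric(wavelengths), cadence_min = cadence_min,
         days = days, start = start, lat = lat, lon_start = lon_start,
         lon_end = lon_end, changepoint_lon = changepoint_lon,
         peak_center = peak_center, peak_sigma = peak_sigma,
         yield_n = yield_n, yield_ratio = yield_ratio, b_slope = b_slope,
         chl = chl, par_max = par_max, baseline_amp = baseline_amp,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "ship_sim_config"
  )
}

# solve the OC3 polynomial for the band ratio giving a target chlorophyll;
# restricted to the monotone branch of the default coefficient set
.oc3_ratio_for_chl <- function(chl, coeffs = oc3_coefficients()) {
  target <- log10(chl)
  f <- function(r) {
    coeffs[1] + coeffs[2] * r + coeffs[3] * r^2 + coeffs[4] * r^3 +
      coeffs[5] * r^4 - target
  }
  10^stats::uniroot(f, c(-0.4, 0.75), tol = 1e-12)$root
}

#' Generate a synthetic shipboard hyperspectral transect
#'
#' Water-leaving radiance is a smooth baseline plus a Gaussian fluorescence
#' emission peak whose amplitude encodes
#' `FLH = yield(PAR, regime) * chl`: the per-unit-amplitude FLH of the peak
#' is computed with [compute_flh()] itself, so the configured yield is
#' recovered exactly by the analysis at zero noise. The yield follows the
#' saturating response `a * tanh(b * PAR / a)` with the regime-dependent
#' plateau (`yield_ratio` times higher west of the change-point), PAR
#' follows the clear-sky diel cycle at the ship position, and reflectance
#' spectra are constructed so the OC3 algorithm returns the configured
#' chlorophyll.
#'
#' @param cfg A [ship_sim_config()].
#' @return A [radiometry_record()] with attribute `"truth"` (regime,
#'   true yield, plateau values and chlorophyll).
#' @export
gen_ship_transect <- function(cfg) {
  stopifnot(inherits(cfg, "ship_sim_config"))
  n <- as.integer(cfg$days * 24 * 60 / cfg$cadence_min)
  time <- cfg$start + seq(0, by = cfg$cadence_min * 60, length.out = n)
  lon <- seq(cfg$lon_start, cfg$lon_end, length.out = n)
  lat <- rep(cfg$lat, n)
  regime <- ifelse(lon <= cfg$changepoint_lon, "fe_limited", "n_limited")

  lst <- local_solar_time(time, lon)
  sza <- solar_zenith(lat, as.Date(time, tz = "UTC"), lst)
  par <- cfg$par_max * pmax(0, cos(sza * pi / 180))

  a <- ifelse(regime == "fe_limited", cfg$yield_n * cfg$yield_ratio,
              cfg$yield_n)
  fchl_true <- tanh_response(par, a, cfg$b_slope)
  flh_true <- fchl_true * cfg$chl

  wl <- cfg$wavelengths
  gauss <- exp(-(wl - cfg$peak_center)^2 / (2 * cfg$peak_sigma^2))
  unit_flh <- compute_flh(wl, gauss)   # FLH per unit peak amplitude
  baseline <- cfg$baseline_amp *
    (0.4 + exp(-(wl - 440)^2 / (2 * 160^2)))

  lw <- outer(rep(1, n), baseline) + outer(flh_true / unit_flh, gauss)
  if (cfg$noise_cv > 0) {
    lw <- lw * .with_seed(cfg$seed, {
      matrix(1 + stats::rnorm(length(lw), sd = cfg$noise_cv), nrow = n)
    })
  }

  ratio <- .oc3_ratio_for_chl(cfg$chl)
  g <- 0.004
  anchors_wl <- c(320, 412, 443, 489, 547, 620, 750, 950)
  anchors_v <- c(ratio * g * 1.05, ratio * g * 1.02, ratio * g,
                 ratio * g * 0.8, g, g * 0.3, g * 0.02, g * 0.01)
  rrs_base <- stats::approx(anchors_wl, anchors_v, xout = wl,
                            rule = 2)$y
  rrs <- outer(rep(1, n), rrs_base)

  rec <- radiometry_record(wl, lw, rrs, time, lat, lon, par)
  attr(rec, "truth") <- list(regime = regime, fchl = fchl_true,
                             plateau = a, chl = cfg$chl,
                             b_slope = cfg$b_slope)
  rec
}

#' Generate a treatment-structured nutrient-addition bioassay table
#'
#' Triplicate lognormal chlorophyll responses per treatment, with the
#' control multiplier fixed at 1, plus per-bottle chlorophyll-normalized
#' active fluorescence in which every Fe-amended treatment sits
#' `fchl_fe_drop`-fold below the unamended pool (the field-scale contrast).
#' The lognormal noise is mean-exact, so `cv = 0` returns the multipliers
#' themselves.
#'
#' @param effects Named treatment -> chlorophyll multiplier map; a
#'   `control` entry with multiplier 1 is added if absent.
#' @param cv Lognormal coefficient of variation of the replicate noise.
#' @param seed Integer seed.
#' @param chl0 Control-bottle chlorophyll a (mg m^-3).
#' @param n_rep Replicates per treatment.
#' @param site Site label.
#' @param duration_days Incubation duration (attached as an attribute).
#' @param fchl_minus_fe Chlorophyll-normalized active fluorescence of the
#'   -Fe pool (relative units).
#' @param fchl_fe_drop Fold-reduction of that yield under Fe amendment.
#' @return Tibble (`site`, `treatment`, `replicate`, `chl`,
#'   `fchl_active`) with attributes `duration_days` and `effects`.
#' @export
gen_bioassay <- function(effects = c(control = 1, `+Fe` = 2, `+N` = 1.1,
                                     `+N+Fe` = 2.2),
                         cv = 0.1, seed = 1L, chl0 = 0.2, n_rep = 3L,
                         site = "site1", duration_days = 2,
                         fchl_minus_fe = 3.2, fchl_fe_drop = 3.2) {
  stopifnot(all(effects > 0), cv >= 0, chl0 > 0, n_rep >= 1)
  if (!"control" %in% names(effects)) {
    effects <- c(control = 1, effects)
  }
  effects[["control"]] <- 1
  trt <- rep(names(effects), each = n_rep)
  mult <- rep(unname(effects), each = n_rep)
  has_fe <- grepl("fe", tolower(trt), fixed = TRUE)
  fchl_mean <- ifelse(has_fe, fchl_minus_fe / fchl_fe_drop, fchl_minus_fe)
  n <- length(trt)
  draws <- .with_seed(seed, {
    if (cv == 0) {
      list(chl = rep(1, n), fchl = rep(1, n))
    } else {
      sdlog <- sqrt(log(1 + cv^2))
      # meanlog offset makes the draws mean-exact
      list(chl = stats::rlnorm(n, -sdlog^2 / 2, sdlog),
           fchl = stats::rlnorm(n, -sdlog^2 / 2, sdlog))
    }
  })
  out <- tibble::tibble(
    site = site,
    treatment = trt,
    replicate = rep(seq_len(n_rep), times = length(effects)),
    chl = chl0 * mult * draws$chl,
    fchl_active = fchl_mean * draws$fchl
  )
  attr(out, "duration_days") <- duration_days
  attr(out, "effects") <- effects
  out
}

#' Generate a diel active-fluorometry (Fo/Fm/sigmaPSII) series
#'
#' Emulates the contrasting diel fluorescence physiology of the two
#' nutrient regimes: the Fe-limited regime has lower dawn/dusk Fv/Fm and
#' pronounced night-time reductions (mirrored in sigmaPSII); the N-limited
#' regime has higher dawn/dusk values and much weaker night-time dips. Both
#' regimes share the daytime non-photochemical-quenching depression. The
#' filtrate blank is added to both Fo and Fm, so the analysis-side blank
#' correction recovers the true ratio exactly at zero noise.
#'
#' @param days Series duration (days).
#' @param regime `"fe_limited"` or `"n_limited"`.
#' @param blank Filtrate blank fluorescence added to Fo and Fm.
#' @param seed Integer seed.
#' @param cadence_min Sampling cadence (minutes).
#' @param lat,lon Ship position (degrees).
#' @param start First timestamp (UTC).
#' @param noise_sd Additive instrument noise on Fo and Fm.
#' @return Tibble (`time`, `f_o`, `f_m`, `sigma_psii`, `blank`) with
#'   attribute `"truth"` (true Fv/Fm series and regime parameters).
#' @export
gen_diel_frrf <- function(days = 3, regime = c("fe_limited", "n_limited"),
                          blank = 0.05, seed = 1L, cadence_min = 5,
                          lat = 0, lon = -140,
                          start = as.POSIXct("2019-02-01 00:00:00",
                                             tz = "UTC"),
                          noise_sd = 0.003) {
  regime <- match.arg(regime)
  stopifnot(blank >= 0, noise_sd >= 0)
  p <- switch(regime,
    fe_limited = list(dawn = 0.35, day_npq = 0.12, night_dip = 0.08,
                      sigma_base = 5.5, sigma_night_frac = 0.15),
    n_limited = list(dawn = 0.52, day_npq = 0.12, night_dip = 0.02,
                     sigma_base = 4.5, sigma_night_frac = 0)
  )
  n <- as.integer(days * 24 * 60 / cadence_min)
  time <- start + seq(0, by = cadence_min * 60, length.out = n)
  lst <- local_solar_time(time, lon)
  sza <- solar_zenith(rep(lat, n), as.Date(time, tz = "UTC"), lst)
  elev <- (90 - sza) * pi / 180
  rel_light <- pmax(0, sin(elev))          # daytime NPQ forcing
  night_shape <- pmax(0, -sin(elev))       # peaks at solar midnight

  fvfm_true <- p$dawn - p$day_npq * rel_light - p$night_dip * night_shape
  sigma_true <- p$sigma_base * (1 - p$sigma_night_frac * night_shape)

  f_m_true <- rep(1, n)
  f_o_true <- f_m_true * (1 - fvfm_true)
  obs <- .with_seed(seed, {
    list(f_o = f_o_true + blank + stats::rnorm(n, sd = noise_sd),
         f_m = f_m_true + blank + stats::rnorm(n, sd = noise_sd))
  })
  f_m <- pmax(obs$f_m, blank + 1e-6)
  f_o <- pmin(pmax(obs$f_o, 0), f_m)

  out <- tibble::tibble(time = time, f_o = f_o, f_m = f_m,
                        sigma_psii = sigma_true, blank = blank)
  attr(out, "truth") <- list(fvfm = fvfm_true, params = p,
                             regime = regime, lat = lat, lon = lon)
  out
}
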