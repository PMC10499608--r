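# Small scene used throughout: coarser grid and shorter record than the
# defaults, enough to exercise every coupling quickly.
small_scene <- function(...) {
  scene_config(lat = seq(-4, 4, by = 2), lon = seq(-148, -92, by = 4),
               months = 60, ...)
}

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_scene(seed = 21)
  a <- gen_satellite_record(cfg)
  b <- gen_satellite_record(cfg)
  expect_identical(a$nflh$values, b$nflh$values)
  expect_identical(a$sst$values, b$sst$values)

  m1 <- gen_model_limitation(cfg, s_model = 0.06)
  m2 <- gen_model_limitation(cfg, s_model = 0.06)
  expect_identical(m1$l_fe_diatom$values, m2$l_fe_diatom$values)

  s1 <- gen_ship_transect(ship_sim_config(days = 1, seed = 5))
  s2 <- gen_ship_transect(ship_sim_config(days = 1, seed = 5))
  expect_identical(s1$lw, s2$lw)

  f1 <- gen_diel_frrf(days = 1, seed = 5)
  f2 <- gen_diel_frrf(days = 1, seed = 5)
  expect_identical(f1$f_o, f2$f_o)

  b1 <- gen_bioassay(seed = 5)
  b2 <- gen_bioassay(seed = 5)
  expect_identical(b1$chl, b2$chl)

  # a different seed changes the realization
  expect_false(identical(
    a$nflh$values, gen_satellite_record(small_scene(seed = 22))$nflh$values))
})

test_that("the ENSO anomaly has the configured amplitude and vanishes when disabled", {
  still <- gen_satellite_record(small_scene(seed = 1, enso_amp = 0))
  expect_identical(still$truth$enso, rep(0, 60))
  expect_equal(max(still$sst$values, na.rm = TRUE),
               min(still$sst$values, na.rm = TRUE), tolerance = 0.5)

  # stationary sd approaches enso_amp over long records
  long <- scene_config(lat = 0, lon = -120, months = 2400, seed = 2,
                       enso_amp = 0.9, enso_ar1 = 0.9)
  expect_equal(sd(gen_satellite_record(long)$truth$enso), 0.9,
               tolerance = 0.15)
})

test_that("a noise-free scene encodes the prescribed limitation-SST sensitivity exactly", {
  cfg <- small_scene(seed = 3, s_true = 0.03,
                     noise = list(nflh_cv = 0, chl_cv = 0, sst_sd = 0),
                     missing_frac = 0)
  scene <- gen_satellite_record(cfg)
  dsst <- anomalies(region_series(scene$sst, c(-5, 5, -150, -90))$value)
  fit <- rma_regression(dsst, anomalies(scene$truth$limitation),
                        n_boot = 0)
  expect_equal(fit$slope, 0.03, tolerance = 1e-10)
  expect_equal(scene$truth$clip_frac, 0)

  # the yield field is the inverse image of the limitation under the
  # analysis-side scaling
  expect_equal(scale_fchl(scene$truth$fchl, cfg$scaling),
               scene$truth$limitation, tolerance = 1e-12)
})

test_that("generated chlorophyll keeps at least 95% of pixels inside the mask", {
  scene <- gen_satellite_record(small_scene(seed = 4))
  m <- mask_chl(scene$chl)
  present <- !is.na(scene$chl$values)
  expect_gte(sum(m) / sum(present), 0.95)
})

test_that("model limitation fields weight to the target and respect s_model", {
  cfg <- small_scene(seed = 5)
  mod <- gen_model_limitation(cfg, s_model = 0.06, noise_sd = 0)
  fe_lim <- model_fe_lim(
    list(mod$l_fe_diatom, mod$l_fe_nano),
    list(mod$biomass_diatom, mod$biomass_nano)
  )
  # biomass-weighted term reproduces the target series at every pixel
  expect_equal(fe_lim$values[, 1, 1], mod$truth$fe_lim, tolerance = 1e-12)

  dsst <- anomalies(region_series(mod$sst, c(-5, 5, -150, -90))$value)
  fit <- rma_regression(dsst, anomalies(mod$truth$fe_lim), n_boot = 0)
  expect_equal(fit$slope, 0.06, tolerance = 1e-10)

  # s_model = 0 gives a flat limitation field
  flat <- gen_model_limitation(cfg, s_model = 0, noise_sd = 0)
  expect_equal(diff(range(flat$truth$fe_lim)), 0)

  # zero offset with equal biomass: both groups carry the same term
  same <- gen_model_limitation(cfg, s_model = 0.06, group_offset = 0,
                               biomass = c(diatom = 1, nano = 1),
                               noise_sd = 0)
  expect_identical(same$l_fe_diatom$values, same$l_fe_nano$values)

  # the observation and model records share one ENSO realization
  scene <- gen_satellite_record(cfg)
  expect_identical(scene$truth$enso, mod$truth$enso)
})

test_that("ship transect spectra encode the configured yield and chlorophyll", {
  cfg <- ship_sim_config(days = 2, noise_cv = 0)
  rec <- gen_ship_transect(cfg)
  truth <- attr(rec, "truth")

  # FLH of the generated spectra matches yield * chl up to the small
  # curvature of the smooth baseline over the FLH bands
  flh <- compute_flh(rec$wavelengths, rec$lw)
  baseline_flh <- compute_flh(
    rec$wavelengths,
    cfg$baseline_amp * (0.4 + exp(-(rec$wavelengths - 440)^2 / (2 * 160^2))))
  expect_equal(flh, truth$fchl * cfg$chl + baseline_flh, tolerance = 1e-10)
  expect_lt(abs(baseline_flh), 0.02 * max(truth$fchl) * cfg$chl)

  # doubling chlorophyll doubles the fluorescence peak amplitude
  cfg2 <- ship_sim_config(days = 2, noise_cv = 0, chl = 2 * cfg$chl)
  flh2 <- compute_flh(rec$wavelengths, gen_ship_transect(cfg2)$lw)
  expect_equal(flh2 - baseline_flh, 2 * (flh - baseline_flh),
               tolerance = 1e-10)

  # OC3 on the generated reflectance returns the configured chlorophyll
  chl_oc3 <- compute_oc3_chl(rec$wavelengths, rec$rrs)
  expect_equal(unique(round(chl_oc3, 10)), cfg$chl, tolerance = 1e-6)

  # the regime switch happens at the configured change-point
  expect_identical(truth$regime,
                   ifelse(rec$lon <= cfg$changepoint_lon,
                          "fe_limited", "n_limited"))
})

test_that("bioassay tables have exact means at zero noise and proper null behaviour", {
  exact <- gen_bioassay(effects = c(control = 1, `+Fe` = 2, `+N` = 1.5),
                        cv = 0, chl0 = 0.2)
  expect_equal(exact$chl[exact$treatment == "+Fe"], rep(0.4, 3))
  expect_equal(exact$chl[exact$treatment == "control"], rep(0.2, 3))
  expect_equal(attr(exact, "duration_days"), 2)

  # all multipliers 1: downstream ANOVA finds nothing in >= 90% of seeds
  hits <- vapply(1:100, function(s) {
    b <- gen_bioassay(effects = c(control = 1, `+Fe` = 1, `+N` = 1,
                                  `+N+Fe` = 1), cv = 0.1, seed = s)
    any(anova_tukey(split(b$chl, b$treatment))$table$significant)
  }, logical(1))
  expect_gte(mean(!hits), 0.90)

  # a 2-fold response at 5% noise is flagged against the control
  b2 <- gen_bioassay(effects = c(control = 1, `+Fe` = 2), cv = 0.05,
                     seed = 7)
  res <- anova_tukey(split(b2$chl, b2$treatment))
  expect_true(all(res$table$significant[grepl("control",
                                              res$table$pair)]))
})

test_that("diel fluorometry encodes the regime contrast and the blank exactly", {
  fe <- gen_diel_frrf(days = 2, regime = "fe_limited", blank = 0.08,
                      noise_sd = 0, seed = 1)
  nl <- gen_diel_frrf(days = 2, regime = "n_limited", blank = 0.08,
                      noise_sd = 0, seed = 1)

  # blank correction recovers the true ratio; blank = 0 is the identity
  expect_equal(fvfm(fe$f_o, fe$f_m, fe$blank), attr(fe, "truth")$fvfm,
               tolerance = 1e-12)
  fe0 <- gen_diel_frrf(days = 2, regime = "fe_limited", blank = 0,
                       noise_sd = 0, seed = 1)
  expect_equal(fvfm(fe0$f_o, fe0$f_m, 0), attr(fe0, "truth")$fvfm,
               tolerance = 1e-12)

  # regime contrast: Fe limitation lowers Fv/Fm and deepens the
  # night-time reductions
  v_fe <- fvfm(fe$f_o, fe$f_m, fe$blank)
  v_nl <- fvfm(nl$f_o, nl$f_m, nl$blank)
  expect_lt(max(v_fe), max(v_nl))
  night <- diel_partition(fe$time, attr(fe, "truth")$lat,
                          attr(fe, "truth")$lon) == "night"
  dip_fe <- max(v_fe[night]) - min(v_fe[night])
  dip_nl <- max(v_nl[night]) - min(v_nl[night])
  expect_gt(dip_fe, 2 * dip_nl)

  # sigma-PSII night-time reduction only under Fe limitation
  expect_gt(diff(range(fe$sigma_psii)), 0.5)
  expect_lt(diff(range(nl$sigma_psii)), 1e-12)
})
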