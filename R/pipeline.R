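# Pipeline orchestration: a single configuration object, deterministic
# execution of simulate -> ship -> field -> satellite -> compare, and a
# machine-readable report.

#' Pipeline configuration
#'
#' Collects every stage parameter in one resolved object. All seeds derive
#' from the single `seed`, so a configuration determines the run completely.
#'
#' @param seed Master integer seed.
#' @param scene [scene_config()] for the satellite/model scene.
#' @param ship [ship_sim_config()] for the radiometry transect.
#' @param s_model Model limitation-SST sensitivity handed to
#'   [gen_model_limitation()].
#' @param scaling [scaling_spec()] for the observation-side limitation
#'   index.
#' @param box Regional lat/lon box `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param chl_range Chlorophyll validity bounds (mg m^-3) for
#'   [mask_chl()].
#' @param overpass_local_time Local solar time for the nFLH
#'   denormalization.
#' @param midday_window Local-time window for [midday_extract()].
#' @param bioassay_effects,bioassay_cv Treatment multipliers and noise for
#'   [gen_bioassay()].
#' @param scan_pct Threshold-scan percentage for [sensitivity()].
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            scene = scene_config(seed = seed),
                            ship = ship_sim_config(seed = seed + 1L),
                            s_model = 0.06,
                            scaling = scaling_spec(),
                            box = c(-5, 5, -150, -90),
                            chl_range = c(0.1, 0.4),
                            overpass_local_time = 13.5,
                            midday_window = c(12, 15),
                            bioassay_effects = c(control = 1, `+Fe` = 2,
                                                 `+N` = 1.1, `+N+Fe` = 2.2),
                            bioassay_cv = 0.1,
                            scan_pct = 10) {
  structure(
    list(seed = as.integer(seed), scene = scene, ship = ship,
         s_model = s_model, scaling = scaling, box = box,
         chl_range = chl_range,
         overpass_local_time = overpass_local_time,
         midday_window = midday_window,
         bioassay_effects = bioassay_effects, bioassay_cv = bioassay_cv,
         scan_pct = scan_pct),
    class = "pipeline_config"
  )
}

# recursively strip classes and render dates, so configs serialize to YAML
.serialize_config <- function(x) {
  if (inherits(x, "Date") || inherits(x, "POSIXct")) return(format(x))
  if (is.list(x)) {
    return(lapply(unclass(x), .serialize_config))
  }
  if (is.numeric(x) || is.character(x) || is.logical(x)) {
    if (!is.null(names(x))) return(as.list(x))
    return(x)
  }
  x
}

#' Run the full diagnostic pipeline on synthetic inputs
#'
#' Executes the selected stages in order: `simulate` (generate the
#' satellite scene, paired model fields, ship transect, bioassay table and
#' diel fluorometry), `ship` (yield series, midday extraction, PAR
#' response), `field` (growth rates, pooled +/-Fe contrast, blank-corrected
#' Fv/Fm), `satellite` (denormalize, mask, yield field, regional anomaly
#' series) and `compare` (the sensitivity ratio). Identical configurations
#' give identical outputs. When `out_dir` is supplied, the resolved
#' configuration (YAML), the regional series and yield tables (CSV) and the
#' report (JSON) are written next to each other.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory (created if absent).
#' @param stages Character subset of
#'   `c("simulate", "ship", "field", "satellite", "compare")`; later stages
#'   require the earlier ones.
#' @return A report list (invisibly when writing): per-stage headline
#'   numbers and the underlying result objects under `$objects`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         stages = c("simulate", "ship", "field",
                                    "satellite", "compare")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  all_stages <- c("simulate", "ship", "field", "satellite", "compare")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(s) {
    if (!s %in% stages) {
      stop(sprintf("stage `%s` requires stage `%s` in the same run",
                   setdiff(all_stages, stages)[1], s), call. = FALSE)
    }
  }
  report <- list(seed = cfg$seed)
  objects <- list()

  ## simulate ---------------------------------------------------------
  if (!"simulate" %in% stages) {
    stop("every run starts from the `simulate` stage", call. = FALSE)
  }
  scene <- gen_satellite_record(cfg$scene)
  model <- gen_model_limitation(cfg$scene, s_model = cfg$s_model)
  shiprec <- gen_ship_transect(cfg$ship)
  bio <- gen_bioassay(effects = cfg$bioassay_effects, cv = cfg$bioassay_cv,
                      seed = cfg$seed + 2L)
  frrf <- gen_diel_frrf(regime = "fe_limited", seed = cfg$seed + 3L)
  objects$scene <- scene
  objects$model <- model
  report$simulate <- list(
    months = cfg$scene$months,
    grid = c(length(cfg$scene$lat), length(cfg$scene$lon)),
    ship_records = nrow(shiprec$lw),
    clip_frac = scene$truth$clip_frac
  )

  ## ship -------------------------------------------------------------
  if ("ship" %in% stages) {
    yield <- build_yield_series(shiprec)
    mid <- midday_extract(yield, window = cfg$midday_window)
    pr <- par_response(yield)
    west <- mid$points$lon <= cfg$ship$changepoint_lon
    ratio_mid <- mean(mid$points$fchl[west], na.rm = TRUE) /
      mean(mid$points$fchl[!west], na.rm = TRUE)
    objects$yield <- yield
    objects$midday <- mid
    objects$par_response <- pr
    report$ship <- list(
      n_records = nrow(yield),
      n_midday = nrow(mid$points),
      midday_fchl_regime_ratio = ratio_mid,
      tanh_a = if (!pr$degenerate) pr$fit$a else NA_real_,
      tanh_b = if (!pr$degenerate) pr$fit$b else NA_real_
    )
  }

  ## field ------------------------------------------------------------
  if ("field" %in% stages) {
    ctrl <- mean(bio$chl[bio$treatment == "control"])
    trt_means <- tapply(bio$chl, bio$treatment, mean)
    rates <- net_growth_rate(trt_means, ctrl,
                             attr(bio, "duration_days"))
    contrast <- pool_fe_contrast(bio, response = "fchl_active")
    fv_corr <- fvfm(frrf$f_o, frrf$f_m, frrf$blank)
    objects$bioassay <- bio
    objects$fe_contrast <- contrast
    report$field <- list(
      growth_rates = as.list(rates),
      fe_pool_fold_change = contrast$minus_fe$mean / contrast$plus_fe$mean,
      fe_pool_p = contrast$test$p_value,
      fvfm_mean = mean(fv_corr)
    )
  }

  ## satellite --------------------------------------------------------
  if ("satellite" %in% stages || "compare" %in% stages) {
    flh <- denormalize_nflh(scene$nflh, cfg$overpass_local_time)
    msk <- mask_chl(scene$chl, cfg$chl_range[1], cfg$chl_range[2])
    fs <- fchl_sat(flh, scene$chl, msk)
    fchl_rs <- region_series(fs, cfg$box)
    sst_rs <- region_series(scene$sst, cfg$box)
    obs_series <- tibble::tibble(time = fchl_rs$time,
                                 fchl = fchl_rs$value,
                                 sst = sst_rs$value)
    objects$fchl_sat <- fs
    objects$obs_series <- obs_series
    report$satellite <- list(
      retained_pixel_frac = mean(msk),
      months_flagged = sum(fchl_rs$flagged)
    )
  }

  ## compare ----------------------------------------------------------
  if ("compare" %in% stages) {
    fe_lim <- model_fe_lim(
      list(model$l_fe_diatom, model$l_fe_nano),
      list(model$biomass_diatom, model$biomass_nano)
    )
    model_rs <- region_series(fe_lim, cfg$box)
    model_sst_rs <- region_series(model$sst, cfg$box)
    model_series <- tibble::tibble(time = model_rs$time,
                                   fe_lim = model_rs$value,
                                   sst = model_sst_rs$value)
    rep_sens <- sensitivity(obs_series, model_series, spec = cfg$scaling,
                            scan_pct = cfg$scan_pct)
    objects$model_series <- model_series
    objects$sensitivity <- rep_sens
    report$compare <- list(
      obs_slope = rep_sens$obs$slope,
      obs_r2 = rep_sens$obs$r_squared,
      model_slope = rep_sens$model$slope,
      model_r2 = rep_sens$model$r_squared,
      sensitivity_ratio = rep_sens$ratio,
      scan_max_change_pct = max(abs(
        rep_sens$threshold_scan$ratio_change_pct), na.rm = TRUE)
    )
  }

  report$objects <- objects

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(.serialize_config(cfg),
                     file.path(out_dir, "config.yaml"))
    if (!is.null(objects$yield)) {
      utils::write.csv(objects$yield, file.path(out_dir, "yield.csv"),
                       row.names = FALSE)
    }
    if (!is.null(objects$obs_series)) {
      utils::write.csv(objects$obs_series,
                       file.path(out_dir, "obs_series.csv"),
                       row.names = FALSE)
    }
    if (!is.null(objects$model_series)) {
      utils::write.csv(objects$model_series,
                       file.path(out_dir, "model_series.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report[setdiff(names(report), "objects")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
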