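# Conversion of F/Chl to a model-comparable Fe-limitation index, the
# biomass-weighted model limitation term, and the emergent-constraint
# comparison of observed versus modelled SST sensitivity.

#' Scaling specification mapping F/Chl to the model limitation range
#'
#' The satellite fluorescence yield is mapped affinely onto the limitation
#' range of the biogeochemical model: `fchl_lower` maps to 0 (no Fe
#' limitation) and `fchl_upper` to `lim_max`, the maximum Fe limitation the
#' model predicts. Defaults: lower anchor 0, upper anchor
#' 0.7 W m^-2 sr^-1 um^-1 \[mg Chl m^-3\]^-1 (the yield above which the
#' global pixel fraction reaches an asymptote), ceiling 0.78. `lim_max` is
#' configuration sourced from the model, never inferred from the data.
#'
#' @param fchl_lower Yield mapping to limitation 0.
#' @param fchl_upper Yield mapping to limitation `lim_max`; must exceed
#'   `fchl_lower`.
#' @param lim_max Limitation ceiling in (0, 1\].
#' @param clip Clip scaled values into \[0, lim_max\].
#' @return An object of class `"scaling_spec"`.
#' @export
scaling_spec <- function(fchl_lower = 0, fchl_upper = 0.7, lim_max = 0.78,
                         clip = TRUE) {
  stopifnot(is.numeric(fchl_lower), is.numeric(fchl_upper),
            fchl_upper > fchl_lower, lim_max > 0, lim_max <= 1,
            is.logical(clip))
  structure(list(fchl_lower = fchl_lower, fchl_upper = fchl_upper,
                 lim_max = lim_max, clip = clip),
            class = "scaling_spec")
}

#' Scale F/Chl to an Fe-limitation index
#'
#' `limitation = lim_max * (fchl - fchl_lower) / (fchl_upper - fchl_lower)`,
#' clipped into \[0, lim_max\] when the spec requests it. Affine and
#' order-preserving below the clip, so regression slopes propagate by the
#' constant factor `lim_max / (fchl_upper - fchl_lower)` on clip-free
#' series. Missing yields stay missing.
#'
#' @param fchl Numeric vector/array of yields, or a [gridded_field()].
#' @param spec A [scaling_spec()].
#' @return Limitation values of the same shape (a `gridded_field` named
#'   `"fe_lim"` for field input).
#' @export
scale_fchl <- function(fchl, spec = scaling_spec()) {
  stopifnot(inherits(spec, "scaling_spec"))
  f <- function(v) {
    lim <- spec$lim_max * (v - spec$fchl_lower) /
      (spec$fchl_upper - spec$fchl_lower)
    if (spec$clip) lim <- pmin(pmax(lim, 0), spec$lim_max)
    lim
  }
  if (inherits(fchl, "gridded_field")) {
    return(.gf_map(fchl, f, var = "fe_lim", units = "1"))
  }
  f(fchl)
}

#' Biomass-weighted model Fe-limitation term
#'
#' The model reports, per phytoplankton group, the fractional Fe limitation
#' of maximum growth `l_fe` in \[0, 1\] (1 = unlimited growth). Weighting by
#' each group's carbon biomass and subtracting from 1 gives
#' `fe_lim = 1 - sum(biomass_i * l_fe_i) / sum(biomass_i)`, so higher values
#' mean stronger Fe limitation. Invariant to uniform rescaling of all
#' biomasses.
#'
#' @param l_fe List of group growth-limitation terms (numeric
#'   vectors/arrays of a common shape, or [gridded_field()]s on a common
#'   grid), values in \[0, 1\].
#' @param biomass List of matching carbon-biomass weights (same shapes, or
#'   scalars), non-negative with positive totals everywhere.
#' @return Fe-limitation term of the common shape (a `gridded_field` named
#'   `"fe_lim"` for field input).
#' @export
model_fe_lim <- function(l_fe, biomass) {
  stopifnot(is.list(l_fe), is.list(biomass),
            length(l_fe) == length(biomass), length(l_fe) >= 1L)
  is_gf <- inherits(l_fe[[1]], "gridded_field")
  template <- if (is_gf) l_fe[[1]] else NULL
  get_vals <- function(x) if (inherits(x, "gridded_field")) x$values else x
  lv <- lapply(l_fe, get_vals)
  bv <- lapply(biomass, get_vals)
  rng <- range(unlist(lapply(lv, range, na.rm = TRUE)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("l_fe terms must lie in [0, 1]", call. = FALSE)
  }
  if (any(unlist(lapply(bv, min, na.rm = TRUE)) < 0)) {
    stop("biomasses must be non-negative", call. = FALSE)
  }
  num <- Reduce(`+`, Map(`*`, bv, lv))
  den <- Reduce(`+`, Map(function(b, l) b + 0 * l, bv, lv))
  if (any(den == 0, na.rm = TRUE)) {
    stop("zero total biomass at some cells", call. = FALSE)
  }
  fe_lim <- 1 - num / den
  if (is_gf) {
    return(gridded_field(fe_lim, template$time, template$lat,
                         template$lon, var = "fe_lim", units = "1"))
  }
  fe_lim
}

#' Emergent-constraint comparison of Fe-limitation SST sensitivity
#'
#' Regresses the observation-derived and model Fe-limitation anomaly series
#' on their SST anomalies (value minus record average) with the
#' ranged-major-axis estimator, and reports the ratio of model to observed
#' slope — the factor by which the model over- (ratio > 1) or
#' under-responds (ratio < 1) to ENSO-driven SST change. A threshold scan
#' repeats the observational regression with the upper scaling anchor
#' perturbed by `+/- scan_pct` percent, probing the robustness of the ratio
#' to that operational choice.
#'
#' @param obs_series Data frame with `time`, `fchl` (regional satellite
#'   yield) and `sst` columns; >= `min_months` rows.
#' @param model_series Data frame with `time`, `fe_lim` and `sst` columns.
#' @param spec [scaling_spec()] applied to the observed yields.
#' @param scan_pct Percentage perturbation of `fchl_upper` for the scan.
#' @param n_boot Bootstrap resamples for slope confidence intervals
#'   (0 skips them; the reliability flag then falls back to the
#'   regression p-value).
#' @param seed Seed for the bootstrap.
#' @param min_months Minimum record length for anomaly work.
#' @return An object of class `"sensitivity_report"`: list with `obs` and
#'   `model` ([rma_regression()] results), `ratio`, `reliable`,
#'   `threshold_scan` (tibble `pct`, `fchl_upper`, `obs_slope`, `ratio`,
#'   `ratio_change_pct`) and `n_months`.
#' @export
sensitivity <- function(obs_series, model_series, spec = scaling_spec(),
                        scan_pct = 10, n_boot = 0L, seed = NULL,
                        min_months = 24L) {
  stopifnot(all(c("time", "fchl", "sst") %in% names(obs_series)),
            all(c("time", "fe_lim", "sst") %in% names(model_series)))
  ok_o <- stats::complete.cases(obs_series[c("fchl", "sst")])
  ok_m <- stats::complete.cases(model_series[c("fe_lim", "sst")])
  if (sum(ok_o) < min_months || sum(ok_m) < min_months) {
    stop(sprintf("need >= %d complete months in both series", min_months),
         call. = FALSE)
  }
  obs <- obs_series[ok_o, ]
  mod <- model_series[ok_m, ]

  fit_obs <- function(sp) {
    lim <- scale_fchl(obs$fchl, sp)
    rma_regression(anomalies(obs$sst), anomalies(lim),
                   n_boot = n_boot, seed = seed)
  }
  obs_fit <- fit_obs(spec)
  model_fit <- rma_regression(anomalies(mod$sst), anomalies(mod$fe_lim),
                              n_boot = n_boot, seed = seed)

  reliable <- if (n_boot > 0L) {
    !(obs_fit$slope_ci_low <= 0 && obs_fit$slope_ci_high >= 0)
  } else {
    obs_fit$p_value < 0.05
  }
  ratio <- if (obs_fit$slope != 0) model_fit$slope / obs_fit$slope else
    NA_real_

  pcts <- c(-scan_pct, 0, scan_pct)
  scan <- lapply(pcts, function(p) {
    up <- spec$fchl_upper * (1 + p / 100)
    sp <- scaling_spec(spec$fchl_lower, up, spec$lim_max, spec$clip)
    f <- fit_obs(sp)
    r <- if (f$slope != 0) model_fit$slope / f$slope else NA_real_
    c(up = up, slope = f$slope, ratio = r)
  })
  scan <- do.call(rbind, scan)
  base_ratio <- ratio
  threshold_scan <- tibble::tibble(
    pct = pcts,
    fchl_upper = scan[, "up"],
    obs_slope = scan[, "slope"],
    ratio = scan[, "ratio"],
    ratio_change_pct = 100 * (scan[, "ratio"] - base_ratio) / base_ratio
  )

  structure(
    list(obs = obs_fit, model = model_fit, ratio = ratio,
         reliable = reliable, threshold_scan = threshold_scan,
         n_months = c(obs = nrow(obs), model = nrow(mod)),
         spec = spec),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Fe-limitation sensitivity to SST anomalies\n")
  cat(sprintf("  observed slope  %.4g (R2 = %.2f, p = %.3g, n = %d)\n",
              x$obs$slope, x$obs$r_squared, x$obs$p_value, x$obs$n))
  cat(sprintf("  model slope     %.4g (R2 = %.2f, p = %.3g, n = %d)\n",
              x$model$slope, x$model$r_squared, x$model$p_value,
              x$model$n))
  cat(sprintf("  model/observed ratio = %.3g%s\n", x$ratio,
              if (isTRUE(x$reliable)) "" else "  (observed slope unreliable)"))
  rng <- range(abs(x$threshold_scan$ratio_change_pct), na.rm = TRUE)
  cat(sprintf("  +/-%g%% upper-anchor scan moves the ratio by up to %.1f%%\n",
              max(abs(x$threshold_scan$pct)), rng[2]))
  invisible(x)
}
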