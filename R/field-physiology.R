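# Active-fluorometry and bioassay reductions: blank-corrected Fv/Fm, diel
# partitioning, chlorophyll-normalized active fluorescence, net growth rates
# and the pooled +/-Fe treatment contrast.

#' Blank-corrected photochemical efficiency Fv/Fm
#'
#' Minimum (`f_o`) and maximum (`f_m`) fluorescence are first corrected for
#' the filtrate blank, then
#' `Fv/Fm = ((f_m - blank) - (f_o - blank)) / (f_m - blank)`.
#' A blank at or above `f_m` leaves no photochemical signal and is an error;
#' a blank above `f_o` is physically suspicious (negative corrected minimum
#' fluorescence) and triggers a warning but is still computed.
#'
#' @param f_o Minimum fluorescence (instrument units), vectorized.
#' @param f_m Maximum fluorescence, same length.
#' @param blank Filtrate blank fluorescence (scalar or per-record).
#' @return Fv/Fm in \[0, 1).
#' @export
fvfm <- function(f_o, f_m, blank = 0) {
  n <- max(length(f_o), length(f_m), length(blank))
  f_o <- rep_len(as.numeric(f_o), n)
  f_m <- rep_len(as.numeric(f_m), n)
  blank <- rep_len(as.numeric(blank), n)
  if (any(f_m < f_o, na.rm = TRUE)) {
    stop("f_m must be >= f_o", call. = FALSE)
  }
  if (any(blank >= f_m, na.rm = TRUE)) {
    stop("blank >= f_m: no photochemical signal left after correction",
         call. = FALSE)
  }
  if (any(blank > f_o, na.rm = TRUE)) {
    warning("blank exceeds f_o for some records (negative corrected Fo)",
            call. = FALSE)
  }
  ((f_m - blank) - (f_o - blank)) / (f_m - blank)
}

#' Partition a time series into day and night
#'
#' Default mode is astronomical: night is solar elevation below zero at the
#' record's position and time. A PAR-threshold mode is available since
#' "night" admits other operational definitions.
#'
#' @param time `POSIXct` timestamps (UTC).
#' @param lat,lon Position in degrees (scalar or per-record);
#'   |lat| <= 66 required for the solar mode.
#' @param par PAR series, needed for `mode = "par"`.
#' @param mode `"solar"` (default) or `"par"`.
#' @param par_threshold Night is `par < par_threshold` in PAR mode
#'   (umol photons m^-2 s^-1).
#' @return Character vector, `"day"` or `"night"`, per record.
#' @export
diel_partition <- function(time, lat, lon, par = NULL,
                           mode = c("solar", "par"), par_threshold = 1) {
  mode <- match.arg(mode)
  if (mode == "par") {
    if (is.null(par)) stop("PAR mode needs `par`", call. = FALSE)
    return(ifelse(par < par_threshold, "night", "day"))
  }
  n <- length(time)
  lat <- rep_len(as.numeric(lat), n)
  lon <- rep_len(as.numeric(lon), n)
  if (any(abs(lat) > 66)) {
    stop("astronomical day/night partition is restricted to |lat| <= 66",
         call. = FALSE)
  }
  lst <- local_solar_time(time, lon)
  sza <- solar_zenith(lat, as.Date(time, tz = "UTC"), lst)
  ifelse(sza > 90, "night", "day")
}

#' Chlorophyll-normalized active fluorescence
#'
#' Mean night-time stimulated fluorescence divided by solvent-extracted
#' chlorophyll a — the active-fluorometry analogue of the passive F/Chl
#' yield.
#'
#' @param night_fluorescence Night-subset fluorescence values (instrument
#'   units); must be non-empty.
#' @param extracted_chl Chlorophyll a (mg m^-3), > 0.
#' @return Fluorescence per unit chlorophyll.
#' @export
fchl_active <- function(night_fluorescence, extracted_chl) {
  v <- night_fluorescence[is.finite(night_fluorescence)]
  if (length(v) == 0L) {
    stop("empty night-time fluorescence subset", call. = FALSE)
  }
  if (!is.finite(extracted_chl) || extracted_chl <= 0) {
    stop("extracted chlorophyll must be > 0", call. = FALSE)
  }
  mean(v) / extracted_chl
}

#' Chlorophyll-based net growth rate
#'
#' `mu = ln(chl_treatment / chl_control) / t` (per day). The control bottle,
#' not the initial, is the reference, so that shared incubation artefacts
#' (e.g. photoacclimation to deck-incubator light) cancel.
#'
#' @param chl_treatment,chl_control Final chlorophyll a (mg m^-3), > 0,
#'   vectorized.
#' @param t_days Incubation duration in days (default 2).
#' @return Net growth rate in d^-1.
#' @export
net_growth_rate <- function(chl_treatment, chl_control, t_days = 2) {
  if (any(t_days <= 0)) stop("t_days must be > 0", call. = FALSE)
  if (any(chl_treatment <= 0, na.rm = TRUE) ||
      any(chl_control <= 0, na.rm = TRUE)) {
    stop("chlorophyll concentrations must be > 0", call. = FALSE)
  }
  log(chl_treatment / chl_control) / t_days
}

#' Pooled comparison of all treatments with versus without added Fe
#'
#' Partitions experimental treatments into a -Fe pool (control and any
#' treatment whose label does not mention Fe) and a +Fe pool (any label
#' containing "Fe", e.g. `+Fe`, `+N+Fe`, `+N+Fe+X`), and compares the two
#' pools with an unpaired two-sided t-test ([ttest_unpaired()]).
#'
#' @param table Data frame with a `treatment` column and the response in
#'   `value` (or a column named by `response`).
#' @param response Name of the response column.
#' @param var_equal Passed to [ttest_unpaired()].
#' @return List with `minus_fe` / `plus_fe` summaries (`mean`, `sd`, `n`,
#'   `values`) and `test`, the t-test result.
#' @export
pool_fe_contrast <- function(table, response = "value", var_equal = FALSE) {
  stopifnot(is.data.frame(table), "treatment" %in% names(table),
            response %in% names(table))
  has_fe <- grepl("fe", tolower(table$treatment), fixed = TRUE)
  v_minus <- table[[response]][!has_fe]
  v_plus <- table[[response]][has_fe]
  if (length(v_minus) < 2L || length(v_plus) < 2L) {
    stop("both the -Fe and +Fe pools need >= 2 values", call. = FALSE)
  }
  summ <- function(v) list(mean = mean(v, na.rm = TRUE),
                           sd = stats::sd(v, na.rm = TRUE),
                           n = sum(is.finite(v)), values = v)
  list(minus_fe = summ(v_minus), plus_fe = summ(v_plus),
       test = ttest_unpaired(v_minus, v_plus, var_equal = var_equal))
}
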