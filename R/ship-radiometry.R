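# Shipboard hyperspectral radiometry: fluorescence line height, OC3
# chlorophyll, the passive fluorescence yield F/Chl, midday extraction and
# the PAR-response characterization.

#' Bundle a hyperspectral above-water radiometry record series
#'
#' Holds a common ascending wavelength grid, one row of water-leaving
#' radiance (and optionally remote-sensing reflectance) per timestamp, and
#' per-record position and PAR.
#'
#' @param wavelengths Strictly increasing wavelength grid (nm). For FLH use
#'   it must cover 667-748 nm.
#' @param lw Matrix of spectral water-leaving radiance
#'   (W m^-2 sr^-1 um^-1), one row per record, `ncol == length(wavelengths)`.
#' @param rrs Optional matrix of remote-sensing reflectance (sr^-1), same
#'   shape as `lw`.
#' @param time `POSIXct` timestamps (UTC), one per record.
#' @param lat,lon Positions in degrees.
#' @param par Photosynthetically active radiation
#'   (umol photons m^-2 s^-1).
#' @return An object of class `"radiometry_record"`.
#' @export
radiometry_record <- function(wavelengths, lw, rrs = NULL, time, lat, lon,
                              par) {
  wavelengths <- as.numeric(wavelengths)
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  lw <- matrix(as.numeric(lw), ncol = length(wavelengths))
  n <- nrow(lw)
  if (!is.null(rrs)) {
    rrs <- matrix(as.numeric(rrs), ncol = length(wavelengths))
    stopifnot(nrow(rrs) == n)
  }
  stopifnot(length(time) == n, length(lat) == n, length(lon) == n,
            length(par) == n)
  structure(
    list(wavelengths = wavelengths, lw = lw, rrs = rrs,
         time = as.POSIXct(time, tz = "UTC"),
         lat = as.numeric(lat), lon = as.numeric(lon),
         par = as.numeric(par)),
    class = "radiometry_record"
  )
}

#' @export
print.radiometry_record <- function(x, ...) {
  cat(sprintf(
    "<radiometry_record> %d spectra, %d bands (%.0f-%.0f nm)%s\n",
    nrow(x$lw), length(x$wavelengths), min(x$wavelengths),
    max(x$wavelengths), if (is.null(x$rrs)) "" else ", with Rrs"))
  invisible(x)
}

# Extract band radiances at the given centres from one or more spectra.
# "interp": linear interpolation at the centre wavelength (grid-independent).
# "window": mean of samples within +/- half_width nm, falling back to
# interpolation when the window is empty.
.extract_bands <- function(wavelengths, spec_mat, bands,
                           band_method = c("interp", "window"),
                           half_width = 2) {
  band_method <- match.arg(band_method)
  spec_mat <- matrix(spec_mat, ncol = length(wavelengths))
  out <- matrix(NA_real_, nrow = nrow(spec_mat), ncol = length(bands))
  for (b in seq_along(bands)) {
    ctr <- bands[b]
    if (ctr < min(wavelengths) || ctr > max(wavelengths)) next
    if (band_method == "window") {
      in_win <- which(abs(wavelengths - ctr) <= half_width)
      if (length(in_win) > 0L) {
        out[, b] <- rowMeans(spec_mat[, in_win, drop = FALSE])
        next
      }
    }
    hi <- findInterval(ctr, wavelengths)
    if (wavelengths[hi] == ctr) {
      out[, b] <- spec_mat[, hi]
    } else {
      frac <- (ctr - wavelengths[hi]) /
        (wavelengths[hi + 1L] - wavelengths[hi])
      out[, b] <- spec_mat[, hi] * (1 - frac) + spec_mat[, hi + 1L] * frac
    }
  }
  out
}

#' Fluorescence line height from a water-leaving radiance spectrum
#'
#' Height of the chlorophyll fluorescence radiance peak above the linear
#' baseline between the flanking bands, evaluated with the approximate
#' central wavelengths of the MODIS-Aqua wavebands (667, 678 and 748 nm):
#' `FLH = L678 - L667 - (L748 - L667) * (678 - 667) / (748 - 667)`.
#' Any spectral component affine in wavelength contributes nothing.
#'
#' @param wavelengths Ascending wavelength grid (nm), or a
#'   [radiometry_record()] (in which case `lw` is taken from it).
#' @param lw Radiance spectrum (vector) or one-spectrum-per-row matrix.
#' @param bands Band centres `c(left, peak, right)` in nm.
#' @param band_method Band extraction: `"interp"` (default, linear
#'   interpolation at the centre) or `"window"` (mean within
#'   `+/- half_width` nm, interpolating when the window is empty).
#' @param half_width Window half-width in nm for `band_method = "window"`.
#' @return FLH in the units of `lw` (one value per spectrum); `NA` where a
#'   band lies outside the grid.
#' @export
compute_flh <- function(wavelengths, lw = NULL, bands = c(667, 678, 748),
                        band_method = c("interp", "window"),
                        half_width = 2) {
  if (inherits(wavelengths, "radiometry_record")) {
    rec <- wavelengths
    wavelengths <- rec$wavelengths
    lw <- rec$lw
  }
  stopifnot(length(bands) == 3, bands[1] < bands[2], bands[2] < bands[3])
  bl <- .extract_bands(wavelengths, lw, bands, band_method, half_width)
  flh <- bl[, 2] - bl[, 1] -
    (bl[, 3] - bl[, 1]) * (bands[2] - bands[1]) / (bands[3] - bands[1])
  if (is.vector(lw)) flh[[1]] else flh
}

#' Operational OC3 maximum-band-ratio coefficient set
#'
#' Fourth-order polynomial coefficients (`c0..c4`) for the MODIS OC3
#' chlorophyll algorithm. The vintage of the coefficient set is an
#' operational choice that changes with reprocessing; it is therefore
#' configuration, with this widely used set as the default.
#'
#' @return Numeric vector of 5 polynomial coefficients.
#' @export
oc3_coefficients <- function() {
  c(0.2424, -2.7423, 1.8017, 0.0015, -1.2280)
}

#' OC3 chlorophyll from remote-sensing reflectance
#'
#' Standard maximum-band-ratio polynomial:
#' `chl = 10 ^ sum(c_i * r^i)` with
#' `r = log10(max(Rrs_blue1, Rrs_blue2) / Rrs_green)`.
#'
#' @param wavelengths Ascending wavelength grid (nm), or a
#'   [radiometry_record()] with `rrs`.
#' @param rrs Reflectance spectrum (vector) or one-per-row matrix (sr^-1).
#' @param coeffs Polynomial coefficients `c0..c4`; see
#'   [oc3_coefficients()].
#' @param bands Band centres `c(blue1, blue2, green)` in nm.
#' @param band_method,half_width Band extraction, as in [compute_flh()].
#' @return Chlorophyll a (mg m^-3); `NA` where any reflectance is
#'   non-positive or missing.
#' @export
compute_oc3_chl <- function(wavelengths, rrs = NULL,
                            coeffs = oc3_coefficients(),
                            bands = c(443, 489, 547),
                            band_method = c("interp", "window"),
                            half_width = 2) {
  if (inherits(wavelengths, "radiometry_record")) {
    rec <- wavelengths
    if (is.null(rec$rrs)) stop("record carries no Rrs", call. = FALSE)
    wavelengths <- rec$wavelengths
    rrs <- rec$rrs
  }
  stopifnot(length(coeffs) == 5, length(bands) == 3)
  bl <- .extract_bands(wavelengths, rrs, bands, band_method, half_width)
  blue <- pmax(bl[, 1], bl[, 2])
  green <- bl[, 3]
  bad <- !is.finite(bl[, 1]) | !is.finite(bl[, 2]) | !is.finite(green) |
    bl[, 1] <= 0 | bl[, 2] <= 0 | green <= 0
  r <- log10(blue / green)
  chl <- 10^(coeffs[1] + coeffs[2] * r + coeffs[3] * r^2 +
               coeffs[4] * r^3 + coeffs[5] * r^4)
  chl[bad] <- NA_real_
  if (is.vector(rrs)) chl[[1]] else chl
}

#' Local apparent solar time from UTC and longitude
#'
#' `local = UTC + longitude / 15` hours (mod 24): solar time, the convention
#' used for the midday extraction window.
#'
#' @param time `POSIXct` timestamps (UTC).
#' @param lon Longitude in degrees.
#' @return Decimal hours in \[0, 24).
#' @export
local_solar_time <- function(time, lon) {
  lt <- as.POSIXlt(time, tz = "UTC")
  utc_h <- lt$hour + lt$min / 60 + lt$sec / 3600
  (utc_h + lon / 15) %% 24
}

#' Chlorophyll-normalized passive fluorescence yield per record
#'
#' Computes FLH and chlorophyll per spectrum and normalizes:
#' `fchl = FLH / chl`. Chlorophyll comes from OC3 when the record carries
#' reflectance; an extracted-chlorophyll table can be supplied instead or in
#' addition, in which case a cross-validation regression of OC3 against
#' extracted values (nearest timestamps within `match_tol_min` minutes) is
#' attached as attribute `"chl_validation"`.
#'
#' @param rec A [radiometry_record()].
#' @param extracted_chl Optional data frame with `time` and `chl` columns
#'   (solvent-extracted chlorophyll a, mg m^-3).
#' @param use_extracted Normalize with the extracted values (matched by
#'   time) instead of OC3.
#' @param match_tol_min Matching tolerance in minutes for the validation.
#' @param ... Passed to [compute_flh()] and [compute_oc3_chl()].
#' @return A tibble (one row per record): `time`, `local_time`, `lat`,
#'   `lon`, `par`, `flh`, `chl`, `fchl`. `fchl` is `NA` where chlorophyll is
#'   missing or non-positive.
#' @export
build_yield_series <- function(rec, extracted_chl = NULL,
                               use_extracted = FALSE, match_tol_min = 30,
                               ...) {
  stopifnot(inherits(rec, "radiometry_record"))
  flh <- compute_flh(rec$wavelengths, rec$lw, ...)
  chl_oc3 <- if (!is.null(rec$rrs)) {
    compute_oc3_chl(rec$wavelengths, rec$rrs, ...)
  } else {
    rep(NA_real_, nrow(rec$lw))
  }
  chl <- chl_oc3
  validation <- NULL
  if (!is.null(extracted_chl)) {
    stopifnot(all(c("time", "chl") %in% names(extracted_chl)))
    et <- as.POSIXct(extracted_chl$time, tz = "UTC")
    idx <- vapply(et, function(tt) {
      which.min(abs(as.numeric(rec$time) - as.numeric(tt)))
    }, integer(1))
    dt_min <- abs(as.numeric(rec$time[idx]) - as.numeric(et)) / 60
    ok <- dt_min <= match_tol_min & is.finite(chl_oc3[idx])
    if (sum(ok) >= 3) {
      validation <- tryCatch(
        rma_regression(extracted_chl$chl[ok], chl_oc3[idx][ok],
                       n_boot = 0),
        error = function(e) NULL)  # degenerate (e.g. constant) matches
    }
    if (use_extracted) {
      chl <- rep(NA_real_, nrow(rec$lw))
      chl[idx[ok]] <- extracted_chl$chl[ok]
    }
  }
  fchl <- ifelse(is.finite(chl) & chl > 0, flh / chl, NA_real_)
  out <- tibble::tibble(
    time = rec$time,
    local_time = local_solar_time(rec$time, rec$lon),
    lat = rec$lat, lon = rec$lon, par = rec$par,
    flh = flh, chl = chl, fchl = fchl
  )
  attr(out, "chl_validation") <- validation
  out
}

#' Extract the midday (satellite-overpass-like) window
#'
#' Keeps records whose local solar time falls inside the window (default
#' 12:00-15:00, approximately bracketing the MODIS-Aqua overpass) and
#' summarizes each local day by its mean and standard deviation.
#'
#' @param series Yield tibble from [build_yield_series()] (needs
#'   `local_time`, `time`, `lon`, `fchl`).
#' @param window Local-time window `c(start_hour, end_hour)`, inclusive.
#' @return List with `points` (the retained rows) and `daily` (tibble
#'   `date`, `mean`, `sd`, `n` of `fchl` per local day).
#' @export
midday_extract <- function(series, window = c(12, 15)) {
  stopifnot(all(c("local_time", "time", "lon", "fchl") %in% names(series)))
  keep <- series$local_time >= window[1] & series$local_time <= window[2]
  pts <- series[keep, , drop = FALSE]
  if (nrow(pts) == 0L) {
    warning("no records inside the midday window", call. = FALSE)
    daily <- tibble::tibble(date = as.Date(character()),
                            mean = numeric(), sd = numeric(),
                            n = integer())
    return(list(points = pts, daily = daily))
  }
  # local calendar day: shift UTC by the longitude offset
  local_date <- as.Date(pts$time + pts$lon / 15 * 3600, tz = "UTC")
  sp <- split(pts$fchl, local_date)
  daily <- tibble::tibble(
    date = as.Date(names(sp)),
    mean = unname(vapply(sp, function(v) mean(v, na.rm = TRUE),
                         numeric(1))),
    sd = unname(vapply(sp, function(v) stats::sd(v, na.rm = TRUE),
                       numeric(1))),
    n = unname(vapply(sp, function(v) sum(is.finite(v)), integer(1)))
  )
  list(points = pts, daily = daily)
}

#' PAR response of the passive fluorescence yield
#'
#' Bin-averages F/Chl over PAR bins and fits the saturating curve
#' `a * tanh(b * PAR / a)` to the bin means via [fit_tanh_response()].
#' Empty bins are omitted. A constant yield (or too few occupied bins) is a
#' degenerate response: the bins are returned with `fit = NULL` and
#' `degenerate = TRUE`.
#'
#' @param series Yield tibble with `par` and `fchl` columns.
#' @param bins PAR bin edges (umol photons m^-2 s^-1).
#' @return List with `bins` (tibble `par_mid`, `mean`, `sd`, `n`), `fit`
#'   (a `tanh_fit` or `NULL`) and `degenerate`.
#' @export
par_response <- function(series, bins = seq(0, 2200, by = 100)) {
  stopifnot(all(c("par", "fchl") %in% names(series)))
  ok <- is.finite(series$par) & is.finite(series$fchl)
  par <- series$par[ok]
  fchl <- series$fchl[ok]
  cut_idx <- findInterval(par, bins, rightmost.closed = TRUE)
  cut_idx[cut_idx == 0 | cut_idx >= length(bins)] <- NA
  mids <- (bins[-length(bins)] + bins[-1]) / 2
  sp <- split(fchl, factor(cut_idx, levels = seq_along(mids)))
  n <- vapply(sp, length, integer(1))
  keep <- n > 0
  btab <- tibble::tibble(
    par_mid = mids[keep],
    mean = vapply(sp[keep], mean, numeric(1)),
    sd = vapply(sp[keep], stats::sd, numeric(1)),
    n = n[keep]
  )
  degenerate <- nrow(btab) < 5 || stats::sd(btab$mean) == 0
  fit <- NULL
  if (!degenerate) {
    fit <- tryCatch(fit_tanh_response(btab$par_mid, btab$mean),
                    error = function(e) NULL)
    if (is.null(fit)) degenerate <- TRUE
  }
  list(bins = btab, fit = fit, degenerate = degenerate)
}
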