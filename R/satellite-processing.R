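# Satellite-side pipeline: solar geometry, nFLH denormalization, chlorophyll
# masking, per-pixel fluorescence yield, regional extraction, anomaly series
# and along-track averaging.

#' Solar zenith angle from latitude, date and local solar time
#'
#' Day-of-year approximation: solar declination from the Spencer Fourier
#' series, hour angle directly from local (apparent) solar time, and
#' `cos(SZA) = sin(lat) sin(dec) + cos(lat) cos(dec) cos(H)`. Accuracy is a
#' few hundredths of a degree at low latitudes, ample for denormalizing
#' monthly composites. Validated for |lat| <= 66 degrees; higher latitudes
#' are computed with a warning.
#'
#' @param lat Latitude in degrees (vectorized).
#' @param date `Date` (vectorized, recycled against `lat`).
#' @param local_solar_time Local apparent solar time in decimal hours
#'   (default 13.5, the nominal MODIS-Aqua overpass).
#' @return Solar zenith angle in degrees.
#' @export
solar_zenith <- function(lat, date, local_solar_time = 13.5) {
  n <- max(length(lat), length(date), length(local_solar_time))
  lat <- rep_len(as.numeric(lat), n)
  date <- rep_len(as.Date(date), n)
  lst <- rep_len(as.numeric(local_solar_time), n)
  if (any(abs(lat) > 66)) {
    warning("latitude outside the validated |lat| <= 66 deg domain",
            call. = FALSE)
  }
  doy <- as.POSIXlt(date)$yday + 1L
  g <- 2 * pi * (doy - 1 + (lst - 12) / 24) / 365
  dec <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- lat * pi / 180
  h <- (lst - 12) * 15 * pi / 180
  cosz <- sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(h)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

#' Remove the geometry normalization from satellite nFLH
#'
#' The normalized fluorescence line height product removes solar/viewing
#' geometry; at the fully light-saturated irradiances of the early-afternoon
#' overpass the physically comparable quantity is FLH itself, recovered to
#' first order by multiplying nFLH by the cosine of the solar zenith angle at
#' each pixel latitude for the composite mid-point date. Pixels with the sun
#' at or below the horizon (SZA >= 90 degrees) are masked.
#'
#' @param nflh A [gridded_field()] of normalized fluorescence line height.
#' @param overpass_local_time Local solar time (hours) used for the zenith
#'   angle.
#' @return A [gridded_field()] named `"flh"` with the same axes and units.
#' @export
denormalize_nflh <- function(nflh, overpass_local_time = 13.5) {
  stopifnot(inherits(nflh, "gridded_field"))
  sza <- outer(seq_along(nflh$time), seq_along(nflh$lat),
               function(t, i) solar_zenith(nflh$lat[i], nflh$time[t],
                                           overpass_local_time))
  cosz <- cos(sza * pi / 180)
  cosz[cosz <= 0] <- NA_real_
  fac <- array(rep(cosz, times = length(nflh$lon)), dim = dim(nflh$values))
  gridded_field(nflh$values * fac, nflh$time, nflh$lat, nflh$lon,
                var = "flh", units = nflh$units)
}

#' Chlorophyll validity mask for satellite fluorescence yields
#'
#' Excludes pixels with chlorophyll a strictly below `lo` or strictly above
#' `hi` (defaults 0.1 and 0.4 mg m^-3, bracketing the FLH detection limit
#' and the range over which chlorophyll tracks phytoplankton absorption
#' linearly). Values exactly on either bound are retained; missing
#' chlorophyll is excluded.
#'
#' @param chl A [gridded_field()] of chlorophyll a (mg m^-3).
#' @param lo,hi Inclusive validity bounds (mg m^-3).
#' @return Logical array of the field's dimensions; `TRUE` = keep.
#' @export
mask_chl <- function(chl, lo = 0.1, hi = 0.4) {
  stopifnot(inherits(chl, "gridded_field"), lo < hi)
  m <- !is.na(chl$values) & chl$values >= lo & chl$values <= hi
  m
}

#' Satellite chlorophyll-normalized fluorescence yield
#'
#' Element-wise FLH / chlorophyll on pixels passing the chlorophyll mask.
#'
#' @param flh Denormalized fluorescence line height [gridded_field()].
#' @param chl Co-registered chlorophyll a [gridded_field()].
#' @param mask Logical keep-mask; defaults to [mask_chl()] of `chl`.
#' @return A [gridded_field()] named `"fchl_sat"`,
#'   units W m^-2 sr^-1 um^-1 \[mg Chl m^-3\]^-1.
#' @export
fchl_sat <- function(flh, chl, mask = NULL) {
  stopifnot(inherits(flh, "gridded_field"), inherits(chl, "gridded_field"))
  .gf_check_aligned(flh, chl)
  if (is.null(mask)) mask <- mask_chl(chl)
  vals <- flh$values / chl$values
  vals[!mask] <- NA_real_
  gridded_field(vals, flh$time, flh$lat, flh$lon, var = "fchl_sat",
                units = "W m-2 sr-1 um-1 [mg Chl m-3]-1")
}

#' Monthly regional mean series over a lat/lon box
#'
#' Area mean per month of unmasked pixels inside the box, weighted by
#' cos(latitude) (a negligible refinement near the equator, documented for
#' completeness). Months whose valid-pixel fraction falls below
#' `min_valid_frac` are flagged (value retained).
#'
#' @param gf A [gridded_field()].
#' @param box Numeric `c(lat_min, lat_max, lon_min, lon_max)`; the default is
#'   the standard Nino3 box (5 S - 5 N, 150 W - 90 W).
#' @param min_valid_frac Minimum fraction of box pixels that must be valid.
#' @return A tibble with `time`, `value`, `n_valid`, `frac_valid`,
#'   `flagged`.
#' @export
region_series <- function(gf, box = c(-5, 5, -150, -90),
                          min_valid_frac = 0.2) {
  stopifnot(inherits(gf, "gridded_field"), length(box) == 4)
  ii <- which(gf$lat >= box[1] & gf$lat <= box[2])
  jj <- which(gf$lon >= box[3] & gf$lon <= box[4])
  if (length(ii) == 0L || length(jj) == 0L) {
    stop("region box contains no grid cells", call. = FALSE)
  }
  w <- cos(gf$lat[ii] * pi / 180)
  wmat <- matrix(rep(w, times = length(jj)), nrow = length(ii))
  nt <- length(gf$time)
  value <- numeric(nt)
  n_valid <- integer(nt)
  for (t in seq_len(nt)) {
    slab <- gf$values[t, ii, jj, drop = TRUE]
    slab <- matrix(slab, nrow = length(ii))
    ok <- !is.na(slab)
    n_valid[t] <- sum(ok)
    value[t] <- if (n_valid[t] == 0L) NA_real_ else
      sum(slab[ok] * wmat[ok]) / sum(wmat[ok])
  }
  frac <- n_valid / (length(ii) * length(jj))
  tibble::tibble(time = gf$time, value = value, n_valid = n_valid,
                 frac_valid = frac, flagged = frac < min_valid_frac)
}

#' Anomalies as value minus record average
#'
#' Default mode subtracts the full-record mean, so the anomaly series means
#' to zero by construction. `mode = "climatology"` instead subtracts the
#' month-of-year climatological mean, removing the seasonal cycle.
#'
#' @param x Numeric vector, or a data frame with `time` and `value` columns
#'   (as produced by [region_series()]).
#' @param time Calendar dates, required for climatology mode on a bare
#'   vector.
#' @param mode `"record"` (default) or `"climatology"`.
#' @return Same shape as the input: a numeric vector of anomalies, or the
#'   input tibble with an `anomaly` column added.
#' @export
anomalies <- function(x, time = NULL, mode = c("record", "climatology")) {
  mode <- match.arg(mode)
  if (is.data.frame(x)) {
    stopifnot(all(c("time", "value") %in% names(x)))
    x$anomaly <- anomalies(x$value, time = x$time, mode = mode)
    return(x)
  }
  x <- as.numeric(x)
  if (mode == "record") {
    return(x - mean(x, na.rm = TRUE))
  }
  if (is.null(time)) {
    stop("climatology mode needs `time`", call. = FALSE)
  }
  mo <- format(as.Date(time), "%m")
  clim <- tapply(x, mo, mean, na.rm = TRUE)
  x - as.numeric(clim[mo])
}

#' Great-circle along-track averaging
#'
#' Mean of unmasked pixels within `radius_km` of each track point, using
#' haversine great-circle distances on the grid-cell centres. Multi-month
#' fields are first collapsed to their time-mean (climatology); pass
#' `time_index` to use a single composite instead.
#'
#' @param gf A [gridded_field()].
#' @param points Data frame with `lat` and `lon` columns (ship sampling
#'   positions).
#' @param radius_km Selection radius in kilometres.
#' @param time_index Optional single time index; default averages over time.
#' @return A tibble with `lat`, `lon`, `value`, `n_pixels` per point.
#' @export
track_average <- function(gf, points, radius_km = 100, time_index = NULL) {
  stopifnot(inherits(gf, "gridded_field"),
            all(c("lat", "lon") %in% names(points)))
  slab <- if (is.null(time_index)) {
    apply(gf$values, c(2, 3), function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  } else {
    matrix(gf$values[time_index, , ], nrow = length(gf$lat))
  }
  grid <- expand.grid(i = seq_along(gf$lat), j = seq_along(gf$lon))
  gpts <- cbind(gf$lon[grid$j], gf$lat[grid$i])
  vals <- slab[cbind(grid$i, grid$j)]
  out <- lapply(seq_len(nrow(points)), function(k) {
    d <- geosphere::distHaversine(c(points$lon[k], points$lat[k]), gpts)
    sel <- d <= radius_km * 1000 & !is.na(vals)
    c(value = if (any(sel)) mean(vals[sel]) else NA_real_,
      n_pixels = sum(sel))
  })
  out <- do.call(rbind, out)
  tibble::tibble(lat = points$lat, lon = points$lon,
                 value = unname(out[, "value"]),
                 n_pixels = as.integer(out[, "n_pixels"]))
}
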