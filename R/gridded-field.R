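# Gridded monthly satellite/model fields: a (time, lat, lon) cube with a
# missing-value mask, serialized to a self-describing long-format CSV.

#' Construct a gridded field
#'
#' A `gridded_field` holds one variable on a regular (time, lat, lon) grid:
#' monthly composite mid-point dates, degree axes (latitude north-positive,
#' longitude in \[-180, 180)), and a numeric cube with `NA` marking masked
#' pixels.
#'
#' @param values Numeric array with `dim = c(length(time), length(lat),
#'   length(lon))`.
#' @param time Vector of `Date` composite mid-points, strictly increasing.
#' @param lat,lon Numeric axes in degrees, strictly monotone.
#' @param var Variable name (e.g. `"nflh"`, `"chl"`, `"sst"`, `"fchl_sat"`,
#'   `"fe_lim"`).
#' @param units Units string.
#' @return An object of class `"gridded_field"`.
#' @export
gridded_field <- function(values, time, lat, lon, var, units = "") {
  time <- as.Date(time)
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  values <- array(as.numeric(values),
                  dim = c(length(time), length(lat), length(lon)))
  .check_axis(as.numeric(time), "time", ascending = TRUE)
  .check_axis(lat, "lat")
  .check_axis(lon, "lon")
  structure(
    list(var = as.character(var), units = as.character(units),
         time = time, lat = lat, lon = lon, values = values),
    class = "gridded_field"
  )
}

# time must increase; spatial axes may run in either direction
.check_axis <- function(ax, name, ascending = FALSE) {
  if (length(ax) == 0L || anyNA(ax)) {
    stop(sprintf("axis `%s` is empty or has missing values", name),
         call. = FALSE)
  }
  if (length(ax) > 1L) {
    d <- diff(ax)
    ok <- if (ascending) all(d > 0) else all(d > 0) || all(d < 0)
    if (!ok) {
      stop(sprintf("axis `%s` is not strictly monotone", name),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %s [%s]\n", x$var, x$units))
  cat(sprintf("  %d months (%s .. %s), %d x %d grid, %.1f%% masked\n",
              length(x$time), format(min(x$time)), format(max(x$time)),
              length(x$lat), length(x$lon),
              100 * mean(is.na(x$values))))
  invisible(x)
}

# elementwise transform preserving grid metadata
.gf_map <- function(gf, f, var = gf$var, units = gf$units) {
  gridded_field(f(gf$values), gf$time, gf$lat, gf$lon, var, units)
}

.gf_check_aligned <- function(a, b) {
  if (!identical(a$time, b$time) || !identical(a$lat, b$lat) ||
      !identical(a$lon, b$lon)) {
    stop("gridded fields are not co-registered (axes differ)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a gridded field to long-format CSV
#'
#' The file is self-describing: comment lines carry the variable name, units
#' and the three axes in storage order, followed by a `time,lat,lon,value`
#' table (masked pixels as empty values). [read_gridded()] inverts it
#' exactly.
#'
#' @param gf A [gridded_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(gf, path) {
  stopifnot(inherits(gf, "gridded_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ferrolux gridded field v1",
    paste0("# variable: ", gf$var),
    paste0("# units: ", gf$units),
    paste0("# time: ", paste(format(gf$time), collapse = " ")),
    paste0("# lat: ", paste(format(gf$lat, trim = TRUE, digits = 15),
                            collapse = " ")),
    paste0("# lon: ", paste(format(gf$lon, trim = TRUE, digits = 15),
                            collapse = " "))
  ), con)
  idx <- expand.grid(t = seq_along(gf$time), i = seq_along(gf$lat),
                     j = seq_along(gf$lon))
  df <- data.frame(
    time = format(gf$time[idx$t]),
    lat = gf$lat[idx$i],
    lon = gf$lon[idx$j],
    value = gf$values[cbind(idx$t, idx$i, idx$j)]
  )
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a gridded field written by [write_gridded()]
#'
#' Axes are validated for strict monotonicity and every grid cell must be
#' present exactly once; violations raise a format error naming the
#' offending component.
#'
#' @param path File path.
#' @param variable Optional expected variable name; a mismatch is an error.
#' @return A [gridded_field()].
#' @export
read_gridded <- function(path, variable = NULL) {
  lines <- readLines(path, n = 6L)
  if (length(lines) < 6L || !startsWith(lines[1], "# ferrolux gridded")) {
    stop("not a ferrolux gridded-field file: ", path, call. = FALSE)
  }
  meta <- function(key) {
    ln <- lines[startsWith(lines, paste0("# ", key, ":"))]
    if (length(ln) != 1L) {
      stop("gridded-field header missing `", key, "`", call. = FALSE)
    }
    trimws(sub(paste0("^# ", key, ":"), "", ln))
  }
  var <- meta("variable")
  if (!is.null(variable) && !identical(var, variable)) {
    stop(sprintf("file holds variable `%s`, not `%s`", var, variable),
         call. = FALSE)
  }
  units <- meta("units")
  time <- as.Date(strsplit(meta("time"), "\\s+")[[1]])
  lat <- as.numeric(strsplit(meta("lat"), "\\s+")[[1]])
  lon <- as.numeric(strsplit(meta("lon"), "\\s+")[[1]])
  .check_axis(as.numeric(time), "time", ascending = TRUE)
  .check_axis(lat, "lat")
  .check_axis(lon, "lon")

  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "lat", "lon", "value")
  if (!all(need %in% names(df))) {
    stop("gridded-field table must have columns time,lat,lon,value",
         call. = FALSE)
  }
  ti <- match(as.Date(df$time), time)
  ii <- match(df$lat, lat)
  jj <- match(df$lon, lon)
  if (anyNA(ti) || anyNA(ii) || anyNA(jj)) {
    stop("gridded-field table contains coordinates absent from the axes",
         call. = FALSE)
  }
  n_cells <- length(time) * length(lat) * length(lon)
  if (nrow(df) != n_cells || anyDuplicated(cbind(ti, ii, jj)) > 0) {
    stop("gridded-field table does not cover the grid exactly once",
         call. = FALSE)
  }
  vals <- array(NA_real_, dim = c(length(time), length(lat), length(lon)))
  vals[cbind(ti, ii, jj)] <- df$value
  gridded_field(vals, time, lat, lon, var, units)
}
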