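# Sensor stream IO: typed traces, delimited-text readers/writers, terrain grids.

.stream_schemas <- list(
  accel    = list(cols = c("time", "surge", "sway", "heave"),
                  nominal_rate = 200, class = "accel_trace"),
  pressure = list(cols = c("time", "pressure_hpa"),
                  nominal_rate = 20, class = "pressure_trace"),
  gps      = list(cols = c("time", "lon", "lat"), optional = "ground_speed",
                  nominal_rate = 1, class = "gps_track"),
  wind     = list(cols = c("time", "u", "v"),
                  nominal_rate = NA_real_, class = "wind_series")
)

.trace_rate <- function(time, nominal) {
  if (length(time) > 1) 1 / stats::median(diff(time)) else nominal
}

.validate_trace <- function(df, stream_kind) {
  sch <- .stream_schemas[[stream_kind]]
  d <- diff(df$time)
  if (length(d) && any(d <= 0)) {
    stop("non-monotone time in ", stream_kind, " stream: first offending index ",
         which(d <= 0)[1] + 1L, call. = FALSE)
  }
  if (stream_kind == "accel" && any(!is.finite(df$heave))) {
    stop("non-finite heave values in acceleration stream", call. = FALSE)
  }
  if (stream_kind == "pressure" &&
      any(df$pressure_hpa <= 300 | df$pressure_hpa >= 1100)) {
    stop("pressure outside the plausible (300, 1100) hPa range", call. = FALSE)
  }
  if (stream_kind == "gps" &&
      (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))) {
    stop("GPS fix outside valid lon/lat bounds", call. = FALSE)
  }
  if (stream_kind == "wind" && any(!is.finite(df$u) | !is.finite(df$v))) {
    stop("non-finite wind components", call. = FALSE)
  }
  invisible(df)
}

.new_trace <- function(df, stream_kind) {
  sch <- .stream_schemas[[stream_kind]]
  df <- as_tibble(df)
  .validate_trace(df, stream_kind)
  attr(df, "rate_hz") <- .trace_rate(df$time, sch$nominal_rate)
  attr(df, "stream_kind") <- stream_kind
  class(df) <- c(sch$class, "sensor_trace", class(df))
  df
}

#' Construct typed sensor traces
#'
#' Lightweight tibble subclasses for the four logger streams: tri-axial
#' acceleration (g, 200 Hz nominal), barometric pressure (hPa, 20 Hz), GPS
#' fixes (decimal degrees WGS84, 1 Hz) and hourly wind components
#' (m s^-1, east/north positive). Time is numeric seconds since flight start
#' and must be strictly increasing. The realised sampling rate is stored in
#' the `rate_hz` attribute.
#'
#' @param time Numeric seconds since flight start, strictly increasing.
#' @param surge,sway,heave Acceleration in g along the three body axes.
#' @param pressure_hpa Barometric pressure, hPa; must lie in (300, 1100).
#' @param lon,lat Decimal degrees (WGS84).
#' @param ground_speed Optional ground speed, m s^-1.
#' @param u,v Wind components, m s^-1, positive = air moving east/north.
#' @return A tibble of the corresponding trace class.
#' @examples
#' accel_trace(time = c(0, 0.005, 0.01), surge = 0, sway = 0, heave = 1)
#' @export
accel_trace <- function(time, surge, sway, heave) {
  .new_trace(tibble(time = time, surge = surge, sway = sway, heave = heave),
             "accel")
}

#' @rdname accel_trace
#' @export
pressure_trace <- function(time, pressure_hpa) {
  .new_trace(tibble(time = time, pressure_hpa = pressure_hpa), "pressure")
}

#' @rdname accel_trace
#' @export
gps_track <- function(time, lon, lat, ground_speed = NULL) {
  df <- tibble(time = time, lon = lon, lat = lat)
  if (!is.null(ground_speed)) df$ground_speed <- ground_speed
  .new_trace(df, "gps")
}

#' @rdname accel_trace
#' @export
wind_series <- function(time, u, v) {
  .new_trace(tibble(time = time, u = u, v = v), "wind")
}

.parse_time_column <- function(time) {
  if (is.numeric(time)) return(as.numeric(time))
  tt <- readr::parse_datetime(as.character(time))
  if (any(is.na(tt))) {
    stop("time column is neither numeric seconds nor ISO-8601", call. = FALSE)
  }
  as.numeric(tt) - as.numeric(tt[1])
}

#' Read and write sensor stream CSVs
#'
#' One stream per comma-delimited file with a header. Expected columns:
#' accel `time,surge,sway,heave`; pressure `time,pressure_hpa`; gps
#' `time,lon,lat` (optional `ground_speed`); wind `time,u,v`. The time column
#' may be numeric seconds or ISO-8601 timestamps (converted to seconds since
#' the first sample). All type invariants are enforced on read; writing and
#' re-reading preserves every numeric field.
#'
#' @param path Path to a CSV file.
#' @param stream_kind One of `"accel"`, `"pressure"`, `"gps"`, `"wind"`.
#' @param trace A trace produced by [accel_trace()] and friends.
#' @return `read_sensor_csv()` returns the typed trace; `write_sensor_csv()`
#'   returns `path` invisibly.
#' @export
read_sensor_csv <- function(path,
                            stream_kind = c("accel", "pressure", "gps", "wind")) {
  stream_kind <- match.arg(stream_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sch <- .stream_schemas[[stream_kind]]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(sch$cols, names(df))
  if (length(missing)) {
    stop("format error in ", path, ": missing column '", missing[1], "'",
         call. = FALSE)
  }
  df$time <- .parse_time_column(df$time)
  keep <- intersect(c(sch$cols, sch$optional), names(df))
  .new_trace(df[keep], stream_kind)
}

#' @rdname read_sensor_csv
#' @export
write_sensor_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  readr::write_csv(as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' Bundle one flight's synchronized streams
#'
#' A flight record holds the acceleration, pressure and GPS streams of one
#' flight on a shared time base (seconds since flight start), together with
#' the reference sea-level pressure recorded at the release site, which the
#' altimetry uses to correct for synoptic pressure changes.
#'
#' @param flight_id,bird_id Non-empty identifiers.
#' @param accel,pressure,gps Typed traces (see [accel_trace()]).
#' @param p0_sealevel Reference sea-level pressure, hPa.
#' @param release_time Optional release timestamp (informational).
#' @return An object of class `flight_record`.
#' @export
flight_record <- function(flight_id, bird_id, accel, pressure, gps,
                          p0_sealevel = 1013.25, release_time = NA) {
  stopifnot(inherits(accel, "accel_trace"), inherits(pressure, "pressure_trace"),
            inherits(gps, "gps_track"))
  if (!nzchar(flight_id) || !nzchar(bird_id)) {
    stop("flight_id and bird_id must be non-empty", call. = FALSE)
  }
  if (!is.finite(p0_sealevel) || p0_sealevel <= 300 || p0_sealevel >= 1100) {
    stop("p0_sealevel outside plausible range", call. = FALSE)
  }
  t_lo <- max(accel$time[1], pressure$time[1], gps$time[1])
  t_hi <- min(max(accel$time), max(pressure$time), max(gps$time))
  if (t_lo >= t_hi) stop("sensor streams do not overlap in time", call. = FALSE)
  structure(
    list(flight_id = flight_id, bird_id = bird_id, accel = accel,
         pressure = pressure, gps = gps, p0_sealevel = p0_sealevel,
         release_time = release_time),
    class = "flight_record"
  )
}

#' @export
print.flight_record <- function(x, ...) {
  cat("<flight_record> ", x$flight_id, " (bird ", x$bird_id, ")\n", sep = "")
  cat(sprintf("  accel: %d samples @ %.0f Hz | pressure: %d @ %.0f Hz | gps: %d fixes\n",
              nrow(x$accel), attr(x$accel, "rate_hz"),
              nrow(x$pressure), attr(x$pressure, "rate_hz"), nrow(x$gps)))
  cat(sprintf("  duration: %.1f s | p0 (sea level): %.2f hPa\n",
              flight_duration(x), x$p0_sealevel))
  invisible(x)
}

#' Duration of a flight record
#'
#' The common duration over which all three streams have data, measured from
#' time zero: the minimum over streams of (last timestamp + one sample
#' interval).
#'
#' @param flight A `flight_record`.
#' @return Duration in seconds.
#' @export
flight_duration <- function(flight) {
  stopifnot(inherits(flight, "flight_record"))
  span <- function(tr) {
    r <- attr(tr, "rate_hz")
    max(tr$time) + if (is.finite(r) && r > 0) 1 / r else 0
  }
  min(span(flight$accel), span(flight$pressure), span(flight$gps))
}

# ---- terrain -----------------------------------------------------------------

#' Regular terrain elevation grid
#'
#' @param lon,lat Strictly increasing grid-node coordinates, decimal degrees.
#' @param elevation Matrix of elevations (m ASL), `length(lon)` rows by
#'   `length(lat)` columns.
#' @return An object of class `terrain_grid`.
#' @export
terrain_grid <- function(lon, lat, elevation) {
  elevation <- as.matrix(elevation)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0)) {
    stop("grid coordinates must be strictly increasing", call. = FALSE)
  }
  if (!all(dim(elevation) == c(length(lon), length(lat)))) {
    stop("elevation matrix must be length(lon) x length(lat)", call. = FALSE)
  }
  if (any(!is.finite(elevation))) stop("non-finite elevations", call. = FALSE)
  structure(list(lon = lon, lat = lat, elevation = elevation),
            class = "terrain_grid")
}

#' Read a gridded terrain CSV
#'
#' Three columns `lon,lat,elevation` forming a complete regular grid
#' (one row per node, any order).
#'
#' @param path Path to the CSV.
#' @return A [terrain_grid()].
#' @export
read_terrain_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("lon", "lat", "elevation"), names(df))
  if (length(missing)) {
    stop("format error in ", path, ": missing column '", missing[1], "'",
         call. = FALSE)
  }
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  if (nrow(df) != length(lon) * length(lat)) {
    stop("terrain CSV is not a complete regular grid", call. = FALSE)
  }
  z <- matrix(NA_real_, length(lon), length(lat))
  z[cbind(match(df$lon, lon), match(df$lat, lat))] <- df$elevation
  terrain_grid(lon, lat, z)
}

#' Bilinear terrain sampling
#'
#' Elevation at arbitrary points by bilinear interpolation of the four
#' surrounding grid nodes. Vectorized over points.
#'
#' @param grid A [terrain_grid()].
#' @param lon,lat Query coordinates, decimal degrees; must fall inside the
#'   grid bounds.
#' @return Elevation in metres ASL (numeric vector).
#' @export
sample_terrain <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "terrain_grid"))
  out <- lon < grid$lon[1] | lon > grid$lon[length(grid$lon)] |
    lat < grid$lat[1] | lat > grid$lat[length(grid$lat)]
  if (any(out)) {
    i <- which(out)[1]
    stop(sprintf("point outside terrain grid: fix %d at (%.5f, %.5f)",
                 i, lon[i], lat[i]), call. = FALSE)
  }
  ix <- pmin(pmax(findInterval(lon, grid$lon), 1L), length(grid$lon) - 1L)
  iy <- pmin(pmax(findInterval(lat, grid$lat), 1L), length(grid$lat) - 1L)
  x0 <- grid$lon[ix]; x1 <- grid$lon[ix + 1L]
  y0 <- grid$lat[iy]; y1 <- grid$lat[iy + 1L]
  tx <- (lon - x0) / (x1 - x0)
  ty <- (lat - y0) / (y1 - y0)
  z00 <- grid$elevation[cbind(ix, iy)]
  z10 <- grid$elevation[cbind(ix + 1L, iy)]
  z01 <- grid$elevation[cbind(ix, iy + 1L)]
  z11 <- grid$elevation[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}
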