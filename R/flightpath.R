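# Barometric altimetry, climb rate, track geometry and the wind triangle.

# ISA constants for the hypsometric map
.isa <- list(T0 = 288.15, L = 0.0065, Rd = 287.053, g = 9.80665)

#' Barometric altitude above sea level
#'
#' Inverts the ISA hypsometric relation
#' `h = (T0/L) * (1 - (P/p0)^(L*Rd/g))` after smoothing the pressure with a
#' centred 2 s moving average, using the sea-level reference pressure
#' recorded at the release site (so synoptic pressure changes are factored
#' in).
#'
#' @param trace A [pressure_trace()].
#' @param p0_sealevel Sea-level reference pressure, hPa, in (900, 1100).
#' @param smooth_seconds Smoothing window, s.
#' @return A tibble of class `altitude_series` with columns `time` and
#'   `altitude_asl` (m).
#' @seealso [altitude_to_pressure()] for the exact inverse map.
#' @export
pressure_to_altitude <- function(trace, p0_sealevel, smooth_seconds = 2) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (p0_sealevel <= 900 || p0_sealevel >= 1100) {
    stop("p0_sealevel must lie in (900, 1100) hPa", call. = FALSE)
  }
  if (any(trace$pressure_hpa <= 0)) {
    stop("non-positive pressure", call. = FALSE)
  }
  rate <- attr(trace, "rate_hz") %||% .trace_rate(trace$time, 20)
  w <- max(1L, round(smooth_seconds * rate))
  w <- min(w, nrow(trace))
  ps <- running_mean(trace$pressure_hpa, w)
  if (mean(ps - p0_sealevel > 5) > 0.05) {
    warning("pressure persistently exceeds p0 by > 5 hPa: below-sea-level readings",
            call. = FALSE)
  }
  ex <- .isa$L * .isa$Rd / .isa$g
  h <- (.isa$T0 / .isa$L) * (1 - (ps / p0_sealevel)^ex)
  out <- tibble(time = trace$time, altitude_asl = h)
  attr(out, "p0_sealevel") <- p0_sealevel
  class(out) <- c("altitude_series", class(out))
  out
}

#' ISA pressure at altitude
#'
#' Exact inverse of [pressure_to_altitude()]'s hypsometric map (no
#' smoothing): `P = p0 * (1 - L*h/T0)^(g/(L*Rd))`.
#'
#' @param altitude_asl Altitude ASL, m (vectorized).
#' @param p0_sealevel Sea-level pressure, hPa.
#' @return Pressure in hPa.
#' @export
altitude_to_pressure <- function(altitude_asl, p0_sealevel) {
  ex <- .isa$g / (.isa$L * .isa$Rd)
  p0_sealevel * (1 - .isa$L * altitude_asl / .isa$T0)^ex
}

#' Climb rate per second
#'
#' Altitude ASL is resampled to 1 Hz by linear interpolation and first
#' differences give the climb rate Vz (m s^-1), assigned to the end of each
#' one-second interval.
#'
#' @param altitude An `altitude_series` (or tibble with `time`,
#'   `altitude_asl`), spanning at least 2 s.
#' @return A tibble with columns `time` and `vz`.
#' @export
climb_rate <- function(altitude) {
  if (max(altitude$time) - min(altitude$time) < 2) {
    stop("need at least 2 s of altitude data", call. = FALSE)
  }
  secs <- seq(ceiling(min(altitude$time)), floor(max(altitude$time)), by = 1)
  a1 <- approx(altitude$time, altitude$altitude_asl, xout = secs)$y
  tibble(time = secs[-1], vz = diff(a1))
}

#' Altitude above ground level
#'
#' Subtracts bilinearly sampled terrain elevation from altitude ASL, with GPS
#' positions linearly interpolated to the altitude timestamps.
#'
#' @param altitude An `altitude_series`.
#' @param gps A [gps_track()] covering the altitude time span.
#' @param terrain A [terrain_grid()] covering the track.
#' @return The input altitude tibble with added columns `terrain_elev` and
#'   `altitude_agl`.
#' @export
altitude_agl <- function(altitude, gps, terrain) {
  stopifnot(inherits(terrain, "terrain_grid"))
  lon <- approx(gps$time, gps$lon, xout = altitude$time, rule = 2)$y
  lat <- approx(gps$time, gps$lat, xout = altitude$time, rule = 2)$y
  elev <- sample_terrain(terrain, lon, lat)
  altitude$terrain_elev <- elev
  altitude$altitude_agl <- altitude$altitude_asl - elev
  altitude
}

# wrap degrees into (-180, 180]
.wrap180 <- function(a) {
  r <- ((a + 180) %% 360) - 180
  r[r == -180] <- 180
  r
}

#' Turning angles along a GPS track
#'
#' Headings between consecutive fixes are great-circle initial bearings;
#' the turning angle is the heading change between consecutive pairs of
#' fixes, wrapped into (-180, 180], with clockwise turns positive.
#'
#' @param gps A [gps_track()] with at least 3 fixes.
#' @return A tibble with columns `time` (the middle fix of each triple) and
#'   `turning_deg`.
#' @export
turning_angles <- function(gps) {
  n <- nrow(gps)
  if (n < 3) stop("need at least 3 GPS fixes", call. = FALSE)
  p <- cbind(gps$lon, gps$lat)
  hd <- geosphere::bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE]) %% 360
  tibble(time = gps$time[2:(n - 1)], turning_deg = .wrap180(diff(hd)))
}

#' Circular standard deviation of angles
#'
#' `sqrt(-2 ln R) * 180 / pi`, with `R` the mean resultant length of the
#' angles; the per-segment measure of horizontal track tortuosity. Invariant
#' to rotating all angles by a constant and to their order. Returns `Inf`
#' (with a warning) in the degenerate `R = 0` case.
#'
#' @param angles_deg Angles in degrees (at least 2).
#' @return Circular SD in degrees.
#' @export
circular_sd <- function(angles_deg) {
  a <- angles_deg[!is.na(angles_deg)]
  if (length(a) < 2) stop("need at least 2 angles", call. = FALSE)
  r <- a * pi / 180
  R <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  if (R < 1e-12) {
    warning("mean resultant length is zero: circular SD degenerate (Inf)",
            call. = FALSE)
    return(Inf)
  }
  R <- min(R, 1)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Airspeed and headwind component from the wind triangle
#'
#' The air velocity is the ground velocity minus the wind vector; airspeed is
#' its magnitude. The headwind component (HWC) is the negative projection of
#' the wind onto the unit track direction, so positive HWC means flight into
#' a headwind and negative HWC flight with a tailwind.
#'
#' @param ground_u,ground_v Ground velocity components, m s^-1 (east, north).
#' @param wind_u,wind_v Wind components, m s^-1 (east, north).
#' @return A tibble with columns `airspeed` and `hwc` (m s^-1); `hwc` is `NA`
#'   where the ground speed is zero.
#' @export
airspeed_hwc <- function(ground_u, ground_v, wind_u, wind_v) {
  stopifnot(all(is.finite(c(ground_u, ground_v, wind_u, wind_v))))
  gs <- sqrt(ground_u^2 + ground_v^2)
  airspeed <- sqrt((ground_u - wind_u)^2 + (ground_v - wind_v)^2)
  hwc <- ifelse(gs > 0, -(wind_u * ground_u + wind_v * ground_v) / gs, NA_real_)
  tibble(airspeed = airspeed, hwc = hwc)
}

#' Per-step track metrics
#'
#' Decomposes a GPS track into steps between consecutive fixes: great-circle
#' heading, ground speed (geodesic distance over elapsed time), turning angle
#' relative to the previous step, and — when hourly wind records are supplied
#' — airspeed and headwind component via [airspeed_hwc()], with the wind
#' linearly interpolated in time and held spatially constant.
#'
#' @param gps A [gps_track()] with at least 2 fixes.
#' @param wind Optional [wind_series()]; `NULL` means still air.
#' @return A tibble of class `track_steps` with columns `time` (step start),
#'   `heading`, `ground_speed`, `turning_angle`, `airspeed`, `hwc`.
#' @export
track_steps <- function(gps, wind = NULL) {
  n <- nrow(gps)
  if (n < 2) stop("need at least 2 GPS fixes", call. = FALSE)
  p <- cbind(gps$lon, gps$lat)
  dt <- diff(gps$time)
  dist <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
  heading <- geosphere::bearing(p[-n, , drop = FALSE], p[-1, , drop = FALSE]) %% 360
  speed <- dist / dt
  tm <- gps$time[-n]
  turning <- c(NA_real_, .wrap180(diff(heading)))
  if (is.null(wind)) {
    wu <- wv <- rep(0, n - 1L)
  } else {
    wu <- approx(wind$time, wind$u, xout = tm, rule = 2)$y
    wv <- approx(wind$time, wind$v, xout = tm, rule = 2)$y
  }
  th <- heading * pi / 180
  aw <- airspeed_hwc(speed * sin(th), speed * cos(th), wu, wv)
  out <- tibble(time = tm, heading = heading, ground_speed = speed,
                turning_angle = turning, airspeed = aw$airspeed, hwc = aw$hwc)
  class(out) <- c("track_steps", class(out))
  out
}
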