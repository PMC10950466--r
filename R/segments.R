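# 15 s segmentation and assembly of the per-segment analysis table.

#' Segment grid for a given duration
#'
#' Contiguous `window_s` windows from time zero; the final partial window is
#' kept when it is at least `min_tail_s` long, otherwise dropped and counted
#' as excluded (the `excluded` attribute).
#'
#' @param duration Duration, s.
#' @param window_s Segment length, s.
#' @param min_tail_s Minimum length of the final partial segment, s.
#' @return A tibble with columns `segment_id`, `start`, `end`, `duration` and
#'   attribute `excluded` (count of dropped tails).
#' @export
segment_grid <- function(duration, window_s = 15, min_tail_s = 10) {
  stopifnot(duration >= 0, window_s > 0, min_tail_s > 0, min_tail_s <= window_s)
  n_full <- floor(duration / window_s + 1e-9)
  starts <- window_s * seq_len(n_full) - window_s
  ends <- starts + window_s
  tail_len <- duration - n_full * window_s
  excluded <- 0L
  if (tail_len >= min_tail_s - 1e-9) {
    starts <- c(starts, n_full * window_s)
    ends <- c(ends, duration)
  } else if (tail_len > 1e-9) {
    excluded <- 1L
  }
  out <- tibble(segment_id = seq_along(starts), start = starts, end = ends,
                duration = ends - starts)
  attr(out, "excluded") <- excluded
  out
}

#' Divide a flight into 15 s segments
#'
#' @param flight A [flight_record()] or a numeric duration in seconds.
#' @param window_s,min_tail_s See [segment_grid()].
#' @return A segment tibble (see [segment_grid()]).
#' @examples
#' segment_flight(73) # 5 segments, the last 13 s long
#' @export
segment_flight <- function(flight, window_s = 15, min_tail_s = 10) {
  duration <- if (inherits(flight, "flight_record")) {
    flight_duration(flight)
  } else {
    as.numeric(flight)
  }
  segment_grid(duration, window_s = window_s, min_tail_s = min_tail_s)
}

#' Names of the eight per-segment response variables
#'
#' @return Character vector of response column names in the segment table.
#' @export
flap_responses <- function() {
  c("altitude_agl", "tortuosity", "wb_freq_mean", "wb_amp_mean",
    "airspeed_mean", "wb_freq_sd", "wb_amp_sd", "airspeed_sd")
}

#' Covariates assigned to each response sub-model
#'
#' Turbulence and headwind component enter every sub-model; climb rate and
#' (square-root) flight altitude additionally enter the kinematic and
#' airspeed sub-models, to account for the influence of ascents/descents and
#' flight height.
#'
#' @param response One of [flap_responses()].
#' @return Character vector of covariate column names.
#' @export
flap_covariates <- function(response) {
  base <- c("sqrt_turbulence", "hwc")
  extra <- c("wb_freq_mean", "wb_amp_mean", "airspeed_mean",
             "wb_freq_sd", "wb_amp_sd", "airspeed_sd")
  if (response %in% extra) c(base, "climb_rate", "sqrt_altitude_agl") else base
}

.seg_mean <- function(x) if (length(x)) mean(x) else NA_real_
.seg_sd <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_

#' Assemble the per-segment analysis table
#'
#' Joins the per-segment outputs of the kinematics, altimetry, track and
#' turbulence stages into one row per segment: the eight responses (mean
#' altitude AGL, tortuosity, mean and SD of wingbeat frequency, amplitude and
#' airspeed) and the model covariates (sqrt turbulence proxy, headwind
#' component, mean climb rate, sqrt mean altitude AGL). Rows with any
#' undefined response — e.g. segments with fewer than two wingbeats, whose
#' kinematic SDs are undefined — are dropped with a message; the count is
#' kept in the `dropped` attribute.
#'
#' @param segments Segment table from [segment_flight()].
#' @param wingbeats A `wingbeat_series` from [detect_wingbeats()].
#' @param altitude An `altitude_series`, ideally with `altitude_agl` (see
#'   [altitude_agl()]); plain ASL is used when AGL is absent.
#' @param track A `track_steps` tibble from [track_steps()].
#' @param turbulence Per-segment turbulence from [segment_turbulence()].
#' @param flight_id Identifier stored in the `flight_id` column.
#' @param gps Optional [gps_track()] used to fill the segment mid-point
#'   longitude/latitude.
#' @return A tibble of class `flight_segments`.
#' @export
build_segment_table <- function(segments, wingbeats, altitude, track,
                                turbulence, flight_id = "flight", gps = NULL) {
  agl <- if ("altitude_agl" %in% names(altitude)) {
    altitude$altitude_agl
  } else {
    altitude$altitude_asl
  }
  vz <- climb_rate(altitude)
  rows <- purrr::map(seq_len(nrow(segments)), function(i) {
    s <- segments$start[i]; e <- segments$end[i]
    wb <- wingbeats[!is.na(wingbeats$frequency_hz) &
                      wingbeats$peak_time >= s & wingbeats$peak_time < e, ]
    ai <- altitude$time >= s & altitude$time < e
    ti <- track$time >= s & track$time < e
    vi <- vz$time > s & vz$time <= e
    turns <- track$turning_angle[ti]
    turns <- turns[!is.na(turns)]
    mid <- (s + e) / 2
    tibble(
      flight_id = flight_id,
      segment_id = segments$segment_id[i],
      start = s, end = e, duration = e - s, mid_time = mid,
      mid_lon = if (!is.null(gps)) approx(gps$time, gps$lon, mid, rule = 2)$y else NA_real_,
      mid_lat = if (!is.null(gps)) approx(gps$time, gps$lat, mid, rule = 2)$y else NA_real_,
      n_beats = nrow(wb),
      altitude_agl = .seg_mean(agl[ai]),
      tortuosity = if (length(turns) >= 2) circular_sd(turns) else NA_real_,
      wb_freq_mean = .seg_mean(wb$frequency_hz),
      wb_amp_mean = .seg_mean(wb$amplitude_g[!is.na(wb$amplitude_g)]),
      airspeed_mean = .seg_mean(track$airspeed[ti]),
      wb_freq_sd = .seg_sd(wb$frequency_hz),
      wb_amp_sd = .seg_sd(wb$amplitude_g[!is.na(wb$amplitude_g)]),
      airspeed_sd = .seg_sd(track$airspeed[ti]),
      hwc = .seg_mean(track$hwc[ti]),
      climb_rate = .seg_mean(vz$vz[vi])
    )
  })
  out <- bind_rows(rows)
  out <- left_join(out,
                   turbulence[, c("segment_id", "proxy_hpa", "sqrt_proxy",
                                  "w_star", "u_star")],
                   by = "segment_id")
  out$sqrt_turbulence <- out$sqrt_proxy
  out$sqrt_altitude_agl <- sqrt(pmax(out$altitude_agl, 0))
  need <- c(flap_responses(), "sqrt_turbulence", "hwc", "climb_rate",
            "sqrt_altitude_agl")
  complete <- stats::complete.cases(out[need]) &
    apply(is.finite(as.matrix(out[need])), 1, all)
  if (any(!complete)) {
    message(sum(!complete), " segment(s) dropped (undefined responses, e.g. < 2 wingbeats)")
  }
  res <- out[complete, ]
  attr(res, "dropped") <- sum(!complete)
  class(res) <- c("flight_segments", class(res))
  res
}

#' Run the full per-flight pipeline
#'
#' Orientation correction (optional), wingbeat detection, barometric
#' altimetry (ASL, AGL, climb rate), track decomposition, per-segment
#' turbulence proxy, and segment-table assembly for one flight.
#'
#' @param flight A [flight_record()].
#' @param terrain Optional [terrain_grid()] for AGL conversion.
#' @param wind Optional [wind_series()] for the wind triangle.
#' @param level_window Optional `c(t0, t1)` window of level flight for
#'   [correct_orientation()]; `NULL` skips the correction.
#' @param min_prominence_g Passed to [detect_wingbeats()].
#' @param window_s,min_tail_s Segmentation parameters.
#' @return A `flight_segments` tibble (see [build_segment_table()]).
#' @export
analyze_flight <- function(flight, terrain = NULL, wind = NULL,
                           level_window = NULL, min_prominence_g = NULL,
                           window_s = 15, min_tail_s = 10) {
  stopifnot(inherits(flight, "flight_record"))
  accel <- flight$accel
  if (!is.null(level_window)) {
    accel <- correct_orientation(accel, level_window)
  }
  wingbeats <- detect_wingbeats(accel, min_prominence_g = min_prominence_g)
  altitude <- pressure_to_altitude(flight$pressure, flight$p0_sealevel)
  if (!is.null(terrain)) {
    altitude <- altitude_agl(altitude, flight$gps, terrain)
  }
  track <- track_steps(flight$gps, wind)
  segments <- segment_flight(flight, window_s = window_s,
                             min_tail_s = min_tail_s)
  turb <- segment_turbulence(flight$pressure, segments)
  build_segment_table(segments, wingbeats, altitude, track, turb,
                      flight_id = flight$flight_id, gps = flight$gps)
}

#' @rdname analyze_flight
#' @param flights A list of `flight_record`s.
#' @param ... Passed on to `analyze_flight()`.
#' @export
analyze_flights <- function(flights, ...) {
  out <- purrr::map(flights, analyze_flight, ...)
  out <- bind_rows(out)
  class(out) <- c("flight_segments", class(out))
  out
}

#' Standardize (scale and centre) response columns
#'
#' Centres each response to mean 0 and scales to SD 1, storing the constants
#' in the `standardization` attribute so [unstandardize_responses()] can
#' invert the transform exactly.
#'
#' @param table A segment table.
#' @param responses Columns to standardize.
#' @return The table with standardized columns.
#' @export
standardize_responses <- function(table, responses = flap_responses()) {
  cons <- purrr::map(responses, function(r) {
    x <- table[[r]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("zero variance in response '", r, "': cannot standardize",
           call. = FALSE)
    }
    table[[r]] <<- (x - mean(x)) / s
    tibble(response = r, center = mean(x), scale = s)
  })
  attr(table, "standardization") <- bind_rows(cons)
  table
}

#' @rdname standardize_responses
#' @export
unstandardize_responses <- function(table) {
  cons <- attr(table, "standardization")
  if (is.null(cons)) stop("table carries no standardization attribute", call. = FALSE)
  for (i in seq_len(nrow(cons))) {
    r <- cons$response[i]
    table[[r]] <- table[[r]] * cons$scale[i] + cons$center[i]
  }
  attr(table, "standardization") <- NULL
  table
}

#' @export
autoplot.flight_segments <- function(object, responses = flap_responses(), ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[c("sqrt_turbulence", responses)],
                            all_of(responses),
                            names_to = "response", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sqrt_turbulence, y = .data$value)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = expression(sqrt(turbulence ~ proxy) ~ (hPa^{1/2})),
                  y = NULL)
}
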