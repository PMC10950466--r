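# Tag-orientation correction and wingbeat detection from heave acceleration.

#' Centred running mean
#'
#' Moving average over a window of `window_events` samples, centred on each
#' sample and truncated at the series edges, so the output has the same
#' length as the input. For even windows the extra sample is taken on the
#' trailing side.
#'
#' @param x Numeric series.
#' @param window_events Window length in samples (>= 1, <= length of series).
#' @return Numeric vector, same length as `x`.
#' @export
running_mean <- function(x, window_events) {
  n <- length(x)
  if (n == 0) stop("empty series", call. = FALSE)
  w <- as.integer(window_events)
  if (w < 1 || w > n) stop("window_events must be in [1, length(x)]", call. = FALSE)
  left <- (w - 1L) %/% 2L
  right <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Correct tag orientation against gravity
#'
#' Small deployment-to-deployment differences in tag orientation are removed
#' by finding the mean acceleration vector over a window of level flapping
#' flight (where the cycle-averaged specific force is gravity) and applying
#' the single rotation that maps it onto the heave axis (0, 0, 1). Per-sample
#' vector norms are preserved; after correction the window-mean heave equals
#' the window-mean vector magnitude (1 g in level flight).
#'
#' @param trace An [accel_trace()].
#' @param level_window Length-2 numeric `c(t0, t1)`: a window of level flight
#'   of at least 2 s, inside the trace.
#' @return The rotated `accel_trace`.
#' @export
correct_orientation <- function(trace, level_window) {
  stopifnot(inherits(trace, "accel_trace"), length(level_window) == 2)
  t0 <- level_window[1]; t1 <- level_window[2]
  if (t1 - t0 < 2) {
    stop("level_window must cover a segment of level flight of at least 2 s",
         call. = FALSE)
  }
  if (t0 < min(trace$time) || t1 > max(trace$time)) {
    stop("level_window must lie inside the trace", call. = FALSE)
  }
  sel <- trace$time >= t0 & trace$time <= t1
  m <- c(mean(trace$surge[sel]), mean(trace$sway[sel]), mean(trace$heave[sel]))
  nm <- sqrt(sum(m^2))
  if (nm == 0) stop("zero mean acceleration in level window", call. = FALSE)
  u <- m / nm
  ez <- c(0, 0, 1)
  axis <- c(u[2] * ez[3] - u[3] * ez[2],
            u[3] * ez[1] - u[1] * ez[3],
            u[1] * ez[2] - u[2] * ez[1])
  s <- sqrt(sum(axis^2))
  cth <- u[3]
  if (s < 1e-12) {
    R <- if (cth > 0) diag(3) else diag(c(1, -1, -1)) # 180 deg about surge
  } else {
    k <- axis / s
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + s * K + (1 - cth) * (K %*% K)
  }
  M <- cbind(trace$surge, trace$sway, trace$heave) %*% t(R)
  accel_trace(trace$time, M[, 1], M[, 2], M[, 3])
}

# 3-point parabola refinement of a local extremum's value (sub-sample)
.refine_peak_value <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(y[i])
  a <- y[i - 1L]; b <- y[i]; cc <- y[i + 1L]
  den <- a - 2 * b + cc
  if (!is.finite(den) || den >= -1e-300) return(b)
  b - (a - cc)^2 / (8 * den)
}
.refine_trough_value <- function(y, i) -.refine_peak_value(-y, i)

#' Detect wingbeats from heave acceleration
#'
#' The detector smooths the raw heave over `smooth_events` samples, takes a
#' centred difference spanning `diff_events` samples, and marks candidate
#' peaks at positive-to-negative transitions of this differential. Candidates
#' whose local peak-to-trough excursion in the *raw* heave falls below
#' `min_prominence_g` are rejected, removing high-frequency oscillations that
#' would otherwise register as false peaks. Peak times are refined to
#' sub-sample precision by linear interpolation of the differential's zero
#' crossing; cycle extrema are refined with a 3-point parabola.
#'
#' Per beat, the frequency is the reciprocal of the period to the previous
#' peak and the amplitude is the peak-to-trough range of raw heave over the
#' half-open interval from the previous peak; both are undefined (NA) for the
#' first beat.
#'
#' @param trace An [accel_trace()] of at least 1 s.
#' @param smooth_events Smoothing window, samples.
#' @param diff_events Span of the centred difference, samples.
#' @param min_prominence_g Prominence threshold in g. `NULL` (default) uses
#'   0.25 x the median candidate excursion, mirroring the per-flight manual
#'   threshold adjustment of the field workflow.
#' @return A tibble of class `wingbeat_series` with columns `peak_time`,
#'   `frequency_hz`, `amplitude_g`; detector settings are stored in the
#'   `settings` attribute. Empty (zero rows) when nothing passes the filter.
#' @examples
#' tm <- seq(0, 10, by = 1 / 200)
#' tr <- accel_trace(tm, 0, 0, 1 + 2 * sin(2 * pi * 6 * tm))
#' wb <- detect_wingbeats(tr, min_prominence_g = 0.5)
#' mean(wb$frequency_hz, na.rm = TRUE)
#' @export
detect_wingbeats <- function(trace, smooth_events = 20, diff_events = 20,
                             min_prominence_g = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  if (max(trace$time) - min(trace$time) < 1) {
    stop("trace must span at least 1 s", call. = FALSE)
  }
  if (!is.null(min_prominence_g) && min_prominence_g < 0) {
    stop("min_prominence_g must be >= 0", call. = FALSE)
  }
  h <- trace$heave
  tm <- trace$time
  n <- length(h)
  s <- running_mean(h, smooth_events)
  half <- max(1L, as.integer(diff_events) %/% 2L)
  d <- rep(NA_real_, n)
  idx <- (half + 1L):(n - half)
  d[idx] <- s[idx + half] - s[idx - half]
  ok <- !is.na(d)
  cand <- which(ok[-n] & ok[-1] & d[-n] > 0 & d[-1] <= 0)

  settings <- list(smooth_events = smooth_events, diff_events = diff_events,
                   min_prominence_g = min_prominence_g)
  empty <- tibble(peak_time = numeric(), frequency_hz = numeric(),
                  amplitude_g = numeric())
  if (!length(cand)) {
    return(.new_wingbeat_series(empty, settings))
  }
  m <- length(cand)
  exc <- numeric(m)
  for (k in seq_len(m)) {
    lo <- if (k > 1L) cand[k - 1L] else 1L
    hi <- if (k < m) cand[k + 1L] else n
    exc[k] <- max(h[lo:hi]) - min(h[lo:hi])
  }
  thr <- min_prominence_g %||% (0.25 * stats::median(exc))
  settings$min_prominence_g <- thr
  peaks <- cand[exc >= thr]
  if (!length(peaks)) {
    warning("all wingbeat candidates rejected by the prominence filter",
            call. = FALSE)
    return(.new_wingbeat_series(empty, settings))
  }
  dt <- stats::median(diff(tm))
  # sub-sample peak time: zero crossing of the differential
  pt <- tm[peaks] + dt * d[peaks] / (d[peaks] - d[peaks + 1L])
  nb <- length(peaks)
  amp <- rep(NA_real_, nb)
  if (nb >= 2L) {
    for (k in 2:nb) {
      i1 <- peaks[k - 1L]
      i2 <- peaks[k] - 1L
      # the cycle's peak is the detected peak itself: search raw heave only in
      # a quarter-cycle neighbourhood of it, so the following beat's peak
      # cannot leak into this cycle's amplitude
      q <- max(2L, (i2 - i1) %/% 4L)
      pk <- max(i1 - q, 1L):min(i1 + q, n)
      seg <- h[i1:i2]
      amp[k] <- .refine_peak_value(h, pk[which.max(h[pk])]) -
        .refine_trough_value(h, i1 + which.min(seg) - 1L)
    }
  }
  out <- tibble(peak_time = pt,
                frequency_hz = c(NA_real_, 1 / diff(pt)),
                amplitude_g = amp)
  .new_wingbeat_series(out, settings)
}

.new_wingbeat_series <- function(df, settings) {
  attr(df, "settings") <- settings
  class(df) <- c("wingbeat_series", class(df))
  df
}

#' Flapping wing speed
#'
#' Product of mean wingbeat frequency and mean (peak-to-trough heave)
#' amplitude, a proxy for propulsive effort. Callers compute it separately
#' for ascents (Vz > 0) and descents (Vz < 0).
#'
#' @param mean_frequency Mean wingbeat frequency, Hz (>= 0).
#' @param mean_amplitude Mean wingbeat amplitude, g (>= 0).
#' @return Flapping wing speed in g Hz (vectorized).
#' @export
flapping_wing_speed <- function(mean_frequency, mean_amplitude) {
  if (any(mean_frequency < 0, na.rm = TRUE) ||
      any(mean_amplitude < 0, na.rm = TRUE)) {
    stop("frequency and amplitude must be >= 0", call. = FALSE)
  }
  mean_frequency * mean_amplitude
}

#' @export
autoplot.wingbeat_series <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object), c("frequency_hz", "amplitude_g"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_time, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Detected wingbeats")
}
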