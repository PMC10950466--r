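# Pressure-based turbulence proxy, inertial-subrange spectral fit,
# boundary-layer velocity scales, climatology comparison.

#' Pressure-fluctuation IQR turbulence proxy
#'
#' Within a flight segment the barometric pressure is detrended with an
#' ordinary-least-squares line (isolating fluctuations from steady climb or
#' descent) and the interquartile range of the residuals — quartiles by
#' linear interpolation (type 7) — is the turbulence proxy. Translation
#' invariant and linear in the residual amplitude.
#'
#' @param pressure A [pressure_trace()] (or numeric vector, with `time`).
#' @param time Sample times, s; taken from the trace when omitted.
#' @param detrend Remove the within-segment linear trend first (default).
#'   `FALSE` only subtracts the mean — kept as a sensitivity switch.
#' @param min_duration_s Minimum segment length, s; shorter segments are the
#'   ones the segmentation excludes.
#' @return Proxy value, hPa.
#' @export
pressure_fluctuation_iqr <- function(pressure, time = NULL, detrend = TRUE,
                                     min_duration_s = 10) {
  if (inherits(pressure, "pressure_trace")) {
    time <- pressure$time
    pressure <- pressure$pressure_hpa
  }
  n <- length(pressure)
  if (is.null(time)) time <- seq_len(n)
  dt <- stats::median(diff(time))
  if (n * dt < min_duration_s - 1e-9) {
    stop(sprintf("segment too short: %.2f s < %g s minimum", n * dt,
                 min_duration_s), call. = FALSE)
  }
  r <- if (detrend) {
    stats::.lm.fit(cbind(1, time), pressure)$residuals
  } else {
    pressure - mean(pressure)
  }
  IQR(r, type = 7)
}

# Welch-averaged one-sided PSD: Hann window, 50% overlap, per-segment mean
# removal; density convention is variance per Hz (so integral over f gives
# the series variance).
.welch_psd <- function(x, fs, nperseg = 256, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1)))
  scale <- fs * sum(w^2)
  nf <- nperseg %/% 2L - 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    X <- fft((seg - mean(seg)) * w)
    acc <- acc + 2 * Mod(X[2:(nf + 1L)])^2 / scale
  }
  list(f = (1:nf) * fs / nperseg, psd = acc / length(starts),
       n_segments = length(starts))
}

#' Fit the -5/3 inertial-subrange power law
#'
#' Computes a Welch-averaged periodogram of a wind-speed series and fits
#' `log S = log A - (5/3) log f` over the inertial band by least squares with
#' the slope *fixed* at -5/3, estimating only the spectral constant `A` — a
#' qualitative measure of the turbulence present. The residual SD in log
#' space reports how well the series follows the ideal law.
#'
#' @param x Wind-speed series: numeric vector or the tibble returned by
#'   [simulate_turbulent_wind()].
#' @param fs Sampling rate, Hz (taken from the tibble attribute if present).
#' @param band Inertial band `c(f_lo, f_hi)`, Hz, inside (0, fs/2).
#' @param nperseg Welch segment length, samples.
#' @return An object of class `spectral_fit`: list with `constant` (A),
#'   `band`, `resid_sd` (log-space residual SD), `n_freq`, `n_segments`.
#' @export
spectral_constant <- function(x, fs = NULL, band = c(0.1, 5), nperseg = 256) {
  if (is.data.frame(x)) {
    fs <- fs %||% attr(x, "fs")
    x <- x$speed
  }
  if (is.null(fs)) stop("fs must be supplied", call. = FALSE)
  if (length(x) < 64) stop("need at least 64 samples", call. = FALSE)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop("band must lie within (0, fs/2)", call. = FALSE)
  }
  ps <- .welch_psd(x, fs, nperseg = nperseg)
  sel <- ps$f >= band[1] & ps$f <= band[2]
  if (!any(sel)) stop("no periodogram frequencies inside the band", call. = FALSE)
  logS <- log(ps$psd[sel])
  logf <- log(ps$f[sel])
  logA <- mean(logS + (5 / 3) * logf)
  structure(
    list(constant = exp(logA), band = band,
         resid_sd = stats::sd(logS + (5 / 3) * logf - logA),
         n_freq = sum(sel), n_segments = ps$n_segments),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> A = %.4g over [%.3g, %.3g] Hz (fixed -5/3 slope); log-resid SD %.3f (%d freqs, %d Welch segments)\n",
              x$constant, x$band[1], x$band[2], x$resid_sd, x$n_freq,
              x$n_segments))
  invisible(x)
}

#' Deardorff convective velocity scale
#'
#' `w* = (g * zi * Q0v / theta_v)^(1/3)` for positive surface buoyancy flux;
#' zero under stable or neutral stratification — the velocity scale of
#' thermally generated boundary-layer turbulence.
#'
#' @param q0v Surface kinematic virtual heat flux, K m s^-1 (vectorized).
#' @param zi Boundary-layer depth, m (> 0).
#' @param theta_v Reference virtual potential temperature, K, in (200, 330).
#' @param g Gravitational acceleration, m s^-2.
#' @return `w*` in m s^-1.
#' @export
convective_velocity <- function(q0v, zi, theta_v, g = 9.80665) {
  if (any(zi <= 0)) stop("zi must be > 0", call. = FALSE)
  if (any(theta_v <= 200 | theta_v >= 330)) {
    stop("theta_v outside the plausible (200, 330) K range", call. = FALSE)
  }
  ifelse(q0v > 0, (g * zi * q0v / theta_v)^(1 / 3), 0)
}

#' Friction (shear) velocity scale
#'
#' `u* = sqrt(|tau| / rho)` with `|tau| = sqrt(tau_x^2 + tau_y^2)` — the
#' velocity scale of mechanically (shear-) generated turbulence from surface
#' stress. Invariant to rotation of the stress components.
#'
#' @param tau_x,tau_y Surface stress components, N m^-2 (vectorized).
#' @param rho Air density, kg m^-3 (> 0).
#' @return `u*` in m s^-1.
#' @export
shear_velocity <- function(tau_x, tau_y, rho) {
  if (any(rho <= 0)) stop("rho must be > 0", call. = FALSE)
  sqrt(sqrt(tau_x^2 + tau_y^2) / rho)
}

#' Pooled two-sample t-test for climatology comparison
#'
#' Compares boundary-layer velocity scales sampled during flights with the
#' seasonal climatology using a pooled-variance two-sample t-test
#' (`df = n_a + n_b - 2`), two-sided.
#'
#' @param sample_a,sample_b Numeric samples, each with at least 2 values.
#' @return A tibble with columns `statistic` (t), `df`, `p_value`.
#' @export
climatology_ttest <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0 &&
      mean(sample_a) == mean(sample_b)) {
    # identical constant-difference case t.test refuses; define t = 0
    return(tibble(statistic = 0,
                  df = length(sample_a) + length(sample_b) - 2,
                  p_value = 1))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Per-segment turbulence context
#'
#' Applies [pressure_fluctuation_iqr()] to each segment of a flight's
#' pressure stream and attaches optional boundary-layer velocity scales.
#'
#' @param pressure A [pressure_trace()].
#' @param segments Segment table from [segment_flight()].
#' @param w_star,u_star Optional per-segment (or scalar) velocity scales,
#'   m s^-1.
#' @param detrend Passed to [pressure_fluctuation_iqr()].
#' @return A tibble with columns `segment_id`, `proxy_hpa`, `sqrt_proxy`,
#'   `w_star`, `u_star`.
#' @export
segment_turbulence <- function(pressure, segments, w_star = NA_real_,
                               u_star = NA_real_, detrend = TRUE) {
  stopifnot(inherits(pressure, "pressure_trace"))
  proxy <- purrr::map_dbl(seq_len(nrow(segments)), function(i) {
    sel <- pressure$time >= segments$start[i] & pressure$time < segments$end[i]
    if (!any(sel)) return(NA_real_)
    pressure_fluctuation_iqr(pressure$pressure_hpa[sel], pressure$time[sel],
                             detrend = detrend)
  })
  tibble(segment_id = segments$segment_id, proxy_hpa = proxy,
         sqrt_proxy = sqrt(proxy),
         w_star = rep_len(w_star, nrow(segments)),
         u_star = rep_len(u_star, nrow(segments)))
}
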