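# Synthetic flight generator: flapping heave, OU-driven altitude/pressure,
# wind-advected GPS track, all with known ground truth.

#' Configuration for a synthetic flight
#'
#' The generator emulates the statistical structure the segment analysis
#' assumes: a flapping heave signal whose stroke-to-stroke frequency and
#' amplitude variability grows linearly with a known turbulence level `T`
#' (per-beat SD = `sigma0 + gamma * T`), a barometric altitude built from a
#' slow trend plus an Ornstein-Uhlenbeck vertical displacement whose
#' stationary SD is proportional to `T`, and a GPS track advected by a
#' constant wind plus OU horizontal gusts. Turbulence is piecewise constant
#' on the same 15 s grid the segmentation uses.
#'
#' Defaults describe a homing pigeon cruising over gently rolling farmland:
#' 6 Hz wingbeats of 2 g half-amplitude (4 g peak-to-trough), 19 m s^-1
#' airspeed, light (2, 1) m s^-1 wind, 480 m ASL over ~400 m terrain
#' (about 80 m above ground).
#'
#' @param duration Flight duration, s (>= 30).
#' @param f0 Base wingbeat frequency, Hz.
#' @param A0 Base heave half-amplitude, g (detected peak-to-trough is 2*A0).
#' @param turbulence Turbulence level `T >= 0`: scalar or one value per 15 s
#'   segment (recycled across the segment grid).
#' @param sigma0_f,gamma_f Baseline SD and per-unit-T gain of per-beat
#'   frequency, Hz.
#' @param sigma0_a,gamma_a Baseline SD and per-unit-T gain of per-beat
#'   half-amplitude, g.
#' @param freq_slope Change of mean wingbeat frequency per unit T, Hz
#'   (0 = mean kinematics independent of turbulence).
#' @param amp_slope Change of mean half-amplitude per unit T, g.
#' @param constant_wing_speed If `TRUE`, the mean half-amplitude is set to
#'   `A0 * f0 / f(T)` so the frequency-amplitude product stays constant as
#'   `freq_slope` shifts the frequency.
#' @param tau_ou Relaxation time of the OU gust/displacement processes, s.
#' @param disp_per_t Stationary SD of the OU vertical displacement per unit
#'   T, m.
#' @param gust_per_t Stationary SD of each horizontal OU gust component per
#'   unit T, m s^-1.
#' @param mean_altitude Mean altitude ASL, m.
#' @param climb_mps Slow linear altitude trend, m s^-1.
#' @param alt_wander_sd Stationary SD of the slow altitude trajectory (an OU
#'   wander with relaxation `tau_wander`, independent of turbulence —
#'   behavioural height variation), m.
#' @param tau_wander Relaxation time of the slow altitude wander, s.
#' @param wind Length-2 wind vector `c(u, v)`, m s^-1 (east, north).
#' @param airspeed Mean airspeed, m s^-1.
#' @param heading Geographic heading of the air velocity, degrees.
#' @param start_lon,start_lat Release point, decimal degrees.
#' @param p0_sealevel Sea-level reference pressure, hPa.
#' @param accel_noise_sd Accelerometer white-noise SD, g.
#' @param pressure_noise_sd Pressure-sensor white-noise SD, hPa.
#' @param gps_noise_m GPS position noise SD, m (per fix, each axis).
#' @param accel_rate,pressure_rate,gps_rate Sampling rates, Hz.
#' @param seed Integer seed; all randomness flows from it through named
#'   substreams, so equal seeds give bit-identical flights.
#' @param flight_id,bird_id Identifiers for the generated record.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_flight()]
#' @export
sim_config <- function(duration = 300, f0 = 6, A0 = 2, turbulence = 1,
                       sigma0_f = 0.05, gamma_f = 0.15,
                       sigma0_a = 0.05, gamma_a = 0.2,
                       freq_slope = 0, amp_slope = 0,
                       constant_wing_speed = FALSE,
                       tau_ou = 2, disp_per_t = 1.5, gust_per_t = 0.5,
                       mean_altitude = 480, climb_mps = 0,
                       alt_wander_sd = 3, tau_wander = 60,
                       wind = c(u = 2, v = 1), airspeed = 19, heading = 45,
                       start_lon = 8.97, start_lat = 47.77,
                       p0_sealevel = 1013.25,
                       accel_noise_sd = 0.02, pressure_noise_sd = 0.02,
                       gps_noise_m = 1,
                       accel_rate = 200, pressure_rate = 20, gps_rate = 1,
                       seed = 1, flight_id = "sim-1", bird_id = "bird-1") {
  cfg <- list(duration = duration, f0 = f0, A0 = A0, turbulence = turbulence,
              sigma0_f = sigma0_f, gamma_f = gamma_f,
              sigma0_a = sigma0_a, gamma_a = gamma_a,
              freq_slope = freq_slope, amp_slope = amp_slope,
              constant_wing_speed = isTRUE(constant_wing_speed),
              tau_ou = tau_ou, disp_per_t = disp_per_t,
              gust_per_t = gust_per_t,
              mean_altitude = mean_altitude, climb_mps = climb_mps,
              alt_wander_sd = alt_wander_sd, tau_wander = tau_wander,
              wind = c(u = unname(wind[1]), v = unname(wind[2])),
              airspeed = airspeed, heading = heading,
              start_lon = start_lon, start_lat = start_lat,
              p0_sealevel = p0_sealevel,
              accel_noise_sd = accel_noise_sd,
              pressure_noise_sd = pressure_noise_sd,
              gps_noise_m = gps_noise_m,
              accel_rate = accel_rate, pressure_rate = pressure_rate,
              gps_rate = gps_rate, seed = as.integer(seed),
              flight_id = flight_id, bird_id = bird_id)
  num <- cfg[!(names(cfg) %in% c("flight_id", "bird_id", "constant_wing_speed"))]
  if (any(!is.finite(unlist(num)))) {
    stop("non-finite sim_config entry", call. = FALSE)
  }
  if (duration < 30) stop("duration must be >= 30 s", call. = FALSE)
  if (f0 <= 0 || A0 <= 0 || tau_ou <= 0) {
    stop("f0, A0 and tau_ou must be positive", call. = FALSE)
  }
  if (tau_wander <= 0) stop("tau_wander must be positive", call. = FALSE)
  if (any(c(sigma0_f, gamma_f, sigma0_a, gamma_a, disp_per_t, gust_per_t,
            alt_wander_sd, accel_noise_sd, pressure_noise_sd, gps_noise_m) < 0)) {
    stop("noise SDs and gains must be >= 0", call. = FALSE)
  }
  if (any(turbulence < 0)) stop("turbulence levels must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$duration, "s flight;", x$f0, "Hz /", x$A0,
      "g base stroke; T =", paste(unique(x$turbulence), collapse = ", "),
      "; seed", x$seed, "\n")
  invisible(x)
}

#' Build a sim_config from a YAML file
#'
#' Reads the `simulation:` section (or the whole document if absent) and
#' passes the fields to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y <- y$simulation
  if (!is.null(y$wind)) y$wind <- unlist(y$wind)
  if (!is.null(y$turbulence)) y$turbulence <- unlist(y$turbulence)
  do.call(sim_config, y)
}

#' Ornstein-Uhlenbeck sample path
#'
#' Exact discretization `x[t+1] = a x[t] + sqrt(1 - a^2) sd * eps`,
#' `a = exp(-dt/tau)`, initialized from the stationary distribution, so the
#' process is stationary with SD `sd` and autocorrelation time `tau` from the
#' first sample. Uses the current RNG state.
#'
#' @param n Number of samples.
#' @param dt Time step, s.
#' @param tau Relaxation time, s (> 0).
#' @param sd Stationary standard deviation (>= 0).
#' @return Numeric vector of length `n`.
#' @export
sim_ou <- function(n, dt, tau, sd = 1) {
  stopifnot(n >= 1, dt > 0, tau > 0, sd >= 0)
  a <- exp(-dt / tau)
  x0 <- rnorm(1)
  innov <- rnorm(n, 0, sqrt(1 - a^2))
  sd * as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
}

# derive named substream seeds from the master seed (keeps streams independent
# of each other's sample counts)
.substream_seeds <- function(seed, names) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

#' Simulate one flight with known ground truth
#'
#' Generates a complete [flight_record()] (acceleration, pressure, GPS) plus
#' the ground truth every downstream stage can be checked against: the
#' per-segment turbulence level, the true per-beat frequency and amplitude,
#' the true altitude series and the configured wind.
#'
#' Heave is `1 g + A_k sin(2 pi f_k t)` with fresh per-beat draws; negative
#' draws are clamped at 0.1 of the base value. Pressure follows the exact
#' inverse of the ISA hypsometric map used by [pressure_to_altitude()], so
#' altimetry round-trips are clean. GPS positions integrate
#' airspeed-heading + wind + OU gusts at 1 Hz.
#'
#' @param config A [sim_config()].
#' @return A list with elements `flight` (a `flight_record`) and `truth`
#'   (list: `segments` tibble with per-segment `turbulence`, `beats` tibble
#'   with true per-beat `frequency_hz` and peak-to-trough `amplitude_g`,
#'   `altitude` tibble, `wind`, `airspeed`, `heading`).
#' @examples
#' fl <- simulate_flight(sim_config(duration = 60, seed = 7))
#' fl$flight
#' @export
simulate_flight <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  seeds <- .substream_seeds(cfg$seed, c("beats", "accel_noise", "alt_ou",
                                        "alt_wander", "pressure_noise",
                                        "gust_u", "gust_v", "gps_noise"))
  seg <- segment_grid(cfg$duration)
  seg$turbulence <- rep_len(cfg$turbulence, nrow(seg))
  t_level <- function(t) {
    i <- pmin(pmax(findInterval(t, seg$start), 1L), nrow(seg))
    seg$turbulence[i]
  }

  # --- per-beat kinematics ---------------------------------------------------
  set.seed(seeds[["beats"]])
  n_max <- ceiling(cfg$duration * cfg$f0 * 2) + 16L
  b_start <- b_f <- b_a <- numeric(n_max)
  t <- 0; k <- 0L
  while (t < cfg$duration) {
    k <- k + 1L
    Tk <- t_level(t)
    f_mean <- max(cfg$f0 + cfg$freq_slope * Tk, 0.1 * cfg$f0)
    a_mean <- if (cfg$constant_wing_speed) {
      cfg$A0 * cfg$f0 / f_mean
    } else {
      max(cfg$A0 + cfg$amp_slope * Tk, 0.1 * cfg$A0)
    }
    f_k <- max(rnorm(1, f_mean, cfg$sigma0_f + cfg$gamma_f * Tk), 0.1 * cfg$f0)
    a_k <- max(rnorm(1, a_mean, cfg$sigma0_a + cfg$gamma_a * Tk), 0.1 * cfg$A0)
    b_start[k] <- t; b_f[k] <- f_k; b_a[k] <- a_k
    t <- t + 1 / f_k
  }
  b_start <- b_start[1:k]; b_f <- b_f[1:k]; b_a <- b_a[1:k]

  # --- acceleration ----------------------------------------------------------
  n_a <- round(cfg$duration * cfg$accel_rate)
  t_a <- (seq_len(n_a) - 1) / cfg$accel_rate
  bi <- pmax(findInterval(t_a, b_start), 1L)
  heave <- 1 + b_a[bi] * sin(2 * pi * b_f[bi] * (t_a - b_start[bi]))
  set.seed(seeds[["accel_noise"]])
  if (cfg$accel_noise_sd > 0) {
    surge <- rnorm(n_a, 0, cfg$accel_noise_sd)
    sway <- rnorm(n_a, 0, cfg$accel_noise_sd)
    heave <- heave + rnorm(n_a, 0, cfg$accel_noise_sd)
  } else {
    surge <- sway <- numeric(n_a)
  }
  accel <- accel_trace(t_a, surge, sway, heave)

  # --- altitude & pressure ---------------------------------------------------
  n_p <- round(cfg$duration * cfg$pressure_rate)
  t_p <- (seq_len(n_p) - 1) / cfg$pressure_rate
  set.seed(seeds[["alt_ou"]])
  z_unit <- sim_ou(n_p, 1 / cfg$pressure_rate, cfg$tau_ou, 1)
  set.seed(seeds[["alt_wander"]])
  wander <- if (cfg$alt_wander_sd > 0) {
    sim_ou(n_p, 1 / cfg$pressure_rate, cfg$tau_wander, cfg$alt_wander_sd)
  } else 0
  alt_true <- cfg$mean_altitude + cfg$climb_mps * t_p + wander +
    cfg$disp_per_t * t_level(t_p) * z_unit
  p_true <- altitude_to_pressure(alt_true, cfg$p0_sealevel)
  set.seed(seeds[["pressure_noise"]])
  p_obs <- p_true + if (cfg$pressure_noise_sd > 0) {
    rnorm(n_p, 0, cfg$pressure_noise_sd)
  } else 0
  pressure <- pressure_trace(t_p, p_obs)

  # --- GPS track -------------------------------------------------------------
  n_g <- max(2L, round(cfg$duration * cfg$gps_rate))
  dt_g <- 1 / cfg$gps_rate
  t_g <- (seq_len(n_g) - 1) * dt_g
  th <- cfg$heading * pi / 180
  set.seed(seeds[["gust_u"]])
  gust_u <- cfg$gust_per_t * t_level(t_g) * sim_ou(n_g, dt_g, cfg$tau_ou, 1)
  set.seed(seeds[["gust_v"]])
  gust_v <- cfg$gust_per_t * t_level(t_g) * sim_ou(n_g, dt_g, cfg$tau_ou, 1)
  v_e <- cfg$airspeed * sin(th) + cfg$wind[["u"]] + gust_u
  v_n <- cfg$airspeed * cos(th) + cfg$wind[["v"]] + gust_v
  x <- cumsum(c(0, v_e[-n_g])) * dt_g
  y <- cumsum(c(0, v_n[-n_g])) * dt_g
  set.seed(seeds[["gps_noise"]])
  if (cfg$gps_noise_m > 0) {
    x <- x + rnorm(n_g, 0, cfg$gps_noise_m)
    y <- y + rnorm(n_g, 0, cfg$gps_noise_m)
  }
  phi <- cfg$start_lat * pi / 180
  m_per_deg_lat <- 111132.92 - 559.82 * cos(2 * phi) + 1.175 * cos(4 * phi)
  m_per_deg_lon <- 111412.84 * cos(phi) - 93.5 * cos(3 * phi)
  gps <- gps_track(t_g, cfg$start_lon + x / m_per_deg_lon,
                   cfg$start_lat + y / m_per_deg_lat)

  flight <- flight_record(cfg$flight_id, cfg$bird_id, accel, pressure, gps,
                          p0_sealevel = cfg$p0_sealevel)
  truth <- list(
    segments = seg,
    beats = tibble(start_time = b_start, frequency_hz = b_f,
                   half_amplitude_g = b_a, amplitude_g = 2 * b_a),
    altitude = tibble(time = t_p, altitude_asl = alt_true),
    wind = cfg$wind, airspeed = cfg$airspeed, heading = cfg$heading,
    config = cfg
  )
  list(flight = flight, truth = truth)
}

#' Synthesize a turbulent wind-speed series with a -5/3 spectrum
#'
#' Gaussian series generated by inverse-FFT spectral shaping so the one-sided
#' power spectral density follows the Kolmogorov inertial-subrange law
#' `S(f) = A * f^(-5/3)` (flattened below `f_floor` to keep the variance
#' finite). Band-averaged spectral density is linear in `A`; the log-log
#' periodogram slope over the inertial band is approximately -5/3.
#'
#' @param A Spectral constant (> 0); the density scale, units of
#'   variance per Hz at 1 Hz.
#' @param fs Sampling rate, Hz.
#' @param duration Series duration, s; `fs * duration` must be >= 64.
#' @param f_floor Frequency below which the target spectrum is held flat, Hz.
#' @return A tibble with columns `time` and `speed` (zero-mean fluctuation,
#'   m s^-1), with attributes `fs` and `A`.
#' @seealso [spectral_constant()] for the inverse (analysis) operation.
#' @export
simulate_turbulent_wind <- function(A, fs, duration, f_floor = 0.05) {
  if (!is.finite(A) || A <= 0) stop("A must be > 0", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  n <- round(fs * duration)
  if (n < 64) stop("series too short: need at least 64 samples", call. = FALSE)
  m <- n %/% 2L
  f <- (1:m) * fs / n
  S <- A * pmax(f, f_floor)^(-5 / 3)
  Z <- complex(n)
  even <- n %% 2L == 0L
  mm <- if (even) m - 1L else m
  X <- sqrt(S[1:mm] * fs * n / 4) *
    complex(real = rnorm(mm), imaginary = rnorm(mm))
  Z[2:(mm + 1)] <- X
  Z[n:(n - mm + 1)] <- Conj(X)
  if (even) Z[m + 1] <- sqrt(S[m] * fs * n / 2) * rnorm(1)
  x <- Re(fft(Z, inverse = TRUE)) / n
  out <- tibble(time = (seq_len(n) - 1) / fs, speed = x)
  attr(out, "fs") <- fs
  attr(out, "A") <- A
  out
}
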