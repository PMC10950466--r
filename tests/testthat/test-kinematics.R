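test_that("running_mean matches the direct windowed mean", {
  expect_equal(running_mean(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(running_mean(rep(2.5, 10), 7), rep(2.5, 10))
  set.seed(2)
  x <- rnorm(200)
  rm20 <- running_mean(x, 20)
  for (i in c(30, 100, 170)) {
    expect_equal(rm20[i], mean(x[(i - 9):(i + 10)]), tolerance = 1e-12)
  }
  expect_error(running_mean(numeric(0), 1), "empty")
  expect_error(running_mean(1:5, 6), "window")
})

test_that("orientation correction levels a tilted tag and preserves norms", {
  tm <- (0:999) / 200
  level <- accel_trace(tm, rep(0, 1000), rep(0, 1000), rep(1, 1000))
  out <- correct_orientation(level, c(0, 4))
  expect_lt(max(abs(out$heave - level$heave)), 1e-9)

  # gravity tilted 10 degrees in the surge-heave plane
  th <- 10 * pi / 180
  tilted <- accel_trace(tm, rep(sin(th), 1000), rep(0, 1000),
                        rep(cos(th), 1000))
  corr <- correct_orientation(tilted, c(0, 4))
  expect_equal(mean(corr$heave), 1, tolerance = 1e-6)
  expect_lt(abs(mean(corr$surge)), 1e-6)

  # per-sample norms preserved under the rotation
  set.seed(8)
  wob <- accel_trace(tm, sin(th) + rnorm(1000, 0, 0.1), rnorm(1000, 0, 0.1),
                     cos(th) + rnorm(1000, 0, 0.3))
  cw <- correct_orientation(wob, c(0, 4))
  n_before <- sqrt(wob$surge^2 + wob$sway^2 + wob$heave^2)
  n_after <- sqrt(cw$surge^2 + cw$sway^2 + cw$heave^2)
  expect_lt(max(abs(n_before - n_after)), 1e-9)

  expect_error(correct_orientation(level, c(0, 1)), "at least 2 s")
})

test_that("wingbeat detection matches the analytic cycle count of a sinusoid", {
  tr <- make_sine_trace(freq = 6, half_amp = 2, duration = 10)
  wb <- detect_wingbeats(tr, min_prominence_g = 0.5)
  expect_gte(nrow(wb), 59)
  expect_lte(nrow(wb), 60)
  expect_equal(mean(wb$frequency_hz, na.rm = TRUE), 6, tolerance = 0.05 / 6)
  expect_equal(mean(wb$amplitude_g, na.rm = TRUE), 4, tolerance = 0.1 / 4)
  expect_true(all(diff(wb$peak_time) > 0))

  # constant heave: no oscillation, no beats
  flat <- accel_trace((0:399) / 200, rep(0, 400), rep(0, 400), rep(1, 400))
  expect_identical(nrow(detect_wingbeats(flat, min_prominence_g = 0.1)), 0L)
})

test_that("sub-threshold ripple does not create false peaks", {
  clean <- make_sine_trace(freq = 6, half_amp = 2, duration = 10)
  rippled <- make_sine_trace(freq = 6, half_amp = 2, duration = 10,
                             ripple_hz = 50, ripple_amp = 0.1)
  n_clean <- nrow(detect_wingbeats(clean, min_prominence_g = 0.5))
  n_rip <- nrow(detect_wingbeats(rippled, min_prominence_g = 0.5))
  expect_identical(n_rip, n_clean)
})

test_that("detected frequency is robust to white noise", {
  set.seed(12)
  clean <- make_sine_trace(freq = 6, half_amp = 2, duration = 10)
  noisy <- make_sine_trace(freq = 6, half_amp = 2, duration = 10,
                           noise_sd = 0.1)
  f0 <- mean(detect_wingbeats(clean, min_prominence_g = 0.5)$frequency_hz,
             na.rm = TRUE)
  f1 <- mean(detect_wingbeats(noisy, min_prominence_g = 0.5)$frequency_hz,
             na.rm = TRUE)
  expect_lt(abs(f1 - f0) / f0, 0.02)
})

test_that("raising the prominence threshold never increases the beat count", {
  set.seed(13)
  tr <- make_sine_trace(freq = 6, half_amp = 2, duration = 8, noise_sd = 0.15)
  counts <- vapply(c(0, 0.3, 0.8, 1.5, 3, 4.5),
                   function(p) nrow(suppressWarnings(
                     detect_wingbeats(tr, min_prominence_g = p))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-segment kinematic variability tracks the turbulence ladder", {
  cfg <- sim_config(duration = 300, turbulence = rep(c(0, 0.5, 1, 2, 3), 4),
                    seed = 17)
  fl <- simulate_flight(cfg)
  wb <- detect_wingbeats(fl$flight$accel)
  seg <- fl$truth$segments
  sds <- purrr::map_dfr(seq_len(nrow(seg)), function(i) {
    w <- wb[!is.na(wb$frequency_hz) & wb$peak_time >= seg$start[i] &
              wb$peak_time < seg$end[i], ]
    tibble::tibble(true_t = seg$turbulence[i],
                   sd_f = sd(w$frequency_hz),
                   sd_a = sd(w$amplitude_g, na.rm = TRUE))
  })
  expect_gt(cor(sds$sd_f, sds$true_t, method = "spearman"), 0.8)
  expect_gt(cor(sds$sd_a, sds$true_t, method = "spearman"), 0.8)
})

test_that("flapping wing speed is the frequency-amplitude product", {
  expect_equal(flapping_wing_speed(6, 2), 12)
  expect_equal(flapping_wing_speed(0, 5), 0)
  expect_error(flapping_wing_speed(-1, 2), ">= 0")

  # noiseless simulation: segment wing speed = f0 * (2 A0) = 24 g Hz
  cfg <- sim_config(duration = 30, turbulence = 0, sigma0_f = 0, sigma0_a = 0,
                    accel_noise_sd = 0, pressure_noise_sd = 0, gps_noise_m = 0,
                    seed = 3)
  fl <- simulate_flight(cfg)
  wb <- detect_wingbeats(fl$flight$accel, min_prominence_g = 0.5)
  ws <- flapping_wing_speed(mean(wb$frequency_hz, na.rm = TRUE),
                            mean(wb$amplitude_g, na.rm = TRUE))
  expect_equal(ws, 24, tolerance = 0.6 / 24)
})
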