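test_that("hypsometric inversion matches the ISA oracle", {
  pr <- pressure_trace((0:99) / 20, rep(1013.25, 100))
  alt <- pressure_to_altitude(pr, 1013.25)
  expect_lt(max(abs(alt$altitude_asl)), 1e-9)

  pr500 <- pressure_trace((0:99) / 20, rep(954.61, 100))
  alt500 <- pressure_to_altitude(pr500, 1013.25)
  expect_equal(alt500$altitude_asl[50], 500, tolerance = 0.5 / 500)

  # exact inverse map round-trips
  h <- seq(0, 3000, by = 25)
  p <- altitude_to_pressure(h, 1000)
  tr <- pressure_trace(seq_along(h) / 20, p)
  back <- pressure_to_altitude(tr, 1000, smooth_seconds = 0)
  expect_lt(max(abs(back$altitude_asl - h)), 1e-6)

  expect_error(pressure_to_altitude(pr, 1200), "900, 1100")
})

test_that("below-sea-level readings trigger a warning", {
  pr <- pressure_trace((0:99) / 20, rep(1010, 100))
  expect_warning(pressure_to_altitude(pr, 1000), "below-sea-level")
})

test_that("climb rate recovers constant and linear profiles", {
  tm <- (0:200) / 20
  flat <- tibble::tibble(time = tm, altitude_asl = rep(480, 201))
  expect_lt(max(abs(climb_rate(flat)$vz)), 1e-9)
  lin <- tibble::tibble(time = tm, altitude_asl = 100 + 2 * tm)
  vz <- climb_rate(lin)$vz
  expect_equal(vz, rep(2, length(vz)), tolerance = 1e-6)
  expect_error(climb_rate(flat[1:20, ]), "2 s")
})

test_that("climb-rate sign matches the simulated trend", {
  cfg <- sim_config(duration = 60, climb_mps = 1, turbulence = 0.2, seed = 19)
  fl <- simulate_flight(cfg)
  alt <- pressure_to_altitude(fl$flight$pressure, cfg$p0_sealevel)
  vz <- climb_rate(alt)$vz
  expect_gt(mean(sign(vz) == 1), 0.95)
})

test_that("AGL subtracts terrain and conserves ASL", {
  gp <- gps_track(0:20, 8.97 + (0:20) * 1e-4, rep(47.77, 21))
  alt <- tibble::tibble(time = seq(0, 20, by = 0.5),
                        altitude_asl = rep(480, 41))
  class(alt) <- c("altitude_series", class(alt))
  out <- altitude_agl(alt, gp, flat_terrain(400))
  expect_equal(out$altitude_agl, rep(80, 41))
  expect_equal(out$altitude_agl + out$terrain_elev, out$altitude_asl)

  # ramp terrain crossed at constant ASL: AGL falls at -terrain slope
  ramp <- terrain_grid(seq(8.9, 9.1, by = 0.01), c(47.7, 47.8),
                       matrix(rep((0:20) * 10, 2), 21, 2))
  out2 <- altitude_agl(alt, gp, ramp)
  dagl_dlon <- coef(lm(out2$altitude_agl ~ approx(gp$time, gp$lon,
                                                  alt$time)$y))[2]
  expect_equal(unname(dagl_dlon), -10 / 0.01, tolerance = 1e-6)
})

test_that("turning angles follow the clockwise-positive convention", {
  east <- gps_track(0:4, 8.97 + (0:4) * 3e-4, rep(47.77, 5))
  expect_lt(max(abs(turning_angles(east)$turning_deg)), 1e-6)

  # east then south: clockwise turn, +90
  lon <- c(8.97, 8.9703, 8.9703)
  lat <- c(47.77, 47.77, 47.7698)
  turn <- turning_angles(gps_track(0:2, lon, lat))$turning_deg
  expect_equal(turn, 90, tolerance = 1e-3)

  # wrap-around: heading 350 then 10 is +20, not -340
  expect_equal(flapturb:::.wrap180(10 - 350), 20)
  expect_equal(flapturb:::.wrap180(180), 180)
  expect_equal(flapturb:::.wrap180(-180), 180)
})

test_that("circular SD matches the closed form and its invariances", {
  expect_equal(circular_sd(rep(33, 5)), 0, tolerance = 1e-9)
  expect_equal(circular_sd(c(45, -45)), sqrt(-2 * log(cos(pi / 4))) * 180 / pi,
               tolerance = 1e-6)
  set.seed(3)
  a <- runif(40, -120, 120)
  expect_equal(circular_sd(a + 55), circular_sd(a), tolerance = 1e-9)
  expect_equal(circular_sd(sample(a)), circular_sd(a), tolerance = 1e-12)
  # near-uniform angles diverge (R -> 0 flagged as degenerate)
  expect_warning(big <- circular_sd(seq(-179, 180, by = 1) + 0.25),
                 "degenerate")
  expect_gt(big, 500)
  expect_error(circular_sd(5), "at least 2")
})

test_that("wind triangle resolves head- and tailwinds", {
  still <- airspeed_hwc(20, 0, 0, 0)
  expect_equal(still$airspeed, 20)
  expect_equal(still$hwc, 0)
  head <- airspeed_hwc(20, 0, -5, 0)
  expect_equal(head$airspeed, 25)
  expect_equal(head$hwc, 5)
  tailw <- airspeed_hwc(20, 0, 5, 0)
  expect_equal(tailw$airspeed, 15)
  expect_equal(tailw$hwc, -5)
})

test_that("wind-triangle inequality holds for every step", {
  set.seed(23)
  gu <- rnorm(200, 10, 5); gv <- rnorm(200, 5, 5)
  wu <- rnorm(200, 0, 3); wv <- rnorm(200, 0, 3)
  res <- airspeed_hwc(gu, gv, wu, wv)
  vg <- sqrt(gu^2 + gv^2); w <- sqrt(wu^2 + wv^2)
  expect_true(all(res$airspeed >= abs(vg - w) - 1e-9))
  expect_true(all(res$airspeed <= vg + w + 1e-9))
})

test_that("track_steps reproduces a constant-velocity geometry", {
  # pure eastward 20 m/s at lat 0 where 1 deg lon ~ 111319.49 m
  m_per_deg <- 111319.4908
  gp <- gps_track(0:59, (0:59) * 20 / m_per_deg, rep(0, 60))
  tr <- track_steps(gp, steady_wind(-5, 0))
  expect_equal(mean(tr$heading), 90, tolerance = 1e-3)
  expect_equal(mean(tr$ground_speed), 20, tolerance = 1e-3)
  expect_equal(mean(tr$airspeed), 25, tolerance = 1e-3)
  expect_equal(mean(tr$hwc), 5, tolerance = 1e-3)
  expect_true(all(abs(tr$turning_angle[-1]) < 1e-6))
})
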