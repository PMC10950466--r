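# Fixtures are generated in code: sine flapping traces, flat/ramp terrain,
# steady wind, and scaled-down simulated flights.

make_sine_trace <- function(freq = 6, half_amp = 2, duration = 10, rate = 200,
                            noise_sd = 0, ripple_hz = NULL, ripple_amp = 0) {
  tm <- (seq_len(round(duration * rate)) - 1) / rate
  h <- 1 + half_amp * sin(2 * pi * freq * tm)
  if (!is.null(ripple_hz)) h <- h + ripple_amp * sin(2 * pi * ripple_hz * tm)
  if (noise_sd > 0) h <- h + rnorm(length(tm), 0, noise_sd)
  accel_trace(tm, rep(0, length(tm)), rep(0, length(tm)), h)
}

flat_terrain <- function(elev = 400) {
  terrain_grid(seq(8.5, 9.7, by = 0.05), seq(47.4, 48.3, by = 0.05),
               matrix(elev, 25, 19))
}

steady_wind <- function(u = 2, v = 1) {
  wind_series(c(0, 3600), c(u, u), c(v, v))
}

# a multi-flight segment table from the simulator; T ladder spans [0, 3]
sim_segment_table <- function(n_flights = 4, duration = 300, seed = 1, ...) {
  ladder <- c(0, 0.5, 1, 2, 3)
  tg <- flat_terrain()
  ws <- steady_wind()
  tabs <- lapply(seq_len(n_flights), function(i) {
    cfg <- sim_config(duration = duration,
                      turbulence = rep_len(ladder, duration %/% 15),
                      seed = seed * 1000L + i,
                      flight_id = paste0("f", i), bird_id = paste0("b", i),
                      ...)
    fl <- simulate_flight(cfg)
    st <- suppressMessages(analyze_flight(fl$flight, terrain = tg, wind = ws))
    st$true_t <- fl$truth$segments$turbulence[match(st$segment_id,
                                                    fl$truth$segments$segment_id)]
    st
  })
  dplyr::bind_rows(tabs)
}
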