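# a segment-like table with a known linear covariate effect and flight
# random intercepts
known_effect_table <- function(n = 1000, slope = 0.5, noise_sd = 0.2,
                               seed = 40) {
  set.seed(seed)
  fl <- sample(paste0("f", 1:5), n, replace = TRUE)
  fx <- stats::setNames(rnorm(5, 0, 0.3), paste0("f", 1:5))
  tibble::tibble(
    flight_id = fl,
    sqrt_turbulence = runif(n, 0.1, 1.8),
    hwc = rnorm(n, 0, 2),
    response = slope * sqrt_turbulence + fx[fl] + rnorm(n, 0, noise_sd)
  )
}

test_that("a known linear turbulence effect is recovered", {
  tab <- known_effect_table()
  fit <- fit_response_model(tab, "response",
                            covariates = c("sqrt_turbulence", "hwc"))
  cv <- range(tab$sqrt_turbulence)
  eff <- partial_effect(fit, "sqrt_turbulence", cv)
  truth <- 0.5 * diff(cv)
  expect_equal(diff(eff), truth, tolerance = 0.2)
})

test_that("null covariate effects shrink toward flat", {
  tab <- known_effect_table()
  fit <- fit_response_model(tab, "response",
                            covariates = c("sqrt_turbulence", "hwc"))
  grid <- seq(min(tab$hwc), max(tab$hwc), length.out = 50)
  eff <- partial_effect(fit, "hwc", grid)
  expect_lt(diff(range(eff)), 0.1 * sd(tab$response))
})

test_that("refitting is deterministic", {
  tab <- known_effect_table(n = 300)
  f1 <- fit_response_model(tab, "response",
                           covariates = c("sqrt_turbulence", "hwc"))
  f2 <- fit_response_model(tab, "response",
                           covariates = c("sqrt_turbulence", "hwc"))
  expect_equal(coef(f1$model), coef(f2$model), tolerance = 1e-8)
})

test_that("fit preconditions and collinearity are enforced", {
  tab <- known_effect_table(n = 40)
  expect_error(fit_response_model(tab, "response",
                                  covariates = c("sqrt_turbulence", "hwc")),
               "at least 50")
  tab2 <- known_effect_table(n = 200)
  tab2$flight_id <- rep(c("a", "b"), 100)
  expect_error(fit_response_model(tab2, "response",
                                  covariates = c("sqrt_turbulence", "hwc")),
               "at least 3 flights")
  tab3 <- known_effect_table(n = 200)
  tab3$dup <- 2 * tab3$sqrt_turbulence
  expect_error(fit_response_model(tab3, "response",
                                  covariates = c("sqrt_turbulence", "dup")),
               "collinear")
})

test_that("effect_range_percent reports centred effects as % of range", {
  tab <- known_effect_table()
  fit <- fit_response_model(tab, "response",
                            covariates = c("sqrt_turbulence", "hwc"))
  es <- effect_range_percent(fit, "sqrt_turbulence")
  rng <- max(tab$response) - min(tab$response)
  expect_equal(es$response_range, rng)
  expect_equal(es$pct_at_max, 100 * es$effect_at_max / rng, tolerance = 1e-12)
  expect_equal(es$pct_at_min, 100 * es$effect_at_min / rng, tolerance = 1e-12)
  # centred smooth: effects at the two extremes bracket zero for a monotone
  # positive effect
  expect_lt(es$effect_at_min, 0)
  expect_gt(es$effect_at_max, 0)

  # flat effect (pure-noise response) gives ~0% at both ends
  set.seed(41)
  tab0 <- tab
  tab0$response <- rnorm(nrow(tab))
  fit0 <- fit_response_model(tab0, "response",
                             covariates = c("sqrt_turbulence", "hwc"))
  es0 <- effect_range_percent(fit0, "sqrt_turbulence")
  expect_lt(max(abs(c(es0$pct_at_min, es0$pct_at_max))), 2)
})

test_that("standardized and unstandardized fits agree in % of range", {
  tab <- sim_segment_table(n_flights = 3, duration = 300, seed = 42)
  std <- standardize_responses(tab, responses = "wb_freq_sd")
  raw_fit <- fit_response_model(tab, "wb_freq_sd")
  std_fit <- fit_response_model(std, "wb_freq_sd")
  raw_es <- effect_range_percent(raw_fit)
  std_es <- effect_range_percent(std_fit)
  expect_equal(std_es$pct_at_max, raw_es$pct_at_max, tolerance = 1e-6)
  expect_equal(std_es$pct_at_min, raw_es$pct_at_min, tolerance = 1e-6)
})

test_that("tidy and glance expose the model summaries", {
  tab <- known_effect_table(n = 300)
  fit <- fit_response_model(tab, "response",
                            covariates = c("sqrt_turbulence", "hwc"))
  td <- tidy(fit)
  expect_true(all(c("term", "edf", "p.value") %in% names(td)))
  expect_identical(nrow(td), 3L) # two smooths + random intercept
  gl <- glance(fit)
  expect_identical(gl$n, 300L)
  expect_gt(gl$deviance_explained, 0.5)
  expect_true(is.finite(gl$residual_ar1))
})

test_that("autoplot methods return ggplot objects", {
  tab <- known_effect_table(n = 200)
  fit <- fit_response_model(tab, "response",
                            covariates = c("sqrt_turbulence", "hwc"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(effect_range_percent(fit)), "ggplot")
  wb <- detect_wingbeats(make_sine_trace(duration = 5), min_prominence_g = 0.5)
  expect_s3_class(autoplot(wb), "ggplot")
})
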