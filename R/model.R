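# Penalized additive sub-models with flight random intercepts and
# Table-1-style partial-effect summaries.

#' Box-Cox transformation exponent
#'
#' Profile-likelihood-maximizing lambda for the normal-errors model on a grid
#' from -2 to 2 in steps of 0.05, via `MASS::boxcox`. A warning is raised
#' when the optimum sits on a grid endpoint (the grid should then be
#' widened).
#'
#' @param y Positive response values.
#' @return The lambda maximizing the profile likelihood.
#' @export
boxcox_lambda <- function(y) {
  if (any(y <= 0)) stop("Box-Cox requires strictly positive values", call. = FALSE)
  grid <- seq(-2, 2, by = 0.05)
  bc <- MASS::boxcox(y ~ 1, lambda = grid, plotit = FALSE)
  lam <- bc$x[which.max(bc$y)]
  if (lam <= min(grid) + 1e-9 || lam >= max(grid) - 1e-9) {
    warning("Box-Cox optimum at the grid boundary (lambda = ", lam, ")",
            call. = FALSE)
  }
  lam
}

#' Fit one response sub-model
#'
#' An additive model `response ~ s(covariate_1) + ... + s(flight_id, re)`
#' with thin-plate shrinkage smooths (`bs = "ts"`, so effects of null
#' covariates shrink toward flat) and a flight random intercept, fitted by
#' REML with `mgcv::gam`. The covariate set defaults to the sub-model
#' assignment of [flap_covariates()].
#'
#' @param table A `flight_segments` table with at least 50 rows from at least
#'   3 flights.
#' @param response Response column name (one of [flap_responses()], or any
#'   numeric column).
#' @param covariates Covariate column names; `NULL` uses
#'   `flap_covariates(response)`.
#' @param k Basis dimension per smooth (reduced automatically when a
#'   covariate has few unique values).
#' @return An object of class `flap_fit` wrapping the `gam` fit.
#' @export
fit_response_model <- function(table, response, covariates = NULL, k = 10) {
  covariates <- covariates %||% flap_covariates(response)
  if (nrow(table) < 50) stop("need at least 50 segments", call. = FALSE)
  if (length(unique(table$flight_id)) < 3) {
    stop("need at least 3 flights for the random intercept", call. = FALSE)
  }
  dat <- as.data.frame(table[c(response, covariates, "flight_id")])
  dat$flight_id <- factor(dat$flight_id)
  qrk <- qr(scale(as.matrix(dat[covariates]), scale = FALSE))
  if (qrk$rank < length(covariates)) {
    drop_idx <- setdiff(seq_along(covariates), sort(qrk$pivot[seq_len(qrk$rank)]))
    stop("rank-deficient design: collinear term(s) ",
         paste(covariates[drop_idx], collapse = ", "), call. = FALSE)
  }
  terms <- vapply(covariates, function(cv) {
    ki <- min(k, length(unique(dat[[cv]])) - 1L)
    sprintf("s(%s, bs = 'ts', k = %d)", cv, max(ki, 3L))
  }, character(1))
  fml <- stats::as.formula(paste(response, "~",
                                 paste(c(terms, "s(flight_id, bs = 're')"),
                                       collapse = " + ")))
  fit <- mgcv::gam(fml, data = dat, method = "REML")
  structure(list(model = fit, response = response, covariates = covariates,
                 data = dat),
            class = "flap_fit")
}

#' @export
print.flap_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<flap_fit> %s ~ %s + (1 | flight)\n", x$response,
              paste(x$covariates, collapse = " + ")))
  cat(sprintf("  n = %d, deviance explained = %.1f%%, residual AR(1) = %.2f\n",
              g$n, 100 * g$deviance_explained, g$residual_ar1))
  invisible(x)
}

#' Centred partial effect of one covariate
#'
#' Evaluates the fitted smooth's contribution to the response at given
#' covariate values. mgcv centres each smooth over the fitting data, so the
#' returned effects are deviations from the response mean attributable to the
#' covariate; the random intercept and the other smooths do not enter.
#'
#' @param fit A `flap_fit`.
#' @param covariate One of the fit's covariates.
#' @param at Covariate values at which to evaluate.
#' @return Numeric vector of centred partial effects (response units).
#' @export
partial_effect <- function(fit, covariate, at) {
  stopifnot(inherits(fit, "flap_fit"), covariate %in% fit$covariates)
  nd <- as.data.frame(purrr::map(fit$data[fit$covariates], function(x) {
    rep(stats::median(x), length(at))
  }))
  nd[[covariate]] <- at
  nd$flight_id <- factor(levels(fit$data$flight_id)[1],
                         levels = levels(fit$data$flight_id))
  tm <- predict(fit$model, newdata = nd, type = "terms")
  as.numeric(tm[, grep(paste0("s\\(", covariate, "\\)"), colnames(tm))])
}

#' Partial effect at covariate extremes as % of response range
#'
#' Evaluates the centred partial effect of a covariate at its observed
#' minimum and maximum and expresses each as a percentage of the response's
#' observed range (max - min) — the effect-size summary of the analysis.
#'
#' @param fit A `flap_fit`.
#' @param covariate Covariate name (default the turbulence proxy).
#' @return A one-row tibble of class `effect_summary`: `response`,
#'   `covariate`, `response_range`, `effect_at_min`, `effect_at_max`,
#'   `pct_at_min`, `pct_at_max`.
#' @export
effect_range_percent <- function(fit, covariate = "sqrt_turbulence") {
  stopifnot(inherits(fit, "flap_fit"))
  y <- fit$data[[fit$response]]
  rng <- max(y) - min(y)
  if (rng <= 0) stop("response range is zero", call. = FALSE)
  cv <- range(fit$data[[covariate]])
  eff <- partial_effect(fit, covariate, cv)
  out <- tibble(response = fit$response, covariate = covariate,
                response_range = rng,
                effect_at_min = eff[1], effect_at_max = eff[2],
                pct_at_min = 100 * eff[1] / rng,
                pct_at_max = 100 * eff[2] / rng)
  class(out) <- c("effect_summary", class(out))
  out
}

#' Fit all eight response sub-models
#'
#' @param table A `flight_segments` table.
#' @param responses Responses to fit (default all eight).
#' @param k Basis dimension per smooth.
#' @return A named list of `flap_fit`s, class `flap_fits`.
#' @export
fit_flight_models <- function(table, responses = flap_responses(), k = 10) {
  fits <- purrr::map(responses, function(r) fit_response_model(table, r, k = k))
  names(fits) <- responses
  structure(fits, class = "flap_fits")
}

#' Effect-size table across sub-models
#'
#' One row per response: the observed response range and the centred partial
#' effect of the covariate at its minimum and maximum, each as % of the
#' range.
#'
#' @param fits A `flap_fits` list.
#' @param covariate Covariate to summarise (default turbulence).
#' @return An `effect_summary` tibble with one row per response.
#' @export
effect_table <- function(fits, covariate = "sqrt_turbulence") {
  out <- bind_rows(purrr::map(fits, effect_range_percent, covariate = covariate))
  class(out) <- c("effect_summary", class(out))
  out
}

# pooled per-flight lag-1 residual autocorrelation (diagnostic)
.residual_ar1 <- function(fit) {
  r <- residuals(fit$model)
  fl <- fit$data$flight_id
  num <- 0; den <- 0
  for (f in levels(fl)) {
    x <- r[fl == f]
    if (length(x) >= 3) {
      x <- x - mean(x)
      num <- num + sum(x[-1] * x[-length(x)])
      den <- den + sum(x^2)
    }
  }
  if (den > 0) num / den else NA_real_
}

#' @export
tidy.flap_fit <- function(x, ...) {
  st <- summary(x$model)$s.table
  tibble(term = rownames(st), edf = st[, "edf"], ref_df = st[, "Ref.df"],
         statistic = st[, 3], p.value = st[, "p-value"])
}

#' @export
glance.flap_fit <- function(x, ...) {
  sm <- summary(x$model)
  tibble(n = nrow(x$data),
         deviance_explained = sm$dev.expl,
         r_squared = sm$r.sq,
         aic = stats::AIC(x$model),
         residual_ar1 = .residual_ar1(x),
         df_residual = stats::df.residual(x$model))
}

#' @export
autoplot.flap_fit <- function(object, n_grid = 100, ...) {
  df <- bind_rows(purrr::map(object$covariates, function(cv) {
    at <- seq(min(object$data[[cv]]), max(object$data[[cv]]),
              length.out = n_grid)
    tibble(covariate = cv, x = at,
           effect = partial_effect(object, cv, at))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$effect)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = NULL, y = paste("partial effect on", object$response))
}

#' @export
autoplot.effect_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("pct_at_min", "pct_at_max"),
                            names_to = "where", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$pct,
                                   fill = .data$where)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "partial effect (% of response range)", x = NULL)
}
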