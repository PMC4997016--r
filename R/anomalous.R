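#' Fit the anomalous-diffusion model to an MSD curve
#'
#' Fits `MSD(dt) = 4 * Gamma * dt^alpha + offset` by nonlinear least squares
#' with the transport coefficient `Gamma`, the anomalous exponent `alpha` and
#' the offset all free. The offset captures the dynamic localization error
#' (static precision plus motion blur) and may be negative; fitting it freely
#' per curve is what makes `alpha` trustworthy at microsecond lags where true
#' displacements are comparable to the localization uncertainty. A log-log
#' cross-check slope (`alpha_loglog`, the slope of `log(MSD - offset)` vs
#' `log(dt)`) is reported when the offset-corrected values are positive.
#'
#' Classification: `BROWNIAN` when `|alpha - 1| <= brownian_band`, `SUB`
#' below, `SUPER` above.
#'
#' Fit loss: for a single time-averaged MSD the statistical error grows with
#' lag — approximately `sd(MSD_k) ~ MSD_k * sqrt(k / n_pairs)` for
#' overlapping pairs — so unweighted least squares lets the noisiest long
#' lags dominate and inflates the variance of `alpha`. The default
#' `weights = "gls"` uses inverse-variance weights `1 / (k * MSD_k^2)`;
#' `"none"` (plain least squares on the linear MSD) and `"pairs"`
#' (pair-count weights) are available.
#'
#' @param curve An `msd_curve`.
#' @param fit_range_s Length-2 lag range (s) used for fitting; default the
#'   whole curve.
#' @param weights `"gls"` (default), `"none"` or `"pairs"`.
#' @param brownian_band Half-width of the Brownian classification band on
#'   `alpha` (default 0.1).
#' @return An object of class `anomalous_fit` with components `gamma`
#'   (um^2/s^alpha), `alpha`, `offset_um2`, `d_micro_um2_s` (two-point
#'   microscopic rate when the first two lags are present), `fit_rms`,
#'   `alpha_loglog`, `classification`, `degenerate`, and the fitted data.
#' @examples
#' tr <- simulate_brownian(sim_config(4000, d_free = 1, seed = 2))
#' fit <- fit_anomalous(time_averaged_msd(tr))
#' coef(fit)
#' @export
fit_anomalous <- function(curve, fit_range_s = NULL,
                          weights = c("gls", "none", "pairs"),
                          brownian_band = 0.1) {
  stopifnot(inherits(curve, "msd_curve"))
  weights <- match.arg(weights)
  dat <- as.data.frame(curve)
  if (!is.null(fit_range_s)) {
    stopifnot(length(fit_range_s) == 2)
    dat <- dat[dat$lag_s >= fit_range_s[1] & dat$lag_s <= fit_range_s[2], ]
  }
  if (nrow(dat) < 5L) stop("need at least 5 lags within fit_range_s")
  t <- dat$lag_s; y <- dat$msd_um2
  dt <- attr(curve, "frame_interval_s")
  w <- switch(weights,
    none = rep(1, nrow(dat)),
    pairs = dat$n_pairs / mean(dat$n_pairs),
    gls = {
      k <- pmax(t / dt, 1)
      v <- k * pmax(y, .Machine$double.eps)^2
      (1 / v) / mean(1 / v)
    })

  d_micro <- tryCatch(suppressWarnings(microscopic_d(curve)),
                      error = function(e) NA_real_)

  # starting values: offset by linear extrapolation of the first two points
  # to lag zero, then log-log regression on the corrected curve
  c0 <- y[1] - (y[2] - y[1]) * t[1] / (t[2] - t[1])
  yc <- y - c0
  if (all(yc > 0)) {
    lf <- stats::lm(log(yc) ~ log(t))
    a0 <- min(max(coef(lf)[2], 0.05), 2)
    g0 <- exp(coef(lf)[1]) / 4
  } else {
    a0 <- 1
    g0 <- max((y[length(y)] - y[1]) / (4 * (t[length(t)] - t[1])), 1e-8)
  }

  span <- diff(range(y))
  if (!is.finite(span) || span <= .Machine$double.eps * max(abs(y), 1)) {
    # constant curve: Gamma ~ 0, offset-only fit
    return(new_anomalous_fit(gamma = 0, alpha = 1, offset = mean(y),
                             d_micro = d_micro, fit_rms = stats::sd(y) %||% 0,
                             alpha_loglog = NA_real_, data = dat,
                             degenerate = TRUE, brownian_band = brownian_band))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 4 * g * t^a + c,
                      start = list(g = max(g0, 1e-10), a = a0, c = c0),
                      lower = c(g = 0, a = 0.01, c = -Inf),
                      upper = c(g = Inf, a = 2, c = Inf),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_anomalous_fit(gamma = NA_real_, alpha = NA_real_,
                             offset = NA_real_, d_micro = d_micro,
                             fit_rms = NA_real_, alpha_loglog = NA_real_,
                             data = dat, degenerate = TRUE,
                             brownian_band = brownian_band))
  }
  p <- coef(fit)
  resid <- y - (4 * p[["g"]] * t^p[["a"]] + p[["c"]])
  yc <- y - p[["c"]]
  alpha_ll <- if (all(yc > 0)) {
    unname(coef(stats::lm(log(yc) ~ log(t)))[2])
  } else NA_real_

  new_anomalous_fit(gamma = unname(p[["g"]]), alpha = unname(p[["a"]]),
                    offset = unname(p[["c"]]), d_micro = d_micro,
                    fit_rms = sqrt(mean(resid^2)), alpha_loglog = alpha_ll,
                    data = dat, degenerate = FALSE,
                    brownian_band = brownian_band)
}

new_anomalous_fit <- function(gamma, alpha, offset, d_micro, fit_rms,
                              alpha_loglog, data, degenerate, brownian_band) {
  classification <- if (degenerate || !is.finite(alpha)) {
    "DEGENERATE"
  } else if (abs(alpha - 1) <= brownian_band) {
    "BROWNIAN"
  } else if (alpha < 1) "SUB" else "SUPER"
  structure(list(gamma = gamma, alpha = alpha, offset_um2 = offset,
                 d_micro_um2_s = d_micro, fit_rms = fit_rms,
                 alpha_loglog = alpha_loglog,
                 classification = classification,
                 degenerate = degenerate,
                 brownian_band = brownian_band,
                 fit_range_s = range(data$lag_s),
                 data = data),
            class = "anomalous_fit")
}

#' @export
print.anomalous_fit <- function(x, ...) {
  cat("Anomalous-diffusion fit: MSD = 4*Gamma*dt^alpha + offset\n")
  cat(sprintf("  Gamma  = %.4g um^2/s^alpha\n  alpha  = %.4g  [%s]\n",
              x$gamma, x$alpha, x$classification))
  cat(sprintf("  offset = %.4g um^2\n", x$offset_um2))
  if (is.finite(x$d_micro_um2_s %||% NA)) {
    cat(sprintf("  microscopic D = %.4g um^2/s\n", x$d_micro_um2_s))
  }
  invisible(x)
}

#' @export
coef.anomalous_fit <- function(object, ...) {
  c(gamma = object$gamma, alpha = object$alpha, offset = object$offset_um2)
}

#' @export
summary.anomalous_fit <- function(object, ...) {
  cat(sprintf(paste0("Anomalous-diffusion fit over %.3g - %.3g s (%d lags)\n",
                     "  Gamma = %.4g um^2/s^alpha, alpha = %.4g, offset = %.4g um^2\n",
                     "  log-log cross-check slope: %.4g\n",
                     "  residual RMS: %.3g um^2; classification: %s%s\n"),
              object$fit_range_s[1], object$fit_range_s[2], nrow(object$data),
              object$gamma, object$alpha, object$offset_um2,
              object$alpha_loglog, object$fit_rms, object$classification,
              if (object$degenerate) " (degenerate)" else ""))
  invisible(object)
}

#' @export
predict.anomalous_fit <- function(object, lag_s = NULL, ...) {
  if (is.null(lag_s)) lag_s <- object$data$lag_s
  4 * object$gamma * lag_s^object$alpha + object$offset_um2
}

#' @export
residuals.anomalous_fit <- function(object, ...) {
  object$data$msd_um2 - predict(object)
}

#' @export
plot.anomalous_fit <- function(x, ..., log = "xy") {
  graphics::plot(x$data$lag_s, x$data$msd_um2, log = log,
                 xlab = expression(Delta * t ~ (s)),
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  tt <- exp(seq(log(min(x$data$lag_s)), log(max(x$data$lag_s)), length.out = 100))
  graphics::lines(tt, predict(x, tt), col = "red3")
  invisible(x)
}
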