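#' Time-averaged mean squared displacement
#'
#' Computes the 2D time-averaged MSD of a single trajectory using all
#' overlapping displacement pairs: at lag `k` frames,
#' `MSD(k*dt) = mean_i |r(i+k) - r(i)|^2` over the `N - k` start frames. The
#' default lag grid is pseudo-logarithmic (at most `n_lags` points) from one
#' frame up to `max_lag_s`, which avoids over-weighting strongly correlated
#' long lags when the curve is fitted.
#'
#' @param traj A `trajectory` (gap-free).
#' @param max_lag_s Largest lag in seconds (default 20 ms, capped at half the
#'   trajectory duration).
#' @param lags Integer frame lags to evaluate, or `"pseudolog"` / `"all"`.
#' @param n_lags Number of points of the pseudo-logarithmic grid.
#' @param min_pairs Lags with fewer displacement pairs are dropped with a
#'   warning (default 10).
#' @return An object of class `msd_curve`: a data frame with `lag_s`,
#'   `msd_um2`, `n_pairs`, and attributes `n_steps` and `frame_interval_s`.
#' @examples
#' tr <- simulate_brownian(sim_config(2000, d_free = 1, seed = 1))
#' curve <- time_averaged_msd(tr)
#' @export
time_averaged_msd <- function(traj, max_lag_s = 0.02, lags = "pseudolog",
                              n_lags = 30L, min_pairs = 10L) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- frame_interval(traj)
  n <- nrow(traj)
  k_cap <- n - 1L
  k_max <- min(k_cap, max(1L, floor(max_lag_s / dt + 1e-9)))
  if (is.character(lags)) {
    lags <- match.arg(lags, c("pseudolog", "all"))
    ks <- if (lags == "all") seq_len(k_max) else pseudolog_lags(k_max, n_lags)
  } else {
    ks <- sort(unique(as.integer(lags)))
    if (any(ks < 1L) || any(ks > k_cap)) {
      stop("requested lags outside 1..(n_steps - 1)")
    }
  }
  x <- traj$x_um; y <- traj$y_um
  msd <- numeric(length(ks)); np <- integer(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    dx <- x[(k + 1L):n] - x[1L:(n - k)]
    dy <- y[(k + 1L):n] - y[1L:(n - k)]
    msd[i] <- mean(dx * dx + dy * dy)
    np[i] <- n - k
  }
  keep <- np >= min_pairs
  if (any(!keep)) {
    warning(sprintf("dropped %d lag(s) with fewer than %d pairs",
                    sum(!keep), min_pairs))
  }
  new_msd_curve(lag_s = ks[keep] * dt, msd_um2 = msd[keep],
                n_pairs = np[keep], n_steps = n, frame_interval_s = dt)
}

new_msd_curve <- function(lag_s, msd_um2, n_pairs, n_steps, frame_interval_s) {
  out <- data.frame(lag_s = lag_s, msd_um2 = msd_um2, n_pairs = n_pairs)
  attr(out, "n_steps") <- n_steps
  attr(out, "frame_interval_s") <- frame_interval_s
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags (%.3g - %.3g s), trajectory of %d steps\n",
              nrow(x), min(x$lag_s), max(x$lag_s), attr(x, "n_steps")))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ..., log = "xy") {
  graphics::plot(x$lag_s, x$msd_um2, log = log,
                 xlab = expression(Delta * t ~ (s)),
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

#' Length-weighted ensemble MSD
#'
#' Averages per-trajectory time-averaged MSD curves with weights proportional
#' to each trajectory's step count, `w_i = N_i / sum_j N_j`, so long
#' trajectories dominate according to the amount of data they carry. All
#' curves must share the frame-interval grid; the ensemble is computed on the
#' lags common to every curve.
#'
#' @param curves A list of `msd_curve` objects.
#' @return An `msd_curve`; `n_pairs` holds the summed pair counts and the
#'   `n_steps` attribute the summed step count.
#' @export
ensemble_msd <- function(curves) {
  if (!length(curves)) stop("ensemble_msd() needs at least one curve")
  stopifnot(all(vapply(curves, inherits, logical(1), "msd_curve")))
  dts <- vapply(curves, attr, numeric(1), "frame_interval_s")
  if (max(dts) - min(dts) > 1e-12 * max(dts)) {
    stop("curves do not share a common frame-interval grid")
  }
  keys <- lapply(curves, function(cv) round(cv$lag_s / dts[1]))
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("curves share no common lags")
  common <- sort(common)
  n_i <- vapply(curves, attr, numeric(1), "n_steps")
  w <- n_i / sum(n_i)
  msd <- numeric(length(common)); np <- numeric(length(common))
  for (j in seq_along(curves)) {
    idx <- match(common, keys[[j]])
    msd <- msd + w[j] * curves[[j]]$msd_um2[idx]
    np <- np + curves[[j]]$n_pairs[idx]
  }
  new_msd_curve(lag_s = common * dts[1], msd_um2 = msd, n_pairs = as.integer(np),
                n_steps = sum(n_i), frame_interval_s = dts[1])
}

#' Microscopic diffusion rate from the first two MSD points
#'
#' The two-point finite-difference estimate
#' `D = [MSD(2*dt) - MSD(dt)] / (4*dt)`, i.e. the diffusion rate at the
#' shortest accessible timescale (20 us at 50 kHz sampling). The difference
#' cancels any static offset in the MSD, making the estimate robust to
#' localization error. With `method = "origin"` the slope through the origin
#' `MSD(dt) / (4*dt)` is returned instead (offset-sensitive).
#'
#' @param curve An `msd_curve` containing lags `dt` and `2*dt`.
#' @param method `"two-point"` (default) or `"origin"`.
#' @return Diffusion rate in um^2/s. Negative values (noise-dominated) are
#'   returned with a warning, not clipped.
#' @export
microscopic_d <- function(curve, method = c("two-point", "origin")) {
  stopifnot(inherits(curve, "msd_curve"))
  method <- match.arg(method)
  dt <- attr(curve, "frame_interval_s")
  k <- round(curve$lag_s / dt)
  i1 <- match(1, k); i2 <- match(2, k)
  if (is.na(i1) || (method == "two-point" && is.na(i2))) {
    stop("curve must contain the first two lags (dt and 2*dt)")
  }
  d <- if (method == "two-point") {
    (curve$msd_um2[i2] - curve$msd_um2[i1]) / (4 * dt)
  } else {
    curve$msd_um2[i1] / (4 * dt)
  }
  if (d < 0) warning("negative microscopic D (noise-dominated estimate)")
  d
}

#' Transient diffusion rate along a trajectory
#'
#' Chops the trajectory into non-overlapping segments of `segment_len` steps
#' (default 146) and computes the microscopic (two-point MSD) diffusion rate
#' of each segment, timestamped at the segment centre. The trailing remainder
#' shorter than a segment is dropped.
#'
#' @param traj A `trajectory`.
#' @param segment_len Steps per segment (default 146).
#' @return A data frame with `t_s` (segment-centre time), `d_um2_s` and
#'   `segment` index.
#' @export
transient_d <- function(traj, segment_len = 146L) {
  stopifnot(inherits(traj, "trajectory"))
  segment_len <- as.integer(segment_len)
  if (segment_len < 3L) stop("segment_len must be at least 3")
  n <- nrow(traj)
  n_seg <- n %/% segment_len
  if (n_seg < 1L) stop("trajectory shorter than one segment")
  if (n_seg < 2L) {
    warning("trajectory shorter than two segments; returning a single-segment result")
  }
  dt <- frame_interval(traj)
  out <- data.frame(segment = seq_len(n_seg), t_s = NA_real_, d_um2_s = NA_real_)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1L) * segment_len + 1L):(s * segment_len)
    sub <- as_trajectory(as.data.frame(traj)[idx, , drop = FALSE],
                         frame_interval_s = dt)
    cv <- suppressWarnings(time_averaged_msd(sub, lags = 1:2, min_pairs = 2L))
    out$d_um2_s[s] <- suppressWarnings(microscopic_d(cv))
    out$t_s[s] <- mean(traj$t_s[idx])
  }
  out
}
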