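#' Parameters of the transient-confinement detector
#'
#' Defaults follow the probability-level method of Simson, Sheets and
#' Jacobson: a forward window of 25 steps, a 10-step moving average of the
#' raw probability level, and a critical level of 1 (99% confidence that a
#' flagged segment is not Brownian).
#'
#' @param window_steps Forward window length in steps; a window of `W` steps
#'   spans `W + 1` points and `t = W * dt` of elapsed time.
#' @param smooth_steps Moving-average window (steps) applied to the raw
#'   probability level.
#' @param l_critical Critical probability level `L_c`.
#' @param d_ref_um2_s Diffusion rate used in the statistic; `NULL` (default)
#'   means estimate it per trajectory as the microscopic (two-point MSD)
#'   rate.
#' @param l_max Cap on the probability level when the window displacement is
#'   degenerate (R = 0).
#' @param merge_gap_steps Events separated by fewer steps are merged
#'   (smoothing artifacts); default `smooth_steps`.
#' @return An object of class `confinement_params`.
#' @export
confinement_params <- function(window_steps = 25L, smooth_steps = 10L,
                               l_critical = 1.0, d_ref_um2_s = NULL,
                               l_max = 10, merge_gap_steps = smooth_steps) {
  stop_if_not_scalar_num(window_steps, "window_steps", 3)
  stop_if_not_scalar_num(smooth_steps, "smooth_steps", 1)
  stop_if_not_scalar_num(l_critical, "l_critical", 0, strict = TRUE)
  if (!is.null(d_ref_um2_s)) {
    stop_if_not_scalar_num(d_ref_um2_s, "d_ref_um2_s", 0, strict = TRUE)
  }
  structure(list(window_steps = as.integer(window_steps),
                 smooth_steps = as.integer(smooth_steps),
                 l_critical = l_critical, d_ref_um2_s = d_ref_um2_s,
                 l_max = l_max,
                 merge_gap_steps = as.integer(merge_gap_steps)),
            class = "confinement_params")
}

# Simson-Sheets-Jacobson probability that a Brownian particle of diffusion
# rate D stays within radius R for time t, in the calibrated regime psi < 0.1:
#   log10(psi) = 0.2048 - 2.5117 * (D * t / R^2),  psi capped at 1.
simson_psi <- function(d, t, r2) {
  log10psi <- 0.2048 - 2.5117 * (d * t / r2)
  pmin(10^log10psi, 1)
}

#' Probability level of transient confinement
#'
#' For each start index `i`, the forward window of `window_steps` steps
#' (points `i .. i + window_steps`) gives `R`, the largest displacement from
#' the window's first point, and the elapsed time `t = window_steps * dt`.
#' The probability `psi` that free Brownian motion of rate `D` stays within
#' `R` for `t` follows the Simson calibration
#' `log10(psi) = 0.2048 - 2.5117 * D * t / R^2` (capped at 1), and the
#' probability level is `L = -log10(psi) - 1` when `psi < 0.1`, else 0.
#' Trailing indices without a full window are `NA`.
#'
#' @param traj A `trajectory` longer than `window_steps`.
#' @param params A [confinement_params()].
#' @return Numeric vector of length `nrow(traj)` with the raw probability
#'   level per start index (`NA` where no full window exists), with the
#'   reference diffusion rate in attribute `d_ref_um2_s`.
#' @export
probability_level <- function(traj, params = confinement_params()) {
  stopifnot(inherits(traj, "trajectory"), inherits(params, "confinement_params"))
  n <- nrow(traj)
  W <- params$window_steps
  if (n <= W) stop("trajectory must be longer than window_steps")
  d_ref <- params$d_ref_um2_s
  if (is.null(d_ref)) {
    d_ref <- suppressWarnings(microscopic_d(time_averaged_msd(traj, lags = 1:4)))
    if (!is.finite(d_ref) || d_ref <= 0) {
      stop("per-trajectory microscopic D is not positive; pass d_ref_um2_s explicitly")
    }
  }
  dt <- frame_interval(traj)
  t_win <- W * dt
  x <- traj$x_um; y <- traj$y_um
  n_valid <- n - W
  r2 <- rep(0, n_valid)
  idx <- seq_len(n_valid)
  for (k in seq_len(W)) {
    d2 <- (x[idx + k] - x[idx])^2 + (y[idx + k] - y[idx])^2
    r2 <- pmax(r2, d2)
  }
  L <- rep(NA_real_, n)
  zero <- r2 == 0
  if (any(zero)) {
    warning("window(s) with zero displacement; probability level capped at l_max")
    r2[zero] <- Inf # placeholder, overwritten below
  }
  psi <- simson_psi(d_ref, t_win, r2)
  Li <- ifelse(psi < 0.1, -log10(psi) - 1, 0)
  Li <- pmin(Li, params$l_max)
  Li[zero] <- params$l_max
  L[idx] <- Li
  attr(L, "d_ref_um2_s") <- d_ref
  L
}

#' Detect transient confinement events
#'
#' Smooths the raw probability level with a centered moving average of
#' `smooth_steps`, flags contiguous runs with smoothed `L > l_critical` as
#' confinement events (runs closer than `merge_gap_steps` are merged), and
#' reports per event the residence time and an estimated confinement
#' diameter from the localizations spanned by the event (the flagged run
#' extended by the detection window).
#'
#' @param traj A `trajectory`.
#' @param params A [confinement_params()].
#' @param loc_noise_nm Known localization error (std per axis, nm) subtracted
#'   in quadrature by the size estimator; `NULL` to skip correction.
#' @return A data frame of class `confinement_events` with columns
#'   `start_idx`, `end_idx` (1-based frame rows, `end_idx` exclusive of the
#'   last confined window start), `residence_s`, `diameter_nm`, `peak_L`.
#'   Attributes: `flagged_fraction` (flagged share of valid window starts)
#'   and `d_ref_um2_s`.
#' @export
detect_confinements <- function(traj, params = confinement_params(),
                                loc_noise_nm = NULL) {
  L <- probability_level(traj, params)
  dt <- frame_interval(traj)
  W <- params$window_steps
  n <- nrow(traj)
  valid <- which(!is.na(L))
  Ls <- moving_average(L, params$smooth_steps)
  # ends of the valid range lack a full smoothing window: fall back to raw L
  # there so short trajectories remain usable
  Ls[is.na(Ls) & !is.na(L)] <- L[is.na(Ls) & !is.na(L)]

  above <- !is.na(Ls) & Ls > params$l_critical
  runs <- rle(above[valid])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev_start <- valid[starts[runs$values]]
  ev_end <- valid[ends[runs$values]]

  # merge events separated by short gaps
  if (length(ev_start) > 1L && params$merge_gap_steps > 0L) {
    keep_s <- ev_start[1]; merged_s <- c(); merged_e <- c()
    cur_e <- ev_end[1]
    for (i in seq_along(ev_start)[-1]) {
      if (ev_start[i] - cur_e <= params$merge_gap_steps) {
        cur_e <- ev_end[i]
      } else {
        merged_s <- c(merged_s, keep_s); merged_e <- c(merged_e, cur_e)
        keep_s <- ev_start[i]; cur_e <- ev_end[i]
      }
    }
    merged_s <- c(merged_s, keep_s); merged_e <- c(merged_e, cur_e)
    ev_start <- merged_s; ev_end <- merged_e
  }

  events <- data.frame(start_idx = integer(0), end_idx = integer(0),
                       residence_s = numeric(0), diameter_nm = numeric(0),
                       peak_L = numeric(0))
  for (i in seq_along(ev_start)) {
    s <- ev_start[i]; e <- ev_end[i]
    pts_end <- min(e + W, n) # the last confined window extends W steps further
    pts <- traj[s:pts_end, c("x_um", "y_um")]
    dia <- estimate_confinement_size(pts, loc_noise_nm = loc_noise_nm)
    events <- rbind(events, data.frame(
      start_idx = s, end_idx = e + 1L,
      residence_s = (e + 1L - s) * dt,
      diameter_nm = dia,
      peak_L = max(L[s:e], na.rm = TRUE)))
  }
  flagged <- if (length(valid)) sum(above[valid]) / length(valid) else 0
  attr(events, "flagged_fraction") <- flagged
  attr(events, "d_ref_um2_s") <- attr(L, "d_ref_um2_s")
  class(events) <- c("confinement_events", "data.frame")
  events
}

#' Estimate the diameter of a confinement zone
#'
#' Uses the disk identity: for points uniformly distributed over a disk of
#' radius `a`, the mean squared distance from the centroid is `a^2 / 2`, so
#' `diameter = 2 * sqrt(2) * RMS` distance from the centroid. When the
#' localization error `sigma` (per axis) is known its contribution
#' `2 * sigma^2` to the mean squared distance is subtracted in quadrature.
#'
#' @param points Data frame or matrix with columns `x_um`, `y_um` (or two
#'   unnamed columns), at least 5 rows.
#' @param loc_noise_nm Optional localization error std per axis in nm.
#' @return Diameter in nm (>= 0).
#' @export
estimate_confinement_size <- function(points, loc_noise_nm = NULL) {
  pts <- as.data.frame(points)
  if (!all(c("x_um", "y_um") %in% names(pts))) {
    if (ncol(pts) < 2) stop("'points' needs two coordinate columns")
    names(pts)[1:2] <- c("x_um", "y_um")
  }
  if (nrow(pts) < 5L) stop("need at least 5 points to estimate a confinement size")
  msq <- mean((pts$x_um - mean(pts$x_um))^2 + (pts$y_um - mean(pts$y_um))^2)
  if (!is.null(loc_noise_nm)) {
    msq <- max(msq - 2 * (loc_noise_nm * 1e-3)^2, 0)
  }
  2 * sqrt(2 * msq) * 1e3
}

#' Calibrate the detector's false-positive behaviour on Brownian nulls
#'
#' Runs [detect_confinements()] on computer-generated Brownian trajectories
#' matched in length, frame interval, diffusion rate and localization error —
#' the null against which detected confinements are judged. Inputs can be a
#' population of trajectories (each spawns matched controls) or explicit
#' parameters.
#'
#' @param trajs List of `trajectory` objects to match, or `NULL` to use
#'   `n_steps` / `d` / `frame_interval_s` directly.
#' @param params A [confinement_params()].
#' @param n_sim Number of null trajectories (>= 1; a production
#'   calibration uses hundreds).
#' @param d,n_steps,frame_interval_s,loc_noise_nm Null parameters when
#'   `trajs` is `NULL`.
#' @param seed Root seed.
#' @return A list with `flagged_fraction` (mean share of window starts
#'   flagged), `confidence_pct = 100 * (1 - flagged_fraction)`, `event_rate_per_s`,
#'   and the null `diameters_nm` / `residences_s` pooled over events.
#' @export
calibrate_null <- function(trajs = NULL, params = confinement_params(),
                           n_sim = 100L, d = 0.24, n_steps = 10000L,
                           frame_interval_s = 2e-5, loc_noise_nm = 3,
                           seed = 1L) {
  seeds <- child_seeds(seed, n_sim)
  fracs <- numeric(n_sim)
  n_events <- 0L
  total_time <- 0
  dias <- c(); ress <- c()
  for (i in seq_len(n_sim)) {
    tr <- if (!is.null(trajs)) {
      src <- trajs[[((i - 1L) %% length(trajs)) + 1L]]
      matched_brownian_control(src, loc_noise_nm = loc_noise_nm, seed = seeds[i])
    } else {
      simulate_brownian(sim_config(n_steps, frame_interval_s = frame_interval_s,
                                   d_free = d, loc_noise_nm = loc_noise_nm,
                                   seed = seeds[i]))
    }
    ev <- detect_confinements(tr, params, loc_noise_nm = loc_noise_nm)
    fracs[i] <- attr(ev, "flagged_fraction")
    n_events <- n_events + nrow(ev)
    total_time <- total_time + (nrow(tr) - 1L) * frame_interval(tr)
    if (nrow(ev)) {
      dias <- c(dias, ev$diameter_nm)
      ress <- c(ress, ev$residence_s)
    }
  }
  list(flagged_fraction = mean(fracs),
       confidence_pct = 100 * (1 - mean(fracs)),
       event_rate_per_s = n_events / total_time,
       n_events = n_events,
       diameters_nm = dias,
       residences_s = ress)
}
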