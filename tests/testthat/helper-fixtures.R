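# Shared fixtures and independent oracles for the test suite.

# Brute-force time-averaged MSD: explicit double loop over (start, lag)
# pairs. Deliberately naive -- this is the oracle the fast implementation is
# checked against.
msd_brute <- function(traj, ks) {
  n <- nrow(traj)
  vapply(ks, function(k) {
    acc <- 0
    for (i in seq_len(n - k)) {
      acc <- acc + (traj$x_um[i + k] - traj$x_um[i])^2 +
        (traj$y_um[i + k] - traj$y_um[i])^2
    }
    acc / (n - k)
  }, numeric(1))
}

# Straight-line trajectory builder.
make_traj <- function(x, y, dt = 2e-5) {
  n <- length(x)
  as_trajectory(data.frame(frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
                           x_um = x, y_um = y), frame_interval_s = dt)
}

# Random-walk trajectory with given per-step sd (no noise model).
random_traj <- function(n, step_sd = 5e-3, dt = 2e-5, seed = 1) {
  withr::with_seed(seed, {
    make_traj(cumsum(rnorm(n, 0, step_sd)), cumsum(rnorm(n, 0, step_sd)), dt)
  })
}

# Reflecting random walk confined to a disk: the degenerate permanently
# confined particle used by the detector tests.
confined_walk <- function(n, radius_um, d = 0.24, dt = 2e-5, seed = 1,
                          center = c(0, 0)) {
  withr::with_seed(seed, {
    sdstep <- sqrt(2 * d * dt)
    x <- numeric(n); y <- numeric(n)
    cx <- 0; cy <- 0
    for (i in 2:n) {
      nx <- x[i - 1] + rnorm(1, 0, sdstep)
      ny <- y[i - 1] + rnorm(1, 0, sdstep)
      r <- sqrt(nx^2 + ny^2)
      if (r > radius_um) {
        f <- (2 * radius_um - r) / r
        if (f < 0) f <- 0.5
        nx <- nx * f; ny <- ny * f
      }
      x[i] <- nx; y[i] <- ny
    }
    make_traj(x + center[1], y + center[2], dt)
  })
}

# Exact anomalous MSD curve (noiseless model evaluation).
model_curve <- function(gamma, alpha, offset, n_lags = 20, dt = 2e-5) {
  ks <- seq_len(n_lags)
  rafttrack:::new_msd_curve(lag_s = ks * dt,
                            msd_um2 = 4 * gamma * (ks * dt)^alpha + offset,
                            n_pairs = rep(1000L, n_lags),
                            n_steps = 10000L, frame_interval_s = dt)
}
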