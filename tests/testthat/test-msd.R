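test_that("time-averaged MSD handles the closed-form limit cases", {
  stat <- make_traj(rep(1, 50), rep(-2, 50))
  cv <- suppressWarnings(time_averaged_msd(stat, lags = 1:10, min_pairs = 2))
  expect_true(all(cv$msd_um2 == 0))

  v <- 3.0 # um/s along x
  dt <- 2e-5
  bal <- make_traj(v * (0:99) * dt, rep(0, 100), dt)
  cv <- time_averaged_msd(bal, lags = 1:20, min_pairs = 2)
  expect_equal(cv$msd_um2, (v * cv$lag_s)^2, tolerance = 1e-12)
})

test_that("fast MSD equals the brute-force oracle on short trajectories", {
  for (seed in 1:5) {
    n <- sample(10:100, 1)
    tr <- random_traj(n, seed = seed)
    ks <- seq_len(n - 1)
    cv <- suppressWarnings(time_averaged_msd(tr, lags = ks, min_pairs = 1))
    expect_equal(cv$msd_um2, msd_brute(tr, ks), tolerance = 1e-12)
    expect_equal(cv$n_pairs, n - ks)
  }
})

test_that("lags with too few pairs are dropped with a warning", {
  tr <- random_traj(30, seed = 2)
  expect_warning(cv <- time_averaged_msd(tr, lags = c(1, 25), min_pairs = 10),
                 "fewer than")
  expect_equal(nrow(cv), 1L)
})

test_that("ensemble MSD is the length-weighted mean of its inputs", {
  dt <- 2e-5
  mk <- function(val, n_steps) {
    rafttrack:::new_msd_curve(lag_s = (1:5) * dt, msd_um2 = rep(val, 5),
                              n_pairs = rep(n_steps - 1L, 5),
                              n_steps = n_steps, frame_interval_s = dt)
  }
  # hand-computed: weights 100/400 and 300/400 -> 0.25*1 + 0.75*2 = 1.75
  ens <- ensemble_msd(list(mk(1.0, 100L), mk(2.0, 300L)))
  expect_equal(ens$msd_um2, rep(1.75, 5))
  expect_equal(attr(ens, "n_steps"), 400L)

  # identical curves: ensemble equals each input (weights sum to one)
  same <- ensemble_msd(list(mk(1.3, 200L), mk(1.3, 200L), mk(1.3, 200L)))
  expect_equal(same$msd_um2, rep(1.3, 5))

  # single curve is the identity
  one <- mk(0.7, 150L)
  expect_equal(ensemble_msd(list(one))$msd_um2, one$msd_um2)
  expect_error(ensemble_msd(list()), "at least one")
})

test_that("two-point microscopic D cancels any static offset", {
  dt <- 2e-5
  for (c0 in c(0, 4e-4, -1e-4)) {
    cv <- rafttrack:::new_msd_curve(lag_s = (1:5) * dt,
                                    msd_um2 = 4 * 0.9 * (1:5) * dt + c0,
                                    n_pairs = rep(100L, 5), n_steps = 1000L,
                                    frame_interval_s = dt)
    expect_equal(microscopic_d(cv), 0.9, tolerance = 1e-12)
    # the through-origin variant keeps the offset (and may warn when the
    # offset drives it negative)
    expect_equal(suppressWarnings(microscopic_d(cv, method = "origin")),
                 0.9 + c0 / (4 * dt), tolerance = 1e-9)
  }
})

test_that("microscopic D is ~0 for a stationary noisy particle", {
  tr <- simulate_brownian(sim_config(2e4, d_free = 0, loc_noise_nm = 3, seed = 9))
  d <- suppressWarnings(microscopic_d(time_averaged_msd(tr, lags = 1:4)))
  # noise floor: sd of the estimate is ~ 4*sigma^2/(4*dt*sqrt(n)) scale
  expect_lt(abs(d), 0.05)
})

test_that("microscopic D estimates recover the simulated truth", {
  d_true <- 1.48
  ds <- vapply(1:20, function(i) {
    tr <- simulate_brownian(sim_config(6000, d_free = d_true, seed = 700 + i))
    microscopic_d(time_averaged_msd(tr, lags = 1:4))
  }, numeric(1))
  expect_lt(abs(mean(ds) / d_true - 1), 0.05)
})

test_that("transient D partitions the trajectory and finds rate changes", {
  tr <- random_traj(1000, seed = 3)
  td <- transient_d(tr)
  expect_equal(nrow(td), 6L) # floor(1000 / 146)

  # piecewise rates: fast first half, slow second half
  t1 <- simulate_brownian(sim_config(1460, d_free = 1.2, seed = 41))
  t2 <- simulate_brownian(sim_config(1460, d_free = 0.13, seed = 42))
  df2 <- as.data.frame(t2)[, 1:4]
  df2$frame <- df2$frame + 1460L
  df2$t_s <- df2$t_s + 1460 * 2e-5
  df2$x_um <- df2$x_um + tail(t1$x_um, 1)
  df2$y_um <- df2$y_um + tail(t1$y_um, 1)
  both <- as_trajectory(rbind(as.data.frame(t1)[, 1:4], df2),
                        frame_interval_s = 2e-5)
  td <- transient_d(both)
  expect_lt(abs(mean(td$d_um2_s[1:10]) / 1.2 - 1), 0.3)
  expect_lt(abs(mean(td$d_um2_s[11:20]) / 0.13 - 1), 0.3)

  # homogeneous motion shows no trend in the segment series
  th <- simulate_brownian(sim_config(30000, d_free = 1.0, seed = 43))
  td <- transient_d(th)
  fit <- lm(d_um2_s ~ t_s, data = td)
  ci <- confint(fit)["t_s", ]
  expect_true(ci[1] < 0 && ci[2] > 0)

  expect_warning(transient_d(random_traj(200, seed = 1)), "single-segment")
})
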