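test_that("probability level reproduces hand-evaluated reference values", {
  # D = 0.24 um^2/s, R = 16 nm: psi just above 0.1 at t = 0.5 ms -> L = 0;
  # psi ~ 7.1e-3 at t = 1.0 ms -> L ~ 1.15
  psi1 <- rafttrack:::simson_psi(0.24, 5e-4, 0.016^2)
  expect_equal(psi1, 0.106, tolerance = 5e-3)
  psi2 <- rafttrack:::simson_psi(0.24, 1e-3, 0.016^2)
  expect_equal(psi2, 7.1e-3, tolerance = 5e-3)
  L2 <- -log10(psi2) - 1
  expect_equal(L2, 1.15, tolerance = 0.01)
  # unconfined limit: R -> infinity caps psi at 1 -> L = 0
  expect_equal(rafttrack:::simson_psi(0.24, 1e-3, Inf), 1)
})

test_that("probability level masks trailing windows and caps degenerate R", {
  tr <- random_traj(100, seed = 6)
  params <- confinement_params(d_ref_um2_s = 0.24)
  L <- probability_level(tr, params)
  expect_equal(sum(is.na(L)), params$window_steps)
  expect_true(all(L[!is.na(L)] >= 0))

  stat <- make_traj(rep(0.3, 60), rep(0.1, 60))
  expect_warning(L0 <- probability_level(stat, params), "zero displacement")
  expect_true(all(L0[!is.na(L0)] == params$l_max))
})

test_that("a permanently confined particle yields one full-span event", {
  # a 12 nm zone: tight enough that every window's maximum displacement
  # stays in the flagging regime of the probability-level statistic
  tr <- confined_walk(1500, radius_um = 0.006, seed = 8)
  params <- confinement_params(d_ref_um2_s = 0.24)
  ev <- detect_confinements(tr, params)
  expect_equal(nrow(ev), 1L)
  n_valid <- nrow(tr) - params$window_steps
  expect_gte((ev$end_idx - ev$start_idx) / n_valid, 0.9)
  expect_gt(ev$peak_L, params$l_critical)
})

test_that("disk diameter estimator satisfies the uniform-disk identity", {
  withr::with_seed(10, {
    th <- runif(1e4, 0, 2 * pi)
    r <- 0.020 * sqrt(runif(1e4))
    pts <- data.frame(x_um = r * cos(th), y_um = r * sin(th))
    expect_equal(estimate_confinement_size(pts), 40, tolerance = 0.025)

    same <- data.frame(x_um = rep(1, 10), y_um = rep(2, 10))
    expect_equal(estimate_confinement_size(same), 0)

    r2 <- 0.015 * sqrt(runif(5e3))
    th2 <- runif(5e3, 0, 2 * pi)
    noisy <- data.frame(x_um = r2 * cos(th2) + rnorm(5e3, 0, 3e-3),
                        y_um = r2 * sin(th2) + rnorm(5e3, 0, 3e-3))
    est <- estimate_confinement_size(noisy, loc_noise_nm = 3)
    expect_lt(abs(est / 30 - 1), 0.1)
  })
  expect_error(estimate_confinement_size(data.frame(x_um = 1, y_um = 1)),
               "at least 5")
})

test_that("smoothing window of one reduces to raw thresholding", {
  tr <- confined_walk(400, radius_um = 0.02, seed = 12)
  params <- confinement_params(smooth_steps = 1L, merge_gap_steps = 0L,
                               d_ref_um2_s = 0.24)
  L <- probability_level(tr, params)
  ev <- detect_confinements(tr, params)
  above <- which(!is.na(L) & L > params$l_critical)
  flagged <- unlist(lapply(seq_len(nrow(ev)),
                           function(i) ev$start_idx[i]:(ev$end_idx[i] - 1L)))
  expect_equal(sort(flagged), above)
})

test_that("events are invariant under translation and rotation", {
  mask <- disk_domain_mask(0.5, extent_um = 1.4)
  mm <- membrane_model(mask, seed = 4)
  tr <- simulate_membrane(sim_config(2000, d_free = 0.3, seed = 71), mm,
                          d_lo_free = 0.3)
  params <- confinement_params(d_ref_um2_s = 0.24)
  ev0 <- detect_confinements(tr, params)

  th <- pi / 7
  rot <- as.data.frame(tr)
  x <- rot$x_um; y <- rot$y_um
  rot$x_um <- cos(th) * x - sin(th) * y + 5
  rot$y_um <- sin(th) * x + cos(th) * y - 2
  ev1 <- detect_confinements(as_trajectory(rot, frame_interval(tr)), params)
  expect_equal(ev0$start_idx, ev1$start_idx)
  expect_equal(ev0$end_idx, ev1$end_idx)
  expect_equal(ev0$diameter_nm, ev1$diameter_nm, tolerance = 1e-9)
})

test_that("the Brownian null is almost never flagged at the default level", {
  nc <- calibrate_null(n_sim = 20, d = 0.24, n_steps = 8000, seed = 14)
  expect_lte(nc$flagged_fraction, 0.01)
})

test_that("the null rate rises as the critical level drops", {
  rates <- vapply(c(1.0, 0.5, 0.2), function(lc) {
    params <- confinement_params(l_critical = lc)
    calibrate_null(params = params, n_sim = 8, d = 0.24, n_steps = 5000,
                   seed = 15)$flagged_fraction
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("the detector recovers most true trapped dwells above 0.5 ms", {
  mask <- disk_domain_mask(0.8, extent_um = 2)
  mm <- membrane_model(mask, seed = 5)
  # the statistic's reference rate is the lipid's free-phase diffusion rate
  # (the recorded particles explore both phases); the Lo-local microscopic
  # rate would blind the detector to zones larger than ~20 nm
  params <- confinement_params(d_ref_um2_s = 1.43)
  hits <- 0L; total <- 0L
  lo_res <- c(); lo_dia <- c()
  for (s in 1:10) {
    tr <- simulate_membrane(sim_config(4000, d_free = 0.3, seed = 800 + s),
                            mm, d_lo_free = 0.3)
    ev <- detect_confinements(tr, params, loc_noise_nm = 3)
    lo_res <- c(lo_res, ev$residence_s)
    lo_dia <- c(lo_dia, ev$diameter_nm)
    dw <- trapped_dwells(tr)
    dw <- dw[dw$duration_s > 0.5e-3, ]
    dt <- frame_interval(tr)
    for (i in seq_len(nrow(dw))) {
      total <- total + 1L
      i0 <- dw$start_s[i] / dt; i1 <- dw$end_s[i] / dt
      if (nrow(ev) && any(ev$start_idx <= i1 & ev$end_idx >= i0)) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.7)
  # detected sizes reflect the trap field (tens of nm)
  expect_gt(mean(lo_dia), 15)
  expect_lt(mean(lo_dia), 60)

  # the Lo residence distribution dominates the matched Brownian null's
  nc <- calibrate_null(params = params, n_sim = 10, d = 1.43, n_steps = 4000,
                       seed = 16)
  if (length(nc$residences_s) >= 5) {
    ks <- suppressWarnings(ks.test(lo_res, nc$residences_s))
    expect_lt(ks$p.value, 0.05)
  }
  expect_gt(mean(lo_res), mean(nc$residences_s))
})
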