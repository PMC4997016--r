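test_that("degenerate diffusion produces a stationary trajectory", {
  tr <- simulate_brownian(sim_config(100, d_free = 0, loc_noise_nm = 0, seed = 1))
  expect_true(all(tr$x_um == tr$x_um[1]))
  expect_true(all(tr$y_um == tr$y_um[1]))
  expect_error(simulate_brownian(sim_config(100), d = -1), "non-negative")
  expect_error(simulate_brownian(sim_config(100), d = NaN), "finite")
})

test_that("per-axis step variance matches 2*D*dt to within 1%", {
  cfg <- sim_config(1e6, d_free = 1.0, loc_noise_nm = 0, blur_substeps = 1,
                    seed = 12)
  tr <- simulate_brownian(cfg)
  target <- 2 * 1.0 * 2e-5
  expect_lt(abs(var(diff(tr$x_um)) / target - 1), 0.01)
  expect_lt(abs(var(diff(tr$y_um)) / target - 1), 0.01)
})

test_that("seeding gives bit-identical repeats and different streams differ", {
  cfg <- sim_config(500, d_free = 1.2, seed = 77)
  expect_identical(simulate_brownian(cfg), simulate_brownian(cfg))
  cfg2 <- sim_config(500, d_free = 1.2, seed = 78)
  expect_false(identical(simulate_brownian(cfg)$x_um, simulate_brownian(cfg2)$x_um))
})

test_that("per-axis increments are Gaussian", {
  tr <- simulate_brownian(sim_config(1e5 + 1, d_free = 1.48, seed = 3))
  p <- nortest::lillie.test(diff(tr$x_um))$p.value
  expect_gt(p, 0.01)
})

test_that("motion blur lowers the apparent MSD offset below the static one", {
  fit_offset <- function(blur) {
    cfg <- sim_config(5e4, d_free = 1.48, loc_noise_nm = 3,
                      blur_substeps = blur, seed = 90)
    fit_anomalous(time_averaged_msd(simulate_brownian(cfg)))$offset_um2
  }
  expect_lt(fit_offset(10L), fit_offset(1L))
})

test_that("a trap-free membrane reduces to free Brownian motion", {
  mask <- domain_mask(matrix(FALSE, 50, 50), pixel_size_nm = 20)
  mm <- membrane_model(mask, trap_area_fraction = 0)
  cfg <- sim_config(4000, d_free = 1.0, loc_noise_nm = 0, seed = 31)
  tm <- simulate_membrane(cfg, mm, d_lo_free = 0.3)
  tb <- simulate_brownian(sim_config(4000, d_free = 1.0, loc_noise_nm = 0,
                                     seed = 32))
  ks <- ks.test(abs(diff(tm$x_um)), abs(diff(tb$x_um)))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(tm$state == "LD"))
})

test_that("trapped dwell times are exponential with the configured mean", {
  mask <- disk_domain_mask(0.8, extent_um = 2)
  mm <- membrane_model(mask, seed = 3)
  dws <- c()
  s <- 0
  while (length(dws) < 500) {
    s <- s + 1
    tr <- simulate_membrane(sim_config(4000, d_free = 0.3, seed = 100 + s),
                            mm, d_lo_free = 0.3)
    dws <- c(dws, trapped_dwells(tr)$duration_s)
  }
  expect_lt(abs(mean(dws) / 0.62e-3 - 1), 0.05)
})

test_that("reflecting traps bound the true trapped displacement", {
  mask <- disk_domain_mask(0.5, extent_um = 1.4)
  mm <- membrane_model(mask, seed = 8)
  tr <- simulate_membrane(sim_config(3000, d_free = 0.3, seed = 21),
                          mm, d_lo_free = 0.3)
  dw <- trapped_dwells(tr, complete_only = FALSE)
  dt <- frame_interval(tr)
  for (i in seq_len(nrow(dw))) {
    # exclude the escape instant itself (release is just outside the rim)
    idx <- which(tr$t_s >= dw$start_s[i] & tr$t_s < dw$end_s[i] - 1e-6)
    if (!length(idx)) next
    j <- dw$trap[i]
    d <- sqrt((tr$true_x_um[idx] - mm$trap_x[j])^2 +
              (tr$true_y_um[idx] - mm$trap_y[j])^2)
    expect_true(all(d <= mm$trap_r_um[j] + 1e-9))
  }
})

test_that("membrane model enforces its geometric invariants", {
  mask <- disk_domain_mask(0.6, extent_um = 1.6)
  mm <- membrane_model(mask, trap_area_fraction = 0.25, seed = 11)
  expect_true(all(rafttrack:::mask_lookup(mask, mm$trap_x, mm$trap_y)))
  expect_lt(abs(mm$realized_area_fraction / 0.25 - 1), 0.1)
  # empty trap field with positive coverage request is rejected
  broken <- mm
  broken$trap_x <- numeric(0)
  expect_error(simulate_membrane(sim_config(100, seed = 1), broken), "no traps")
})

test_that("long-lag mobility in Lo falls monotonically with trap coverage", {
  mask <- disk_domain_mask(0.8, extent_um = 2)
  d_long <- vapply(c(0.05, 0.2, 0.4), function(frac) {
    mm <- membrane_model(mask, trap_area_fraction = frac, seed = 13)
    msds <- vapply(1:8, function(i) {
      tr <- simulate_membrane(sim_config(2000, d_free = 0.3, loc_noise_nm = 0,
                                         seed = 500 + i), mm, d_lo_free = 0.3)
      cv <- time_averaged_msd(tr, lags = c(45, 50))
      (cv$msd_um2[2] - cv$msd_um2[1]) / (4 * (cv$lag_s[2] - cv$lag_s[1]))
    }, numeric(1))
    mean(msds)
  }, numeric(1))
  expect_true(all(diff(d_long) < 0))
})

test_that("matched Brownian controls honour the null contract", {
  mask <- disk_domain_mask(0.5, extent_um = 1.4)
  mm <- membrane_model(mask, seed = 2)
  tr <- simulate_membrane(sim_config(1000, d_free = 0.3, seed = 61), mm,
                          d_lo_free = 0.3)
  ctrl <- matched_brownian_control(tr, d_est = 0.24, seed = 62)
  expect_equal(nrow(ctrl), 1000L)
  expect_equal(frame_interval(ctrl), frame_interval(tr))
  expect_true(all(ctrl$state == "LD"))
  expect_error(matched_brownian_control(tr, d_est = -1), "positive")

  src <- simulate_brownian(sim_config(1e5, d_free = 0.8, loc_noise_nm = 3,
                                      seed = 63))
  ctrl_big <- matched_brownian_control(src, d_est = 0.8, seed = 64)
  d_back <- microscopic_d(time_averaged_msd(ctrl_big, lags = 1:4))
  expect_lt(abs(d_back / 0.8 - 1), 0.15)
})
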