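test_that("noiseless model curves are inverted to machine precision", {
  cv <- model_curve(gamma = 0.3, alpha = 0.75, offset = 4e-4)
  fit <- fit_anomalous(cv)
  expect_lt(abs(fit$gamma / 0.3 - 1), 1e-6)
  expect_lt(abs(fit$alpha / 0.75 - 1), 1e-6)
  expect_lt(abs(fit$offset_um2 / 4e-4 - 1), 1e-6)
  expect_equal(fit$classification, "SUB")
  expect_equal(fit$alpha_loglog, 0.75, tolerance = 1e-6)
  # model methods are consistent
  expect_equal(unname(coef(fit)), c(fit$gamma, fit$alpha, fit$offset_um2))
  expect_equal(predict(fit), cv$msd_um2, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("classification follows the alpha band", {
  get_class <- function(a) fit_anomalous(model_curve(0.5, a, 1e-5))$classification
  expect_equal(get_class(0.8), "SUB")
  expect_equal(get_class(1.0), "BROWNIAN")
  expect_equal(get_class(1.05), "BROWNIAN")
  expect_equal(get_class(1.3), "SUPER")
  wide <- fit_anomalous(model_curve(0.5, 0.8, 1e-5), brownian_band = 0.25)
  expect_equal(wide$classification, "BROWNIAN")
})

test_that("a constant curve degrades to an offset-only fit", {
  dt <- 2e-5
  cv <- rafttrack:::new_msd_curve(lag_s = (1:10) * dt, msd_um2 = rep(2e-4, 10),
                                  n_pairs = rep(100L, 10), n_steps = 500L,
                                  frame_interval_s = dt)
  fit <- fit_anomalous(cv)
  expect_true(fit$degenerate)
  expect_equal(fit$classification, "DEGENERATE")
  expect_equal(fit$offset_um2, 2e-4)
  expect_equal(fit$gamma, 0)
})

test_that("the fitted offset matches 4*sigma^2 for static noise without blur", {
  sigma_um <- 3e-3
  cfg <- sim_config(1e5, d_free = 1.0, loc_noise_nm = 3, blur_substeps = 1,
                    seed = 19)
  fit <- fit_anomalous(time_averaged_msd(simulate_brownian(cfg)))
  expect_lt(abs(fit$offset_um2 / (4 * sigma_um^2) - 1), 0.2)
})

test_that("fit range restriction and minimum lag count are enforced", {
  cv <- model_curve(0.3, 1.0, 0, n_lags = 30)
  fit <- fit_anomalous(cv, fit_range_s = c(2e-5, 2e-4))
  expect_equal(nrow(fit$data), 10L)
  expect_error(fit_anomalous(cv, fit_range_s = c(2e-5, 6e-5)), "at least 5")
})
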