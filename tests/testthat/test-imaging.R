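static_traj <- function(n, x = 0.513, y = 0.487, dt = 2e-5) {
  make_traj(rep(x, n), rep(y, n), dt)
}

test_that("synthesized noise matches the PSF model's SNR specification", {
  psf <- psf_model(snr = 20, contrast = 0.1)
  st <- synthesize_stack(static_traj(200), psf, n_pix = 40, seed = 21)
  # particle-free corner: temporal std per pixel should equal the noise std
  corner <- st$frames[, 1:8, 1:8]
  measured <- mean(apply(corner, c(2, 3), sd))
  expect_lt(abs(measured / (0.1 * 1000 / 20) - 1), 0.05)
})

test_that("zero contrast yields a pure background stack", {
  psf <- psf_model(contrast = 1e-12, snr = 20)
  st <- synthesize_stack(static_traj(11), psf, n_pix = 24, seed = 22)
  bgfree <- remove_background(st, background = attr(st, "background"))
  expect_lt(abs(median(bgfree$frames) - 1), 1e-6)
  expect_lt(max(abs(bgfree$frames - 1)), 1e-6)
})

test_that("the domain field is imaged as a ~1% contrast step", {
  mask <- domain_mask(cbind(matrix(TRUE, 24, 12), matrix(FALSE, 24, 12)),
                      pixel_size_nm = 48, origin_um = c(0, 0))
  psf <- psf_model(contrast = 1e-12) # no particle signal, no noise
  tr <- static_traj(5, x = 0.55, y = 0.55)
  st <- synthesize_stack(tr, psf, n_pix = 24, pixel_size_nm = 48,
                         origin_um = c(0, 0), gain_sd = 0,
                         illum_amplitude = 0, domain_mask = mask,
                         domain_contrast = 0.01, seed = 23)
  f <- st$frames[1, , ]
  step <- mean(f[, 1:12]) / mean(f[, 13:24]) - 1
  expect_equal(step, 0.01, tolerance = 1e-6)
})

test_that("temporal median background is exact and robust", {
  # static scene of identical frames: background equals any frame exactly
  pattern <- matrix(runif(64, 900, 1100), 8, 8)
  stc <- frame_stack(array(rep(pattern, each = 5), dim = c(5, 8, 8)))
  expect_warning(bg <- temporal_median_background(stc), "stationary")
  expect_equal(bg, pattern, tolerance = 1e-12)

  # odd-length stack with one wild outlier frame: median unmoved
  base <- array(rep(5, 5 * 8 * 8), dim = c(5, 8, 8))
  base[3, , ] <- 1e6
  st2 <- frame_stack(base)
  expect_equal(temporal_median_background(st2), matrix(5, 8, 8))

  # moving particle with low per-pixel occupancy: background recovered
  # within the median's sampling noise everywhere
  trm <- simulate_brownian(sim_config(400, frame_interval_s = 1e-3, d_free = 2,
                                      loc_noise_nm = 0, blur_substeps = 1,
                                      seed = 25))
  psf2 <- psf_model(snr = 20)
  stm <- synthesize_stack(trm, psf2, seed = 26)
  bg_est <- temporal_median_background(stm)
  bg_true <- attr(stm, "background")
  noise_sd <- 0.1 * 1000 / 20
  err <- abs(bg_est - bg_true)
  expect_lt(mean(err), noise_sd / 4)
  expect_lt(max(err), 2 * noise_sd)
})

test_that("a noiseless spot is localized to sub-millipixel accuracy", {
  psf <- psf_model(snr = 1e9)
  tr <- static_traj(3, x = 0.5131, y = 0.4877)
  st <- synthesize_stack(tr, psf, n_pix = 26, pixel_size_nm = 48, seed = 27)
  bgfree <- remove_background(st, background = attr(st, "background"))
  loc <- localize_spot(bgfree$frames[1, , ], psf, pixel_size_nm = 48,
                       origin_um = attr(st, "origin_um"), min_depth = 0)
  expect_lt(abs(loc$x_um - 0.5131) / 48e-3, 1e-3)
  expect_lt(abs(loc$y_um - 0.4877) / 48e-3, 1e-3)
  expect_equal(loc$fit_sigma_nm, psf$sigma_nm, tolerance = 1e-4)
})

test_that("localization precision degrades monotonically with noise", {
  prec <- vapply(c(20, 10, 5), function(snr) {
    psf <- psf_model(snr = snr)
    st <- synthesize_stack(static_traj(120), psf, n_pix = 26, seed = 28)
    locs <- localize_stack(st, psf, background = attr(st, "background"))
    sd(locs$x_um)
  }, numeric(1))
  expect_true(all(diff(prec) > 0))
})

test_that("the full chain re-traces a moving particle near static precision", {
  psf <- psf_model(snr = 20)
  # static benchmark precision (known background)
  sst <- synthesize_stack(static_traj(300), psf, n_pix = 26, seed = 29)
  slocs <- localize_stack(sst, psf, background = attr(sst, "background"))
  static_rms <- sqrt(mean((slocs$x_um - mean(slocs$x_um))^2 +
                          (slocs$y_um - mean(slocs$y_um))^2))

  trm <- simulate_brownian(sim_config(500, frame_interval_s = 1e-3, d_free = 2,
                                      loc_noise_nm = 0, blur_substeps = 1,
                                      seed = 30))
  st <- synthesize_stack(trm, psf, seed = 31)
  locs <- localize_stack(st, psf) # background from the stack's own median
  expect_gt(nrow(locs), 0.95 * nrow(trm))
  m <- merge(as.data.frame(trm), locs, by = "frame", suffixes = c("", ".fit"))
  rms <- sqrt(mean((m$x_um.fit - m$x_um)^2 + (m$y_um.fit - m$y_um)^2))
  expect_lte(rms, 2 * static_rms)
})

test_that("greedy linking resolves tracks and respects the gate", {
  # single particle, no gaps -> one full-length track
  one <- data.frame(frame = 0:29, x_um = seq(0, 0.29, by = 0.01), y_um = 0)
  tracks <- link_localizations(one, max_disp_um = 0.05)
  expect_length(tracks, 1L)
  expect_equal(nrow(tracks[[1]]), 30L)

  # two well-separated particles -> two tracks, zero swaps
  two <- data.frame(frame = rep(0:39, each = 2),
                    x_um = as.vector(rbind(seq(0, 0.39, by = 0.01),
                                           seq(5, 5.39, by = 0.01))),
                    y_um = rep(c(0, 3), 40))
  tracks <- link_localizations(two, max_disp_um = 0.1)
  expect_length(tracks, 2L)
  ys <- vapply(tracks, function(t) length(unique(t$y_um)), integer(1))
  expect_true(all(ys == 1L)) # no identity swaps

  # zero gate: every localization becomes its own track
  tracks <- link_localizations(one, max_disp_um = 0)
  expect_length(tracks, 30L)

  # conservation: localizations are partitioned among tracks
  expect_equal(sum(vapply(tracks, nrow, integer(1))), nrow(one))

  # ambiguity: two equidistant candidates -> conservative break
  amb <- data.frame(frame = c(0L, 1L, 1L), x_um = c(0, 0.01, -0.01), y_um = 0)
  tracks <- link_localizations(amb, max_disp_um = 0.05)
  expect_length(tracks, 3L)
})

test_that("stacks and localizations round-trip through TIFF and CSV", {
  st <- frame_stack(array(runif(4 * 6 * 6, 0, 4000), dim = c(4, 6, 6)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back$frames), dim(st$frames))
  expect_lt(max(abs(back$frames - round(st$frames))), 0.5)

  locs <- data.frame(frame = 0:2, x_um = c(1, 2, 3) * 0.1, y_um = 0.2,
                     fit_amplitude = -0.1, fit_sigma_nm = 127,
                     residual_rms = 0.004)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_localizations_csv(locs, csv)
  expect_equal(read_localizations_csv(csv), locs, tolerance = 1e-9)
})
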