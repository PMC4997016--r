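#' Point-spread-function model for iSCAT-style dark spots
#'
#' The diffraction-limited image of a scattering nanoparticle in iSCAT is a
#' dark (negative-going) Gaussian spot on a bright background. `contrast` is
#' the fractional depth of the spot relative to the local background and
#' `snr` the ratio of the peak depth to the per-pixel noise standard
#' deviation.
#'
#' @param fwhm_nm Full width at half maximum of the spot, nm (default 300).
#' @param contrast Fractional spot depth (default 0.1).
#' @param snr Signal-to-noise ratio (default 20).
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(fwhm_nm = 300, contrast = 0.1, snr = 20) {
  stop_if_not_scalar_num(fwhm_nm, "fwhm_nm", 0, strict = TRUE)
  stop_if_not_scalar_num(contrast, "contrast", 0, strict = TRUE)
  stop_if_not_scalar_num(snr, "snr", 0, strict = TRUE)
  structure(list(fwhm_nm = fwhm_nm, contrast = contrast, snr = snr,
                 sigma_nm = fwhm_nm / (2 * sqrt(2 * log(2)))),
            class = "psf_model")
}

#' Frame stacks
#'
#' A `frame_stack` holds a time series of camera frames as a 3D array
#' `(frame, row, col)` with pixel size and frame interval metadata. Rows are
#' y, columns are x; positions in um are measured from the centre of pixel
#' `[1, 1]` (the 0-based pixel `(0, 0)` of the on-disk convention).
#'
#' @param frames Numeric 3D array `(time, row, col)`, at least 3 frames.
#' @param pixel_size_nm Pixel edge, nm (default 48).
#' @param frame_interval_s Frame interval, seconds.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size_nm = 48, frame_interval_s = 2e-5) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[1] < 3L) stop("need at least 3 frames for background extraction")
  stop_if_not_scalar_num(pixel_size_nm, "pixel_size_nm", 0, strict = TRUE)
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Frame stack: %d frames of %d x %d px (%.3g nm/px, dt = %.3g s)\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

#' Synthesize an iSCAT-like image stack from a trajectory
#'
#' Renders each frame as a stationary non-uniform background (smooth
#' illumination gradient times a fixed per-pixel gain map, with an optional
#' weak domain-contrast step across an Lo mask) multiplied by
#' `1 - contrast * G(r - r_particle)` — a Gaussian dark spot at the particle
#' position — plus white Gaussian noise with standard deviation
#' `contrast * base / snr` (so the peak spot depth over noise equals the PSF
#' model's SNR). Frames in which the particle lies within `2 * FWHM` of the
#' field border are listed in the `flagged_frames` attribute.
#'
#' @param traj A `trajectory`; coordinates must fit inside the field of view.
#' @param psf A [psf_model()].
#' @param n_pix Field size in pixels (square). Default: large enough for the
#'   trajectory extent plus a `4 * FWHM` margin.
#' @param pixel_size_nm Pixel edge, nm (default 48).
#' @param base Mean background level in camera counts (default 1000).
#' @param illum_amplitude Relative amplitude of the smooth illumination
#'   gradient (default 0.1).
#' @param gain_sd Relative std of the per-pixel gain map (default 0.02).
#' @param domain_mask Optional [domain_mask()] imaged at `domain_contrast`.
#' @param domain_contrast Relative intensity step across the Lo mask
#'   (default 0.01).
#' @param origin_um Position (x, y) of the centre of pixel `[1, 1]`;
#'   default centres the trajectory in the field.
#' @param seed Optional seed for gain map and noise.
#' @return A [frame_stack()] with attributes `origin_um`, `background`
#'   (the true stationary background) and `flagged_frames`.
#' @export
synthesize_stack <- function(traj, psf = psf_model(), n_pix = NULL,
                             pixel_size_nm = 48, base = 1000,
                             illum_amplitude = 0.1, gain_sd = 0.02,
                             domain_mask = NULL, domain_contrast = 0.01,
                             origin_um = NULL, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(psf, "psf_model"))
  px <- pixel_size_nm * 1e-3
  fwhm_um <- psf$fwhm_nm * 1e-3
  span_x <- range(traj$x_um); span_y <- range(traj$y_um)
  if (is.null(n_pix)) {
    need <- max(diff(span_x), diff(span_y)) + 8 * fwhm_um
    n_pix <- max(16L, ceiling(need / px))
  }
  if (is.null(origin_um)) {
    origin_um <- c(mean(span_x) - (n_pix - 1) * px / 2,
                   mean(span_y) - (n_pix - 1) * px / 2)
  }
  xs <- origin_um[1] + (seq_len(n_pix) - 1) * px
  ys <- origin_um[2] + (seq_len(n_pix) - 1) * px
  if (min(traj$x_um) < xs[1] || max(traj$x_um) > xs[n_pix] ||
      min(traj$y_um) < ys[1] || max(traj$y_um) > ys[n_pix]) {
    stop("trajectory does not fit within the field of view")
  }
  with_seed(seed, {
    # stationary background: smooth illumination gradient x per-pixel gain
    gx <- (xs - mean(xs)) / (n_pix * px)
    gy <- (ys - mean(ys)) / (n_pix * px)
    illum <- outer(1 + illum_amplitude * gy, 1 + illum_amplitude * gx)
    gain <- matrix(1 + rnorm(n_pix * n_pix, 0, gain_sd), n_pix, n_pix)
    bg <- base * illum * gain
    if (!is.null(domain_mask)) {
      lo <- outer(ys, xs, function(yy, xx) mask_lookup(domain_mask, xx, yy))
      bg <- bg * (1 + domain_contrast * lo)
    }
    sigma_um <- psf$sigma_nm * 1e-3
    noise_sd <- psf$contrast * base / psf$snr
    n_t <- nrow(traj)
    frames <- array(0, dim = c(n_t, n_pix, n_pix))
    border <- 2 * fwhm_um
    flagged <- integer(0)
    for (f in seq_len(n_t)) {
      x0 <- traj$x_um[f]; y0 <- traj$y_um[f]
      spot <- outer(exp(-(ys - y0)^2 / (2 * sigma_um^2)),
                    exp(-(xs - x0)^2 / (2 * sigma_um^2)))
      frames[f, , ] <- bg * (1 - psf$contrast * spot) +
        rnorm(n_pix * n_pix, 0, noise_sd)
      if (x0 - xs[1] < border || xs[n_pix] - x0 < border ||
          y0 - ys[1] < border || ys[n_pix] - y0 < border) {
        flagged <- c(flagged, f)
      }
    }
    st <- frame_stack(frames, pixel_size_nm = pixel_size_nm,
                      frame_interval_s = frame_interval(traj))
    attr(st, "origin_um") <- origin_um
    attr(st, "background") <- bg
    attr(st, "flagged_frames") <- flagged
    st
  })
}

#' Temporal-median background extraction
#'
#' Estimates the stationary background of a stack as the per-pixel median
#' over time. A fast-moving particle occupies any given pixel in a minority
#' of frames, so the median is blind to it; a particle parked on the same
#' pixels for most of the stack would be absorbed into the background (a
#' warning is emitted when the stack shows no temporal variation at all).
#'
#' @param stack A [frame_stack()].
#' @return A background matrix (row, col).
#' @export
temporal_median_background <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  d <- dim(fr)
  m <- matrix(fr, nrow = d[1])
  bg <- matrix(apply(m, 2, stats::median), d[2], d[3])
  if (all(sweep(m, 2, m[1, ]) == 0)) {
    warning("all frames identical: any stationary particle is absorbed into the background")
  }
  bg
}

#' Remove a stationary background from a stack
#'
#' iSCAT contrast is multiplicative on the illumination, so the default mode
#' divides each frame by the background, yielding frames fluctuating around 1
#' with the particle as a dip of depth `contrast`. Subtraction is available
#' as an option.
#'
#' @param stack A [frame_stack()].
#' @param background Background matrix; default [temporal_median_background()].
#' @param mode `"divide"` (default) or `"subtract"`.
#' @return A [frame_stack()] of background-corrected frames.
#' @export
remove_background <- function(stack, background = NULL,
                              mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  if (is.null(background)) background <- temporal_median_background(stack)
  fr <- stack$frames
  out <- array(0, dim(fr))
  for (f in seq_len(dim(fr)[1])) {
    out[f, , ] <- if (mode == "divide") fr[f, , ] / background else fr[f, , ] - background
  }
  st <- frame_stack(out, pixel_size_nm = stack$pixel_size_nm,
                    frame_interval_s = stack$frame_interval_s)
  attr(st, "origin_um") <- attr(stack, "origin_um")
  attr(st, "mode") <- mode
  st
}

#' Localize a dark spot by 2D Gaussian fitting
#'
#' Fits a circularly symmetric 2D Gaussian with constant offset,
#' `I(x, y) = offset + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 s^2))` with
#' `A < 0` for a dark spot, by least squares over a square region of
#' interest of about `5 * FWHM`, and returns the centre in um.
#'
#' @param frame Background-corrected frame matrix (row = y, col = x).
#' @param psf A [psf_model()] providing the expected width.
#' @param pixel_size_nm Pixel edge, nm.
#' @param roi_center Optional length-2 (row, col) candidate position; default
#'   the darkest pixel.
#' @param min_depth Minimum dip depth (offset minus minimum, in frame units)
#'   for a candidate to be fitted; default `5 *` the robust noise scale.
#' @param origin_um Position of the centre of pixel `[1, 1]` (default
#'   `c(0, 0)`).
#' @return A one-row data frame `frame`, `x_um`, `y_um`, `fit_amplitude`,
#'   `fit_sigma_nm`, `residual_rms`, or `NULL` when no acceptable candidate
#'   or fit exists (a gap in the trajectory).
#' @export
localize_spot <- function(frame, psf = psf_model(), pixel_size_nm = 48,
                          roi_center = NULL, min_depth = NULL,
                          origin_um = c(0, 0)) {
  stopifnot(is.matrix(frame))
  px <- pixel_size_nm * 1e-3
  med <- stats::median(frame)
  noise <- stats::mad(frame)
  if (is.null(min_depth)) min_depth <- 5 * noise
  if (is.null(roi_center)) {
    roi_center <- which(frame == min(frame), arr.ind = TRUE)[1, ]
  }
  depth <- med - frame[roi_center[1], roi_center[2]]
  if (depth < min_depth) return(NULL)

  half <- max(3L, round(2.5 * psf$fwhm_nm / pixel_size_nm))
  ri <- max(1L, roi_center[1] - half):min(nrow(frame), roi_center[1] + half)
  ci <- max(1L, roi_center[2] - half):min(ncol(frame), roi_center[2] + half)
  sub <- frame[ri, ci]
  yy <- (ri - 1) * px + origin_um[2]
  xx <- (ci - 1) * px + origin_um[1]
  grid <- expand.grid(y = yy, x = xx)
  gx <- grid$x; gy <- grid$y
  z <- as.vector(sub)
  s0 <- psf$sigma_nm * 1e-3
  start <- list(a = as.numeric(-depth),
                x0 = as.numeric((roi_center[2] - 1) * px + origin_um[1]),
                y0 = as.numeric((roi_center[1] - 1) * px + origin_um[2]),
                s = s0, c = med)
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ c + a * exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * s^2)),
                      start = start,
                      lower = c(a = -Inf, x0 = min(xx), y0 = min(yy),
                                s = 0.3 * s0, c = -Inf),
                      upper = c(a = 0, x0 = max(xx), y0 = max(yy),
                                s = 4 * s0, c = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  # reject fits pinned to the ROI border (divergence)
  if (p[["x0"]] <= min(xx) + 1e-9 || p[["x0"]] >= max(xx) - 1e-9 ||
      p[["y0"]] <= min(yy) + 1e-9 || p[["y0"]] >= max(yy) - 1e-9) {
    return(NULL)
  }
  data.frame(frame = NA_integer_, x_um = p[["x0"]], y_um = p[["y0"]],
             fit_amplitude = p[["a"]], fit_sigma_nm = p[["s"]] * 1e3,
             residual_rms = sqrt(mean(residuals(fit)^2)))
}

#' Localize every frame of a stack
#'
#' Convenience chain: temporal-median background extraction, background
#' correction, and per-frame [localize_spot()]. Frames without an acceptable
#' fit are skipped (gaps).
#'
#' @param stack A raw [frame_stack()].
#' @param psf A [psf_model()].
#' @param mode Background-correction mode, see [remove_background()].
#' @param background Optional known background image; default the temporal
#'   median of the stack itself. A particle that is stationary for most of
#'   the stack is absorbed by its own median, so static-precision benchmarks
#'   must supply a particle-free background here.
#' @param ... Passed to [localize_spot()].
#' @return Data frame of localizations with 0-based `frame` indices.
#' @export
localize_stack <- function(stack, psf = psf_model(),
                           mode = c("divide", "subtract"),
                           background = NULL, ...) {
  mode <- match.arg(mode)
  bgfree <- remove_background(stack, background = background, mode = mode)
  origin <- attr(stack, "origin_um") %||% c(0, 0)
  out <- vector("list", dim(stack$frames)[1])
  for (f in seq_along(out)) {
    loc <- localize_spot(bgfree$frames[f, , ], psf,
                         pixel_size_nm = stack$pixel_size_nm,
                         origin_um = origin, ...)
    if (!is.null(loc)) {
      loc$frame <- f - 1L
      out[[f]] <- loc
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour linking between consecutive frames: candidate
#' pairs within the displacement gate are linked in order of increasing
#' distance; unmatched localizations start new tracks. When a track sees two
#' candidates inside the gate at a distance ratio below `ambiguity_ratio`
#' the assignment is ambiguous and the track is conservatively terminated
#' (no link), the candidates starting fresh tracks.
#'
#' @param locs Data frame of localizations with columns `frame`, `x_um`,
#'   `y_um`, sorted by frame.
#' @param max_disp_um Displacement gate per frame interval, um.
#' @param frame_interval_s Frame interval used for the `t_s` column.
#' @param ambiguity_ratio Distance ratio below which an assignment is
#'   ambiguous (default 1.2).
#' @return List of data frames (`frame`, `t_s`, `x_um`, `y_um`), one per
#'   track; tracks may have length 1.
#' @export
link_localizations <- function(locs, max_disp_um, frame_interval_s = 2e-5,
                               ambiguity_ratio = 1.2) {
  stopifnot(is.data.frame(locs), all(c("frame", "x_um", "y_um") %in% names(locs)))
  if (is.unsorted(locs$frame)) stop("localizations must be sorted by frame")
  n <- nrow(locs)
  track_id <- integer(n)
  next_id <- 0L
  frames <- sort(unique(locs$frame))
  idx_by_frame <- split(seq_len(n), locs$frame)
  # tracks open at the previous frame: named by row index of their last loc
  open <- integer(0)
  terminated <- logical(n)
  for (fi in seq_along(frames)) {
    cur <- idx_by_frame[[as.character(frames[fi])]]
    linked_cur <- rep(FALSE, length(cur))
    if (length(open) && fi > 1L && frames[fi] - frames[fi - 1L] == 1L) {
      dmat <- outer(seq_along(open), seq_along(cur), function(i, j) {
        sqrt((locs$x_um[open[i]] - locs$x_um[cur[j]])^2 +
             (locs$y_um[open[i]] - locs$y_um[cur[j]])^2)
      })
      dmat[dmat > max_disp_um] <- Inf
      # conservative breaks: a track with two close candidates is ended
      drop_track <- rep(FALSE, length(open))
      for (i in seq_along(open)) {
        ds <- sort(dmat[i, is.finite(dmat[i, ])])
        if (length(ds) >= 2 && ds[2] / max(ds[1], 1e-12) < ambiguity_ratio) {
          drop_track[i] <- TRUE
        }
      }
      dmat[drop_track, ] <- Inf
      while (any(is.finite(dmat))) {
        k <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        i <- k[1]; j <- k[2]
        track_id[cur[j]] <- track_id[open[i]]
        linked_cur[j] <- TRUE
        dmat[i, ] <- Inf
        dmat[, j] <- Inf
      }
    }
    for (j in which(!linked_cur)) {
      next_id <- next_id + 1L
      track_id[cur[j]] <- next_id
    }
    open <- cur
  }
  tracks <- split(seq_len(n), track_id)
  lapply(unname(tracks), function(ii) {
    data.frame(frame = locs$frame[ii],
               t_s = locs$frame[ii] * frame_interval_s,
               x_um = locs$x_um[ii], y_um = locs$y_um[ii])
  })
}

#' Read and write multi-page TIFF stacks
#'
#' Stacks are stored as 16-bit unsigned multi-page TIFF. Values are clipped
#' to `[0, 65535]` counts on write. Pixel size and frame interval are not
#' TIFF-standard fields, so they are supplied on read.
#'
#' @param stack A [frame_stack()].
#' @param path File path.
#' @param pixel_size_nm,frame_interval_s Metadata attached on read.
#' @return `read_stack_tiff()` returns a [frame_stack()];
#'   `write_stack_tiff()` returns `path` invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[1]), function(f) {
    m <- stack$frames[f, , ]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, pixel_size_nm = 48, frame_interval_s = 2e-5) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]]
  frame_stack(arr, pixel_size_nm = pixel_size_nm,
              frame_interval_s = frame_interval_s)
}

#' Localization CSV I/O
#'
#' Columns: `frame,x_um,y_um,amp,sigma_nm,residual`.
#'
#' @param locs Localization data frame from [localize_stack()].
#' @param path File path.
#' @export
write_localizations_csv <- function(locs, path) {
  out <- data.frame(frame = locs$frame, x_um = locs$x_um, y_um = locs$y_um,
                    amp = locs$fit_amplitude, sigma_nm = locs$fit_sigma_nm,
                    residual = locs$residual_rms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_localizations_csv
#' @export
read_localizations_csv <- function(path) {
  df <- utils::read.csv(path)
  data.frame(frame = df$frame, x_um = df$x_um, y_um = df$y_um,
             fit_amplitude = df$amp, fit_sigma_nm = df$sigma_nm,
             residual_rms = df$residual)
}
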