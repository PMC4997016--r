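#' Simulation configuration
#'
#' Bundles the acquisition-level parameters shared by every trajectory
#' simulator: the frame interval (default 20 microseconds, i.e. 50 kHz
#' sampling), trajectory length, static localization error, and the number of
#' sub-steps integrated across the exposure to emulate motion blur. With
#' `blur_substeps = 1` the observed position is the instantaneous true
#' position plus noise (no blur).
#'
#' @param n_steps Number of frames (positions) to simulate; >= 2.
#' @param frame_interval_s Frame interval in seconds (default `2e-5`).
#' @param d_free Free (inter-trap / liquid-disordered) diffusion coefficient
#'   in um^2/s used by simulators that take their rate from the config.
#' @param loc_noise_nm Static localization error, standard deviation per axis
#'   in nm (default 3).
#' @param blur_substeps Sub-steps averaged per exposure (default 10); the
#'   exposure is taken to span the full frame interval.
#' @param seed Optional integer seed; when set, identical configs produce
#'   bit-identical trajectories.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_steps = 1000, d_free = 1.48, seed = 1)
#' @export
sim_config <- function(n_steps,
                       frame_interval_s = 2e-5,
                       d_free = 1.0,
                       loc_noise_nm = 3,
                       blur_substeps = 10L,
                       seed = NULL) {
  stop_if_not_scalar_num(n_steps, "n_steps", 2)
  stop_if_not_scalar_num(frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  stop_if_not_scalar_num(d_free, "d_free", 0)
  stop_if_not_scalar_num(loc_noise_nm, "loc_noise_nm", 0)
  stop_if_not_scalar_num(blur_substeps, "blur_substeps", 1)
  if (!is.null(seed)) stop_if_not_scalar_num(seed, "seed")
  structure(list(n_steps = as.integer(n_steps),
                 frame_interval_s = frame_interval_s,
                 d_free = d_free,
                 loc_noise_nm = loc_noise_nm,
                 blur_substeps = as.integer(blur_substeps),
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %d steps @ %.3g s (%.3g kHz), ",
                     "D_free = %.3g um^2/s, noise = %.3g nm, blur substeps = %d\n"),
              x$n_steps, x$frame_interval_s, 1e-3 / x$frame_interval_s,
              x$d_free, x$loc_noise_nm, x$blur_substeps))
  invisible(x)
}
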