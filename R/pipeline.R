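#' Assign trajectory points to membrane domains
#'
#' Labels each frame `"LO"` or `"LD"` by nearest-pixel lookup in a
#' [domain_mask()] (`"UNKNOWN"` outside the mask extent), collects the
#' boundary-crossing events, and emits per-domain sub-trajectories of at
#' least `min_sub_len` frames for MSD analysis. A crossing frame belongs to
#' the domain being entered.
#'
#' @param traj A `trajectory`.
#' @param mask A [domain_mask()].
#' @param min_sub_len Minimum sub-trajectory length in frames (default 1000).
#' @return A list with `labels` (per frame), `crossings` (data frame of
#'   `frame_idx`, `from`, `to`), and `subtrajectories` (list of trajectories
#'   with a `domain` attribute).
#' @export
assign_domains <- function(traj, mask, min_sub_len = 1000L) {
  stopifnot(inherits(traj, "trajectory"), inherits(mask, "domain_mask"))
  px <- mask$pixel_size_nm * 1e-3
  j <- round((traj$x_um - mask$origin_um[1]) / px) + 1
  i <- round((traj$y_um - mask$origin_um[2]) / px) + 1
  inb <- i >= 1 & i <= nrow(mask$mask) & j >= 1 & j <= ncol(mask$mask)
  labels <- rep("UNKNOWN", nrow(traj))
  labels[inb] <- ifelse(mask$mask[cbind(i[inb], j[inb])], "LO", "LD")

  ch <- which(labels[-1] != labels[-length(labels)]) + 1L
  known <- labels[ch] != "UNKNOWN" & labels[ch - 1L] != "UNKNOWN"
  crossings <- data.frame(frame_idx = ch[known],
                          from = labels[ch[known] - 1L],
                          to = labels[ch[known]])

  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  subs <- list()
  dt <- frame_interval(traj)
  for (r in seq_along(runs$values)) {
    if (runs$values[r] == "UNKNOWN" || runs$lengths[r] < min_sub_len) next
    sub <- as_trajectory(as.data.frame(traj)[starts[r]:ends[r], , drop = FALSE],
                         frame_interval_s = dt)
    attr(sub, "domain") <- runs$values[r]
    subs[[length(subs) + 1L]] <- sub
  }
  list(labels = labels, crossings = crossings, subtrajectories = subs)
}

#' Homogeneous-membrane benchmark
#'
#' Simulates a population of free Brownian trajectories at the benchmark
#' scale (62 trajectories of 6,000 steps at 50 kHz by default, with
#' per-particle diffusion rates drawn from a truncated normal distribution),
#' runs the full MSD analysis on each — time-averaged MSD, free-offset
#' anomalous fit, microscopic diffusion rate — and pools step sizes for a
#' Gaussianity check (Lilliefors-corrected Kolmogorov-Smirnov).
#'
#' @param n_traj,n_steps Population size and trajectory length.
#' @param d_mean,d_sd Mean and spread of the per-particle true diffusion
#'   rate, um^2/s (defaults 1.48 and 0.39).
#' @param frame_interval_s,loc_noise_nm,blur_substeps Acquisition parameters.
#' @param max_lag_s MSD lag range upper end (default 20 ms).
#' @param seed Root seed.
#' @return A list of class `homogeneous_benchmark`: `per_traj` (data frame
#'   with `d_true`, `d_micro`, `alpha`, `gamma`, `offset`), `alpha_mode`
#'   (density mode of the alpha histogram), `gauss_p` (step-size normality
#'   p-value on up to 1e5 pooled steps), `ensemble` (length-weighted
#'   ensemble MSD) and `ensemble_fit`.
#' @export
run_benchmark_homogeneous <- function(n_traj = 62L, n_steps = 6000L,
                                      d_mean = 1.48, d_sd = 0.39,
                                      frame_interval_s = 2e-5,
                                      loc_noise_nm = 3, blur_substeps = 10L,
                                      max_lag_s = 0.02, seed = 1L) {
  if (n_traj < 62L || n_steps < 6000L) {
    warning("running below the benchmark scale (62 trajectories of 6,000 steps)")
  }
  seeds <- child_seeds(seed, n_traj + 1L)
  d_true <- with_seed(seeds[n_traj + 1L], {
    d <- rnorm(n_traj, d_mean, d_sd)
    while (any(d <= 0.05)) d[d <= 0.05] <- rnorm(sum(d <= 0.05), d_mean, d_sd)
    d
  })
  per <- data.frame(traj = seq_len(n_traj), d_true = d_true,
                    d_micro = NA_real_, alpha = NA_real_,
                    gamma = NA_real_, offset = NA_real_)
  curves <- vector("list", n_traj)
  steps_x <- c(); steps_y <- c()
  for (i in seq_len(n_traj)) {
    cfg <- sim_config(n_steps, frame_interval_s = frame_interval_s,
                      d_free = d_true[i], loc_noise_nm = loc_noise_nm,
                      blur_substeps = blur_substeps, seed = seeds[i])
    tr <- simulate_brownian(cfg)
    cv <- time_averaged_msd(tr, max_lag_s = max_lag_s)
    ft <- fit_anomalous(cv)
    per$d_micro[i] <- ft$d_micro_um2_s
    per$alpha[i] <- ft$alpha
    per$gamma[i] <- ft$gamma
    per$offset[i] <- ft$offset_um2
    curves[[i]] <- cv
    if (length(steps_x) < 1e5) {
      # standardize per trajectory: particles differ in D, so pooled raw
      # steps would be a normal mixture rather than one Gaussian
      steps_x <- c(steps_x, as.numeric(scale(diff(tr$x_um))))
      steps_y <- c(steps_y, as.numeric(scale(diff(tr$y_um))))
    }
  }
  gauss_p <- nortest::lillie.test(
    steps_x[seq_len(min(length(steps_x), 1e5))])$p.value
  dens <- stats::density(per$alpha, na.rm = TRUE)
  ens <- ensemble_msd(curves)
  out <- list(per_traj = per,
              alpha_mode = dens$x[which.max(dens$y)],
              gauss_p = gauss_p,
              ensemble = ens,
              ensemble_fit = fit_anomalous(ens),
              curves = curves)
  class(out) <- "homogeneous_benchmark"
  out
}

#' @export
print.homogeneous_benchmark <- function(x, ...) {
  cat(sprintf(paste0("Homogeneous-membrane benchmark: %d trajectories\n",
                     "  alpha histogram mode: %.3f\n",
                     "  mean microscopic D: %.3g um^2/s (true mean %.3g)\n",
                     "  step-size normality p: %.3g\n"),
              nrow(x$per_traj), x$alpha_mode, mean(x$per_traj$d_micro),
              mean(x$per_traj$d_true), x$gauss_p))
  invisible(x)
}

#' Raft-membrane experiment on synthetic data
#'
#' Simulates lipid diffusion in a phase-separated membrane — an Lo disk with
#' a calibrated nano-trap field inside an Ld background — at the scale of
#' the raft study (88 Lo and 166 Ld sub-trajectories of >= 1,000 steps by
#' default), and runs the full analysis surface: per-domain time-averaged
#' MSD, length-weighted ensembles, free-offset anomalous fits over the
#' short-lag window, per-trajectory alpha and microscopic D, transient-D
#' traces, confinement detection on Lo trajectories, and a Brownian null
#' calibration of the detector.
#'
#' @param n_lo_traj,n_ld_traj Trajectory counts per domain.
#' @param n_steps Frames per simulated trajectory (default 1500).
#' @param d_ld True Ld diffusion rate, um^2/s (default 1.43).
#' @param d_lo_free Inter-trap viscosity inside Lo, um^2/s.
#' @param trap_area_fraction Trap coverage of the Lo phase; a value from
#'   [calibrate_lo_model()] in calibrated runs.
#' @param lo_radius_um Lo disk radius (default 0.8).
#' @param frame_interval_s,loc_noise_nm,blur_substeps Acquisition parameters.
#' @param fit_range_s Lag range of the ensemble anomalous fits (default
#'   20 us - 1 ms, the subdiffusive window).
#' @param min_sub_len Minimum sub-trajectory length (default 1000).
#' @param n_null Brownian null trajectories for the detector calibration.
#' @param seed Root seed.
#' @return A list of class `raft_experiment` with per-domain ensembles and
#'   fits, per-trajectory statistics, confinement events, and the null
#'   summary.
#' @export
run_raft_experiment <- function(n_lo_traj = 88L, n_ld_traj = 166L,
                                n_steps = 1500L, d_ld = 1.43,
                                d_lo_free = 0.30, trap_area_fraction = 0.30,
                                lo_radius_um = 0.8,
                                frame_interval_s = 2e-5, loc_noise_nm = 3,
                                blur_substeps = 10L,
                                fit_range_s = c(2e-5, 1e-3),
                                min_sub_len = 1000L,
                                n_null = 40L, seed = 1L) {
  seeds <- child_seeds(seed, 3L)
  mask <- disk_domain_mask(lo_radius_um, extent_um = 3 * lo_radius_um)
  model <- membrane_model(mask, trap_area_fraction = trap_area_fraction,
                          seed = seeds[1])
  tseeds <- child_seeds(seeds[2], n_lo_traj + n_ld_traj)

  sim_one <- function(i, start, d_out) {
    cfg <- sim_config(n_steps, frame_interval_s = frame_interval_s,
                      d_free = d_out, loc_noise_nm = loc_noise_nm,
                      blur_substeps = blur_substeps, seed = tseeds[i])
    simulate_membrane(cfg, model, d_lo_free = d_lo_free, start_um = start)
  }

  lo_subs <- list(); ld_subs <- list()
  lo_trajs <- list()
  ld_start <- c(lo_radius_um * 1.35, 0) # in the Ld ring, away from the Lo rim
  for (i in seq_len(n_lo_traj + n_ld_traj)) {
    in_lo <- i <= n_lo_traj
    tr <- sim_one(i, if (in_lo) c(0, 0) else ld_start, d_ld)
    asg <- assign_domains(tr, mask, min_sub_len = min_sub_len)
    for (s in asg$subtrajectories) {
      if (attr(s, "domain") == "LO") {
        lo_subs[[length(lo_subs) + 1L]] <- s
        if (in_lo) lo_trajs[[length(lo_trajs) + 1L]] <- tr
      } else {
        ld_subs[[length(ld_subs) + 1L]] <- s
      }
    }
  }
  if (!length(lo_subs) || !length(ld_subs)) {
    stop("simulation produced no usable sub-trajectories; increase n_steps")
  }

  analyse_domain <- function(subs) {
    curves <- lapply(subs, time_averaged_msd, max_lag_s = 0.02)
    per <- data.frame(
      n_steps = vapply(curves, attr, numeric(1), "n_steps"),
      d_micro = vapply(curves, function(cv)
        suppressWarnings(microscopic_d(cv)), numeric(1)),
      alpha = vapply(curves, function(cv)
        fit_anomalous(cv, fit_range_s = fit_range_s)$alpha, numeric(1)))
    ens <- ensemble_msd(curves)
    list(curves = curves, per_traj = per, ensemble = ens,
         fit_short = fit_anomalous(ens, fit_range_s = fit_range_s),
         fit_full = fit_anomalous(ens))
  }
  lo <- analyse_domain(lo_subs)
  ld <- analyse_domain(ld_subs)

  # reference rate for the confinement statistic: the lipid's free diffusion
  # rate as measured in this run's Ld domain. The recorded particles explore
  # both phases, so the trajectory-level rate entering the statistic is the
  # free-phase one; using the Lo-local microscopic rate instead would blind
  # the detector to zones larger than ~20 nm.
  d_ref_raft <- mean(ld$per_traj$d_micro)
  params <- confinement_params(d_ref_um2_s = d_ref_raft)
  events <- list()
  for (k in seq_along(lo_subs)) {
    ev <- detect_confinements(lo_subs[[k]], params, loc_noise_nm = loc_noise_nm)
    if (nrow(ev)) {
      ev$traj_id <- k
      events[[length(events) + 1L]] <- as.data.frame(ev)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(start_idx = integer(0), end_idx = integer(0),
               residence_s = numeric(0), diameter_nm = numeric(0),
               peak_L = numeric(0), traj_id = integer(0))

  null_len <- as.integer(stats::median(vapply(lo_subs, nrow, integer(1))))
  null_cal <- calibrate_null(params = params, n_sim = n_null,
                             d = d_ref_raft, n_steps = null_len,
                             frame_interval_s = frame_interval_s,
                             loc_noise_nm = loc_noise_nm, seed = seeds[3])

  transient <- if (length(lo_trajs)) transient_d(lo_trajs[[1]]) else NULL

  out <- list(model = model, lo = lo, ld = ld,
              confinement_events = events, null_calibration = null_cal,
              transient_example = transient,
              n_lo_subs = length(lo_subs), n_ld_subs = length(ld_subs),
              params = list(d_ld = d_ld, d_lo_free = d_lo_free,
                            trap_area_fraction = trap_area_fraction,
                            fit_range_s = fit_range_s,
                            d_ref_confinement = d_ref_raft))
  class(out) <- "raft_experiment"
  out
}

#' @export
print.raft_experiment <- function(x, ...) {
  cat(sprintf(paste0("Raft-membrane experiment: %d Lo / %d Ld sub-trajectories\n",
                     "  Ld ensemble alpha (short lags): %.3f\n",
                     "  Lo ensemble alpha (short lags): %.3f\n",
                     "  Lo mean microscopic D: %.3g um^2/s\n",
                     "  confinement events: %d (mean diameter %.3g nm, ",
                     "mean residence %.3g ms)\n",
                     "  null flagged-time fraction: %.3g%%\n"),
              x$n_lo_subs, x$n_ld_subs, x$ld$fit_short$alpha,
              x$lo$fit_short$alpha, mean(x$lo$per_traj$d_micro),
              nrow(x$confinement_events),
              mean(x$confinement_events$diameter_nm),
              1e3 * mean(x$confinement_events$residence_s),
              100 * x$null_calibration$flagged_fraction))
  invisible(x)
}

#' Write a plot-ready CSV report
#'
#' Serializes the analysis surface of a benchmark or raft experiment as tidy
#' CSV files in `outdir` (created if needed): per-trajectory statistics,
#' ensemble MSD curves and fit parameters, confinement events and null
#' histograms. Output is deterministic: identical inputs produce
#' byte-identical files.
#'
#' @param report A `homogeneous_benchmark` or `raft_experiment`.
#' @param outdir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(format(as.data.frame(df), digits = 10, trim = TRUE,
                            scientific = NA),
                     path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
  }
  if (inherits(report, "homogeneous_benchmark")) {
    put(report$per_traj, "benchmark_per_trajectory.csv")
    put(as.data.frame(report$ensemble), "benchmark_ensemble_msd.csv")
    put(data.frame(alpha_mode = report$alpha_mode, gauss_p = report$gauss_p,
                   ensemble_alpha = report$ensemble_fit$alpha),
        "benchmark_summary.csv")
  } else if (inherits(report, "raft_experiment")) {
    put(report$lo$per_traj, "lo_per_trajectory.csv")
    put(report$ld$per_traj, "ld_per_trajectory.csv")
    put(as.data.frame(report$lo$ensemble), "lo_ensemble_msd.csv")
    put(as.data.frame(report$ld$ensemble), "ld_ensemble_msd.csv")
    put(report$confinement_events, "confinement_events.csv")
    put(data.frame(lo_alpha_short = report$lo$fit_short$alpha,
                   ld_alpha_short = report$ld$fit_short$alpha,
                   lo_d_micro_mean = mean(report$lo$per_traj$d_micro),
                   ld_d_micro_mean = mean(report$ld$per_traj$d_micro),
                   null_flagged_fraction = report$null_calibration$flagged_fraction),
        "raft_summary.csv")
    if (!is.null(report$transient_example)) {
      put(report$transient_example, "transient_d_example.csv")
    }
  } else {
    stop("unknown report type")
  }
  invisible(files)
}

# --- run configuration ------------------------------------------------------

run_config_keys <- c(
  "sim.n_steps", "sim.frame_interval_s", "sim.d_free", "sim.loc_noise_nm",
  "sim.blur_substeps",
  "membrane.lo_radius_um", "membrane.trap_area_fraction",
  "membrane.trap_diameter_mean_nm", "membrane.trap_diameter_sd_nm",
  "membrane.trap_escape_rate_s", "membrane.d_lo_free",
  "imaging.pixel_size_nm", "imaging.fwhm_nm", "imaging.contrast", "imaging.snr",
  "msd.max_lag_s", "msd.n_lags", "msd.fit_min_s", "msd.fit_max_s",
  "confinement.window_steps", "confinement.smooth_steps",
  "confinement.l_critical",
  "pipeline.n_lo_traj", "pipeline.n_ld_traj", "pipeline.min_sub_len",
  "seed", "outdir")

#' Run configuration files
#'
#' Pipeline runs are configured through a flat, namespaced key-value file in
#' YAML (`sim.*`, `membrane.*`, `imaging.*`, `msd.*`, `confinement.*`,
#' `pipeline.*`, plus `seed` and `outdir`). Unknown keys are rejected;
#' configurations round-trip through serialization unchanged.
#'
#' @param ... Key-value overrides of the defaults.
#' @param path File path.
#' @param config A named list as returned by `default_run_config()`.
#' @return `default_run_config()` and `read_run_config()` return a named
#'   list; `write_run_config()` returns `path` invisibly.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    "sim.n_steps" = 1500L, "sim.frame_interval_s" = 2e-5, "sim.d_free" = 1.43,
    "sim.loc_noise_nm" = 3, "sim.blur_substeps" = 10L,
    "membrane.lo_radius_um" = 0.8, "membrane.trap_area_fraction" = 0.30,
    "membrane.trap_diameter_mean_nm" = 32, "membrane.trap_diameter_sd_nm" = 10,
    "membrane.trap_escape_rate_s" = 1 / 0.62e-3, "membrane.d_lo_free" = 0.30,
    "imaging.pixel_size_nm" = 48, "imaging.fwhm_nm" = 300,
    "imaging.contrast" = 0.1, "imaging.snr" = 20,
    "msd.max_lag_s" = 0.02, "msd.n_lags" = 30L,
    "msd.fit_min_s" = 2e-5, "msd.fit_max_s" = 1e-3,
    "confinement.window_steps" = 25L, "confinement.smooth_steps" = 10L,
    "confinement.l_critical" = 1,
    "pipeline.n_lo_traj" = 88L, "pipeline.n_ld_traj" = 166L,
    "pipeline.min_sub_len" = 1000L,
    "seed" = 1L, "outdir" = "rafttrack-out")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), run_config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  base <- default_run_config()
  base[names(cfg)] <- cfg
  base
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  bad <- setdiff(names(config), run_config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}
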