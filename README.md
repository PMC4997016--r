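# rafttrack

Single-particle tracking analysis of lipid diffusion in raft-mimetic
membranes, at microsecond time resolution and nanometer precision.

High-speed interferometric scattering (iSCAT) microscopy can track a
gold-nanoparticle-labelled lipid at 50 kHz with ~3 nm localization
precision. At that resolution, diffusion in liquid-ordered (Lo, raft-like)
membrane domains is anomalous: the mean squared displacement grows
sublinearly below ~1 ms, and trajectories show transient confinements in
nanoscopic zones (tens of nm, sub-millisecond dwells) attributed to
clusters of densely packed saturated lipids. `rafttrack` is for
experimentalists and simulators who need that analysis chain as tested,
reusable code:

* **MSD analysis** — time-averaged MSD over all overlapping pairs,
  length-weighted ensemble averaging, and the anomalous-diffusion fit
  `MSD(Δt) = 4ΓΔt^α + c` with the transport coefficient Γ, the exponent α
  and the dynamic-localization-error offset c all free
  (`time_averaged_msd()`, `ensemble_msd()`, `fit_anomalous()` — a classed
  model object with `coef`/`predict`/`plot` methods).
* **Diffusion rates** — the microscopic rate from the first two MSD points,
  `D = [MSD(2Δt) − MSD(Δt)]/(4Δt)` (offset-cancelling), and transient
  rates over 146-step segments (`microscopic_d()`, `transient_d()`).
* **Transient-confinement detection** — the Simson–Sheets–Jacobson
  probability level `log₁₀ψ = 0.2048 − 2.5117·Dt/R²`, `L = −log₁₀ψ − 1`,
  with a 25-step forward window, 10-step smoothing, critical level 1
  (99% confidence), size estimation via the uniform-disk identity
  `diameter = 2√2·RMS`, and false-positive calibration on matched Brownian
  controls (`probability_level()`, `detect_confinements()`,
  `estimate_confinement_size()`, `calibrate_null()`).
* **Synthetic data** — a trajectory-level generator (free diffusion, Lo/Ld
  domain partitioning, reflecting nano-traps with Poisson escape, 3 nm
  localization noise, motion blur over the exposure) and a compact
  image-level chain (iSCAT-like frame synthesis, temporal-median
  background removal, 2D Gaussian dark-spot localization,
  nearest-neighbour linking).
* **Orchestration** — `run_benchmark_homogeneous()` and
  `run_raft_experiment()` reproduce the homogeneous-membrane control and
  the full raft analysis on synthetic data; `write_report()` emits
  deterministic, plot-ready CSV. A thin command-line front end lives in
  `inst/cli/rafttrack.R`.

## Worked example

```r
library(rafttrack)

# homogeneous-membrane control: one 6,000-step trajectory at 50 kHz
tr    <- simulate_brownian(sim_config(n_steps = 6000, d_free = 1.48, seed = 42))
fit   <- fit_anomalous(time_averaged_msd(tr))
print(fit)
#> Anomalous-diffusion fit: MSD = 4*Gamma*dt^alpha + offset
#>   Gamma  = 1.029 um^2/s^alpha
#>   alpha  = 0.9574  [BROWNIAN]
#>   offset = -1.407e-05 um^2
#>   microscopic D = 1.514 um^2/s

# raft membrane: an Lo disk filled with 32 +/- 10 nm traps (0.62 ms dwells)
mask  <- disk_domain_mask(radius_um = 0.8, extent_um = 2)
model <- membrane_model(mask, trap_area_fraction = 0.39, seed = 42)
lo    <- simulate_membrane(sim_config(4000, d_free = 0.3, seed = 43),
                           model, d_lo_free = 0.3)
print(fit_anomalous(time_averaged_msd(lo, max_lag_s = 1e-3)))
#> Anomalous-diffusion fit: MSD = 4*Gamma*dt^alpha + offset
#>   Gamma  = 0.01512 um^2/s^alpha
#>   alpha  = 0.6895  [SUB]
#>   offset = 1.525e-05 um^2
#>   microscopic D = 0.2561 um^2/s

# transient confinements, detected against the lipid's free-phase rate
ev <- detect_confinements(lo, confinement_params(d_ref_um2_s = 1.43),
                          loc_noise_nm = 3)
#> 27 confinement events; mean diameter 35.6 nm, mean residence 2.62 ms
```

The free-membrane trajectory is classified Brownian with α ≈ 0.96 and a
microscopic rate near its true 1.48 µm²/s; the same analysis inside the
trap-filled Lo domain yields α ≈ 0.69 (subdiffusion), a microscopic rate
near 0.24 µm²/s, and confinement events whose size distribution reflects
the ~32 nm trap field.

## Further reading

The methods vignette (`vignettes/raft-diffusion-analysis.Rmd`) documents
the models, estimator conventions (window timing, fit loss, release rules),
the calibration procedure, and what passing the synthetic-data suite does
and does not demonstrate about real membranes.
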