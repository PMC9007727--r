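# pebmeg — MEG source reconstruction with fMRI spatial priors

`pebmeg` solves the distributed MEG inverse problem on a cortical mesh
within a parametric empirical Bayes (PEB) hierarchy, using fMRI
statistical maps as *soft* spatial priors, and ships the complete
simulation study that quantifies what those priors buy.

The model is the two-level Gaussian hierarchy

```
B = L X + E,   E ~ N(0, C_e),   X ~ N(0, Γ)
C_e = Σ_j exp(λ_j) Q_j          (sensor components; white noise by default)
Γ   = Σ_i exp(λ_i) Q_i          (source components)
```

where `B` (channels × time) is the measured field, `L` the lead field of a
single-sphere (Sarvas) head model, and the source covariance `Γ` is a
weighted sum of fixed components: a multiple-sparse-priors (MSP)
dictionary of Green's-function-smoothed cortical patches, plus one
rank-one component `Q_i = q_i q_iᵀ` per suprathreshold fMRI cluster
(thresholded, Voronoi-projected onto the mesh, smoothed with
`G = exp(σA) ≈ Σ_{i=0..8} σⁱAⁱ/i!`). The log hyperparameters `λ` are
estimated by restricted maximum likelihood — damped Fisher-scoring ascent
of the variational free energy `F`, a lower bound on the log model
evidence — so components the data do not support are switched off, which
is precisely why *invalid* priors do little harm. The MAP source estimate
is the posterior mean `X̂ = Γ Lᵀ (L Γ Lᵀ + C_e)⁻¹ B`, and `F` ranks
competing prior sets.

The package is aimed at methods researchers who want a transparent,
fully scriptable PEB/MSP implementation with an honest evaluation
battery: two-dipole evoked + induced simulations at several noise
levels, ROC/AUC detection scoring, peak and centre-of-mass localization
error, VOI-eigenvariate time courses, and time/frequency-domain RMSE.

## Worked example

Invert 100 simulated trials (evoked 10 Hz dipole at (−38, 43, 5) mm MNI,
induced 12–48 Hz dipole at (−54, −13, 5) mm, −10 dB SNR) with and without
valid fMRI priors:

```r
library(pebmeg)

# fixture geometry, single-sphere lead field, MSP patch dictionary
geom <- fixture_geometry(n_vertices = 2000, seed = 3)
L    <- build_leadfield(geom$mesh, geom$sensors, geom$sphere)
spec <- smoothing_spec(geom$mesh$adjacency, sigma = 0.6)
msp  <- build_msp_library(geom$mesh, n_patches = 512, spec, seed = 4)

# synthetic fMRI stat map -> one covariance component per cluster
pspec <- synthetic_prior_spec()
vol   <- make_synthetic_statmap(pspec)
fmri  <- build_prior_set(vol, geom$mesh, height_T = 3, extent_k = 10, spec)
valid <- classify_priors(fmri, geom$mesh, pspec$valid_centers)

# 100 trials of the two-dipole paradigm at -10 dB SNR
trials <- simulate_trials(sim_config(snr_db = -10, seed = 106), geom, L)

for (v in c("none", "valid")) {
  comps <- variant_components(msp, fmri, valid, v, geom$sensors$n_channels)
  fit   <- invert(trials, L, comps, mode = "induced")
  cell  <- evaluate_inversion(fit, trials, geom, study_config())
  cat(sprintf("%-6s AUC %.3f | induced-source cmass error %5.2f mm | F %.6e\n",
              v, cell$auc, cell$localization$cmass_error_mm[2],
              cell$free_energy))
}
```

which prints (about a minute on one CPU):

```
none   AUC 0.990 | induced-source cmass error 10.35 mm | F 1.427362e+08
valid  AUC 1.000 | induced-source cmass error  0.52 mm | F 1.427364e+08
```

Adding the valid fMRI priors raises detection accuracy (AUC), cuts the
induced source's centre-of-mass error twenty-fold, and increases the free
energy — the model with priors is the better explanation of the data, not
merely the more constrained one.

## The analysis workflow

The full study lives in `analysis/` as numbered stages that write
everything under `results/`:

```sh
Rscript analysis/01_simulate.R      # geometry, lead field, trial sets (+ manifest)
Rscript analysis/02_build_priors.R  # synthetic SPM{T}, clusters, priors, MSP library
Rscript analysis/03_invert.R        # 4 prior variants x 2 noise levels, F ranking
Rscript analysis/04_evaluate.R      # AUC/localization/RMSE tables, ROC curves, JSON
```

Stage 4 emits `localization_auc.csv`, `rmse_time.csv`,
`rmse_freq.csv`, per-cell ROC curves, and `metrics.json`.

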