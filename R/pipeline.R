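# Study orchestration: the fixed simulation -> priors -> inversion ->
# evaluation pipeline, run over the prior variants {none, all, valid,
# invalid} and the configured noise levels, plus the seed battery used for
# reporting.  All computation lives in the module functions; this file only
# wires them together deterministically.
#
# Seed scheme: one global seed expands to per-stage seeds by fixed offsets
# (geometry: seed; MSP sampling: seed + 1; trial simulation: seed + 101 + j
# for the j-th noise level), so stages can be rerun independently yet
# reproducibly.  All derived seeds stay far below 2^31.

#' Default study configuration
#'
#' The standard simulation conditions: 2000-vertex fixture mesh, 275
#' channels, 100 trials over 0.55-0.85 s at 600 Hz, dipole moment 10 nA.m,
#' MSP library of 512 patches, Green's-function smoothing sigma = 0.6 with
#' truncation order 8, synthetic stat map thresholded at T = 3 with extent
#' 10 voxels, ROC labeling radius and VOI radius 10 mm.
#'
#' @param seed global integer seed.
#' @param noise_levels SNR levels in dB (`Inf` = noiseless).
#' @param n_vertices,n_trials,n_patches,sigma,truncation_order,height_T,extent_k,voi_radius_mm
#'   study parameters (see Description).
#' @param variants prior variants to run.
#' @param reml [reml_options()].
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         noise_levels = c(Inf, -10),
                         n_vertices = 2000,
                         n_trials = 100,
                         n_patches = 512,
                         sigma = 0.6,
                         truncation_order = 8,
                         height_T = 3,
                         extent_k = 10,
                         voi_radius_mm = 10,
                         variants = c("none", "all", "valid", "invalid"),
                         reml = reml_options()) {
  structure(as.list(environment()), class = "study_config")
}

#' Select the prior variant's component set
#'
#' `"none"` = MSP library only; `"all"` = MSP plus every fMRI component;
#' `"valid"`/`"invalid"` = MSP plus the respective subset.
#'
#' @param msp list of MSP `cov_component`s.
#' @param fmri list of fMRI `cov_component`s.
#' @param is_valid logical vector classifying each fMRI component.
#' @param variant one of "none", "all", "valid", "invalid".
#' @param n_channels sensor dimension for the noise component.
#' @export
variant_components <- function(msp, fmri, is_valid, variant, n_channels) {
  extra <- switch(variant,
                  none = list(),
                  all = fmri,
                  valid = fmri[is_valid],
                  invalid = fmri[!is_valid],
                  stop("unknown prior variant: ", variant))
  component_set(list(identity_component(n_channels)), c(msp, extra))
}

#' Classify fMRI components as valid or invalid priors
#'
#' A component is "valid" when its weighted support centroid lies within
#' `radius_mm` of any true dipole position.
#'
#' @param fmri list of rank-one `cov_component`s.
#' @param mesh `cortical_mesh`.
#' @param dipoles k x 3 matrix, mm.
#' @param radius_mm classification radius (default 20).
#' @export
classify_priors <- function(fmri, mesh, dipoles, radius_mm = 20) {
  vapply(fmri, function(cp) {
    w <- cp$vector
    cen <- colSums(mesh$vertices * w) / sum(w)
    any(sqrt(rowSums(sweep(as.matrix(dipoles), 2, cen)^2)) <= radius_mm)
  }, TRUE)
}

# per-trial posterior pass: accumulates the trial-RMS amplitude matrix and
# the per-trial VOI time courses, in trial chunks to bound memory
trial_posterior_summaries <- function(result, trials, mesh, voi_centers,
                                      voi_radius_mm = 10, chunk = 10) {
  dims <- dim(trials$sensor_data)
  ntr <- dims[1]; p <- dims[2]; nt <- dims[3]
  W <- result$filter
  voi_sel <- lapply(seq_len(nrow(voi_centers)), function(k) {
    d <- sqrt(rowSums(sweep(mesh$vertices, 2, voi_centers[k, ])^2))
    which(d <= voi_radius_mm)
  })
  sumsq <- matrix(0, nrow(W), nt)
  voi_tc <- lapply(voi_sel, function(s) array(0, dim = c(ntr, length(s), nt)))
  for (i0 in seq(1, ntr, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1, ntr)
    Ball <- matrix(aperm(trials$sensor_data[ii, , , drop = FALSE], c(2, 3, 1)),
                   p, nt * length(ii))
    Xall <- W %*% Ball
    for (j in seq_along(ii)) {
      Xi <- Xall[, ((j - 1) * nt + 1):(j * nt)]
      sumsq <- sumsq + Xi^2
      for (k in seq_along(voi_sel))
        voi_tc[[k]][ii[j], , ] <- Xi[voi_sel[[k]], ]
    }
  }
  list(rms = sqrt(sumsq / ntr), voi_tc = voi_tc, voi_sel = voi_sel)
}

# eigenvariate of a vertices x samples block (re-uses the exported rule)
voi_eigenvariate <- function(Y) {
  sv <- svd(Y, nu = 0, nv = 1)
  e <- sv$d[1] * sv$v[, 1]
  if (sum(e * colMeans(Y)) < 0) e <- -e
  as.numeric(e)
}

# time- and frequency-domain RMSE battery for one source
rmse_battery_source <- function(avg_est, per_trial_est, truth, sample_rate) {
  ntr <- nrow(per_trial_est)
  avg_truth <- colMeans(truth)
  # one global sign flip per source (dipole orientation is sign-ambiguous),
  # fixed on the averaged pair and applied to every trial
  flip <- if (sum(avg_est * avg_truth) < 0) -1 else 1
  avg_est <- flip * avg_est
  per_trial_est <- flip * per_trial_est

  unit <- function(x) if (max(abs(x)) > 0) x / max(abs(x)) else x
  sp <- function(x) amplitude_spectrum(unit(x), sample_rate)$amplitude

  rt_avg <- rmse(avg_est, avg_truth, normalize = TRUE)
  rf_avg <- rmse(sp(avg_est), sp(avg_truth), normalize = FALSE)
  rt_tr <- rf_tr <- numeric(ntr)
  for (i in seq_len(ntr)) {
    rt_tr[i] <- rmse(per_trial_est[i, ], truth[i, ], normalize = TRUE)
    rf_tr[i] <- rmse(sp(per_trial_est[i, ]), sp(truth[i, ]), normalize = FALSE)
  }
  list(time = c(averaged = rt_avg, per_trial = mean(rt_tr)),
       freq = c(averaged = rf_avg, per_trial = mean(rf_tr)))
}

#' Evaluate one fitted inversion against a simulated trial set
#'
#' @param result `inversion_result` from [invert()].
#' @param trials `trial_set`.
#' @param geometry fixture geometry list.
#' @param cfg `study_config`.
#' @return list with `map`, `auc`, `roc`, `localization`, `rmse_time`,
#'   `rmse_freq`, `free_energy`.
#' @export
evaluate_inversion <- function(result, trials, geometry, cfg) {
  mesh <- geometry$mesh
  dip <- trials$config$dipole_positions
  sums <- trial_posterior_summaries(result, trials, mesh, dip,
                                    cfg$voi_radius_mm)
  map <- normalize_source_map(sums$rms)
  labels <- ground_truth_labels(mesh, dip, cfg$voi_radius_mm)
  roc <- roc_auc(map, labels)
  loc <- localization_errors(map, dip, mesh)

  nt <- length(trials$time)
  rmse_t <- rmse_f <- list()
  for (k in 1:2) {
    voi_rows <- sums$voi_sel[[k]]
    avg_block <- result$posterior_mean[voi_rows, , drop = FALSE]
    avg_est <- voi_eigenvariate(avg_block)
    ntr <- dim(trials$sensor_data)[1]
    per_est <- matrix(0, ntr, nt)
    for (i in seq_len(ntr))
      per_est[i, ] <- voi_eigenvariate(matrix(sums$voi_tc[[k]][i, , ],
                                              length(voi_rows), nt))
    truth <- matrix(trials$source_truth[, k, ], ntr, nt)
    bt <- rmse_battery_source(avg_est, per_est, truth,
                              trials$config$sample_rate)
    rmse_t[[k]] <- data.frame(source = k, averaged = bt$time["averaged"],
                              per_trial = bt$time["per_trial"])
    rmse_f[[k]] <- data.frame(source = k, averaged = bt$freq["averaged"],
                              per_trial = bt$freq["per_trial"])
  }
  list(map = map, auc = roc$auc, roc = roc, localization = loc,
       rmse_time = do.call(rbind, rmse_t), rmse_freq = do.call(rbind, rmse_f),
       free_energy = result$free_energy,
       n_iterations = result$n_iterations)
}

#' Run the full simulation study for one seed
#'
#' Builds the fixture geometry and lead field, the MSP library, the
#' synthetic fMRI stat map and its prior components, then for every
#' configured noise level simulates 100 trials and runs the four prior
#' variants, evaluating each inversion.
#'
#' @param cfg `study_config`.
#' @param verbose print progress.
#' @return nested list `res[[noise]][[variant]]` of [evaluate_inversion()]
#'   cells, plus attributes `geometry`, `config`.
#' @export
run_study <- function(cfg = study_config(), verbose = FALSE) {
  geom <- fixture_geometry(cfg$n_vertices, seed = cfg$seed)
  mesh <- geom$mesh
  L <- build_leadfield(mesh, geom$sensors, geom$sphere)
  spec <- smoothing_spec(mesh$adjacency, cfg$sigma, cfg$truncation_order)
  msp <- build_msp_library(mesh, cfg$n_patches, spec, seed = cfg$seed + 1)

  pspec <- synthetic_prior_spec()
  vol <- make_synthetic_statmap(pspec)
  fmri <- build_prior_set(vol, mesh, cfg$height_T, cfg$extent_k, spec)
  is_valid <- classify_priors(fmri, mesh, pspec$valid_centers)

  res <- list()
  for (j in seq_along(cfg$noise_levels)) {
    nl <- cfg$noise_levels[j]
    sim <- sim_config(snr_db = nl, n_trials = cfg$n_trials,
                      seed = cfg$seed + 101 + j)
    trials <- simulate_trials(sim, geom, L)
    nl_name <- if (is.finite(nl)) sprintf("%+ddB", nl) else "noiseless"
    res[[nl_name]] <- list()
    for (v in cfg$variants) {
      comps <- variant_components(msp, fmri, is_valid, v, geom$sensors$n_channels)
      t0 <- Sys.time()
      fit <- invert(trials, L, comps, cfg$reml, mode = "induced")
      cell <- evaluate_inversion(fit, trials, geom, cfg)
      if (verbose)
        message(sprintf("seed %d %s %-8s AUC %.3f F %.4e iters %d (%.1fs)",
                        cfg$seed, nl_name, v, cell$auc, cell$free_energy,
                        fit$n_iterations,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      res[[nl_name]][[v]] <- cell
    }
  }
  attr(res, "config") <- cfg
  res
}

#' Run the seed battery and aggregate the study metrics
#'
#' @param seeds integer vector of global seeds (default 1:5).
#' @param ... passed to [study_config()].
#' @param verbose print progress.
#' @return list with `per_seed` (list of [run_study()] results), `summary`
#'   (data.frame of per-cell metrics across seeds), and `config`.
#' @export
run_study_battery <- function(seeds = 1:5, ..., verbose = FALSE) {
  per_seed <- list()
  rows <- list()
  for (s in seeds) {
    cfg <- study_config(seed = s, ...)
    res <- run_study(cfg, verbose = verbose)
    per_seed[[as.character(s)]] <- res
    for (nl in names(res)) for (v in names(res[[nl]])) {
      cell <- res[[nl]][[v]]
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, noise = nl, variant = v, auc = cell$auc,
        peak1 = cell$localization$peak_error_mm[1],
        cmass1 = cell$localization$cmass_error_mm[1],
        peak2 = cell$localization$peak_error_mm[2],
        cmass2 = cell$localization$cmass_error_mm[2],
        free_energy = cell$free_energy,
        rmse_t_avg1 = cell$rmse_time$averaged[1],
        rmse_t_tr1 = cell$rmse_time$per_trial[1],
        rmse_t_avg2 = cell$rmse_time$averaged[2],
        rmse_t_tr2 = cell$rmse_time$per_trial[2],
        rmse_f_avg1 = cell$rmse_freq$averaged[1],
        rmse_f_tr1 = cell$rmse_freq$per_trial[1],
        rmse_f_avg2 = cell$rmse_freq$averaged[2],
        rmse_f_tr2 = cell$rmse_freq$per_trial[2])
    }
  }
  list(per_seed = per_seed, summary = do.call(rbind, rows),
       config = list(seeds = seeds, ...))
}

#' Seed-averaged study summary table
#'
#' @param battery output of [run_study_battery()].
#' @return data.frame of metric means by noise level and variant.
#' @export
battery_means <- function(battery) {
  sm <- battery$summary
  agg <- aggregate(sm[, !(names(sm) %in% c("seed", "noise", "variant"))],
                   by = list(noise = sm$noise, variant = sm$variant), FUN = mean)
  agg[order(agg$noise, agg$variant), ]
}
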