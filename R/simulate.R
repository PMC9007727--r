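# Two-dipole simulation study: an evoked 10 Hz source at (-38, 43, 5) mm MNI
# and an induced source at (-54, -13, 5) mm whose frequency varies from trial
# to trial, over t in [0.55, 0.85] s, 100 trials, at noise levels
# {noiseless, +10 dB, -10 dB}.  Source waveforms:
#
#   evoked:   f1(t)      = sin( (t - t0) * 10 * 2 pi + pi/2 )
#   induced:  f2(t; i,d) = sin( (t - t0) / (i d) * 24 * 2 pi + pi/2 )
#
# with i the trial number and d (delta) a positive per-trial random number,
# so the induced waveform is not phase-locked across trials.  Both start at
# amplitude 1 (phase pi/2) at t = t0.

#' Simulation configuration
#'
#' Defaults are the study conditions: two dipoles at (-38, 43, 5) and
#' (-54, -13, 5) mm MNI, window 0.55-0.85 s sampled at 600 Hz, 100 trials,
#' dipole moment 10 nA.m.  `delta_law` controls the induced source's
#' per-trial random scale: `"scaled_uniform"` (default) draws the product
#' rho_i = i * delta_i ~ Uniform(0.5, 2), so the induced frequency
#' 24 / rho_i spans 12-48 Hz on every trial; `"literal"` draws delta_i
#' itself from Uniform(`delta_range`), in which case the frequency falls
#' with the trial index.
#'
#' @param dipole_positions 2 x 3 matrix, mm MNI.
#' @param t_window length-2 numeric, seconds.
#' @param sample_rate Hz.
#' @param n_trials number of trials.
#' @param snr_db signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param delta_law "scaled_uniform" or "literal".
#' @param delta_range range of the Uniform draw (rho for "scaled_uniform",
#'   delta for "literal").
#' @param t0 waveform onset (default: window start).
#' @param dipole_moment A.m (default 1e-8 = 10 nA.m).
#' @param seed integer seed; every random draw derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dipole_positions = rbind(c(-38, 43, 5), c(-54, -13, 5)),
                       t_window = c(0.55, 0.85),
                       sample_rate = 600,
                       n_trials = 100,
                       snr_db = Inf,
                       delta_law = c("scaled_uniform", "literal"),
                       delta_range = c(0.5, 2),
                       t0 = t_window[1],
                       dipole_moment = 1e-8,
                       seed = 1) {
  delta_law <- match.arg(delta_law)
  stopifnot(t_window[1] < t_window[2], n_trials >= 1, sample_rate > 0,
            delta_range[1] > 0, delta_range[1] <= delta_range[2])
  structure(list(dipole_positions = as.matrix(dipole_positions),
                 t_window = t_window, sample_rate = sample_rate,
                 n_trials = as.integer(n_trials), snr_db = snr_db,
                 delta_law = delta_law, delta_range = delta_range,
                 t0 = t0, dipole_moment = dipole_moment,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Time axis of a simulation window
#' @param cfg `sim_config`.
#' @export
sim_time_axis <- function(cfg) {
  seq(cfg$t_window[1], cfg$t_window[2], by = 1 / cfg$sample_rate)
}

#' Evoked (phase-locked) 10 Hz waveform
#'
#' @param t_axis times, seconds.
#' @param t0 onset, seconds.
#' @return unit-amplitude samples; value 1 at `t = t0`.
#' @export
evoked_timecourse <- function(t_axis, t0) {
  sin((t_axis - t0) * 10 * 2 * pi + pi / 2)
}

#' Induced (trial-varying) waveform
#'
#' Frequency `24 / (i * delta)` Hz; deterministic given `(i, delta)`.
#'
#' @param t_axis times, seconds.
#' @param t0 onset, seconds.
#' @param trial_index trial number i (>= 1).
#' @param delta positive per-trial scale.
#' @export
induced_timecourse <- function(t_axis, t0, trial_index, delta) {
  if (delta <= 0) stop("delta must be positive")
  stopifnot(trial_index >= 1)
  sin((t_axis - t0) / (trial_index * delta) * 24 * 2 * pi + pi / 2)
}

#' Per-trial delta draws under the configured law
#' @keywords internal
draw_deltas <- function(cfg) {
  i <- seq_len(cfg$n_trials)
  u <- runif(cfg$n_trials, cfg$delta_range[1], cfg$delta_range[2])
  switch(cfg$delta_law,
         scaled_uniform = u / i,   # rho_i = i * delta_i ~ U(range)
         literal = u)
}

#' Simulate an MEG trial set
#'
#' Per trial, `B = L X + E`, with the two source waveforms placed on the
#' mesh vertices nearest the configured dipole positions (orientation: the
#' vertex normal, via the fixed-normal lead field) and white Gaussian
#' sensor noise scaled so that `10 log10(signal power / noise power)`
#' equals `snr_db` over the trial (no noise when `snr_db = Inf`).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg `sim_config`.
#' @param geometry output of [fixture_geometry()] (or compatible list).
#' @param L fixed-normal `leadfield` on `geometry$mesh`.
#' @return object of class `trial_set`: `sensor_data`
#'   (trials x channels x samples), `source_truth` (trials x 2 x samples),
#'   `time`, `config`, `realized_deltas`, `source_vertices`.
#' @export
simulate_trials <- function(cfg, geometry, L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(L, "leadfield"))
  if (L$moment_convention != "fixed")
    stop("simulate_trials needs a fixed-normal lead field")
  mesh <- geometry$mesh
  if (ncol(L$matrix) != mesh$n_vertices)
    stop("lead field does not match mesh geometry")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  t_axis <- sim_time_axis(cfg)
  nt <- length(t_axis)
  v1 <- nearest_vertex(cfg$dipole_positions[1, ], mesh)
  v2 <- nearest_vertex(cfg$dipole_positions[2, ], mesh)
  deltas <- draw_deltas(cfg)

  x1 <- evoked_timecourse(t_axis, cfg$t0)                 # same every trial
  l1 <- L$matrix[, v1] * cfg$dipole_moment
  l2 <- L$matrix[, v2] * cfg$dipole_moment
  p <- nrow(L$matrix)

  sensor <- array(0, dim = c(cfg$n_trials, p, nt))
  truth <- array(0, dim = c(cfg$n_trials, 2, nt))
  for (i in seq_len(cfg$n_trials)) {
    x2 <- induced_timecourse(t_axis, cfg$t0, i, deltas[i])
    Bsig <- outer(l1, x1) + outer(l2, x2)
    if (is.finite(cfg$snr_db)) {
      psig <- mean(Bsig^2)
      sigma_n <- sqrt(psig * 10^(-cfg$snr_db / 10))
      Bsig <- Bsig + matrix(rnorm(p * nt, 0, sigma_n), p, nt)
    }
    sensor[i, , ] <- Bsig
    truth[i, 1, ] <- x1
    truth[i, 2, ] <- x2
  }
  structure(list(sensor_data = sensor, source_truth = truth, time = t_axis,
                 config = cfg, realized_deltas = deltas,
                 source_vertices = c(v1, v2)),
            class = "trial_set")
}

#' Synthetic fMRI prior specification
#'
#' Valid blobs sit at the true dipole positions; invalid blobs elsewhere
#' (each at least 30 mm from both dipoles).
#'
#' @param valid_centers k x 3 matrix, mm (default: the two dipoles).
#' @param invalid_centers m x 3 matrix, mm (default: one right-frontal
#'   blob at (44, 31, 9)).
#' @param blob_radius_mm Gaussian half-width parameter (default 8).
#' @param peak_T peak T value of each blob (default 8).
#' @export
synthetic_prior_spec <- function(valid_centers = rbind(c(-38, 43, 5), c(-54, -13, 5)),
                                 invalid_centers = rbind(c(44, 31, 9)),
                                 blob_radius_mm = 8,
                                 peak_T = 8) {
  valid_centers <- as.matrix(valid_centers)
  invalid_centers <- as.matrix(invalid_centers)
  if (nrow(invalid_centers) > 0 && nrow(valid_centers) > 0) {
    for (i in seq_len(nrow(invalid_centers))) {
      d <- sqrt(rowSums(sweep(valid_centers, 2, invalid_centers[i, ])^2))
      if (any(d < 30))
        stop("invalid prior centres must be >= 30 mm from every true dipole")
    }
  }
  structure(list(valid_centers = valid_centers,
                 invalid_centers = invalid_centers,
                 blob_radius_mm = blob_radius_mm, peak_T = peak_T),
            class = "synthetic_prior_spec")
}

#' Default affine/grid for synthetic stat volumes (4 mm isotropic)
#' @export
#' @keywords internal
default_stat_grid <- function() {
  affine <- rbind(c(4, 0, 0, -80),
                  c(0, 4, 0, -100),
                  c(0, 0, 4, -60),
                  c(0, 0, 0, 1))
  list(grid_shape = c(41L, 46L, 39L), affine = affine)
}

#' Synthetic SPM{T}-like volume with valid and invalid clusters
#'
#' Gaussian blobs `peak_T * exp(-d^2 / (2 r^2))` at each centre.  Blobs must
#' not overlap (pairwise centre separation > 2 * blob_radius), so any
#' threshold below `peak_T` that exceeds the inter-blob floor recovers one
#' face-connected cluster per blob.
#'
#' @param spec `synthetic_prior_spec`.
#' @param grid_shape integer 3-vector of volume dimensions.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return `stat_volume`.
#' @export
make_synthetic_statmap <- function(spec, grid_shape = NULL, affine = NULL) {
  if (is.null(grid_shape) || is.null(affine)) {
    g <- default_stat_grid()
    if (is.null(grid_shape)) grid_shape <- g$grid_shape
    if (is.null(affine)) affine <- g$affine
  }
  centers <- rbind(spec$valid_centers, spec$invalid_centers)
  vol <- array(0, dim = grid_shape)
  if (nrow(centers) == 0) return(stat_volume(vol, affine))

  if (nrow(centers) > 1) {
    dd <- as.matrix(dist(centers))
    diag(dd) <- Inf
    if (any(dd < 2 * spec$blob_radius_mm))
      stop("blobs overlap: centre separation below twice the blob radius")
  }
  inv_aff <- solve(affine)
  for (k in seq_len(nrow(centers))) {
    vx <- (inv_aff %*% c(centers[k, ], 1))[1:3] + 1   # 1-based voxel coords
    if (any(vx < 1) || any(vx > grid_shape))
      stop("blob centre outside the volume grid")
  }
  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  mm <- voxel_to_mm(idx, affine)
  for (k in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(mm, 2, centers[k, ])^2)
    vol <- vol + array(spec$peak_T * exp(-d2 / (2 * spec$blob_radius_mm^2)),
                       dim = grid_shape)
  }
  stat_volume(vol, affine)
}
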