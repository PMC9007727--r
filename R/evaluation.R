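# Scoring of inversions against simulated ground truth: normalized source
# maps, peak / centre-of-mass localization error, ROC/AUC over a decision
# threshold sweep, VOI eigenvariate time courses, RMSE in time and frequency
# domains, and the study report layout.

#' Normalized source activity map
#'
#' Per-vertex maximum absolute amplitude over the analysis window, divided
#' by the global maximum, so values lie in [0, 1] and a decision-threshold
#' sweep over [0, 1] is meaningful.  An all-zero input yields an all-zero
#' map flagged `null`.
#'
#' @param posterior_mean sources x samples matrix (or a per-vertex
#'   amplitude vector).
#' @param window optional integer sample indices to restrict to.
#' @return object of class `source_map`: numeric per-vertex scores with
#'   attribute `null`.
#' @export
normalize_source_map <- function(posterior_mean, window = NULL) {
  if (is.matrix(posterior_mean)) {
    if (!is.null(window)) posterior_mean <- posterior_mean[, window, drop = FALSE]
    if (ncol(posterior_mean) == 0) stop("empty window")
    sc <- apply(abs(posterior_mean), 1, max)
  } else {
    sc <- abs(as.numeric(posterior_mean))
  }
  m <- max(sc)
  out <- if (m > 0) sc / m else sc
  structure(out, null = m == 0, class = "source_map")
}

#' Source map from per-trial posteriors
#'
#' Root-mean-square posterior amplitude across trials per vertex and time
#' sample, reduced to a normalized map; captures induced activity that
#' cancels in the trial-averaged waveform.
#'
#' @param result `inversion_result` carrying a posterior filter.
#' @param trials `trial_set`.
#' @param window optional sample indices.
#' @export
source_map_from_trials <- function(result, trials, window = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  dims <- dim(trials$sensor_data)
  acc <- NULL
  for (i in seq_len(dims[1])) {
    Xi <- posterior_timecourse(result, matrix(trials$sensor_data[i, , ], dims[2], dims[3]))
    acc <- if (is.null(acc)) Xi^2 else acc + Xi^2
  }
  normalize_source_map(sqrt(acc / dims[1]), window)
}

#' Ground-truth activity labels on the mesh
#'
#' Vertices within `radius_mm` of any true source position are positive.
#'
#' @param mesh `cortical_mesh`.
#' @param truth_positions k x 3 matrix, mm.
#' @param radius_mm labeling radius (default 10, the VOI radius).
#' @return logical per-vertex vector.
#' @export
ground_truth_labels <- function(mesh, truth_positions, radius_mm = 10) {
  truth_positions <- as.matrix(truth_positions)
  lab <- rep(FALSE, mesh$n_vertices)
  for (k in seq_len(nrow(truth_positions))) {
    d <- sqrt(rowSums(sweep(mesh$vertices, 2, truth_positions[k, ])^2))
    lab <- lab | (d <= radius_mm)
  }
  lab
}

#' ROC curve and AUC for a source map
#'
#' For each decision threshold `beta` on a uniform grid over [0, 1], a
#' vertex is classified active iff `map >= beta`; sensitivity
#' TP/(TP+FN) and specificity TN/(TN+FP) are computed, the curve is
#' traced as (1-specificity, sensitivity) with endpoints (0,0) and (1,1)
#' appended, and the AUC obtained by trapezoidal integration.
#'
#' @param map `source_map` (or numeric scores in [0,1]).
#' @param labels logical ground-truth labels.
#' @param n_thresholds grid size (default 101).
#' @return object of class `roc_curve`: data.frame `curve` (beta,
#'   sensitivity, specificity) and scalar `auc`.
#' @export
roc_auc <- function(map, labels, n_thresholds = 101) {
  scores <- as.numeric(map)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("labels must contain both classes")
  beta <- seq(0, 1, length.out = n_thresholds)
  P <- sum(labels); N <- sum(!labels)
  sens <- spec <- numeric(n_thresholds)
  for (i in seq_along(beta)) {
    pos <- scores >= beta[i]
    sens[i] <- sum(pos & labels) / P
    spec[i] <- sum(!pos & !labels) / N
  }
  x <- c(0, rev(1 - spec), 1)
  y <- c(0, rev(sens), 1)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  auc <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  structure(list(curve = data.frame(beta = beta, sensitivity = sens,
                                    specificity = spec),
                 auc = auc),
            class = "roc_curve")
}

#' Peak and centre-of-mass localization error
#'
#' The mesh is partitioned by proximity to the true source positions;
#' within each partition the regional peak vertex is found, and the
#' centre-of-mass error uses the amplitude-weighted centroid of the
#' connected suprathreshold cluster (threshold `cluster_threshold` x map
#' maximum, default 0.5; if the regional peak falls below that global
#' level, the threshold falls back to `cluster_threshold` x regional peak)
#' containing the peak.
#'
#' @param map `source_map`.
#' @param truth_positions k x 3 matrix, mm.
#' @param mesh `cortical_mesh`.
#' @param cluster_threshold fraction of the map maximum (default 0.5).
#' @return data.frame with one row per source: `peak_error_mm`,
#'   `cmass_error_mm`, `peak_vertex`, `cluster_size`.
#' @export
localization_errors <- function(map, truth_positions, mesh,
                                cluster_threshold = 0.5) {
  if (isTRUE(attr(map, "null"))) stop("cannot localize a null source map")
  truth_positions <- as.matrix(truth_positions)
  stopifnot(nrow(truth_positions) >= 1)
  scores <- as.numeric(map)
  V <- mesh$vertices
  # assign each vertex to its nearest true source
  D <- sapply(seq_len(nrow(truth_positions)), function(k)
    sqrt(rowSums(sweep(V, 2, truth_positions[k, ])^2)))
  D <- matrix(D, ncol = nrow(truth_positions))
  part <- max.col(-D, ties.method = "first")

  out <- lapply(seq_len(nrow(truth_positions)), function(k) {
    sel <- which(part == k)
    pk <- sel[which.max(scores[sel])]
    peak_err <- sqrt(sum((V[pk, ] - truth_positions[k, ])^2))
    thr <- cluster_threshold * max(scores)
    if (scores[pk] < thr) thr <- cluster_threshold * scores[pk]
    supra <- scores >= thr
    cl <- connected_vertices(mesh, pk, supra)
    w <- scores[cl]
    cm <- colSums(V[cl, , drop = FALSE] * w) / sum(w)
    data.frame(source = k,
               peak_error_mm = peak_err,
               cmass_error_mm = sqrt(sum((cm - truth_positions[k, ])^2)),
               peak_vertex = pk,
               cluster_size = length(cl))
  })
  do.call(rbind, out)
}

# connected component (mesh adjacency) of `supra` vertices containing seed
connected_vertices <- function(mesh, seed, supra) {
  A <- mesh$adjacency
  visited <- logical(mesh$n_vertices)
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(v) which(A[v, ] != 0))))
    nb <- nb[supra[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  which(visited)
}

#' First-eigenvariate time course over a volume of interest
#'
#' Stacks the time courses of all vertices within `radius_mm` of
#' `voi_center` and returns the dominant singular mode's temporal component
#' scaled by its singular value, with sign chosen to correlate positively
#' with the VOI mean time course.
#'
#' @param X sources x samples posterior matrix.
#' @param voi_center 3-vector, mm.
#' @param mesh `cortical_mesh`.
#' @param radius_mm VOI radius (default 10).
#' @return numeric time course (class `timecourse_estimate`, with attribute
#'   `voi_vertices`).
#' @export
extract_voi_timecourse <- function(X, voi_center, mesh, radius_mm = 10) {
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, as.numeric(voi_center))^2))
  sel <- which(d <= radius_mm)
  if (!length(sel)) stop("empty VOI: no vertices within ", radius_mm, " mm")
  Y <- X[sel, , drop = FALSE]
  sv <- svd(Y, nu = 0, nv = 1)
  e <- sv$d[1] * sv$v[, 1]
  mn <- colMeans(Y)
  if (sum(e * mn) < 0) e <- -e
  structure(as.numeric(e), voi_vertices = sel, class = "timecourse_estimate")
}

#' Root-mean-square error between two signals
#'
#' With `normalize = TRUE` (default) both signals are scaled to unit
#' maximum absolute amplitude first, because reconstructed source
#' amplitudes carry arbitrary units.
#'
#' @param estimate,truth equal-length numeric vectors.
#' @param normalize scale both to unit max amplitude.
#' @export
rmse <- function(estimate, truth, normalize = TRUE) {
  estimate <- as.numeric(estimate); truth <- as.numeric(truth)
  if (length(estimate) != length(truth)) stop("length mismatch")
  if (normalize) {
    if (max(abs(estimate)) > 0) estimate <- estimate / max(abs(estimate))
    if (max(abs(truth)) > 0) truth <- truth / max(abs(truth))
  }
  sqrt(mean((estimate - truth)^2))
}

#' Single-sided amplitude spectrum
#'
#' Discrete Fourier transform scaled so that a unit-amplitude sinusoid at
#' an on-grid frequency yields peak amplitude 1 (non-DC, non-Nyquist bins
#' doubled).
#'
#' @param x signal samples.
#' @param sample_rate Hz.
#' @return list with `frequency` (Hz) and `amplitude`.
#' @export
amplitude_spectrum <- function(x, sample_rate) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  sp <- Mod(fft(x)) / n
  half <- seq_len(floor(n / 2) + 1)
  amp <- sp[half]
  dbl <- 2:(length(half) - if (n %% 2 == 0) 1 else 0)
  amp[dbl] <- 2 * amp[dbl]
  list(frequency = (half - 1) * sample_rate / n, amplitude = amp)
}

#' Linearly constrained minimum-variance (virtual sensor) time course
#'
#' A unit-gain spatial filter `w = C^-1 l / (l' C^-1 l)` at the lead-field
#' column of the mesh vertex nearest `target_position`, applied per trial.
#' The data covariance is pooled over trials; if ill-conditioned it is
#' regularized by diagonal loading (factor reported via attribute
#' `loading`).  Experimental: provided for comparison only.
#'
#' @param trials `trial_set`.
#' @param L fixed-normal `leadfield`.
#' @param target_position 3-vector, mm.
#' @param mesh `cortical_mesh`.
#' @param loading relative diagonal loading (default 1e-9, raised
#'   automatically until the covariance is invertible).
#' @return trials x samples matrix of virtual-sensor time courses, with
#'   attributes `weights` and `loading`.
#' @export
virtual_sensor_timecourse <- function(trials, L, target_position, mesh,
                                      loading = 1e-9) {
  v <- nearest_vertex(target_position, mesh)
  l <- L$matrix[, v]
  dims <- dim(trials$sensor_data)
  C <- matrix(0, dims[2], dims[2])
  for (i in seq_len(dims[1]))
    C <- C + tcrossprod(matrix(trials$sensor_data[i, , ], dims[2], dims[3]))
  C <- C / (dims[1] * dims[3])
  mu <- loading * sum(diag(C)) / dims[2]
  repeat {
    ok <- tryCatch({ ch <- chol(C + diag(mu, dims[2])); TRUE },
                   error = function(e) FALSE)
    if (ok && kappa(ch) < 1e12) break
    mu <- max(mu * 100, 1e-12 * sum(diag(C)) / dims[2])
    if (mu > sum(diag(C))) stop("data covariance irrecoverably singular")
  }
  Ci_l <- backsolve(ch, backsolve(ch, l, transpose = TRUE))
  w <- Ci_l / sum(l * Ci_l)
  out <- matrix(0, dims[1], dims[3])
  for (i in seq_len(dims[1]))
    out[i, ] <- crossprod(w, matrix(trials$sensor_data[i, , ], dims[2], dims[3]))
  attr(out, "weights") <- w
  attr(out, "loading") <- mu
  out
}

#' Assemble the study report tables
#'
#' Takes a nested list of per-cell metric lists (as produced by
#' [run_study()]) indexed `results[[noise_level]][[variant]]` and emits the
#' three study tables: localization error + AUC, time-domain RMSE, and
#' frequency-domain RMSE.  Missing cells become NA.
#'
#' @param results nested list; each cell a list with elements
#'   `localization` (data.frame), `auc`, `rmse_time`, `rmse_freq`
#'   (data.frames with columns source, averaged, per_trial).
#' @return list of data.frames `table_localization`, `table_rmse_time`,
#'   `table_rmse_freq`.
#' @export
build_report <- function(results) {
  noise_levels <- names(results)
  variants <- unique(unlist(lapply(results, names)))
  loc_rows <- list(); t2 <- list(); t3 <- list()
  for (nl in noise_levels) {
    for (src in 1:2) {
      for (meas in c("peak", "cmass")) {
        row <- list(noise = nl, source = paste0("X", src), measure = meas)
        for (v in variants) {
          cell <- results[[nl]][[v]]
          row[[v]] <- if (is.null(cell)) NA_real_ else {
            lr <- cell$localization
            if (meas == "peak") lr$peak_error_mm[src] else lr$cmass_error_mm[src]
          }
        }
        loc_rows[[length(loc_rows) + 1]] <- as.data.frame(row)
      }
    }
    row <- list(noise = nl, source = "", measure = "AUC")
    for (v in variants) {
      cell <- results[[nl]][[v]]
      row[[v]] <- if (is.null(cell)) NA_real_ else cell$auc
    }
    loc_rows[[length(loc_rows) + 1]] <- as.data.frame(row)

    for (src in 1:2) for (avg in c("averaged", "per_trial")) {
      for (tab in c("rmse_time", "rmse_freq")) {
        row <- list(noise = nl, source = paste0("X", src),
                    measure = if (avg == "averaged") "average of trials" else "per trial")
        for (v in variants) {
          cell <- results[[nl]][[v]]
          row[[v]] <- if (is.null(cell) || is.null(cell[[tab]])) NA_real_ else {
            df <- cell[[tab]]
            df[df$source == src, avg][1]
          }
        }
        if (tab == "rmse_time") t2[[length(t2) + 1]] <- as.data.frame(row)
        else t3[[length(t3) + 1]] <- as.data.frame(row)
      }
    }
  }
  list(table_localization = do.call(rbind, loc_rows),
       table_rmse_time = unique(do.call(rbind, t2)),
       table_rmse_freq = unique(do.call(rbind, t3)))
}
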