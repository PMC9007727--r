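# fMRI statistical volumes -> source-space covariance components.
#
# Pipeline: threshold the SPM{T}-like volume into face-connected clusters,
# binarize (Heaviside), project each cluster onto the cortical mesh by
# Voronoi assignment (each suprathreshold voxel goes to its nearest vertex),
# smooth the vertex indicator with the mesh Green's function
# G = exp(sigma A) truncated at order 8, and form rank-one covariance
# components Q_i = q_i q_i'.

#' 3D statistical volume
#'
#' @param values 3D numeric array of T statistics.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm (NIfTI
#'   convention).
#' @return object of class `stat_volume`.
#' @export
stat_volume <- function(values, affine) {
  values <- as.array(values)
  affine <- as.matrix(affine)
  stopifnot(length(dim(values)) == 3, all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (!all(is.finite(values))) stop("stat volume must be finite")
  structure(list(values = values, affine = affine), class = "stat_volume")
}

#' Voxel indices (1-based, n x 3) to mm coordinates
#' @export
#' @keywords internal
voxel_to_mm <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3)
  h <- cbind(idx - 1, 1)          # affine acts on 0-based indices
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

#' Threshold a statistical volume into clusters
#'
#' Connected components (6-connectivity, i.e. face-adjacent voxels) of the
#' suprathreshold set `values > height_T`, kept if their size reaches
#' `extent_k`, sorted by descending peak value.
#'
#' @param vol `stat_volume`.
#' @param height_T height threshold (strict).
#' @param extent_k minimum cluster extent in voxels (>= 1).
#' @return list of clusters, each a list with `voxel_indices` (n x 3,
#'   1-based), `size`, `peak_value`.
#' @export
threshold_statmap <- function(vol, height_T, extent_k = 1L) {
  stopifnot(inherits(vol, "stat_volume"), is.finite(height_T), extent_k >= 1)
  dm <- dim(vol$values)
  supra <- which(vol$values > height_T)
  if (length(supra) == 0) return(list())

  lab <- integer(length(supra))
  names(lab) <- NULL
  pos <- arrayInd(supra, dm)
  key <- supra                                  # linear index
  lut <- new.env(hash = TRUE, size = length(supra))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lut)
  strides <- c(1L, dm[1], dm[1] * dm[2])

  comp <- 0L
  for (s in seq_along(key)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- pos[cur, ]
      for (ax in 1:3) for (dlt in c(-1L, 1L)) {
        pj <- p[ax] + dlt
        if (pj < 1L || pj > dm[ax]) next
        nk <- key[cur] + dlt * strides[ax]
        j <- lut[[as.character(nk)]]
        if (!is.null(j) && lab[j] == 0L) {
          lab[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }

  clusters <- lapply(seq_len(comp), function(cc) {
    sel <- lab == cc
    list(voxel_indices = pos[sel, , drop = FALSE],
         size = sum(sel),
         peak_value = max(vol$values[key[sel]]))
  })
  clusters <- Filter(function(cl) cl$size >= extent_k, clusters)
  clusters[order(vapply(clusters, `[[`, 0, "peak_value"), decreasing = TRUE)]
}

#' Voronoi projection of a cluster onto the cortical mesh
#'
#' The cluster is binarized (Heaviside); each of its voxels, taken at its mm
#' centre via the volume affine, is assigned to the nearest mesh vertex.
#' The result is a binary vertex indicator: weight 1 on every vertex owning
#' at least one cluster voxel.  Voxels farther than `max_distance_mm` from
#' the mesh are discarded; if none remain, a warning is raised and an
#' all-zero indicator returned.
#'
#' @param cluster one element of [threshold_statmap()]'s output.
#' @param vol the parent `stat_volume` (for the affine).
#' @param mesh `cortical_mesh`.
#' @param max_distance_mm discard radius (default 20).
#' @return object of class `vertex_indicator`: list with `weights`
#'   (per-vertex, >= 0) and `source_cluster`.
#' @export
voronoi_project <- function(cluster, vol, mesh, max_distance_mm = 20) {
  stopifnot(nrow(cluster$voxel_indices) >= 1)
  mm <- voxel_to_mm(cluster$voxel_indices, vol$affine)
  V <- mesh$vertices
  # nearest vertex per voxel (brute force; cluster sizes are small)
  nn <- integer(nrow(mm)); nd <- numeric(nrow(mm))
  for (i in seq_len(nrow(mm))) {
    d2 <- rowSums(sweep(V, 2, mm[i, ])^2)
    nn[i] <- which.min(d2)
    nd[i] <- sqrt(d2[nn[i]])
  }
  keep <- nd <= max_distance_mm
  w <- numeric(mesh$n_vertices)
  if (!any(keep)) {
    warning("cluster lies entirely farther than ", max_distance_mm,
            " mm from the mesh; returning empty indicator")
  } else {
    w[unique(nn[keep])] <- 1
  }
  structure(list(weights = w, source_cluster = cluster), class = "vertex_indicator")
}

#' Smoothing specification for the mesh Green's function
#'
#' `G = exp(sigma * A)` approximated by its Taylor series truncated at
#' `truncation_order` (default 8), with `A` the 0/1 vertex adjacency matrix.
#'
#' @param adjacency symmetric sparse 0/1 matrix with empty diagonal.
#' @param sigma smoothing parameter (>= 0; default 0.6).
#' @param truncation_order series upper index (>= 0; default 8).
#' @export
smoothing_spec <- function(adjacency, sigma = 0.6, truncation_order = 8L) {
  stopifnot(sigma >= 0, truncation_order >= 0)
  if (!Matrix::isSymmetric(adjacency)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  structure(list(adjacency = adjacency, sigma = sigma,
                 truncation_order = as.integer(truncation_order)),
            class = "smoothing_spec")
}

# G %*% X for a matrix of column indicators, by Horner-free series
# accumulation: sum_{i=0..K} sigma^i/i! A^i X.
green_apply <- function(spec, X) {
  X <- Matrix::Matrix(X, sparse = TRUE)
  acc <- X
  term <- X
  if (spec$sigma > 0) {
    for (i in seq_len(spec$truncation_order)) {
      term <- (spec$sigma / i) * (spec$adjacency %*% term)
      acc <- acc + term
    }
  }
  acc
}

#' Green's-function smoothing of a vertex indicator
#'
#' @param q `vertex_indicator` (or bare numeric weight vector).
#' @param spec `smoothing_spec`; its adjacency must match the vertex count.
#' @return `vertex_indicator` with smoothed nonnegative weights.
#' @export
green_smooth <- function(q, spec) {
  w <- if (inherits(q, "vertex_indicator")) q$weights else as.numeric(q)
  if (length(w) != nrow(spec$adjacency))
    stop("indicator length does not match adjacency dimension")
  out <- as.numeric(green_apply(spec, Matrix::Matrix(w, ncol = 1, sparse = TRUE)))
  out[out < 0] <- 0   # guard against roundoff; the series itself is nonnegative
  structure(list(weights = out,
                 source_cluster = if (inherits(q, "vertex_indicator")) q$source_cluster else NULL),
            class = "vertex_indicator")
}

#' Rank-one covariance component from a vertex indicator
#'
#' `Q = q q'`.  With `normalize = TRUE` (default) `q` is scaled to unit
#' Euclidean norm first, so ReML hyperparameters are comparable across
#' components.
#'
#' @param q `vertex_indicator` or numeric vector with at least one positive
#'   weight.
#' @param normalize scale `q` to unit norm.
#' @param level "source" or "sensor".
#' @param label optional component label.
#' @return object of class `cov_component` (form "rank1").
#' @export
make_covariance_component <- function(q, normalize = TRUE, level = "source",
                                      label = NULL) {
  w <- if (inherits(q, "vertex_indicator")) q$weights else as.numeric(q)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("all-zero indicator cannot form a covariance component")
  if (normalize) w <- w / nrm
  structure(list(form = "rank1", vector = w, level = level,
                 label = if (is.null(label)) "rank1" else label),
            class = "cov_component")
}

#' Identity (white-noise) covariance component
#'
#' @param n dimension.
#' @param level "sensor" (default) or "source".
#' @param label component label.
#' @export
identity_component <- function(n, level = "sensor", label = "noise") {
  structure(list(form = "identity", n = as.integer(n), level = level,
                 label = label),
            class = "cov_component")
}

#' Dense matrix of a covariance component
#' @param comp `cov_component`.
#' @export
component_matrix <- function(comp) {
  switch(comp$form,
         rank1 = tcrossprod(comp$vector),
         identity = diag(comp$n),
         full = comp$matrix,
         stop("unknown component form"))
}

#' Full (dense) covariance component
#' @param M symmetric positive semidefinite matrix.
#' @inheritParams make_covariance_component
#' @export
full_component <- function(M, level = "sensor", label = "full") {
  M <- as.matrix(M)
  stopifnot(isSymmetric(M, tol = 1e-8))
  structure(list(form = "full", matrix = M, level = level, label = label),
            class = "cov_component")
}

#' Build the full fMRI prior component set from a volume
#'
#' Composition of [threshold_statmap()], [voronoi_project()],
#' [green_smooth()] and [make_covariance_component()], one rank-one
#' component per suprathreshold cluster, preserving cluster order (by
#' descending peak value).  Clusters that project to an empty indicator are
#' dropped with a warning.
#'
#' @inheritParams threshold_statmap
#' @param mesh `cortical_mesh`.
#' @param spec `smoothing_spec` built on the mesh adjacency.
#' @param max_distance_mm see [voronoi_project()].
#' @return list of `cov_component`s.
#' @export
build_prior_set <- function(vol, mesh, height_T, extent_k, spec,
                            max_distance_mm = 20) {
  clusters <- threshold_statmap(vol, height_T, extent_k)
  comps <- list()
  for (i in seq_along(clusters)) {
    ind <- voronoi_project(clusters[[i]], vol, mesh, max_distance_mm)
    if (all(ind$weights == 0)) next
    sm <- green_smooth(ind, spec)
    comps[[length(comps) + 1L]] <-
      make_covariance_component(sm, normalize = TRUE, level = "source",
                                label = sprintf("fmri_cluster_%d", i))
  }
  comps
}
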