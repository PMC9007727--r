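test_that("source maps normalize to [0,1] with a scale-invariant argmax", {
  X <- matrix(0, 6, 10)
  X[4, 3] <- 2.5
  m <- normalize_source_map(X)
  expect_equal(as.numeric(m), c(0, 0, 0, 1, 0, 0))

  set.seed(2)
  X2 <- matrix(rnorm(60), 6, 10)
  m2 <- normalize_source_map(X2)
  expect_equal(as.numeric(normalize_source_map(3.7 * X2)), as.numeric(m2))
  expect_equal(which.max(m2), which.max(apply(X2^2, 1, max)))
  expect_true(all(m2 >= 0 & m2 <= 1))

  m0 <- normalize_source_map(matrix(0, 4, 5))
  expect_true(attr(m0, "null"))
})

test_that("localization errors match hand-computed peaks and centroids", {
  mesh <- small_geometry()$mesh
  v <- 57
  truth <- mesh$vertices[v, , drop = FALSE]
  scores <- numeric(mesh$n_vertices)
  scores[v] <- 1
  m <- structure(scores, null = FALSE, class = "source_map")
  le <- localization_errors(m, truth, mesh)
  expect_equal(le$peak_error_mm, 0)
  expect_equal(le$cmass_error_mm, 0)

  # symmetric two-vertex cluster straddling the truth midpoint
  nb <- which(mesh$adjacency[v, ] != 0)
  u <- nb[1]
  mid <- (mesh$vertices[v, ] + mesh$vertices[u, ]) / 2
  scores2 <- numeric(mesh$n_vertices)
  scores2[c(v, u)] <- 1
  m2 <- structure(scores2, null = FALSE, class = "source_map")
  le2 <- localization_errors(m2, matrix(mid, 1), mesh)
  expect_lt(le2$cmass_error_mm, le2$peak_error_mm + 1e-9)
  expect_equal(le2$cmass_error_mm, 0, tolerance = 1e-9)

  # centroid equals the brute-force weighted sum over the cluster
  set.seed(6)
  scores3 <- numeric(mesh$n_vertices)
  reach <- c(v, nb)
  scores3[reach] <- runif(length(reach), 0.6, 1)
  scores3 <- scores3 / max(scores3)
  m3 <- structure(scores3, null = FALSE, class = "source_map")
  le3 <- localization_errors(m3, truth, mesh, cluster_threshold = 0.5)
  cl <- which(scores3 >= 0.5)
  cm <- colSums(mesh$vertices[cl, ] * scores3[cl]) / sum(scores3[cl])
  expect_equal(le3$cmass_error_mm, sqrt(sum((cm - truth)^2)),
               tolerance = 1e-9)

  expect_error(localization_errors(normalize_source_map(matrix(0, 4, 2)),
                                   truth, mesh), "null")
})

test_that("ROC/AUC follows Eq-style threshold sweeps and the rank oracle", {
  set.seed(8)
  labels <- rep(FALSE, 400)
  labels[sample(400, 25)] <- TRUE

  perfect <- as.numeric(labels)
  roc <- roc_auc(perfect, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$curve$sensitivity[1], 1)       # beta = 0: everything active
  expect_equal(roc$curve$specificity[roc$curve$beta > 0.999 +
                                       .Machine$double.eps][1], 1,
               tolerance = 1e-12)

  scores <- runif(400)
  r <- roc_auc(scores, labels)
  expect_lt(abs(r$auc - 0.5), 0.15)               # independent scores

  # Mann-Whitney rank statistic oracle at dense thresholds
  auc_rank <- mean(outer(scores[labels], scores[!labels], ">")) +
    0.5 * mean(outer(scores[labels], scores[!labels], "=="))
  expect_lt(abs(r$auc - auc_rank), 1 / 101 + 1e-9)

  # antisymmetry under score inversion
  r_inv <- roc_auc(1 - scores, labels)
  expect_equal(r_inv$auc, 1 - r$auc, tolerance = 1 / 101 + 1e-9)

  # cross-check against an established implementation when available
  if (requireNamespace("pROC", quietly = TRUE)) {
    auc_ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
    expect_lt(abs(r$auc - auc_ref), 1 / 101 + 1e-9)
  }

  expect_error(roc_auc(scores, rep(TRUE, 400)), "classes")
})

test_that("VOI eigenvariates equal the dense SVD oracle and resist noise", {
  mesh <- small_geometry()$mesh
  center <- mesh$vertices[30, ]
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, center)^2))
  radius <- 18                      # coarse test mesh: widen the VOI
  sel <- which(d <= radius)
  expect_gt(length(sel), 2)

  ct <- sin(seq(0, 2 * pi, length.out = 40))
  X <- matrix(0, mesh$n_vertices, 40)
  X[sel, ] <- matrix(rep(ct, each = length(sel)), length(sel))
  e <- extract_voi_timecourse(X, center, mesh, radius_mm = radius)
  expect_gt(abs(cor(as.numeric(e), ct)), 1 - 1e-10)   # rank-1 stack

  set.seed(4)
  X[sel, ] <- outer(runif(length(sel), 0.5, 2), ct)
  e2 <- extract_voi_timecourse(X, center, mesh, radius_mm = radius)
  sv <- svd(X[sel, , drop = FALSE])
  oracle <- sv$d[1] * sv$v[, 1]
  if (sum(oracle * colMeans(X[sel, , drop = FALSE])) < 0) oracle <- -oracle
  expect_equal(as.numeric(e2), oracle, tolerance = 1e-10)

  # orthogonal contamination on a subset of the VOI (weaker than the
  # coherent mode): the eigenvariate tracks the signal better than the mean
  half <- sel[seq_len(max(1, floor(length(sel) / 3)))]
  noise <- cos(seq(0, 24 * pi, length.out = 40)) * 0.8
  Xn <- X
  Xn[half, ] <- matrix(rep(noise, each = length(half)), length(half))
  e3 <- extract_voi_timecourse(Xn, center, mesh, radius_mm = radius)
  mean_tc <- colMeans(Xn[sel, , drop = FALSE])
  expect_gt(abs(cor(as.numeric(e3), ct)), abs(cor(mean_tc, ct)))

  expect_error(extract_voi_timecourse(X, c(500, 500, 500), mesh), "VOI")
})

test_that("rmse matches its closed forms and brute-force evaluation", {
  x <- sin(1:50)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(rep(0.3, 20), numeric(20), normalize = FALSE), 0.3)
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(rmse(a, b, normalize = FALSE), sqrt(mean((a - b)^2)))
  an <- a / max(abs(a)); bn <- b / max(abs(b))
  expect_equal(rmse(a, b), sqrt(mean((an - bn)^2)))
  expect_error(rmse(a, b[1:10]), "length")
})

test_that("amplitude spectra are single-sided, unit-calibrated, Parseval-consistent", {
  fs <- 600
  t_axis <- seq(0, 0.3 - 1 / fs, by = 1 / fs)     # whole periods of 10 Hz
  x <- sin(2 * pi * 10 * t_axis)
  sp <- amplitude_spectrum(x, fs)
  expect_equal(sp$amplitude[sp$frequency == 10], 1, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[sp$frequency != 10]), 1e-9)

  z <- amplitude_spectrum(numeric(32), fs)
  expect_true(all(z$amplitude == 0))

  set.seed(6)
  y <- rnorm(128)
  spy <- amplitude_spectrum(y, fs)
  # Parseval: mean power equals DC^2 + Nyquist^2 + sum(amp^2)/2 over bins
  amp <- spy$amplitude
  nb <- length(amp)
  pwr <- amp[1]^2 + amp[nb]^2 + sum((amp[2:(nb - 1)] / 2)^2 * 2)
  expect_equal(pwr, mean(y^2), tolerance = 1e-10)

  expect_error(amplitude_spectrum(1, fs), "2 samples")
})

test_that("virtual sensor filters satisfy unit gain and recover clean sources", {
  g <- small_geometry()
  L <- small_leadfield()
  cfg <- sim_config(n_trials = 10, snr_db = Inf, seed = 44,
                    dipole_positions = rbind(c(-38, 43, 5), c(-54, -13, 5)))
  tr <- simulate_trials(cfg, g, L)
  target <- cfg$dipole_positions[1, ]
  vs <- virtual_sensor_timecourse(tr, L, target, g$mesh)
  w <- attr(vs, "weights")
  l <- L$matrix[, nearest_vertex(target, g$mesh)]
  expect_lt(abs(sum(w * l) - 1), 1e-10)           # unit-gain constraint
  expect_gt(abs(cor(vs[1, ], tr$source_truth[1, 1, ])), 0.99)
  # linear in the sensor data
  tr2 <- tr; tr2$sensor_data <- 2 * tr$sensor_data
  vs2 <- virtual_sensor_timecourse(tr2, L, target, g$mesh)
  expect_equal(vs2, 2 * vs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("report tables cover the full variant-by-noise grid", {
  cellgen <- function(auc) list(
    localization = data.frame(peak_error_mm = c(1, 2),
                              cmass_error_mm = c(0.5, 1.5)),
    auc = auc,
    rmse_time = data.frame(source = 1:2, averaged = c(0.1, 0.2),
                           per_trial = c(0.2, 0.4)),
    rmse_freq = data.frame(source = 1:2, averaged = c(0.01, 0.02),
                           per_trial = c(0.02, 0.04)))
  res <- list()
  k <- 0
  for (nl in c("noiseless", "+10dB", "-10dB")) {
    res[[nl]] <- list()
    for (v in c("none", "all", "valid", "invalid")) {
      k <- k + 1
      res[[nl]][[v]] <- cellgen(0.5 + k / 100)
    }
  }
  rep1 <- build_report(res)
  auc_rows <- rep1$table_localization[rep1$table_localization$measure == "AUC", ]
  expect_equal(nrow(auc_rows) * 4, 12)            # 4 variants x 3 levels
  expect_false(anyNA(auc_rows[, c("none", "all", "valid", "invalid")]))

  # missing cells surface as NA without aborting
  res$`+10dB`$valid <- NULL
  rep2 <- build_report(res)
  expect_true(anyNA(rep2$table_localization$valid))

  # regeneration from the same inputs is identical
  expect_identical(rep2, build_report(res))
})
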