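# The free energy has an exact closed form for linear-Gaussian models,
# which gives the inversion a strict oracle: at any hyperparameter setting
# it must equal the Gaussian log marginal likelihood of the data.

test_that("free energy equals the closed-form Gaussian marginal likelihood", {
  tm <- toy_model(p = 5, V = 3, seed = 21)
  set.seed(22)
  B <- matrix(rnorm(5 * 9), 5, 9)
  h <- c(log(0.7), log(2.2), log(0.4), log(1.1))
  F1 <- free_energy(B, tm$L, tm$comps, h)

  # oracle 1: dense density with covariance assembled independently
  Lm <- tm$L$matrix
  Sig <- exp(h[1]) * diag(5)
  for (k in 2:4) {
    q <- numeric(3); q[k - 1] <- 1
    Sig <- Sig + exp(h[k]) * (Lm %*% tcrossprod(q) %*% t(Lm))
  }
  expect_equal(F1, dmvnorm_log(B, Sig), tolerance = 1e-10)

  # oracle 2: source-space parameterization via the Weinstein identity
  # logdet(Ce + L G L') = logdet Ce + logdet G + logdet(G^-1 + L' Ce^-1 L)
  G <- diag(exp(h[2:4]))
  Ce <- exp(h[1]) * diag(5)
  logdet <- determinant(Ce)$modulus + determinant(G)$modulus +
    determinant(solve(G) + t(Lm) %*% solve(Ce) %*% Lm)$modulus
  Si <- solve(Ce) - solve(Ce) %*% Lm %*%
    solve(solve(G) + t(Lm) %*% solve(Ce) %*% Lm) %*% t(Lm) %*% solve(Ce)
  F2 <- sum(apply(B, 2, function(b)
    -0.5 * (5 * log(2 * pi) + logdet + sum(b * (Si %*% b)))))
  expect_equal(F1, as.numeric(F2), tolerance = 1e-10)

  # zero data: only the log-normalizer survives
  F0 <- free_energy(matrix(0, 5, 4), tm$L, tm$comps, h)
  expect_equal(F0, -0.5 * 4 * (5 * log(2 * pi) +
                                 determinant(Sig)$modulus[1]),
               tolerance = 1e-10)
})

test_that("free energy matches brute-force marginalization on a tiny model", {
  # 2 sensors, 1 source: integrate P(B|x) P(x) dx numerically per sample
  set.seed(30)
  L1 <- structure(list(matrix = matrix(c(1.3, -0.4), 2, 1),
                       moment_convention = "fixed"), class = "leadfield")
  comps <- component_set(list(identity_component(2)),
                         list(make_covariance_component(1)))
  h <- c(log(0.5), log(1.7))
  B <- matrix(rnorm(2 * 3), 2, 3)
  Fpkg <- free_energy(B, L1, comps, h)
  ce <- 0.5; gv <- 1.7
  l <- c(1.3, -0.4)
  Fnum <- sum(apply(B, 2, function(b) {
    f <- function(x) {
      vapply(x, function(xi)
        exp(-sum((b - l * xi)^2) / (2 * ce)) / (2 * pi * ce) *
          exp(-xi^2 / (2 * gv)) / sqrt(2 * pi * gv), 0)
    }
    log(stats::integrate(f, -40, 40, rel.tol = 1e-12)$value)
  }))
  expect_equal(Fpkg, Fnum, tolerance = 1e-8)
})

test_that("oracle equivalence holds across random small instances", {
  set.seed(40)
  for (rep in 1:8) {
    p <- sample(2:5, 1); V <- sample(2:6, 1)
    tm <- toy_model(p, V, seed = 100 + rep)
    B <- matrix(rnorm(p * 6), p, 6)
    h <- rnorm(V + 1, 0, 1)
    Lm <- tm$L$matrix
    Sig <- exp(h[1]) * diag(p)
    for (k in seq_len(V)) Sig <- Sig + exp(h[k + 1]) * tcrossprod(Lm[, k])
    expect_equal(free_energy(B, tm$L, tm$comps, h), dmvnorm_log(B, Sig),
                 tolerance = 1e-8)
  }
})

test_that("ReML reproduces noiseless data generated within the model class", {
  tm <- toy_model(p = 20, V = 15, seed = 7)
  x <- sin(seq(0, 6 * pi, length.out = 50))
  B <- outer(tm$L$matrix[, 5], x)
  fit <- invert(B, tm$L, tm$comps,
                reml_options(tolerance = 1e-8, max_iter = 256))
  resid <- sqrt(sum((tm$L$matrix %*% fit$posterior_mean - B)^2) / sum(B^2))
  expect_lt(resid, 0.01)
  wsrc <- fit$effective_weights[fit$levels == "source"]
  expect_equal(which.max(wsrc), 5)   # the generating component dominates
  expect_monotone_trajectory(fit)
})

test_that("ReML on zero data returns a zero posterior", {
  tm <- toy_model(p = 8, V = 5, seed = 8)
  fit <- invert(matrix(0, 8, 10), tm$L, tm$comps)
  expect_equal(max(abs(fit$posterior_mean)), 0)
})

test_that("ReML recovers known covariance mixture weights", {
  # Sigma = 2 Q1 + 0.5 I with long time series; weights within 20%
  p <- 8
  set.seed(77)
  u <- rnorm(p); u <- u / sqrt(sum(u^2))
  L <- structure(list(matrix = diag(p), moment_convention = "fixed"),
                 class = "leadfield")
  comps <- component_set(list(identity_component(p)),
                         list(make_covariance_component(u)))
  ch <- chol(2 * tcrossprod(u) + 0.5 * diag(p))
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    B <- t(ch) %*% matrix(rnorm(p * 5000), p, 5000)
    fit <- reml_optimize(B, L, comps)
    w <- fit$effective_weights            # (noise, source)
    if (all(abs(w - c(0.5, 2)) / c(0.5, 2) < 0.2)) ok <- ok + 1
    expect_monotone_trajectory(fit)
  }
  expect_gte(ok, 9)
})

test_that("posterior is linear in the data at fixed hyperparameters", {
  tm <- toy_model(p = 10, V = 6, seed = 9)
  set.seed(10)
  B <- matrix(rnorm(10 * 20), 10, 20)
  fit <- invert(B, tm$L, tm$comps)
  B1 <- matrix(rnorm(10 * 5), 10, 5)
  B2 <- matrix(rnorm(10 * 5), 10, 5)
  expect_equal(posterior_timecourse(fit, B1 + B2),
               posterior_timecourse(fit, B1) + posterior_timecourse(fit, B2),
               tolerance = 1e-10)
})

test_that("a single trial inverts identically through both data paths", {
  g <- small_geometry()
  L <- small_leadfield()
  cfg <- sim_config(n_trials = 1, snr_db = 10, seed = 5)
  tr <- simulate_trials(cfg, g, L)
  spec <- smoothing_spec(g$mesh$adjacency)
  msp <- build_msp_library(g$mesh, 48, spec, seed = 3)
  comps <- component_set(list(identity_component(60)), msp)
  f_avg <- invert(matrix(tr$sensor_data[1, , ], 60), L, comps, mode = "evoked")
  f_tr <- invert(tr, L, comps, mode = "evoked")
  expect_equal(f_tr$posterior_mean, f_avg$posterior_mean, tolerance = 1e-10)
})

test_that("an invalid (support-disjoint) prior is effectively discarded", {
  tm <- toy_model(p = 20, V = 15, seed = 55)
  x <- cos(seq(0, 4 * pi, length.out = 60))
  B <- outer(tm$L$matrix[, 3], x)
  fit0 <- invert(B, tm$L, tm$comps,
                 reml_options(tolerance = 1e-8, max_iter = 256))
  # add one component with support far from the generator
  bad <- numeric(15); bad[12:14] <- 1
  comps2 <- component_set(tm$comps$sensor,
                          c(tm$comps$source,
                            list(make_covariance_component(bad, label = "bad"))))
  fit1 <- invert(B, tm$L, comps2,
                 reml_options(tolerance = 1e-8, max_iter = 256))
  rel <- sqrt(sum((fit1$posterior_mean - fit0$posterior_mean)^2) /
                sum(fit0$posterior_mean^2))
  expect_lt(rel, 0.10)
  wbad <- fit1$effective_weights[fit1$labels == "bad"]
  wgen <- fit1$effective_weights[fit1$labels == "v03"]
  expect_lt(wbad, 1e-3 * wgen)
})

test_that("model comparison ranks by free energy with sensible invariances", {
  tm <- toy_model(p = 10, V = 6, seed = 61)
  set.seed(62)
  B <- matrix(rnorm(10 * 30), 10, 30)
  f1 <- invert(B, tm$L, tm$comps)
  rk <- compare_models(list(a = f1, b = f1))
  expect_equal(rk$delta_F, c(0, 0))

  f2 <- invert(B, tm$L, tm$comps)          # identical model, rerun
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-8)

  expect_error(compare_models(list(f1, invert(B[, 1:10], tm$L, tm$comps))),
               "identical")

  # the model containing the generative component outranks a mismatched one
  wins <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    x <- rnorm(40)
    Bs <- outer(tm$L$matrix[, 2], x) + 0.1 * matrix(rnorm(10 * 40), 10, 40)
    good <- component_set(tm$comps$sensor, tm$comps$source[2])
    badq <- numeric(6); badq[5] <- 1
    badc <- component_set(tm$comps$sensor,
                          list(make_covariance_component(badq)))
    Fg <- invert(Bs, tm$L, good)$free_energy
    Fb <- invert(Bs, tm$L, badc)$free_energy
    if (Fg > Fb) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("the MSP library is deterministic with hop-bounded patches", {
  g <- small_geometry()
  spec <- smoothing_spec(g$mesh$adjacency, 0.6, 8)
  m1 <- build_msp_library(g$mesh, 40, spec, seed = 4)
  m2 <- build_msp_library(g$mesh, 40, spec, seed = 4)
  expect_equal(vapply(m1, function(c) c$vector, numeric(g$mesh$n_vertices)),
               vapply(m2, function(c) c$vector, numeric(g$mesh$n_vertices)))
  expect_length(m1, 40)

  # sigma = 0 with every vertex seeded: the identity dictionary
  sp0 <- smoothing_spec(g$mesh$adjacency, 0)
  mall <- build_msp_library(g$mesh, g$mesh$n_vertices, sp0, seed = 1)
  V <- vapply(mall, function(c) c$vector, numeric(g$mesh$n_vertices))
  expect_equal(unname(V), diag(g$mesh$n_vertices))

  # support within truncation_order graph hops of the seed
  A <- g$mesh$adjacency
  hops <- Matrix::Diagonal(nrow(A))
  reach <- hops
  for (i in 1:8) { hops <- A %*% hops; reach <- reach + hops }
  for (k in c(1, 10, 25)) {
    seedv <- as.integer(sub("msp_", "", m1[[k]]$label))
    expect_true(all(which(m1[[k]]$vector > 0) %in% which(reach[, seedv] != 0)))
  }

  expect_error(build_msp_library(g$mesh, g$mesh$n_vertices + 1, spec),
               "n_patches")
})
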