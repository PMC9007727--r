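# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small geometry for unit tests (fast): ~300 vertices, 60 sensors
small_geometry <- function() {
  cached("small_geom", fixture_geometry(n_vertices = 300, seed = 42,
                                        n_sensors = 60))
}

small_leadfield <- function() {
  cached("small_L", {
    g <- small_geometry()
    build_leadfield(g$mesh, g$sensors, g$sphere)
  })
}

# random dense toy model: p sensors, V sources, identity noise + unit comps
toy_model <- function(p, V, seed = 1) {
  set.seed(seed)
  L <- structure(list(matrix = matrix(rnorm(p * V), p, V),
                      source_positions = matrix(rnorm(V * 3), V, 3),
                      moment_convention = "fixed"),
                 class = "leadfield")
  comps <- component_set(
    list(identity_component(p)),
    lapply(seq_len(V), function(v) {
      e <- numeric(V); e[v] <- 1
      make_covariance_component(e, label = sprintf("v%02d", v))
    }))
  list(L = L, comps = comps)
}

# dense multivariate normal log density at zero mean (independent oracle)
dmvnorm_log <- function(B, Sigma) {
  p <- nrow(B)
  ev <- eigen(Sigma, symmetric = TRUE)
  stopifnot(all(ev$values > 0))
  logdet <- sum(log(ev$values))
  Si <- ev$vectors %*% (t(ev$vectors) / ev$values)
  sum(apply(B, 2, function(b)
    -0.5 * (p * log(2 * pi) + logdet + sum(b * (Si %*% b)))))
}

# trajectory monotonicity with relative slack
expect_monotone_trajectory <- function(result) {
  tj <- result$free_energy_trajectory
  expect_true(all(diff(tj) >= -1e-8 * (1 + abs(tj[-length(tj)]))))
}
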