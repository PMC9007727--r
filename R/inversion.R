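# Parametric empirical Bayes source inversion.
#
# Model: B = L X + E, with E ~ N(0, C_e) at the sensor level and
# X ~ N(0, Gamma) at the source level, where
#
#   C_e   = sum_j exp(lambda_j) Q_j   (sensor components; default: identity)
#   Gamma = sum_i exp(lambda_i) Q_i   (source components: MSP patch library
#                                      and/or fMRI rank-one priors)
#
# Hyperparameters lambda are log-scale (nonnegative weights by construction)
# with weak Gaussian hyperpriors, estimated by restricted maximum likelihood:
# Fisher-scoring ascent of the free energy of the model covariance
# Sigma_B = C_e + L Gamma L' against the data's second-order statistics.
# The posterior (MAP = posterior mean) is X_hat = Gamma L' Sigma_B^{-1} B.
#
# Internally the data covariance is rescaled to unit mean sensor variance
# and every component to trace p, so hyperparameters are O(1) and
# comparable; reported effective weights are mapped back to the original
# scale.  lambda is clamped to [log(1e-6), 32]: the lower bound doubles as
# a minimum noise floor, so even noiseless data are inverted against a
# well-conditioned model covariance (pruned components rest there too,
# at 1e-6 relative weight).

#' Component set for inversion
#'
#' @param sensor_components list of `cov_component`s at the sensor level
#'   (at least one; typically [identity_component()]).
#' @param source_components list of `cov_component`s at the source level.
#' @return object of class `component_set`.
#' @export
component_set <- function(sensor_components, source_components) {
  stopifnot(length(sensor_components) >= 1, length(source_components) >= 1)
  for (cp in sensor_components) stopifnot(inherits(cp, "cov_component"))
  for (cp in source_components) stopifnot(inherits(cp, "cov_component"))
  structure(list(sensor = sensor_components, source = source_components),
            class = "component_set")
}

#' Multiple-sparse-priors patch library
#'
#' Selects `n_patches` seed vertices by deterministic stratified sampling
#' over the mesh (evenly spaced through the vertex ordering, with a seeded
#' phase), smooths each seed's unit indicator with the mesh Green's
#' function, and returns unit-norm rank-one components.
#'
#' @param mesh `cortical_mesh`.
#' @param n_patches number of patches (1..n_vertices; default 512).
#' @param spec `smoothing_spec`; default `smoothing_spec(mesh$adjacency)`.
#' @param seed integer seed for the sampling phase.
#' @return list of `cov_component`s.
#' @export
build_msp_library <- function(mesh, n_patches = 512, spec = NULL, seed = 1) {
  n <- mesh$n_vertices
  if (n_patches < 1 || n_patches > n)
    stop("n_patches must be in [1, n_vertices]")
  if (is.null(spec)) spec <- smoothing_spec(mesh$adjacency)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  phase <- runif(1)
  idx <- unique(pmin(n, pmax(1L, round(seq(phase * n / n_patches, n,
                                           length.out = n_patches)))))
  while (length(idx) < n_patches) {       # fill collisions deterministically
    pool <- setdiff(seq_len(n), idx)
    idx <- sort(c(idx, pool[seq_len(n_patches - length(idx))]))
  }
  Ind <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                              dims = c(n, length(idx)))
  Qm <- green_apply(spec, Ind)
  lapply(seq_along(idx), function(k) {
    q <- as.numeric(Qm[, k])
    q[q < 0] <- 0
    make_covariance_component(q, normalize = TRUE, level = "source",
                              label = sprintf("msp_%04d", idx[k]))
  })
}

# ---- internal model assembly ------------------------------------------------

# Flatten a component set against a lead field into sensor-level handles.
# Each handle: list(kind = "rank1"|"identity"|"full", u or M at sensor level
# BEFORE trace normalization, level, label, q (source vector, if any)).
assemble_handles <- function(L, comps) {
  p <- nrow(L$matrix)
  hs <- list()
  for (cp in comps$sensor) {
    h <- switch(cp$form,
                identity = list(kind = "identity"),
                rank1 = list(kind = "rank1", u = cp$vector),
                full = list(kind = "full", M = cp$matrix))
    h$level <- "sensor"; h$label <- cp$label; h$q <- NULL
    hs[[length(hs) + 1L]] <- h
  }
  for (cp in comps$source) {
    h <- switch(cp$form,
                rank1 = list(kind = "rank1", u = as.numeric(L$matrix %*% cp$vector)),
                identity = list(kind = "full", M = tcrossprod(L$matrix)),
                full = list(kind = "full", M = L$matrix %*% cp$matrix %*% t(L$matrix)))
    h$level <- "source"; h$label <- cp$label
    h$q <- if (cp$form == "rank1") cp$vector else NULL
    hs[[length(hs) + 1L]] <- h
  }
  tr <- vapply(hs, function(h) switch(h$kind,
                                      identity = p,
                                      rank1 = sum(h$u^2),
                                      full = sum(diag(h$M))), 0)
  if (any(tr <= 0)) stop("component with nonpositive trace after projection")
  # Sensor components are normalized to trace p individually; source
  # components share ONE scale (their mean projected trace), preserving the
  # relative depth scaling of the lead field — per-component normalization
  # would silently boost deep patches' source amplitudes by 1/|Lq|^2.
  src <- vapply(hs, function(h) h$level == "source", TRUE)
  tbar <- mean(tr[src])
  for (i in seq_along(hs)) {
    h <- hs[[i]]
    fac <- if (src[i]) p / tbar else p / tr[i]
    hs[[i]]$norm_factor <- fac
    if (h$kind == "rank1") hs[[i]]$un <- h$u * sqrt(fac)
    if (h$kind == "full") hs[[i]]$Mn <- h$M * fac
  }
  hs
}

# Sigma_n for normalized handles at hyperparameters lam
assemble_sigma <- function(hs, lam, p) {
  Sig <- matrix(0, p, p)
  e <- exp(lam)
  r1 <- which(vapply(hs, function(h) h$kind == "rank1", TRUE))
  if (length(r1)) {
    U <- vapply(hs[r1], `[[`, numeric(p), "un")
    Sig <- Sig + U %*% (e[r1] * t(U))
  }
  for (k in seq_along(hs)) {
    if (hs[[k]]$kind == "identity") Sig <- Sig + diag(e[k], p)
    if (hs[[k]]$kind == "full") Sig <- Sig + e[k] * hs[[k]]$Mn
  }
  (Sig + t(Sig)) / 2
}

#' ReML optimizer options
#'
#' @param max_iter maximum Fisher-scoring iterations (default 128).
#' @param tolerance absolute free-energy change declaring convergence
#'   (default 1e-4).
#' @param hyperprior_mean,hyperprior_var Gaussian hyperprior on each log
#'   hyperparameter (defaults log(1e-6) and 32 — weak on the normalized
#'   component scale, yet firm enough that redundant components come to
#'   rest at the hyperprior mean, i.e. are pruned).
#' @param lambda_bounds clamp for log hyperparameters (default
#'   `c(log(1e-6), 32)`).  The lower bound doubles as a minimum
#'   relative-variance floor: even nominally noiseless data are inverted
#'   against a 1e-6 noise floor (the hyperprior mean), which keeps the
#'   model covariance well conditioned and the free-energy landscape
#'   smooth; measurement systems never achieve infinite SNR.
#' @param verbose print one line per iteration.
#' @export
reml_options <- function(max_iter = 128L, tolerance = 1e-4,
                         hyperprior_mean = log(1e-6), hyperprior_var = 32,
                         lambda_bounds = c(log(1e-6), 32), verbose = FALSE) {
  list(max_iter = as.integer(max_iter), tolerance = tolerance,
       hyperprior_mean = hyperprior_mean, hyperprior_var = hyperprior_var,
       lambda_bounds = lambda_bounds, verbose = verbose)
}

#' Gaussian log evidence of data under a component model
#'
#' Evaluates the exact log marginal likelihood of `B` (channels x samples)
#' under `Sigma_B = sum_j exp(h_j) Q_j + L (sum_i exp(h_i) Q_i) L'`, i.e.
#' the closed form of `log integral P(B|X) P(X) dX` for the linear-Gaussian
#' model, optionally plus the log density of the Gaussian hyperprior.
#' Components are used on their original (un-normalized) scale here.
#'
#' @param B data matrix (channels x samples) or `data_matrix`.
#' @param L `leadfield`.
#' @param comps `component_set`.
#' @param h numeric vector of log hyperparameters, ordered sensor components
#'   first then source components.
#' @param hyperprior optional list(mean, var) adding the hyperprior term.
#' @return scalar free energy (log evidence).
#' @export
free_energy <- function(B, L, comps, h, hyperprior = NULL) {
  B <- data_values(B)
  p <- nrow(B); n <- ncol(B)
  K <- length(comps$sensor) + length(comps$source)
  stopifnot(length(h) == K)
  Sig <- matrix(0, p, p)
  k <- 0
  for (cp in comps$sensor) {
    k <- k + 1
    Sig <- Sig + exp(h[k]) * component_matrix(cp)
  }
  Lm <- L$matrix
  for (cp in comps$source) {
    k <- k + 1
    if (cp$form == "rank1") {
      a <- as.numeric(Lm %*% cp$vector)
      Sig <- Sig + exp(h[k]) * tcrossprod(a)
    } else {
      Sig <- Sig + exp(h[k]) * (Lm %*% component_matrix(cp) %*% t(Lm))
    }
  }
  ch <- chol((Sig + t(Sig)) / 2)
  logdet <- 2 * sum(log(diag(ch)))
  quad <- sum(backsolve(ch, B, transpose = TRUE)^2)
  F <- -0.5 * (n * p * log(2 * pi) + n * logdet + quad)
  if (!is.null(hyperprior))
    F <- F + sum(-0.5 * log(2 * pi * hyperprior$var) -
                   (h - hyperprior$mean)^2 / (2 * hyperprior$var))
  F
}

data_values <- function(B) {
  if (inherits(B, "data_matrix")) B$values else as.matrix(B)
}

#' Sensor data matrix
#'
#' @param values channels x samples matrix (tesla).
#' @param sample_rate Hz.
#' @param time optional time axis (seconds).
#' @export
data_matrix <- function(values, sample_rate = NULL, time = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("data must be finite")
  structure(list(values = values, sample_rate = sample_rate, time = time),
            class = "data_matrix")
}

#' ReML hyperparameter optimization
#'
#' Fisher-scoring (EM-equivalent) ascent of the free energy over log
#' hyperparameters, with step-halving so the objective trajectory is
#' non-decreasing.  Either `B` (channels x samples) or precomputed
#' second-order statistics (`C` = average outer product, `n_samples`) may
#' be supplied.
#'
#' @param B data matrix (channels x samples), or NULL when `C` is given.
#' @param L `leadfield`.
#' @param comps `component_set`.
#' @param opts [reml_options()].
#' @param C optional channels x channels average data covariance
#'   `sum_t b_t b_t' / n_samples`.
#' @param n_samples number of samples behind `C`.
#' @return object of class `inversion_result`: `hyperparameters`
#'   (log-lambda on the normalized scale), `effective_weights` (original
#'   component scale), `free_energy`, `free_energy_trajectory`,
#'   `n_iterations`, `converged`, `labels`, plus internal fields used by
#'   [invert()].
#' @export
reml_optimize <- function(B = NULL, L, comps, opts = reml_options(),
                          C = NULL, n_samples = NULL) {
  if (is.null(C)) {
    B <- data_values(B)
    if (ncol(B) < 1) stop("need at least one time sample")
    C <- tcrossprod(B) / ncol(B)
    n_samples <- ncol(B)
  }
  p <- nrow(C)
  stopifnot(nrow(L$matrix) == p)
  hs <- assemble_handles(L, comps)
  K <- length(hs)

  sc <- sum(diag(C)) / p
  if (sc <= 0) sc <- 1               # all-zero data: posterior is zero anyway
  Cn <- C / sc
  n <- n_samples
  eta <- opts$hyperprior_mean
  nu <- opts$hyperprior_var
  lb <- opts$lambda_bounds[1]; ub <- opts$lambda_bounds[2]

  r1 <- which(vapply(hs, function(h) h$kind == "rank1", TRUE))
  Umat <- if (length(r1)) vapply(hs[r1], `[[`, numeric(p), "un") else NULL
  other <- setdiff(seq_len(K), r1)

  objective <- function(lam) {
    Sig <- assemble_sigma(hs, lam, p)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(G = -Inf))
    logdet <- 2 * sum(log(diag(ch)))
    S <- chol2inv(ch)
    G <- -0.5 * n * (sum(S * Cn) + logdet + p * log(2 * pi)) -
      sum((lam - eta)^2) / (2 * nu)
    list(G = G, S = S, chol = ch)
  }

  lam <- rep(-log(K), K)
  ob <- objective(lam)
  if (!is.finite(ob$G)) stop("initial model covariance is not positive definite")
  traj <- ob$G
  converged <- FALSE
  it <- 0
  stall <- 0
  mu <- 1e-4        # Levenberg damping, adapted by step success

  while (it < opts$max_iter) {
    it <- it + 1
    gi <- grad_fisher(hs, lam, ob$S, Cn, n, r1, Umat, other, p)
    g <- gi$g - (lam - eta) / nu
    I <- gi$I
    diag(I) <- diag(I) + 1 / nu

    # damped Fisher-scoring step; the damping is raised until the step
    # ascends (monotone trajectory up to evaluation roundoff, which is
    # ~eps|F| and governs both the accept slack and the stopping rule)
    dI <- pmax(diag(I), 1e-12 * max(diag(I)))
    slack <- 1e-9 * (1 + abs(ob$G))
    repeat {
      step <- tryCatch(solve(I + diag(mu * dI, K), g),
                       error = function(e) g / (dI * (1 + mu)))
      step <- pmax(pmin(step, 16), -16)
      lam_new <- pmax(pmin(lam + step, ub), lb)
      ob_new <- objective(lam_new)
      if (ob_new$G >= ob$G - slack) { mu <- max(mu / 3, 1e-8); break }
      mu <- mu * 10
      if (mu > 1e9) break
    }
    refused <- ob_new$G < ob$G - slack
    if (refused) { ob_new <- ob; lam_new <- lam }
    dF <- ob_new$G - ob$G
    lam <- lam_new; ob <- ob_new
    traj <- c(traj, ob$G)
    if (opts$verbose)
      message(sprintf("reml it %3d  F = %.6e  dF = %.3e  mu = %.1e  active = %d",
                      it, ob$G, dF, mu, sum(lam > lb + 1)))
    if (!is.finite(ob$G)) stop("free energy diverged at iteration ", it)
    tol <- max(opts$tolerance, 1e-7 * abs(ob$G))
    if (refused) stall <- stall + 1 else stall <- 0
    # converge only on an undamped (near-full-Newton) step with small dF;
    # a small dF under heavy damping just means the step was short
    if (stall >= 3 || (!refused && mu <= 1e-3 && abs(dF) < tol)) {
      converged <- TRUE; break
    }
  }

  # Laplace (Occam) term: 0.5 logdet(Pi Sigma_lambda)
  I <- grad_fisher(hs, lam, ob$S, Cn, n, r1, Umat, other, p)$I
  diag(I) <- diag(I) + 1 / nu
  laplace <- -0.5 * (K * log(nu) + determinant(I, logarithm = TRUE)$modulus[1])

  eff <- exp(lam) * sc * vapply(hs, `[[`, 0, "norm_factor")
  labels <- vapply(hs, `[[`, "", "label")
  levels <- vapply(hs, `[[`, "", "level")

  structure(list(
    hyperparameters = lam,
    effective_weights = eff,
    labels = labels,
    levels = levels,
    free_energy = ob$G - 0.5 * n * p * log(sc) + laplace,
    free_energy_trajectory = traj,
    n_iterations = it,
    converged = converged,
    scale = sc,
    handles = hs,
    chol_n = ob$chol,

    n_samples = n,
    posterior_mean = NULL
  ), class = "inversion_result")
}

# Free-energy gradient and Fisher information at lambda.
# g_k = n/2 e^l_k [ tr(S Cn S A_k) - tr(S A_k) ]  (hyperprior added by caller)
# I_kl = n/2 e^{l_k + l_l} tr(S A_k S A_l)
grad_fisher <- function(hs, lam, S, Cn, n, r1, Umat, other, p) {
  K <- length(hs)
  e <- exp(lam)
  g <- numeric(K)
  I <- matrix(0, K, K)
  W2 <- S %*% Cn %*% S

  V1 <- NULL
  if (length(r1)) {
    V1 <- S %*% Umat
    t1 <- colSums(Umat * V1)                 # u' S u
    t2 <- colSums(Umat * (W2 %*% Umat))      # u' S Cn S u
    g[r1] <- 0.5 * n * e[r1] * (t2 - t1)
    M1 <- crossprod(Umat, V1)
    I[r1, r1] <- 0.5 * n * tcrossprod(e[r1]) * M1^2
  }
  if (length(other)) {
    SM <- lapply(other, function(k) {
      if (hs[[k]]$kind == "identity") S else S %*% hs[[k]]$Mn
    })
    for (a in seq_along(other)) {
      k <- other[a]
      h <- hs[[k]]
      if (h$kind == "identity") {
        g[k] <- 0.5 * n * e[k] * (sum(diag(W2)) - sum(diag(S)))
      } else {
        g[k] <- 0.5 * n * e[k] * (sum(W2 * h$Mn) - sum(diag(SM[[a]])))
      }
      I[k, k] <- 0.5 * n * e[k]^2 * sum(SM[[a]] * t(SM[[a]]))
      if (length(r1)) {
        cross <- 0.5 * n * e[k] * e[r1] * colSums(Umat * (SM[[a]] %*% V1))
        I[k, r1] <- cross; I[r1, k] <- cross
      }
      if (a < length(other)) for (b in (a + 1):length(other)) {
        k2 <- other[b]
        v <- 0.5 * n * e[k] * e[k2] * sum(SM[[a]] * t(SM[[b]]))
        I[k, k2] <- v; I[k2, k] <- v
      }
    }
  }
  list(g = g, I = I)
}

#' Posterior spatial filter
#'
#' Returns `W` (vertices x channels) such that `X_hat = W %*% B` is the
#' posterior mean (MAP) source estimate at the fitted hyperparameters.
#' Only rank-one source components contribute rows support.
#'
#' @param result `inversion_result` from [reml_optimize()].
#' @param comps the `component_set` used for the fit.
#' @param n_vertices source-space dimension.
#' @export
posterior_filter <- function(result, comps, n_vertices) {
  hs <- result$handles
  src <- which(vapply(hs, `[[`, "", "level") == "source")
  if (!length(src)) stop("no source components")
  Qmat <- matrix(0, n_vertices, length(src))
  Amat <- NULL
  for (j in seq_along(src)) {
    h <- hs[[src[j]]]
    if (is.null(h$q)) stop("posterior filter requires rank-one source components")
    Qmat[, j] <- h$q
    Amat <- cbind(Amat, h$u)
  }
  w <- result$effective_weights[src]
  # Sigma_orig^{-1} Amat by Cholesky backsolve on the normalized model
  # covariance (numerically stable in the near-singular noiseless regime)
  ch <- result$chol_n
  Z <- backsolve(ch, backsolve(ch, Amat, transpose = TRUE)) / result$scale
  Qmat %*% (w * t(Z))
}

#' Invert MEG data
#'
#' Estimates hyperparameters once from the supplied data — the averaged
#' data for `mode = "evoked"`, or trial-pooled second-order statistics
#' (the average of per-trial outer products) for `mode = "induced"` — and
#' returns the inversion result together with the posterior filter, the
#' posterior mean for the trial-averaged data, and (for trial sets) access
#' to per-trial posterior time courses at fixed hyperparameters.
#'
#' @param data a `trial_set`, `data_matrix`, or channels x samples matrix.
#' @param L fixed-normal `leadfield`.
#' @param comps `component_set`.
#' @param opts [reml_options()].
#' @param mode "induced" (default for trial sets) or "evoked".
#' @return `inversion_result` with `posterior_mean` (sources x samples, for
#'   the averaged data), `filter` (sources x channels), and `mode`.
#' @export
invert <- function(data, L, comps, opts = reml_options(),
                   mode = c("induced", "evoked")) {
  mode <- match.arg(mode)
  nv <- ncol(L$matrix)
  if (inherits(data, "trial_set")) {
    dims <- dim(data$sensor_data)
    ntr <- dims[1]; p <- dims[2]; nt <- dims[3]
    Bavg <- apply(data$sensor_data, c(2, 3), mean)
    if (mode == "evoked") {
      res <- reml_optimize(Bavg, L, comps, opts)
    } else {
      Cs <- matrix(0, p, p)
      for (i in seq_len(ntr)) {
        Bi <- matrix(data$sensor_data[i, , ], p, nt)
        Cs <- Cs + tcrossprod(Bi)
      }
      Cs <- Cs / (ntr * nt)
      res <- reml_optimize(NULL, L, comps, opts, C = Cs, n_samples = ntr * nt)
    }
  } else {
    Bavg <- data_values(data)
    res <- reml_optimize(Bavg, L, comps, opts)
  }
  res$filter <- posterior_filter(res, comps, nv)
  res$posterior_mean <- res$filter %*% Bavg
  res$mode <- mode
  res
}

#' Per-trial posterior time courses at fixed hyperparameters
#'
#' @param result `inversion_result` from [invert()] (must carry `filter`).
#' @param trial_data channels x samples matrix for one trial.
#' @return sources x samples posterior mean.
#' @export
posterior_timecourse <- function(result, trial_data) {
  if (is.null(result$filter)) stop("result carries no posterior filter")
  result$filter %*% data_values(trial_data)
}

#' Rank inversion results by free energy
#'
#' @param results list of `inversion_result`s fitted on identical data.
#' @return data.frame with `model`, `free_energy`, `delta_F` (vs best),
#'   sorted descending.
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 1)
  ns <- vapply(results, `[[`, 0, "n_samples")
  if (length(unique(ns)) != 1)
    stop("results were not computed on identical data shapes")
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("model_", seq_along(results))
  F <- vapply(results, `[[`, 0, "free_energy")
  out <- data.frame(model = nm, free_energy = F)
  out <- out[order(-out$free_energy), ]
  out$delta_F <- out$free_energy - out$free_energy[1]
  rownames(out) <- NULL
  out
}
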