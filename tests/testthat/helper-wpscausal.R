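# shared fixtures, all generated in code

# minimal score_set built directly from matrices (one row per person);
# used to feed hand-computed values into the step-2 machinery
make_scores <- function(Y, A, L, K, confounders = "L", method = "manual") {
  within <- list(Y = as.matrix(Y), A = as.matrix(A), L = as.matrix(L))
  for (v in names(within))
    if (is.null(colnames(within[[v]])))
      colnames(within[[v]]) <- paste0("t", seq_len(ncol(within[[v]])) - 1)
  structure(list(within = within, stable = NULL,
                 waves = lapply(within, function(m)
                   as.integer(sub("^t", "", colnames(m)))),
                 roles = list(outcome = "Y", treatment = "A",
                              confounders = confounders),
                 K = K, person_id = seq_len(nrow(as.matrix(Y))),
                 method = method),
            class = "score_set")
}

# model-true data for the measurement model: stable trait variance phi2 plus
# a stationary AR(1) within process (variance v, lag-1 coefficient a)
sim_measurement_true <- function(n, p, phi2, v = 10, a = 0.5, seed = 1) {
  set.seed(seed)
  Psi <- v * a^abs(outer(seq_len(p), seq_len(p), "-"))
  I <- rnorm(n, 0, sqrt(phi2))
  I + matrix(rnorm(n * p), n, p) %*% chol(Psi)
}

# random PSD pair (Sigma, Psi) with Sigma - Psi PSD (a valid trait split)
random_cov_pair <- function(d, seed) {
  set.seed(seed)
  G <- matrix(rnorm(d * d), d); Psi <- crossprod(G) + diag(d) * 0.5
  H <- matrix(rnorm(d * d), d); Phi <- crossprod(H) * 0.5
  list(sigma = Psi + Phi, psi = Psi)
}

# independent constrained-optimization oracle for the correlation-preserving
# weights: minimize trace MSE subject to W' Sigma W = Psi by an augmented
# Lagrangian, from data-independent random starts
brute_force_weights <- function(sigma, psi, n_starts = 3, seed = 1) {
  d <- nrow(sigma)
  set.seed(seed)
  mse <- function(W) sum(diag(t(W) %*% sigma %*% W)) + sum(diag(psi)) -
    2 * sum(diag(t(W) %*% psi))
  best <- NULL
  for (s in seq_len(n_starts)) {
    W <- diag(d) * 0.5 + matrix(rnorm(d * d, 0, 0.3), d)
    L <- matrix(0, d, d)
    lam <- 100
    for (it in 1:60) {
      obj <- function(w) {
        Wm <- matrix(w, d, d)
        viol <- t(Wm) %*% sigma %*% Wm - psi
        mse(Wm) + sum(L * viol) + lam * sum(viol^2)
      }
      grad <- function(w) {
        Wm <- matrix(w, d, d)
        viol <- t(Wm) %*% sigma %*% Wm - psi
        G <- 2 * sigma %*% Wm - 2 * psi +
          sigma %*% Wm %*% (L + t(L)) + 4 * lam * sigma %*% Wm %*% viol
        as.vector(G)
      }
      W <- matrix(optim(as.vector(W), obj, gr = grad, method = "BFGS",
                        control = list(maxit = 5000,
                                       reltol = 1e-15))$par, d, d)
      viol <- t(W) %*% sigma %*% W - psi
      if (max(abs(viol)) < 1e-11) break
      L <- L + 2 * lam * viol
      if (it %% 6 == 0) lam <- lam * 5
    }
    feas <- max(abs(t(W) %*% sigma %*% W - psi))
    if (feas < 1e-8 && (is.null(best) || mse(W) < best$val))
      best <- list(W = W, val = mse(W))
  }
  best$W
}
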