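#' Measurement-model specification
#'
#' Step 1a fits, separately for each variable, the single-stable-trait-factor
#' model \deqn{X_i = \mu + I_i 1 + X^*_i,\qquad
#' \Sigma = \phi^2 1 1^t + \Psi(\theta),} where \eqn{\Psi(\theta)} carries the
#' serial dependence of the within-person scores. A structure must be imposed
#' on \eqn{\Psi} for identification.
#'
#' @param psi_structure within-person covariance structure. The default,
#'   `"ar1_timevarying"`, has a free initial variance, one autoregressive
#'   coefficient per transition and one innovation variance per occasion (the
#'   structure used throughout the benchmark study); `"ar1_stationary"` is a
#'   two-parameter stationary AR(1); `"compound_symmetry"` and `"toeplitz"`
#'   are the usual exchangeable and banded structures. Note that compound
#'   symmetry is weakly identified jointly with the trait variance (both add
#'   a constant to every covariance).
#' @param estimator `"ml"` (default) or `"gls"` (generalized least squares on
#'   the sample covariance).
#' @param missing `"fiml"` (full-information ML over each person's observed
#'   coordinates, valid under MAR) or `"complete_case"`.
#' @param equal_ar,equal_resid equate the autoregressive coefficients /
#'   innovation variances across occasions (`ar1_timevarying` only); useful
#'   when few occasions leave the free structure under-identified.
#' @param max_restarts additional random restarts attempted when none of the
#'   three deterministic starts converges.
#' @param tol gradient-norm tolerance declared as convergence.
#' @return object of class `"measurement_spec"`.
#' @export
measurement_spec <- function(psi_structure = c("ar1_timevarying",
                                               "ar1_stationary",
                                               "compound_symmetry",
                                               "toeplitz"),
                             estimator = c("ml", "gls"),
                             missing = c("fiml", "complete_case"),
                             equal_ar = FALSE, equal_resid = FALSE,
                             max_restarts = 3, tol = 1e-6) {
  structure(list(psi_structure = match.arg(psi_structure),
                 estimator = match.arg(estimator),
                 missing = match.arg(missing),
                 equal_ar = equal_ar, equal_resid = equal_resid,
                 max_restarts = max_restarts, tol = tol),
            class = "measurement_spec")
}

.structure_code <- function(psi_structure) {
  match(psi_structure, c("ar1_timevarying", "ar1_stationary",
                         "compound_symmetry", "toeplitz"))
}

# expand a reduced parameter vector (equality constraints applied) into the
# full theta understood by the compiled builder
.expand_theta <- function(theta, spec, p) {
  q <- p - 1L
  if (spec$psi_structure != "ar1_timevarying") return(theta)
  v0 <- theta[1]
  na <- if (spec$equal_ar) 1L else q
  a <- theta[1 + seq_len(na)]
  s <- theta[1 + na + seq_len(if (spec$equal_resid) 1L else q)]
  c(v0, rep(a, length.out = q), rep(s, length.out = q))
}

.n_theta <- function(spec, p) {
  q <- p - 1L
  switch(spec$psi_structure,
         ar1_timevarying = 1L + (if (spec$equal_ar) 1L else q) +
           (if (spec$equal_resid) 1L else q),
         ar1_stationary = 2L,
         compound_symmetry = 2L,
         toeplitz = 1L + q)
}

.theta_names <- function(spec, p) {
  q <- p - 1L
  switch(spec$psi_structure,
         ar1_timevarying = c("v0",
                             paste0("a", seq_len(if (spec$equal_ar) 1L else q)),
                             paste0("s", seq_len(if (spec$equal_resid) 1L else q))),
         ar1_stationary = c("a", "s"),
         compound_symmetry = c("v", "c"),
         toeplitz = c("v", paste0("r", seq_len(q))))
}

#' Implied covariance of the stable-trait measurement model
#'
#' @param phi2 stable-trait variance.
#' @param theta structure parameters (full, unconstrained form; for
#'   `ar1_timevarying` this is `(v0, a_1..a_q, s_1..s_q)`).
#' @param spec a [measurement_spec()] (only the structure is used).
#' @param p number of occasions.
#' @param what `"sigma"` for \eqn{\phi^2 11^t + \Psi} or `"psi"` for
#'   \eqn{\Psi} alone.
#' @return p x p symmetric matrix.
#' @export
implied_covariance <- function(phi2, theta, spec = measurement_spec(), p,
                               what = c("sigma", "psi")) {
  what <- match.arg(what)
  psi <- implied_psi_cpp(theta, .structure_code(spec$psi_structure), p)
  if (what == "psi") return(psi)
  psi + phi2 * matrix(1, p, p)
}

# three deterministic starting points from the sample moments: moment-based,
# shrunk, diffuse. Far-lag covariances estimate phi2 because the AR part of
# the covariance dies off with lag while the trait part does not.
.start_values <- function(S, spec) {
  p <- ncol(S)
  lag <- abs(outer(seq_len(p), seq_len(p), "-"))
  far <- S[lag >= 2]
  phi0 <- if (length(far)) max(mean(far), 1e-3 * mean(diag(S)))
  else max(min(S[lag == 1]), 1e-3 * mean(diag(S)))
  vbar <- mean(diag(S))
  mk_theta <- function(phi2, shrink) {
    Psi0 <- S - phi2
    d <- pmax(diag(Psi0), 0.05 * vbar)
    switch(spec$psi_structure,
      ar1_timevarying = {
        a <- numeric(p - 1); s <- numeric(p - 1)
        for (k in seq_len(p - 1)) {
          a[k] <- shrink * Psi0[k + 1, k] / d[k]
          s[k] <- max(d[k + 1] - a[k]^2 * d[k], 0.05 * vbar)
        }
        if (spec$equal_ar) a <- mean(a)
        if (spec$equal_resid) s <- mean(s)
        c(d[1], a, s)
      },
      ar1_stationary = {
        a <- shrink * mean(Psi0[cbind(2:p, 1:(p - 1))] / d[-p])
        a <- max(min(a, 0.9), -0.9)
        c(a, mean(d) * (1 - a^2))
      },
      compound_symmetry = c(mean(d), shrink * mean(Psi0[lag == 1])),
      toeplitz = {
        v <- mean(d)
        r <- vapply(seq_len(p - 1),
                    function(l) shrink * mean(Psi0[lag == l]) / v, numeric(1))
        c(v, pmax(pmin(r, 0.95), -0.95))
      })
  }
  list(c(phi0, mk_theta(phi0, 1)),
       c(phi0 / 2, mk_theta(phi0 / 2, 0.5)),
       c(0.1 * vbar, mk_theta(0.1 * vbar, 0)))
}

.gls_objective <- function(Sigma, S, Sinv) {
  R <- (S - Sigma) %*% Sinv
  0.5 * sum(R * t(R))
}

.num_grad <- function(fn, par, h = 1e-6) {
  vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h * max(1, abs(par[j]))
    (fn(par + e) - fn(par - e)) / (2 * e[j])
  }, numeric(1))
}

#' Fit the stable-trait measurement model to one variable
#'
#' Maximizes the multivariate-normal likelihood of
#' \eqn{\Sigma = \phi^2 11^t + \Psi(\theta)} with saturated means over
#' \eqn{(\mu, \phi^2, \theta)}. Complete data use the concentrated likelihood
#' through the sample moments; with missing cells and `missing = "fiml"` the
#' casewise likelihood is maximized over each person's observed coordinates.
#' Quasi-Newton (BFGS) from three deterministic starting points; variance
#' parameters are unconstrained, and a solution with any negative variance
#' estimate (trait, initial or innovation) is flagged `improper`, the usual
#' boundary pathology of covariance-structure fitting.
#'
#' @param series persons x occasions numeric matrix, `NA` for missing cells.
#' @param spec a [measurement_spec()].
#' @return object of class `"measurement_fit"` with elements `mu`, `phi2`,
#'   `theta` (named), `psi`, `sigma`, `loglik`, `npar`, `fit_indices`,
#'   `converged`, `improper`, `n`, `p`, plus the sample moments used.
#' @export
fit_measurement_model <- function(series, spec = measurement_spec()) {
  series <- as.matrix(series)
  p <- ncol(series)
  if (p < 3 && spec$psi_structure == "ar1_timevarying" &&
      !(spec$equal_ar || spec$equal_resid))
    .warnf("fewer than 3 occasions: free AR(1) structure is not identified")
  keep <- rowSums(!is.na(series)) >= 2
  if (sum(keep) < 2) .stopf("need at least 2 persons with >= 2 observed occasions")
  series <- series[keep, , drop = FALSE]
  n <- nrow(series)
  complete <- !anyNA(series)
  if (!complete && spec$missing == "complete_case") {
    series <- series[stats::complete.cases(series), , drop = FALSE]
    n <- nrow(series)
    if (n < 2) .stopf("fewer than 2 complete cases")
    complete <- TRUE
  }
  code <- .structure_code(spec$psi_structure)
  if (complete) {
    xbar <- colMeans(series)
    S <- .sample_cov(series, divisor = "n")
    Sinv <- if (spec$estimator == "gls") solve(S) else NULL
    obj <- function(par) {
      full <- c(par[1], .expand_theta(par[-1], spec, p))
      if (spec$estimator == "ml") return(cov_ml_objective(full, S, code))
      Sigma <- implied_covariance(par[1], full[-1], spec, p)
      if (.min_eigenvalue(Sigma) < 1e-10) return(1e10)
      .gls_objective(Sigma, S, Sinv)
    }
  } else {
    xbar <- colMeans(series, na.rm = TRUE)
    S <- .sample_cov(series, divisor = "n")   # pairwise, starts only
    pat_key <- apply(!is.na(series), 1, paste, collapse = "")
    groups <- split(seq_len(n), pat_key)
    obj_mu <- function(mu, par) {
      full <- c(par[1], .expand_theta(par[-1], spec, p))
      Sigma <- tryCatch(implied_covariance(par[1], full[-1], spec, p),
                        error = function(e) NULL)
      if (is.null(Sigma)) return(1e12)
      dev <- 0
      for (g in groups) {
        o <- which(!is.na(series[g[1], ]))
        So <- Sigma[o, o, drop = FALSE]
        ch <- tryCatch(chol(So), error = function(e) NULL)
        if (is.null(ch)) return(1e10 - 1e6 * .min_eigenvalue(So))
        Z <- sweep(series[g, o, drop = FALSE], 2, mu[o])
        Q <- forwardsolve(t(ch), t(Z))
        dev <- dev + length(g) * (2 * sum(log(diag(ch))) +
                                    length(o) * log(2 * pi)) + sum(Q^2)
      }
      dev
    }
  }
  starts <- .start_values(S, spec)
  best <- NULL
  # `st` is always c(phi2, theta); FIML prepends the mean parameters itself
  try_starts <- function(starts, maxit = 500, mu0 = xbar) {
    for (st in starts) {
      res <- if (complete) {
        tryCatch(stats::optim(st, obj, method = "BFGS",
                              control = list(maxit = maxit, reltol = 1e-10)),
                 error = function(e) NULL)
      } else {
        fn <- function(pp) obj_mu(pp[seq_len(p)], pp[-seq_len(p)])
        tryCatch(stats::optim(c(mu0, st), fn, method = "BFGS",
                              control = list(maxit = 2 * maxit, reltol = 1e-10)),
                 error = function(e) NULL)
      }
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <<- res
    }
  }
  strip_mu <- function(par) {
    if (complete) list(mu = xbar, par = par)
    else list(mu = par[seq_len(p)], par = par[-seq_len(p)])
  }
  # full run from the moment-based start; the shrunk and diffuse starts are
  # explored briefly and the winner polished, guarding against local optima
  # without paying three full optimizations
  try_starts(starts[1])
  first <- best
  try_starts(starts[-1], maxit = 50)
  if (!identical(best, first)) {
    b <- strip_mu(best$par)
    try_starts(list(b$par), mu0 = b$mu)
  }
  conv <- !is.null(best) && best$convergence == 0 && best$value < 1e9
  if (!conv && spec$max_restarts > 0) {
    # deterministic perturbations of the moment start
    extra <- lapply(seq_len(spec$max_restarts), function(j)
      starts[[1]] * (1 + 0.15 * j * rep_len(c(1, -1), length(starts[[1]]))))
    try_starts(extra)
    conv <- !is.null(best) && best$convergence == 0 && best$value < 1e9
  }
  if (is.null(best) || best$value >= 1e9) {
    err <- simpleError("measurement model failed to converge")
    err$best <- best
    stop(err)
  }
  par <- best$par
  if (!complete) { mu <- par[seq_len(p)]; par <- par[-seq_len(p)] } else mu <- xbar
  phi2 <- par[1]
  theta_red <- par[-1]
  theta_full <- .expand_theta(theta_red, spec, p)
  psi <- implied_covariance(phi2, theta_full, spec, p, what = "psi")
  sigma <- psi + phi2
  improper <- .improper_solution(phi2, theta_full, spec, p)
  loglik <- if (complete) {
    -n / 2 * (p * log(2 * pi) + cov_ml_objective(c(phi2, theta_full), S, code))
  } else {
    -0.5 * obj_mu(mu, c(phi2, theta_red))
  }
  gfun <- if (complete) obj else function(pp) obj_mu(mu, pp)
  grad_norm <- sqrt(sum(.num_grad(gfun, c(phi2, theta_red))^2))
  fit <- structure(list(mu = mu, phi2 = phi2,
                        theta = stats::setNames(theta_red, .theta_names(spec, p)),
                        theta_full = theta_full,
                        psi = psi, sigma = sigma,
                        loglik = loglik,
                        npar = 1L + length(theta_red) + p,
                        converged = conv && grad_norm < max(spec$tol * n, 1e-3),
                        grad_norm = grad_norm,
                        improper = improper,
                        n = n, p = p, spec = spec,
                        sample_cov = S, sample_mean = xbar,
                        complete = complete),
                   class = "measurement_fit")
  fit$fit_indices <- if (complete && spec$estimator == "ml")
    tryCatch(fit_indices(fit), error = function(e)
      c(cfi = NA_real_, rmsea = NA_real_, srmr = NA_real_))
  else c(cfi = NA_real_, rmsea = NA_real_, srmr = NA_real_)
  fit
}

.improper_solution <- function(phi2, theta_full, spec, p) {
  q <- p - 1L
  bad <- phi2 < 0
  bad || switch(spec$psi_structure,
    ar1_timevarying = theta_full[1] <= 0 ||
      any(theta_full[1 + q + seq_len(q)] <= 0),
    ar1_stationary = theta_full[2] <= 0 || abs(theta_full[1]) >= 1,
    compound_symmetry = theta_full[1] <= 0,
    toeplitz = theta_full[1] <= 0)
}

#' @export
print.measurement_fit <- function(x, ...) {
  cat(sprintf("measurement_fit (%s, %s): n=%d, %d occasions\n",
              x$spec$psi_structure, x$spec$estimator, x$n, x$p))
  cat(sprintf("  phi2 = %.4f  (trait share at t0: %.1f%%)\n", x$phi2,
              100 * x$phi2 / x$sigma[1, 1]))
  cat("  theta:", paste(sprintf("%s=%.3f", names(x$theta), x$theta),
                        collapse = " "), "\n")
  cat(sprintf("  loglik = %.2f; converged: %s; improper: %s\n",
              x$loglik, x$converged, x$improper))
  fi <- x$fit_indices
  if (!all(is.na(fi)))
    cat(sprintf("  CFI %.3f  RMSEA %.3f  SRMR %.3f\n",
                fi["cfi"], fi["rmsea"], fi["srmr"]))
  invisible(x)
}

#' Covariance-structure fit indices
#'
#' CFI, RMSEA and SRMR from the maximum-likelihood discrepancy between the
#' fitted and sample covariance, with an independence baseline (free means
#' and variances, zero covariances). Complete-data sufficient statistics are
#' required; under FIML with actual missingness the indices are not computed.
#'
#' @param fit a `measurement_fit`.
#' @param sample_cov,sample_mean,n override the moments stored in the fit
#'   (sample covariance with ML divisor `n`).
#' @return named vector `c(cfi, rmsea, srmr)`.
#' @export
fit_indices <- function(fit, sample_cov = NULL, sample_mean = NULL, n = NULL) {
  S <- sample_cov %||% fit$sample_cov
  xbar <- sample_mean %||% fit$sample_mean
  n <- n %||% fit$n
  p <- ncol(S)
  Sigma <- fit$sigma
  q_cov <- 1L + length(fit$theta)
  df <- p * (p + 1) / 2 - q_cov
  df_b <- p * (p + 1) / 2 - p
  if (df < 0) .stopf("model has negative degrees of freedom")
  if (n <= p) .stopf("n too small for fit indices")
  ldS <- determinant(S, logarithm = TRUE)$modulus
  quad <- drop(crossprod(xbar - fit$mu, solve(Sigma, xbar - fit$mu)))
  Fm <- determinant(Sigma, logarithm = TRUE)$modulus +
    sum(diag(solve(Sigma, S))) - ldS - p + quad
  Fb <- sum(log(diag(S))) - ldS
  chi2 <- max(n * as.numeric(Fm), 0)
  chi2_b <- max(n * as.numeric(Fb), 0)
  lam <- max(chi2 - df, 0)
  lam_b <- max(chi2_b - df_b, 0)
  cfi <- if (max(lam, lam_b) == 0) 1 else 1 - lam / max(lam_b, lam)
  rmsea <- if (df > 0) sqrt(lam / (df * n)) else 0
  d <- sqrt(diag(S))
  Rstd <- (S - Sigma) / (d %o% d)
  srmr <- sqrt(mean(Rstd[upper.tri(Rstd, diag = TRUE)]^2))
  c(cfi = cfi, rmsea = rmsea, srmr = srmr)
}
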