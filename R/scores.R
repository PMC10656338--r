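#' Stacked within-person covariance from sample and trait covariances
#'
#' Implements \eqn{\hat\Psi = S - \hat\Phi^+}, where \eqn{\hat\Phi^+} expands
#' each stable-trait (co)variance over the corresponding occasion block of
#' all-ones: with equal occasion counts this is the Kronecker product
#' \eqn{\hat\Phi \otimes 1 1^t}; with unequal counts each block is
#' \eqn{\hat\phi_{vw} 1_{p_v} 1^t_{p_w}}. The difference need not be PSD in
#' finite samples and is eigenvalue-repaired (with a warning) when it is not.
#'
#' @param S stacked sample covariance (variable-major blocks).
#' @param phi_hat V x V stable-trait covariance.
#' @param layout integer vector of occasion counts per variable, in block
#'   order; must sum to `ncol(S)`.
#' @return repaired \eqn{\hat\Psi} with attributes `"repaired"` and
#'   `"min_eigenvalue"` (see [psd_repair()]), plus `"phi_plus"`.
#' @export
estimate_within_covariance <- function(S, phi_hat, layout) {
  layout <- as.integer(layout)
  if (sum(layout) != ncol(S))
    .stopf("layout blocks (%d) do not match ncol(S) = %d",
           sum(layout), ncol(S))
  if (nrow(phi_hat) != length(layout))
    .stopf("phi_hat dimension does not match number of variable blocks")
  idx <- split(seq_len(sum(layout)), rep(seq_along(layout), layout))
  Phi_plus <- matrix(0, ncol(S), ncol(S))
  for (v in seq_along(layout))
    for (w in seq_along(layout))
      Phi_plus[idx[[v]], idx[[w]]] <- phi_hat[v, w]
  psi <- psd_repair(S - Phi_plus, label = "within-person covariance")
  attr(psi, "phi_plus") <- Phi_plus
  psi
}

#' Correlation-preserving weights for within-person score prediction
#'
#' The best linear predictor \eqn{\hat X^* = W^t (X - \mu)} whose predicted
#' scores reproduce the within-person covariance, \eqn{W^t \Sigma W = \Psi},
#' while minimizing the trace mean squared error
#' \eqn{E[(\hat X^* - X^*)^t(\hat X^* - X^*)]}:
#' \deqn{W^t = \Psi^{1/2} (\Psi^{3/2} \Sigma^{-1} \Psi^{3/2})^{-1/2}
#'   \Psi^{3/2} \Sigma^{-1}.}
#' Matrix powers are taken through the symmetric eigendecomposition with
#' eigenvalues clipped at `1e-8`. When \eqn{\Psi = \Sigma} the weights reduce
#' to the identity, and in the scalar case to \eqn{\sqrt{\psi/\sigma}}.
#'
#' @param sigma stacked measurement covariance \eqn{\Sigma} (invertible).
#' @param psi stacked within-person covariance \eqn{\Psi} (PSD).
#' @return the weight matrix `W` (so scores are `t(W) %*% (x - mu)`).
#' @export
cpp_weights <- function(sigma, psi) {
  if (.min_eigenvalue(psi) < -1e-6) .stopf("psi has eigenvalue < -1e-6")
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) .stopf("sigma is (numerically) singular")
  psi_h <- .sym_power(psi, 0.5)
  psi_3h <- .sym_power(psi, 1.5)
  sigma_inv <- solve(sigma)
  M <- psi_3h %*% sigma_inv %*% psi_3h
  Wt <- psi_h %*% .sym_power(M, -0.5) %*% psi_3h %*% sigma_inv
  t(Wt)
}

# stacked layout bookkeeping: variable-major (all occasions of the outcome,
# then the treatment, then each confounder)
.stack_layout <- function(panel) {
  ord <- c(panel$roles$outcome, panel$roles$treatment, panel$roles$confounders)
  list(variables = ord,
       sizes = vapply(ord, function(v) length(panel$waves[[v]]), integer(1)))
}

.stack_values <- function(panel) {
  ord <- .stack_layout(panel)$variables
  X <- do.call(cbind, lapply(ord, function(v) panel$values[[v]]))
  colnames(X) <- unlist(lapply(ord, function(v)
    paste0(v, ".", colnames(panel$values[[v]]))))
  X
}

#' Predict stable-trait scores for one variable
#'
#' The linear correlation-preserving predictor of the stable trait,
#' \deqn{\hat I_i = \frac{\hat\phi}{\sqrt{1^t \hat\Sigma^{-1} 1}}
#'   1^t \hat\Sigma^{-1} (X_i - \bar X),}
#' evaluated on each person's observed coordinates (MAR). Its variance equals
#' \eqn{\hat\phi^2} on model-true data, so covariances of per-variable
#' predictions estimate the off-diagonal trait covariances.
#'
#' @param series persons x occasions matrix for one variable.
#' @param fit its `measurement_fit` (supplies \eqn{\hat\phi^2}).
#' @param sigma covariance used for \eqn{\hat\Sigma}: `"sample"` (default) or
#'   `"model"` (the fit's implied covariance).
#' @return numeric vector \eqn{\hat I_i}; persons with fewer than one
#'   observed occasion get `NA`. When \eqn{\hat\phi^2 \le 0} the predictor is
#'   identically zero (with attribute `"note"`).
#' @export
predict_stable_traits <- function(series, fit, sigma = c("sample", "model")) {
  sigma <- match.arg(sigma)
  series <- as.matrix(series)
  n <- nrow(series)
  if (fit$phi2 <= 0) {
    out <- rep(0, n)
    attr(out, "note") <- "phi2 at or below zero; stable trait set to 0"
    return(out)
  }
  Sig <- if (sigma == "sample") fit$sample_cov else fit$sigma
  xbar <- fit$sample_mean
  phi <- sqrt(fit$phi2)
  out <- rep(NA_real_, n)
  pat <- apply(!is.na(series), 1, paste, collapse = "")
  for (g in split(seq_len(n), pat)) {
    o <- which(!is.na(series[g[1], ]))
    if (!length(o)) next
    Si <- solve(Sig[o, o, drop = FALSE])
    w <- drop(phi / sqrt(sum(Si %*% rep(1, length(o)))) *
                (rep(1, length(o)) %*% Si))
    out[g] <- sweep(series[g, o, drop = FALSE], 2, xbar[o]) %*% w
  }
  out
}

#' Stable-trait covariance from per-variable predictions
#'
#' Diagonal entries are the fitted trait variances; off-diagonals are the
#' covariances between the per-variable trait predictions.
#'
#' @param I_hat persons x variables matrix of trait predictions.
#' @param phi2 fitted trait variances, one per column of `I_hat`.
#' @return V x V symmetric matrix \eqn{\hat\Phi}.
#' @export
stable_trait_covariance <- function(I_hat, phi2) {
  Phi <- stats::cov(I_hat, use = "pairwise.complete.obs")
  diag(Phi) <- phi2
  (Phi + t(Phi)) / 2
}

#' Predict within-person variability scores
#'
#' Applies the correlation-preserving weights to each person's deviations
#' from the occasion means, \eqn{\hat X^*_i = W^t (X_i - \bar X)}. Persons
#' with complete rows use the global `W`; persons with missing cells get
#' pattern-specific weights `W_i` built from the sample covariance and
#' \eqn{\hat\Psi} restricted to the observed coordinates (MAR), and their
#' scores exist only at observed cells. Persons with fewer than two observed
#' values overall get no scores.
#'
#' @param panel a [panel_data()].
#' @param fits named list of `measurement_fit` objects, one per stacked
#'   variable.
#' @param sigma `"sample"` uses the stacked sample covariance for
#'   \eqn{\Sigma} (the default); `"model"` uses the per-variable model-implied
#'   blocks on the diagonal (cross-variable blocks always come from the
#'   sample).
#' @return object of class `"score_set"`: list with `within` (per-variable
#'   persons x occasions score matrices), `stable` (persons x variables trait
#'   predictions), `W`, `psi_hat`, `phi_hat`, `phi_plus`, `sigma_hat`,
#'   `mu_hat`, `layout`, `fits`, `person_id`, `waves`, `method`.
#' @export
predict_within_scores <- function(panel, fits, sigma = c("sample", "model")) {
  sigma <- match.arg(sigma)
  layout <- .stack_layout(panel)
  ord <- layout$variables
  for (v in ord) {
    if (is.null(fits[[v]])) .stopf("no measurement fit for variable %s", v)
    if (!fits[[v]]$converged)
      .warnf("measurement fit for %s did not converge", v)
  }
  X <- .stack_values(panel)
  mu <- colMeans(X, na.rm = TRUE)
  S <- .sample_cov(X, divisor = "n-1")
  if (sigma == "model") {
    off <- 0L
    for (v in ord) {
      pv <- layout$sizes[[v]]
      S[off + seq_len(pv), off + seq_len(pv)] <- fits[[v]]$sigma
      off <- off + pv
    }
  }
  I_hat <- vapply(ord, function(v)
    predict_stable_traits(panel$values[[v]], fits[[v]]), numeric(nrow(X)))
  colnames(I_hat) <- ord
  phi_hat <- stable_trait_covariance(I_hat,
                                     vapply(ord, function(v)
                                       max(fits[[v]]$phi2, 0), numeric(1)))
  psi_hat <- estimate_within_covariance(S, phi_hat, layout$sizes)
  W <- cpp_weights(S, psi_hat)
  scores <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  obs_ok <- rowSums(!is.na(X)) >= 2
  pat <- apply(!is.na(X), 1, paste, collapse = "")
  for (g in split(which(obs_ok), pat[obs_ok])) {
    o <- which(!is.na(X[g[1], ]))
    if (length(o) == ncol(X)) {
      scores[g, ] <- sweep(X[g, , drop = FALSE], 2, mu) %*% W
    } else {
      psi_o <- psd_repair(S[o, o, drop = FALSE] -
                            attr(psi_hat, "phi_plus")[o, o, drop = FALSE],
                          label = "pattern within-person covariance")
      W_i <- cpp_weights(S[o, o, drop = FALSE], psi_o)
      scores[g, o] <- sweep(X[g, o, drop = FALSE], 2, mu[o]) %*% W_i
    }
  }
  if (any(!obs_ok))
    .warnf("%d person(s) with < 2 observed values: scores unavailable",
           sum(!obs_ok))
  within <- list(); off <- 0L
  for (v in ord) {
    pv <- layout$sizes[[v]]
    m <- scores[, off + seq_len(pv), drop = FALSE]
    colnames(m) <- colnames(panel$values[[v]])
    within[[v]] <- m
    off <- off + pv
  }
  structure(list(within = within, stable = I_hat, W = W,
                 psi_hat = psi_hat, phi_hat = phi_hat,
                 phi_plus = attr(psi_hat, "phi_plus"),
                 sigma_hat = S, mu_hat = mu,
                 layout = layout, fits = fits,
                 person_id = panel$person_id, waves = panel$waves,
                 roles = panel$roles, K = panel$K,
                 method = "proposed"),
            class = "score_set")
}

#' Two-step score prediction front end
#'
#' Fits the measurement model to every role-tagged variable of the panel and
#' predicts within-person and stable-trait scores (the "proposed" centering).
#'
#' @param panel a [panel_data()].
#' @param spec a [measurement_spec()] applied to every variable (or a named
#'   list of specs per variable).
#' @param ... passed to [predict_within_scores()].
#' @return a `score_set`.
#' @export
predict_scores <- function(panel, spec = measurement_spec(), ...) {
  ord <- .stack_layout(panel)$variables
  fits <- lapply(ord, function(v) {
    sp <- if (inherits(spec, "measurement_spec")) spec else spec[[v]]
    fit_measurement_model(panel$values[[v]], sp)
  })
  names(fits) <- ord
  predict_within_scores(panel, fits, ...)
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set (%s): %d persons, variables %s\n", x$method,
              length(x$person_id), paste(names(x$within), collapse = ", ")))
  if (!is.null(x$phi_hat)) {
    cat("  trait covariance (Phi_hat):\n")
    print(round(x$phi_hat, 3))
  }
  invisible(x)
}

#' Assemble a score set from score matrices
#'
#' Builds the container consumed by the second-step estimators from
#' externally supplied within-person score matrices (e.g. scores read back
#' from CSV with [read_scores()]).
#'
#' @param within named list of persons x occasions score matrices with
#'   `"t0", "t1", ...` column names.
#' @param roles list with `outcome`, `treatment`, `confounders`.
#' @param K highest occasion index (inferred when missing).
#' @param stable optional persons x variables matrix of stable-trait scores.
#' @return a `score_set`.
#' @export
as_score_set <- function(within, roles, K = NULL, stable = NULL) {
  within <- lapply(within, function(m) {
    m <- as.matrix(m)
    if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)) - 1)
    m
  })
  waves <- lapply(within, function(m) as.integer(sub("^t", "", colnames(m))))
  if (is.null(K)) K <- max(unlist(waves))
  structure(list(within = within, stable = stable, W = NULL,
                 psi_hat = NULL, phi_hat = NULL, phi_plus = NULL,
                 sigma_hat = NULL, mu_hat = NULL,
                 layout = NULL, fits = NULL,
                 person_id = seq_len(nrow(within[[1]])),
                 waves = waves, roles = roles, K = as.integer(K),
                 method = "external"),
            class = "score_set")
}

# minimal score_set builder used by the non-model centerings
.score_set <- function(within, stable, panel, method) {
  structure(list(within = within, stable = stable, W = NULL,
                 psi_hat = NULL, phi_hat = NULL, phi_plus = NULL,
                 sigma_hat = NULL, mu_hat = NULL,
                 layout = .stack_layout(panel), fits = NULL,
                 person_id = panel$person_id, waves = panel$waves,
                 roles = panel$roles, K = panel$K, method = method),
            class = "score_set")
}

#' Centering comparators for the benchmark study
#'
#' Produces within-person scores by one of five strategies: the latent truth
#' (`"true_score"`, simulated panels only), the two-step correlation-
#' preserving prediction (`"proposed"`), subtraction of observed
#' person-specific means (`"observed_mean"`), no centering beyond the
#' occasion means (`"none"`), or subtraction of the per-variable stable-trait
#' prediction (`"ihat"`).
#'
#' @param panel a [panel_data()]; `"true_score"` requires the simulator's
#'   attached latent truth.
#' @param method centering method.
#' @param spec [measurement_spec()] for the model-based methods.
#' @param fits optional pre-computed measurement fits (named per variable).
#' @return a `score_set`.
#' @export
apply_centering <- function(panel,
                            method = c("proposed", "true_score",
                                       "observed_mean", "none", "ihat"),
                            spec = measurement_spec(), fits = NULL) {
  method <- match.arg(method)
  ord <- .stack_layout(panel)$variables
  if (method == "proposed") {
    if (is.null(fits)) return(predict_scores(panel, spec))
    return(predict_within_scores(panel, fits))
  }
  if (method == "true_score") {
    truth <- attr(panel, "truth")
    if (is.null(truth)) .stopf("panel carries no latent truth")
    within <- truth$within[ord]
    return(.score_set(within, truth$stable[, ord, drop = FALSE], panel,
                      "true_score"))
  }
  if (method == "observed_mean") {
    within <- lapply(panel$values[ord], function(m)
      m - rowMeans(m, na.rm = TRUE))
    stable <- vapply(panel$values[ord], function(m)
      rowMeans(m, na.rm = TRUE) - mean(m, na.rm = TRUE), numeric(nrow(panel$values[[1]])))
    return(.score_set(within, stable, panel, "observed_mean"))
  }
  if (method == "none") {
    within <- lapply(panel$values[ord], function(m)
      sweep(m, 2, colMeans(m, na.rm = TRUE)))
    return(.score_set(within, NULL, panel, "none"))
  }
  # ihat: subtract occasion means and the Eq.-22-type trait prediction
  if (is.null(fits)) {
    fits <- lapply(ord, function(v)
      fit_measurement_model(panel$values[[v]], spec))
    names(fits) <- ord
  }
  within <- list(); stable <- matrix(NA_real_, nrow(panel$values[[1]]),
                                     length(ord), dimnames = list(NULL, ord))
  for (v in ord) {
    I_hat <- predict_stable_traits(panel$values[[v]], fits[[v]])
    stable[, v] <- I_hat
    within[[v]] <- sweep(panel$values[[v]], 2,
                         colMeans(panel$values[[v]], na.rm = TRUE)) - I_hat
  }
  out <- .score_set(within, stable, panel, "ihat")
  out$fits <- fits
  out
}
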