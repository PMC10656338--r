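#' Within-person coefficient set of a first-order linear panel process
#'
#' Coefficients of the first-order linear equations driving the within-person
#' scores of the outcome (Y*), treatment (A*) and confounder (L*):
#' \deqn{Y^*_k = \alpha_Y Y^*_{k-1} + \beta_Y A^*_{k-1} + \gamma_Y L^*_{k-1} + d^{(Y)}_k}
#' \deqn{A^*_k = \alpha_A Y^*_k     + \beta_A A^*_{k-1} + \gamma_A L^*_k     + d^{(A)}_k}
#' \deqn{L^*_k = \alpha_L Y^*_{k-1} + \beta_L A^*_{k-1} + \gamma_L L^*_{k-1} + d^{(L)}_k}
#' The treatment equation is contemporaneous in Y* and L* (the confounders are
#' measured before the treatment level is determined at each occasion).
#' Defaults are the benchmark values used throughout the package's simulation
#' study.
#'
#' @param alpha_Y,beta_Y,gamma_Y outcome-equation coefficients.
#' @param alpha_A,beta_A,gamma_A treatment-equation coefficients.
#' @param alpha_L,beta_L,gamma_L confounder-equation coefficients.
#' @return a named list of class `"wps_coefficients"`.
#' @export
dgp_coefficients <- function(alpha_Y = 0.40, beta_Y = 0.40, gamma_Y = 0.10,
                             alpha_A = 0.20, beta_A = 0.40, gamma_A = 0.30,
                             alpha_L = 0.20, beta_L = 0.20, gamma_L = 0.50) {
  structure(list(alpha_Y = alpha_Y, beta_Y = beta_Y, gamma_Y = gamma_Y,
                 alpha_A = alpha_A, beta_A = beta_A, gamma_A = gamma_A,
                 alpha_L = alpha_L, beta_L = beta_L, gamma_L = gamma_L),
            class = "wps_coefficients")
}

#' Analytic joint effects of treatment impulses under a linear process
#'
#' Path-tracing computation of the true coefficients \eqn{\beta_{kt}} in the
#' implied marginal model \eqn{E(Y^{*\bar a}_{k}) = \sum_t \beta_{kt} a^*_t}
#' for a first-order linear within-person process. Treatments inside the
#' intervention window are set externally, so their generating equation is
#' severed (modularity) and a unit impulse in \eqn{a^*_t} propagates only
#' through the outcome and confounder equations:
#' state \eqn{(y, l)} is seeded with \eqn{(\beta_Y, \beta_L)} at \eqn{t+1} and
#' then advanced by the 2x2 map built from \eqn{(\alpha_Y, \gamma_Y; \alpha_L,
#' \gamma_L)}. The one-step effect therefore equals the cross-lagged
#' coefficient \eqn{\beta_Y}.
#'
#' @param coefficients a [dgp_coefficients()] list (time-constant) describing
#'   the process.
#' @param K number of transitions (outcomes observed at occasions `1..K`).
#' @param window integer vector of intervened treatment occasions, a subset of
#'   `0..K-1`. Defaults to all of them.
#' @return object of class `"joint_effects"`: a list with `beta`, a list over
#'   horizons `k` of named coefficient vectors (`"a0"`, `"a1"`, ...), and
#'   `joint`, the per-horizon sums.
#' @examples
#' fx <- true_joint_effects(dgp_coefficients(), K = 4)
#' fx$beta[["4"]]   # 0.0486 0.09 0.18 0.40
#' @export
true_joint_effects <- function(coefficients = dgp_coefficients(), K,
                               window = NULL) {
  if (is.null(window)) window <- 0:(K - 1)
  if (length(window) == 0 || any(window < 0L) || any(window > K - 1L))
    .stopf("intervention window must lie within 0..%d", K - 1L)
  cf <- coefficients
  M <- matrix(c(cf$alpha_Y, cf$gamma_Y,
                cf$alpha_L, cf$gamma_L), 2, 2, byrow = TRUE)
  # impulse response of (Y*, L*) to a unit treatment impulse at time t
  beta <- vector("list", K)
  names(beta) <- as.character(seq_len(K))
  for (k in seq_len(K)) {
    tt <- window[window < k]
    if (length(tt) == 0) { beta[[k]] <- numeric(0); next }
    b <- vapply(tt, function(t0) {
      state <- c(cf$beta_Y, cf$beta_L)
      steps <- k - t0 - 1L
      for (s in seq_len(steps)) state <- as.vector(M %*% state)
      state[1]
    }, numeric(1))
    names(b) <- paste0("a", tt)
    beta[[k]] <- b
  }
  structure(list(beta = beta,
                 joint = vapply(beta, sum, numeric(1)),
                 coefficients = cf, K = K, window = window),
            class = "joint_effects")
}

#' @export
print.joint_effects <- function(x, digits = 4, ...) {
  cat("True joint effects of within-person treatment impulses\n")
  for (k in rev(seq_along(x$beta))) {
    b <- x$beta[[k]]
    if (!length(b)) next
    cat(sprintf("  E(Y*_%d): %s  (joint %.4g)\n", k,
                paste(sprintf("%s=%.*g", names(b), digits, b), collapse = " "),
                sum(b)))
  }
  invisible(x)
}

# flat named vector (beta_k_t) over horizons, the parameter order used by the
# study runner when comparing estimators against the oracle
.oracle_tau <- function(effects) {
  out <- numeric(0)
  for (k in seq_along(effects$beta)) {
    b <- effects$beta[[k]]
    if (!length(b)) next
    tt <- sub("^a", "", names(b))
    names(b) <- paste0("beta_", k, "_", tt)
    out <- c(out, b)
  }
  out
}
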