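# Symmetric-eigendecomposition matrix powers and small linear-algebra helpers.
# All covariance-type matrices in this package go through these so that
# near-singular inputs are handled the same way everywhere.

# eigenvalues below `clip` are raised to `clip` (PSD repair); used for matrix
# square roots where a strictly PSD argument is required
.sym_power <- function(C, power, clip = 1e-8) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, clip)
  e$vectors %*% (lam^power * t(e$vectors))
}

.min_eigenvalue <- function(C) {
  min(eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Repair a symmetric matrix to positive semidefiniteness
#'
#' Clips eigenvalues below `clip` up to `clip` and reassembles. A warning is
#' emitted when a materially negative eigenvalue (below `-warn_tol`) had to be
#' repaired, since that signals a finite-sample inconsistency in the input
#' (e.g. a sample covariance minus an expanded trait covariance).
#'
#' @param C symmetric matrix.
#' @param clip floor applied to eigenvalues.
#' @param warn_tol negative-eigenvalue magnitude that triggers a warning.
#' @param label character label used in the warning message.
#' @return repaired symmetric positive semidefinite matrix with attribute
#'   `"repaired"` (logical) and `"min_eigenvalue"` (the pre-repair minimum).
#' @export
psd_repair <- function(C, clip = 1e-8, warn_tol = 1e-8, label = "matrix") {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  min_eig <- min(e$values)
  repaired <- min_eig < clip
  if (min_eig < -warn_tol) {
    warning(sprintf("%s repaired to PSD (minimum eigenvalue %.3g)",
                    label, min_eig))
  }
  out <- if (repaired) {
    e$vectors %*% (pmax(e$values, clip) * t(e$vectors))
  } else {
    C
  }
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(C)
  attr(out, "repaired") <- repaired
  attr(out, "min_eigenvalue") <- min_eig
  out
}

# stationary covariance of x_k = A x_{k-1} + e_k, Var(e) = Q, by the
# vectorized discrete Lyapunov equation (I - A (x) A) vec(S) = vec(Q)
.solve_discrete_lyapunov <- function(A, Q) {
  d <- nrow(A)
  S <- solve(diag(d * d) - kronecker(A, A), as.vector(Q))
  matrix(S, d, d)
}

# sample covariance with selectable divisor; rows with NA handled pairwise
.sample_cov <- function(X, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  if (anyNA(X)) {
    S <- stats::cov(X, use = "pairwise.complete.obs")
    if (divisor == "n") S <- S * (nrow(X) - 1) / nrow(X)
    return(S)
  }
  S <- stats::cov(X)
  if (divisor == "n") S <- S * (nrow(X) - 1) / nrow(X)
  S
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
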