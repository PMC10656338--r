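#' Specification of the benchmark data-generating process
#'
#' Describes the synthetic longitudinal panel used to benchmark the two-step
#' estimator: a first-order linear vector-autoregression for the within-person
#' scores (Y*, A*, L*), additive correlated stable-trait factors, and optional
#' misspecification scenarios.
#'
#' The defaults are the benchmark study conditions: initial within-person
#' scores drawn with variances 10 and covariances 3, residual variance 5 for
#' every equation (which keeps Var(X*) near 10 at every occasion), stable
#' trait variances `phi2` with factor correlation 0.3, and temporal group
#' means fixed at zero.
#'
#' @param N number of persons.
#' @param K number of transitions; occasions are `0..K`.
#' @param phi2 stable-trait variance, scalar or length-3 `(Y, A, L)`.
#'   Benchmark values are `10/9`, `30/7` and `10`, i.e. trait shares of 10%,
#'   30% and 50% of the initial measurement variance.
#' @param factor_cor correlation between the three stable-trait factors.
#' @param coefficients a [dgp_coefficients()] object.
#' @param residual_var innovation variance of each within-person equation.
#' @param initial_var,initial_cov variance/covariance of the initial
#'   within-person scores.
#' @param mu optional list of temporal means per variable (default all zero).
#' @param scenario `"none"`, `"measurement_error"` (white measurement noise on
#'   every observation), `"accumulating_loadings"` (time-varying and
#'   cross-variable loadings from the time-invariant factors onto the outcome,
#'   so the factors are no longer pure stable traits), or
#'   `"quadratic_treatment"` (a quadratic confounder term in the treatment
#'   assignment equation).
#' @param me_fraction measurement-error variance as a fraction of the initial
#'   measurement variance `initial_var + phi2` (scenario
#'   `"measurement_error"`; 0.10 or 0.20 in the benchmark).
#' @param quad_coef coefficient on \eqn{Y^{*2}_{k}} in the treatment equation
#'   (scenario `"quadratic_treatment"`).
#' @param treatment_waves `"treatment_only"` generates the treatment at
#'   occasions `0..K-1` (its defined support as a treatment); `"all"` also
#'   measures it at occasion `K`, as in cohort panels where the treatment
#'   variable is simply observed every wave.
#' @param window intervened treatment occasions. Defaults to all occasions
#'   for `K <= 4` and to the last four (`(K-4)..(K-1)`) otherwise, so that a
#'   `K = 8` design intervenes on occasions 4..7 while controlling for the
#'   earlier treatment history.
#' @param dropout optional MAR dropout generator: a list with `intercept` and
#'   `slope`; from occasion 1 on, a person still in the study drops out (all
#'   variables missing from that occasion) with hazard
#'   `plogis(intercept + slope * Y[k-1])`. Off by default: the benchmark
#'   simulation uses complete data.
#' @param seed integer seed; the panel is bit-reproducible given `spec`.
#' @return object of class `"dgp_spec"`.
#' @export
dgp_spec <- function(N, K = 4, phi2 = 10, factor_cor = 0.3,
                     coefficients = dgp_coefficients(),
                     residual_var = c(Y = 5, A = 5, L = 5),
                     initial_var = 10, initial_cov = 3,
                     mu = NULL,
                     scenario = c("none", "measurement_error",
                                  "accumulating_loadings",
                                  "quadratic_treatment"),
                     me_fraction = 0.10, quad_coef = 0.08,
                     treatment_waves = c("treatment_only", "all"),
                     window = NULL, dropout = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  treatment_waves <- match.arg(treatment_waves)
  if (length(phi2) == 1) phi2 <- rep(phi2, 3)
  if (length(residual_var) == 1) residual_var <- rep(residual_var, 3)
  phi2 <- stats::setNames(as.numeric(phi2), c("Y", "A", "L"))
  residual_var <- stats::setNames(as.numeric(residual_var), c("Y", "A", "L"))
  if (any(residual_var <= 0)) .stopf("residual variances must be > 0")
  if (any(phi2 < 0)) .stopf("stable-trait variances must be >= 0")
  if (abs(factor_cor) >= 1) .stopf("|factor correlation| must be < 1")
  if (K < 1) .stopf("K must be >= 1")
  if (is.null(window)) window <- if (K <= 4) 0:(K - 1) else (K - 4):(K - 1)
  init <- matrix(initial_cov, 3, 3); diag(init) <- initial_var
  if (.min_eigenvalue(init) <= 0) .stopf("initial within covariance not PD")
  structure(list(N = as.integer(N), K = as.integer(K), phi2 = phi2,
                 factor_cor = factor_cor, coefficients = coefficients,
                 residual_var = residual_var, initial_cov = init,
                 mu = mu, scenario = scenario, me_fraction = me_fraction,
                 quad_coef = quad_coef, treatment_waves = treatment_waves,
                 window = as.integer(window), dropout = dropout,
                 seed = as.integer(seed)),
            class = "dgp_spec")
}

.rmvnorm <- function(n, Sigma) {
  # symmetric square-root sampler; tolerates semidefinite covariances
  # (e.g. zero trait variance)
  d <- nrow(Sigma)
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  R <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  matrix(stats::rnorm(n * d), n, d) %*% R
}

.trait_cov <- function(spec) {
  sd <- sqrt(spec$phi2)
  R <- matrix(spec$factor_cor, 3, 3); diag(R) <- 1
  R * (sd %o% sd)
}

# core generator of latent within-person scores; treatments in `fix_window`
# (if non-NULL) are set to `fix_values` and their equation is severed
.simulate_within <- function(spec, fix_window = NULL, fix_values = NULL) {
  cf <- spec$coefficients
  N <- spec$N; K <- spec$K
  Yw <- matrix(NA_real_, N, K + 1)
  Lw <- matrix(NA_real_, N, K + 1)
  K_A <- if (spec$treatment_waves == "all") K else K - 1L
  Aw <- matrix(NA_real_, N, K_A + 1)
  init <- .rmvnorm(N, spec$initial_cov)
  Yw[, 1] <- init[, 1]; Aw[, 1] <- init[, 2]; Lw[, 1] <- init[, 3]
  if (!is.null(fix_window) && 0L %in% fix_window)
    Aw[, 1] <- fix_values[[match(0L, fix_window)]]
  for (k in seq_len(K)) {
    Yw[, k + 1] <- cf$alpha_Y * Yw[, k] + cf$beta_Y * Aw[, k] +
      cf$gamma_Y * Lw[, k] +
      stats::rnorm(N, 0, sqrt(spec$residual_var["Y"]))
    Lw[, k + 1] <- cf$alpha_L * Yw[, k] + cf$beta_L * Aw[, k] +
      cf$gamma_L * Lw[, k] +
      stats::rnorm(N, 0, sqrt(spec$residual_var["L"]))
    if (k <= K_A) {
      if (!is.null(fix_window) && k %in% fix_window) {
        Aw[, k + 1] <- fix_values[[match(k, fix_window)]]
      } else {
        quad <- if (spec$scenario == "quadratic_treatment")
          spec$quad_coef * Yw[, k + 1]^2 else 0
        Aw[, k + 1] <- cf$alpha_A * Yw[, k + 1] + quad +
          cf$beta_A * Aw[, k] + cf$gamma_A * Lw[, k + 1] +
          stats::rnorm(N, 0, sqrt(spec$residual_var["A"]))
      }
    }
  }
  colnames(Yw) <- paste0("t", 0:K)
  colnames(Lw) <- paste0("t", 0:K)
  colnames(Aw) <- paste0("t", 0:K_A)
  list(Y = Yw, A = Aw, L = Lw)
}

#' Simulate a benchmark panel with attached latent truth
#'
#' Generates within-person scores by the first-order linear process of the
#' spec, draws correlated stable-trait factors independently of them, and
#' assembles measurements as `X = mu_k + I + X*` (modified under the
#' misspecification scenarios). The latent truth (stable traits and
#' within-person scores) is attached so that estimators can be benchmarked
#' against true-score centering.
#'
#' @param spec a [dgp_spec()].
#' @return a [panel_data()] object; `attr(, "truth")` holds `within` (list of
#'   latent score matrices) and `stable` (N x 3 matrix of factor scores).
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "dgp_spec"))
  set.seed(spec$seed)
  within <- .simulate_within(spec)
  I <- .rmvnorm(spec$N, .trait_cov(spec))
  colnames(I) <- c("Y", "A", "L")
  K <- spec$K
  values <- list()
  for (v in c("Y", "A", "L")) {
    X <- within[[v]]
    waves <- as.integer(sub("^t", "", colnames(X)))
    if (v == "Y" && spec$scenario == "accumulating_loadings") {
      load <- 1 + 0.5 * waves / K
      X <- X + outer(I[, "Y"], load) + 0.3 * I[, "A"] + 0.3 * I[, "L"]
    } else {
      X <- X + I[, v]
    }
    if (!is.null(spec$mu)) X <- sweep(X, 2, spec$mu[[v]][waves + 1], "+")
    if (spec$scenario == "measurement_error") {
      ev <- spec$me_fraction * (spec$initial_cov[1, 1] + spec$phi2[v])
      X <- X + matrix(stats::rnorm(length(X), 0, sqrt(ev)), nrow(X))
    }
    values[[v]] <- X
  }
  if (!is.null(spec$dropout)) {
    gone <- rep(FALSE, spec$N)
    for (k in seq_len(K)) {
      haz <- stats::plogis(spec$dropout$intercept +
                             spec$dropout$slope * values$Y[, k])
      gone <- gone | (stats::runif(spec$N) < haz)
      for (v in names(values)) {
        drop_cols <- which(as.integer(sub("^t", "", colnames(values[[v]]))) >= k)
        values[[v]][gone, drop_cols] <- NA_real_
      }
      # monotone dropout: once out, out for good
    }
  }
  panel <- panel_data(values,
                      roles = list(outcome = "Y", treatment = "A",
                                   confounders = "L"),
                      K = K)
  attr(panel, "truth") <- list(within = within, stable = I)
  attr(panel, "spec") <- spec
  panel
}

#' Counterfactual mean outcome trajectory under fixed treatments
#'
#' Monte-Carlo evaluation of \eqn{E(Y^{*\bar a}_k)}: treatments at the
#' intervened occasions are fixed at `a_values` (their generating equations
#' severed, modularity) and the within-person process is simulated forward.
#' Used as the simulation-based cross-check of [true_joint_effects()].
#'
#' @param spec a [dgp_spec()].
#' @param a_values numeric vector of fixed treatment values, one per occasion
#'   in `spec$window`.
#' @return numeric vector `E(Y*_k)`, `k = 0..K`, averaged over `spec$N`
#'   simulated persons.
#' @export
simulate_counterfactual <- function(spec, a_values) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (length(a_values) != length(spec$window))
    .stopf("need one treatment value per occasion in the window")
  set.seed(spec$seed)
  within <- .simulate_within(spec, fix_window = spec$window,
                             fix_values = as.list(a_values))
  colMeans(within$Y)
}

#' Implied stationary covariance of the within-person process
#'
#' Solves the discrete Lyapunov equation for the reduced form of the
#' within-person vector autoregression (the contemporaneous treatment equation
#' is substituted out). Reported alongside empirical moments because the
#' benchmark fixes the initial covariance at (10, 3), which is close to, but
#' not exactly, the stationary solution.
#'
#' @param spec a [dgp_spec()].
#' @return 3x3 stationary covariance of `(Y*, A*, L*)`.
#' @export
stationary_within_covariance <- function(spec) {
  cf <- spec$coefficients
  # structural: x_k = B x_k + C x_{k-1} + e_k with x = (Y*, A*, L*)
  B <- matrix(0, 3, 3)
  B[2, 1] <- cf$alpha_A; B[2, 3] <- cf$gamma_A
  C <- rbind(c(cf$alpha_Y, cf$beta_Y, cf$gamma_Y),
             c(0,          cf$beta_A, 0),
             c(cf$alpha_L, cf$beta_L, cf$gamma_L))
  G <- solve(diag(3) - B)
  A <- G %*% C
  Q <- G %*% diag(spec$residual_var) %*% t(G)
  S <- .solve_discrete_lyapunov(A, Q)
  dimnames(S) <- list(c("Y", "A", "L"), c("Y", "A", "L"))
  S
}

#' Analytic covariance path of the within-person process
#'
#' Exact wave-by-wave covariance of `(Y*, A*, L*)` implied by the spec's
#' coefficients, initial covariance and residual variances (reduced form of
#' the contemporaneous treatment equation). Because the benchmark fixes the
#' initial covariance below the stationary solution, the variances drift
#' upward with the wave; this function makes that drift explicit.
#'
#' @param spec a [dgp_spec()].
#' @return list of 3x3 covariance matrices, one per occasion `0..K`.
#' @export
implied_covariance_path <- function(spec) {
  cf <- spec$coefficients
  B <- matrix(0, 3, 3)
  B[2, 1] <- cf$alpha_A; B[2, 3] <- cf$gamma_A
  C <- rbind(c(cf$alpha_Y, cf$beta_Y, cf$gamma_Y),
             c(0,          cf$beta_A, 0),
             c(cf$alpha_L, cf$beta_L, cf$gamma_L))
  G <- solve(diag(3) - B)
  A <- G %*% C
  Q <- G %*% diag(spec$residual_var) %*% t(G)
  S <- spec$initial_cov
  dimnames(S) <- list(c("Y", "A", "L"), c("Y", "A", "L"))
  out <- vector("list", spec$K + 1)
  out[[1]] <- S
  for (k in seq_len(spec$K)) {
    S <- A %*% S %*% t(A) + Q
    dimnames(S) <- dimnames(out[[1]])
    out[[k + 1]] <- S
  }
  names(out) <- paste0("t", 0:spec$K)
  out
}

#' Share of measurement variance due to the stable trait
#'
#' @param phi2 stable-trait variance(s).
#' @param within_var within-person score variance at the same occasion.
#' @return `phi2 / (phi2 + within_var)`.
#' @export
trait_variance_share <- function(phi2, within_var = 10) {
  phi2 / (phi2 + within_var)
}
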