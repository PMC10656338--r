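#' Blip specification for a linear structural nested mean model
#'
#' The identity-link blip of treatment \eqn{A^*_l} on the later outcome
#' \eqn{Y^*_m} is \eqn{h_{l,m} = (\beta_{ml} + \sum_j \gamma_{mlj}
#' L^*_{jl}) A^*_l}: a main effect per (horizon, treatment-occasion) pair and
#' optional moderation by concurrent confounder scores. The blip vanishes at
#' the reference treatment \eqn{a^* = 0} (the person's own expected level).
#'
#' @param K number of transitions.
#' @param window intervened treatment occasions carrying blips (default: all
#'   for `K <= 4`, else the last four).
#' @param interactions character vector of confounder variable names whose
#'   concurrent scores moderate each blip (empty for main effects only).
#' @return object of class `"blip_spec"` with the parameter naming
#'   `beta_<m>_<l>` and `gamma_<m>_<l>_<confounder>`.
#' @export
blip_spec <- function(K, window = NULL, interactions = character(0)) {
  window <- window %||% (if (K <= 4) 0:(K - 1) else (K - 4):(K - 1))
  pairs <- do.call(rbind, lapply(sort(window), function(l)
    if (l + 1 <= K) data.frame(m = (l + 1):K, l = l)))
  pairs <- pairs[order(pairs$l, pairs$m), ]
  nm <- character(0)
  for (i in seq_len(nrow(pairs))) {
    nm <- c(nm, sprintf("beta_%d_%d", pairs$m[i], pairs$l[i]))
    for (j in interactions)
      nm <- c(nm, sprintf("gamma_%d_%d_%s", pairs$m[i], pairs$l[i], j))
  }
  structure(list(K = K, window = sort(window), interactions = interactions,
                 pairs = pairs, par_names = nm),
            class = "blip_spec")
}

# blip value h_{l,m} for all persons at given tau
.blip_value <- function(tau, scores, blip, l, m) {
  a <- .sc(scores, scores$roles$treatment, l)
  eff <- tau[sprintf("beta_%d_%d", m, l)]
  out <- rep(eff, length(a))
  for (j in blip$interactions) {
    lj <- .sc(scores, j, l)
    out <- out + tau[sprintf("gamma_%d_%d_%s", m, l, j)] * lj
  }
  out * a
}

#' Blip-removed outcome transformation
#'
#' For each intervened occasion \eqn{l}, the vector \eqn{U^*_{il}(\tau)} with
#' components \eqn{Y^*_{im} - \sum_{l'=l}^{m-1} h_{l',m}} for
#' \eqn{m = l+1, \dots, K}: the outcomes with the modeled effects of
#' treatments from \eqn{l} onward removed. At the true \eqn{\tau} its
#' conditional mean equals that of the treatment-free (reference) regime from
#' \eqn{l} on; at \eqn{\tau = 0} it is the raw outcome scores.
#'
#' @param tau named parameter vector (see [blip_spec()]).
#' @param scores a `score_set`.
#' @param blip a [blip_spec()].
#' @return named list over occasions `l`; each element a persons x horizons
#'   matrix with columns `m<m>`.
#' @export
transform_U <- function(tau, scores, blip) {
  Y <- scores$roles$outcome
  out <- list()
  for (l in blip$window) {
    ms <- (l + 1):blip$K
    n <- nrow(scores$within[[Y]])
    U <- vapply(ms, function(m) {
      u <- .sc(scores, Y, m)
      for (lp in blip$window[blip$window >= l & blip$window <= m - 1])
        u <- u - .blip_value(tau, scores, blip, lp, m)
      u
    }, numeric(n))
    if (!is.matrix(U)) U <- matrix(U, nrow = n)
    colnames(U) <- paste0("m", ms)
    out[[paste0("t", l)]] <- U
  }
  out
}

#' Nuisance models for G-estimation
#'
#' Model A is the linear-normal treatment model
#' \eqn{f(A^*_l \mid Y^*_l, A^*_{l-1}, L^*_l; \eta)} at each intervened
#' occasion; model B is the linear model for the conditional mean of
#' \eqn{U^*_l(\tau)} given the same first-order history. Model B depends on
#' \eqn{\tau} and is refitted as \eqn{\tau} updates during G-estimation.
#' Either model can be deliberately reduced (or enriched with the squared
#' outcome score) to study double robustness.
#'
#' @param scores a `score_set`.
#' @param blip a [blip_spec()].
#' @param tau parameter value at which model B is evaluated (default all 0).
#' @param a_quadratic include the squared concurrent outcome in model A.
#' @param b_terms regressors for model B: `"full"` (concurrent outcome and
#'   confounder scores plus lagged treatment) or `"reduced"` (lagged
#'   treatment only; a deliberately misspecified conditional-mean model).
#' @return list with `model_A` (per occasion: `coef`, `sigma`, `n`) and
#'   `model_B` (per occasion and horizon: coefficient vector).
#' @export
fit_nuisance_models <- function(scores, blip = blip_spec(scores$K),
                                tau = NULL, a_quadratic = FALSE,
                                b_terms = c("full", "reduced")) {
  b_terms <- match.arg(b_terms)
  if (is.null(tau))
    tau <- stats::setNames(rep(0, length(blip$par_names)), blip$par_names)
  A <- scores$roles$treatment
  model_A <- lapply(blip$window, function(l) {
    X <- .history_frame(scores, l, quadratic = a_quadratic)
    .fit_density_model(.sc(scores, A, l), X)
  })
  names(model_A) <- paste0("t", blip$window)
  U <- transform_U(tau, scores, blip)
  model_B <- lapply(blip$window, function(l) {
    X <- .b_frame(scores, l, b_terms)
    apply(U[[paste0("t", l)]], 2, function(u) .fit_density_model(u, X)$coef)
  })
  names(model_B) <- paste0("t", blip$window)
  list(model_A = model_A, model_B = model_B)
}

.b_frame <- function(scores, l, b_terms) {
  X <- .history_frame(scores, l, quadratic = FALSE)
  if (b_terms == "reduced") X <- X[, intersect("A_lag", names(X)), drop = FALSE]
  X
}

#' G-estimation of the linear structural nested mean model
#'
#' Solves the estimating equations that set to zero, at every intervened
#' occasion \eqn{l} and horizon \eqn{m}, the empirical conditional covariance
#' between the treatment residual \eqn{A^*_l - E(A^*_l \mid \text{history})}
#' (times the moderating confounder score for interaction parameters) and the
#' model-B residual of \eqn{U^*_{l,m}(\tau)}, weighted by the reciprocal
#' residual variance of each component (the locally efficient choice under
#' homoscedasticity: the derivative \eqn{\partial U/\partial\tau} of the
#' identity-link linear blip is closed-form, and its conditional expectation
#' substitutes the model-A mean for the current treatment). The solver is
#' Newton-Raphson with a central-difference Jacobian; the equations are
#' affine in \eqn{\tau} for the linear blip, so convergence is immediate, and
#' the variance weights are updated in a short outer loop. The estimator is
#' doubly robust: consistent when either model A or model B is correctly
#' specified.
#'
#' @param scores a `score_set`.
#' @param blip a [blip_spec()].
#' @param a_quadratic,b_terms nuisance-model specification, see
#'   [fit_nuisance_models()].
#' @param tol convergence tolerance on the estimating-function norm.
#' @param max_iter Newton iterations per variance-weight update.
#' @param v_updates outer updates of the variance weights.
#' @return object of class `"snmm_fit"`: `tau` (named), `U_values` at the
#'   solution, `model_A`, `model_B`, `V`, `converged`, `iterations`,
#'   `residual_norm`.
#' @export
g_estimate <- function(scores, blip = blip_spec(scores$K),
                       a_quadratic = FALSE, b_terms = "full",
                       tol = 1e-10, max_iter = 100, v_updates = 3) {
  A <- scores$roles$treatment
  p <- length(blip$par_names)
  # treatment residuals per occasion (model A is free of tau: fit once)
  nuis <- fit_nuisance_models(scores, blip, a_quadratic = a_quadratic,
                              b_terms = b_terms)
  dA <- lapply(blip$window, function(l) {
    a <- .sc(scores, A, l)
    X <- .history_frame(scores, l, quadratic = a_quadratic)
    a - .density_mean(nuis$model_A[[paste0("t", l)]], X, length(a))
  })
  names(dA) <- paste0("t", blip$window)
  # pre-factor model-B designs
  B_qr <- lapply(blip$window, function(l) {
    Xm <- .design_matrix(.b_frame(scores, l, b_terms), length(dA[[1]]))
    list(X = Xm)
  })
  names(B_qr) <- paste0("t", blip$window)
  moments <- function(tau, V) {
    tau <- stats::setNames(tau, blip$par_names)
    U <- transform_U(tau, scores, blip)
    g <- stats::setNames(numeric(p), blip$par_names)
    Vout <- list()
    for (l in blip$window) {
      key <- paste0("t", l)
      Ul <- U[[key]]
      Xm <- B_qr[[key]]$X
      d <- dA[[key]]
      Vl <- stats::setNames(numeric(ncol(Ul)), colnames(Ul))
      for (j in seq_len(ncol(Ul))) {
        m <- as.integer(sub("^m", "", colnames(Ul)[j]))
        u <- Ul[, j]
        ok <- stats::complete.cases(cbind(u, Xm, d))
        cf <- qr.coef(qr(Xm[ok, , drop = FALSE]), u[ok])
        rU <- u[ok] - drop(Xm[ok, , drop = FALSE] %*% cf)
        vv <- if (is.null(V)) 1 else V[[key]][j]
        Vl[j] <- stats::var(rU)
        g[sprintf("beta_%d_%d", m, l)] <- mean(d[ok] * rU) / vv
        for (cn in blip$interactions) {
          lj <- .sc(scores, cn, l)[ok]
          g[sprintf("gamma_%d_%d_%s", m, l, cn)] <- mean(d[ok] * lj * rU) / vv
        }
      }
      Vout[[key]] <- Vl
    }
    attr(g, "V") <- Vout
    g
  }
  tau <- stats::setNames(rep(0, p), blip$par_names)
  # variance weights initialized at tau = 0 and held fixed within each Newton
  # loop: the estimating function is then affine in tau for the linear blip
  V <- attr(moments(tau, NULL), "V")
  iterations <- 0L
  converged <- FALSE
  for (vu in seq_len(v_updates)) {
    for (it in seq_len(max_iter)) {
      iterations <- iterations + 1L
      g0 <- moments(tau, V)
      if (sqrt(sum(g0^2)) < tol) { converged <- TRUE; break }
      J <- matrix(0, p, p, dimnames = list(blip$par_names, blip$par_names))
      for (j in seq_len(p)) {
        h <- 1e-6 * max(1, abs(tau[j]))
        tp <- tau; tp[j] <- tp[j] + h
        tm <- tau; tm[j] <- tm[j] - h
        J[, j] <- (moments(tp, V) - moments(tm, V)) / (2 * h)
      }
      step <- tryCatch(solve(J, g0), error = function(e) {
        .stopf("singular Jacobian in G-estimation (rcond %.2e)", rcond(J))
      })
      tau <- tau - step
      if (sqrt(sum(step^2)) < 1e-12) break
    }
    g0 <- moments(tau, V)
    V <- attr(g0, "V")   # update variance weights at the current solution
    converged <- sqrt(sum(g0^2)) < tol
  }
  g_final <- moments(tau, V)
  if (!converged && sqrt(sum(g_final^2)) >= tol)
    .stopf("G-estimation did not converge (residual norm %.3e after %d iterations)",
           sqrt(sum(g_final^2)), iterations)
  nuis_final <- fit_nuisance_models(scores, blip, tau = tau,
                                    a_quadratic = a_quadratic,
                                    b_terms = b_terms)
  structure(list(tau = tau, blip = blip,
                 U_values = transform_U(tau, scores, blip),
                 model_A = nuis_final$model_A, model_B = nuis_final$model_B,
                 V = V, converged = TRUE, iterations = iterations,
                 residual_norm = sqrt(sum(g_final^2))),
            class = "snmm_fit")
}

#' @export
print.snmm_fit <- function(x, ...) {
  cat("SNMM (G-estimation) blip parameter estimates\n")
  print(round(x$tau, 4))
  cat(sprintf("  converged in %d iteration(s); estimating-function norm %.2e\n",
              x$iterations, x$residual_norm))
  if (!is.null(x$se)) { cat("  bootstrap SEs:\n"); print(round(x$se, 4)) }
  invisible(x)
}

#' Joint effect of a one-unit treatment-history increment
#'
#' Sums the blip effects of raising every intervened treatment before the
#' horizon by one unit, evaluated at supplied confounder score values (the
#' moderated effect); with all interaction parameters zero it reduces to
#' \eqn{\sum_t \beta_{kt}}.
#'
#' @param fit an `snmm_fit`.
#' @param horizon outcome horizon \eqn{k}.
#' @param confounder_values named list (per moderating confounder) of score
#'   values indexed by intervened occasion, e.g. `list(L = c("0" = .2))`.
#' @return scalar joint effect.
#' @export
joint_effect <- function(fit, horizon, confounder_values = NULL) {
  blip <- fit$blip
  if (horizon < 1 || horizon > blip$K) .stopf("horizon outside fitted range")
  tt <- blip$window[blip$window <= horizon - 1]
  if (!length(tt)) return(0)
  total <- 0
  for (l in tt) {
    eff <- fit$tau[sprintf("beta_%d_%d", horizon, l)]
    for (j in blip$interactions) {
      lv <- confounder_values[[j]][as.character(l)]
      if (is.null(lv) || is.na(lv))
        .stopf("no value supplied for confounder %s at occasion %d", j, l)
      eff <- eff + fit$tau[sprintf("gamma_%d_%d_%s", horizon, l, j)] * lv
    }
    total <- total + eff
  }
  unname(total)
}

#' One-call SNMM with optional person-level bootstrap
#'
#' @param scores a `score_set`.
#' @param blip a [blip_spec()] (default: main effects at every intervened
#'   occasion).
#' @param nboot bootstrap replicates for standard errors (0 = none; B = 500
#'   recommended when uncertainty is needed).
#' @param ... passed to [g_estimate()].
#' @return an `snmm_fit`, with `se` when `nboot > 0`.
#' @export
snmm <- function(scores, blip = NULL, nboot = 0, ...) {
  blip <- blip %||% blip_spec(scores$K, window = .default_window(scores))
  fit <- g_estimate(scores, blip, ...)
  if (nboot > 0) {
    n <- length(scores$person_id)
    boots <- vapply(seq_len(nboot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(g_estimate(.subset_scores(scores, idx), blip, ...)$tau,
                      error = function(e) rep(NA_real_, length(fit$tau)))
      est[names(fit$tau)]
    }, numeric(length(fit$tau)))
    fit$se <- apply(matrix(boots, nrow = length(fit$tau),
                           dimnames = list(names(fit$tau), NULL)),
                    1, stats::sd, na.rm = TRUE)
    fit$nboot <- nboot
  }
  fit
}
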