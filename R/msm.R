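# ---- step-2 helpers shared by the MSM and SNMM fitters ----

# score column for variable `v` at occasion k, or NULL when not on its grid
.sc <- function(scores, v, k) {
  m <- scores$within[[v]]
  j <- match(paste0("t", k), colnames(m))
  if (is.na(j)) NULL else m[, j]
}

.treat_occasions <- function(scores) {
  intersect(scores$waves[[scores$roles$treatment]], 0:(scores$K - 1))
}

.default_window <- function(scores) {
  tw <- .treat_occasions(scores)
  if (scores$K <= 4) tw else tw[tw >= scores$K - 4]
}

# regressor frame at occasion t for the treatment/nuisance models: lagged
# treatment, concurrent outcome and confounder scores (the outcome is part of
# the confounder set), optionally the squared concurrent outcome
.history_frame <- function(scores, t, quadratic = FALSE) {
  df <- list()
  a_lag <- if (t >= 1) .sc(scores, scores$roles$treatment, t - 1) else NULL
  if (!is.null(a_lag)) df$A_lag <- a_lag
  y <- .sc(scores, scores$roles$outcome, t)
  if (!is.null(y)) {
    df$Y <- y
    if (quadratic) df$Y_sq <- y^2
  }
  for (l in scores$roles$confounders) {
    x <- .sc(scores, l, t)
    if (!is.null(x)) df[[paste0("L_", l)]] <- x
  }
  as.data.frame(df)
}

.design_matrix <- function(X, n) {
  Xm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (length(X) && ncol(X) > 0) Xm <- cbind(Xm, as.matrix(X))
  Xm
}

.fit_density_model <- function(y, X) {
  Xm <- .design_matrix(X, length(y))
  ok <- stats::complete.cases(cbind(y, Xm))
  Xm <- Xm[ok, , drop = FALSE]
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) .stopf("degenerate regressors in treatment model")
  cf <- qr.coef(qrX, y[ok])
  res <- y[ok] - drop(Xm %*% cf)
  list(coef = cf, sigma = sqrt(sum(res^2) / length(res)), n = sum(ok))
}

.density_mean <- function(model, X, n) {
  Xm <- .design_matrix(X, n)
  drop(Xm %*% model$coef[colnames(Xm)])
}

#' Treatment-assignment models for continuous treatments
#'
#' Fits, at every treatment occasion, the normal linear models for the
#' stabilized-weight numerator \eqn{f(A^*_t \mid A^*_{t-1})} and denominator
#' \eqn{f(A^*_t \mid A^*_{t-1}, Y^*_t, L^*_t)} (the outcome score is part of
#' the confounder history). At the earliest occasion the treatment-lag term
#' is empty, so the numerator is the marginal normal density.
#'
#' @param scores a `score_set`.
#' @param occasions treatment occasions to model (default: all).
#' @param quadratic include the squared concurrent outcome score in the
#'   denominator model (correct specification under a quadratic treatment
#'   assignment process).
#' @return object of class `"treatment_models"`: per-occasion lists with
#'   `numerator` and `denominator` (`coef`, `sigma`, `n`).
#' @export
fit_treatment_models <- function(scores, occasions = NULL, quadratic = FALSE) {
  occasions <- occasions %||% .treat_occasions(scores)
  A <- scores$roles$treatment
  out <- lapply(occasions, function(t) {
    a <- .sc(scores, A, t)
    if (is.null(a)) .stopf("treatment has no score at occasion %d", t)
    den_X <- .history_frame(scores, t, quadratic = quadratic)
    num_X <- den_X[, intersect("A_lag", names(den_X)), drop = FALSE]
    list(occasion = t,
         numerator = .fit_density_model(a, num_X),
         denominator = .fit_density_model(a, den_X))
  })
  names(out) <- paste0("t", occasions)
  structure(list(models = out, occasions = occasions, quadratic = quadratic),
            class = "treatment_models")
}

#' Stabilized inverse-probability weights for continuous treatments
#'
#' Per person and horizon \eqn{k}, the product over weighted treatment
#' occasions \eqn{t \le k-1} of the normal-density ratios
#' \deqn{w_{ik} = \prod_t \frac{f(A^*_{it} \mid A^*_{i(t-1)})}
#'   {f(A^*_{it} \mid A^*_{i(t-1)}, Y^*_{it}, L^*_{it})}.}
#' By default every intervened occasion is weighted, including the earliest
#' one (whose numerator is the marginal density); `include_initial = FALSE`
#' leaves the earliest intervened treatment unweighted, the convention under
#' which \eqn{w_{i1} = 1} as an empty product. Under a correctly specified
#' denominator the weights have mean close to 1.
#'
#' @param models a [fit_treatment_models()] result.
#' @param scores a `score_set`.
#' @param horizons outcome horizons (default `1..K`).
#' @param window intervened treatment occasions (default: all treatment
#'   occasions for `K <= 4`, else the last four).
#' @param include_initial weight the earliest occasion of the window.
#' @param truncate optional length-2 probability vector; weights are
#'   truncated to these quantiles per horizon (off by default) and the
#'   truncation is recorded in attribute `"truncated"`.
#' @return persons x horizons matrix of weights (columns named by horizon).
#' @export
stabilized_weights <- function(models, scores, horizons = NULL, window = NULL,
                               include_initial = TRUE, truncate = NULL) {
  horizons <- horizons %||% seq_len(scores$K)
  window <- window %||% .default_window(scores)
  A <- scores$roles$treatment
  n <- nrow(scores$within[[A]])
  wocc <- sort(window)
  if (!include_initial) wocc <- wocc[-1]
  ratio <- matrix(1, n, length(wocc),
                  dimnames = list(NULL, paste0("t", wocc)))
  for (j in seq_along(wocc)) {
    t <- wocc[j]
    mod <- models$models[[paste0("t", t)]]
    if (is.null(mod)) .stopf("no treatment model for occasion %d", t)
    a <- .sc(scores, A, t)
    den_X <- .history_frame(scores, t, quadratic = models$quadratic)
    num_X <- den_X[, intersect("A_lag", names(den_X)), drop = FALSE]
    f_num <- stats::dnorm(a, .density_mean(mod$numerator, num_X, n),
                          mod$numerator$sigma)
    f_den <- stats::dnorm(a, .density_mean(mod$denominator, den_X, n),
                          mod$denominator$sigma)
    bad <- which(!is.na(f_den) & f_den < 1e-300)
    if (length(bad))
      .stopf("treatment density underflow (positivity) for person %d at occasion %d",
             bad[1], t)
    ratio[, j] <- f_num / f_den
  }
  W <- matrix(1, n, length(horizons),
              dimnames = list(NULL, paste0("k", horizons)))
  for (h in seq_along(horizons)) {
    use <- wocc[wocc <= horizons[h] - 1]
    if (length(use))
      W[, h] <- apply(ratio[, paste0("t", use), drop = FALSE], 1, prod)
  }
  truncated <- FALSE
  if (!is.null(truncate)) {
    for (h in seq_len(ncol(W))) {
      qs <- stats::quantile(W[, h], truncate, na.rm = TRUE)
      W[, h] <- pmin(pmax(W[, h], qs[1]), qs[2])
    }
    truncated <- TRUE
  }
  attr(W, "truncated") <- truncated
  attr(W, "window") <- window
  W
}

#' Marginal structural model for joint treatment effects
#'
#' Weighted least squares, per horizon \eqn{k}, of the outcome score
#' \eqn{Y^*_k} on the intervened treatment history (coefficients
#' \eqn{\beta_{kt}}), with any controlled (non-intervened) earlier treatments
#' entered as covariates. A rank-deficient design (as arises under
#' observed-mean centering, whose centered treatment columns sum to zero) is
#' flagged and the affected coefficients reported unavailable.
#'
#' @param scores a `score_set`.
#' @param weights persons x horizons matrix from [stabilized_weights()] (or
#'   all ones for unweighted estimation).
#' @param horizons outcome horizons (default `1..K`).
#' @param window intervened treatment occasions.
#' @param controlled treatment occasions entered as covariates (default: all
#'   treatment occasions outside the window).
#' @return object of class `"msm_fit"`: `tau` (named vector `beta_<k>_<t>`
#'   over intervened coefficients, `NA` when unavailable), `joint` per-horizon
#'   coefficient sums, `rank_deficient` per-horizon flags, `weights` summary.
#' @export
fit_msm <- function(scores, weights, horizons = NULL, window = NULL,
                    controlled = NULL) {
  horizons <- horizons %||% seq_len(scores$K)
  window <- window %||% .default_window(scores)
  controlled <- controlled %||% setdiff(.treat_occasions(scores), window)
  A <- scores$roles$treatment
  Y <- scores$roles$outcome
  tau <- numeric(0); rankdef <- logical(0); joint <- numeric(0)
  for (k in horizons) {
    y <- .sc(scores, Y, k)
    if (is.null(y)) .stopf("no outcome score at horizon %d", k)
    iv <- sort(window[window <= k - 1])
    ct <- sort(controlled[controlled <= k - 1])
    if (!length(iv)) next
    X <- cbind(`(Intercept)` = 1,
               do.call(cbind, c(
                 stats::setNames(lapply(iv, function(t) .sc(scores, A, t)),
                                 paste0("beta_", k, "_", iv)),
                 if (length(ct))
                   stats::setNames(lapply(ct, function(t) .sc(scores, A, t)),
                                   paste0("ctrl_", ct)))))
    w <- weights[, paste0("k", k)]
    ok <- stats::complete.cases(cbind(y, X, w))
    if (!any(ok)) .stopf("no usable observations at horizon %d", k)
    fit <- stats::lm.wfit(X[ok, , drop = FALSE], y[ok], w[ok])
    cf <- fit$coefficients
    kd <- anyNA(cf[paste0("beta_", k, "_", iv)]) || fit$rank < ncol(X)
    b <- cf[paste0("beta_", k, "_", iv)]
    if (kd) b[] <- NA_real_  # aliased design: joint effects not identified
    tau <- c(tau, b)
    rankdef <- c(rankdef, stats::setNames(kd, paste0("k", k)))
    joint <- c(joint, stats::setNames(sum(b), paste0("k", k)))
  }
  structure(list(tau = tau, joint = joint, rank_deficient = rankdef,
                 horizons = horizons, window = window, controlled = controlled,
                 mean_weight = colMeans(weights, na.rm = TRUE)),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("MSM (stabilized IPW) joint-effect estimates\n")
  print(round(x$tau, 4))
  if (any(x$rank_deficient))
    cat("  rank-deficient horizons:",
        paste(names(which(x$rank_deficient)), collapse = ", "),
        "(coefficients unavailable)\n")
  if (!is.null(x$se)) {
    cat("  bootstrap SEs:\n"); print(round(x$se, 4))
  }
  invisible(x)
}

#' One-call MSM with optional person-level bootstrap
#'
#' Convenience wrapper: treatment models, stabilized weights and the weighted
#' regression in one step, with nonparametric person-level bootstrap standard
#' errors on request (B = 500 is a reasonable default when uncertainty is
#' needed; the Monte-Carlo study runs with `nboot = 0`).
#'
#' @param scores a `score_set`.
#' @param horizons,window,controlled see [fit_msm()].
#' @param quadratic,include_initial,truncate see [fit_treatment_models()] and
#'   [stabilized_weights()].
#' @param nboot bootstrap replicates (0 = no standard errors).
#' @return an `msm_fit`, with `se` when `nboot > 0`.
#' @export
msm <- function(scores, horizons = NULL, window = NULL, controlled = NULL,
                quadratic = FALSE, include_initial = TRUE, truncate = NULL,
                nboot = 0) {
  run <- function(sc) {
    tm <- fit_treatment_models(sc, quadratic = quadratic)
    w <- stabilized_weights(tm, sc, horizons = horizons, window = window,
                            include_initial = include_initial,
                            truncate = truncate)
    fit_msm(sc, w, horizons = horizons, window = window,
            controlled = controlled)
  }
  fit <- run(scores)
  if (nboot > 0) {
    n <- length(scores$person_id)
    boots <- vapply(seq_len(nboot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(run(.subset_scores(scores, idx))$tau,
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

.subset_scores <- function(scores, idx) {
  scores$within <- lapply(scores$within, function(m) m[idx, , drop = FALSE])
  if (!is.null(scores$stable))
    scores$stable <- scores$stable[idx, , drop = FALSE]
  scores$person_id <- scores$person_id[idx]
  scores
}
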