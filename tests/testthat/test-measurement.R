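test_that("implied covariance matches the hand-computed AR(1) recursion", {
  # p = 3, theta = (v0, a1, a2, s1, s2): psi filled by the lag recursion
  theta <- c(2, 0.5, 0.3, 1, 0.8)
  psi <- implied_covariance(0, theta, measurement_spec(), p = 3, what = "psi")
  by_hand <- matrix(c(2.0, 1.0,  0.30,
                      1.0, 1.5,  0.45,
                      0.3, 0.45, 0.935), 3, 3)
  expect_equal(psi, by_hand, tolerance = 1e-12)
  sig <- implied_covariance(1.5, theta, measurement_spec(), p = 3)
  expect_equal(sig, by_hand + 1.5, tolerance = 1e-12)
  expect_identical(sig, t(sig))
})

test_that("zero AR coefficients give a diagonal within-covariance", {
  theta <- c(3, 0, 0, 0, 2, 2, 2)
  psi <- implied_covariance(0, theta, measurement_spec(), p = 4, what = "psi")
  expect_equal(psi, diag(c(3, 2, 2, 2)), tolerance = 1e-14)
})

test_that("parameters are recovered on model-true data", {
  # trait variance 10 over a stationary AR(1) within process (a=.5, var 10)
  X <- sim_measurement_true(5000, 5, phi2 = 10, v = 10, a = 0.5, seed = 2)
  fit <- fit_measurement_model(X, measurement_spec())
  expect_true(fit$converged)
  expect_false(fit$improper)
  expect_equal(fit$phi2, 10, tolerance = 0.12)
  expect_equal(unname(fit$theta["v0"]), 10, tolerance = 0.12)
  expect_equal(unname(fit$theta[paste0("a", 1:4)]), rep(0.5, 4),
               tolerance = 0.2)
  # attained likelihood is at least that of the generating parameters
  S <- fit$sample_cov
  code <- wpscausal:::.structure_code("ar1_timevarying")
  F_true <- wpscausal:::cov_ml_objective(c(10, 10, rep(0.5, 4), rep(7.5, 4)),
                                         S, code)
  F_fit <- wpscausal:::cov_ml_objective(c(fit$phi2, fit$theta_full), S, code)
  expect_lte(F_fit, F_true + 1e-6)
  # stationary structure on the same data
  fit2 <- fit_measurement_model(X, measurement_spec("ar1_stationary"))
  expect_equal(fit2$phi2, 10, tolerance = 0.12)
  expect_equal(unname(fit2$theta["a"]), 0.5, tolerance = 0.05)
  expect_equal(unname(fit2$theta["s"]), 7.5, tolerance = 0.4)
})

test_that("bias shrinks with sample size on model-true data", {
  err <- sapply(c(500, 5000), function(n) {
    est <- sapply(1:4, function(r) {
      X <- sim_measurement_true(n, 4, phi2 = 4, v = 8, a = 0.4,
                                seed = 100 + r)
      fit_measurement_model(X, measurement_spec())$phi2
    })
    abs(mean(est) - 4)
  })
  expect_lt(err[2], max(err[1], 0.15))
})

test_that("a trait-free process drives the trait variance to zero", {
  X <- sim_measurement_true(5000, 4, phi2 = 0, v = 10, a = 0.5, seed = 9)
  fit <- fit_measurement_model(X, measurement_spec())
  expect_lte(fit$phi2, 0.05)
})

test_that("negative variance estimates are flagged improper", {
  # within-covariance with NEGATIVE long-lag dependence forces phi2 < 0
  set.seed(12)
  p <- 4
  R <- diag(p); R[abs(row(R) - col(R)) >= 2] <- -0.25
  X <- matrix(rnorm(3000 * p), 3000, p) %*% chol(10 * R)
  fit <- fit_measurement_model(X, measurement_spec())
  expect_true(fit$improper)
  expect_lt(fit$phi2, 0)
})

test_that("FIML and complete-case agree on complete data", {
  X <- sim_measurement_true(400, 4, phi2 = 3, seed = 33)
  f1 <- fit_measurement_model(X, measurement_spec(missing = "fiml"))
  f2 <- fit_measurement_model(X, measurement_spec(missing = "complete_case"))
  expect_equal(f1$phi2, f2$phi2, tolerance = 1e-6)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-5)
})

test_that("FIML uses partially observed rows", {
  set.seed(44)
  X <- sim_measurement_true(1500, 4, phi2 = 4, seed = 44)
  Xm <- X
  drop_idx <- sample(nrow(X), 500)
  Xm[drop_idx, 4] <- NA   # MCAR deletion of the last occasion
  fit <- fit_measurement_model(Xm, measurement_spec(missing = "fiml"))
  full <- fit_measurement_model(X, measurement_spec())
  expect_equal(fit$phi2, full$phi2, tolerance = 0.5)
  expect_false(fit$improper)
})

test_that("fit indices behave at their defining points", {
  X <- sim_measurement_true(800, 4, phi2 = 4, seed = 5)
  fit <- fit_measurement_model(X, measurement_spec())
  fi <- fit$fit_indices
  expect_true(fi["cfi"] >= 0 && fi["cfi"] <= 1)
  expect_gte(fi["rmsea"], 0)
  expect_gte(fi["srmr"], 0)
  # implied covariance equal to S: perfect fit
  S <- fit$sample_cov
  perfect <- list(sigma = S, mu = fit$sample_mean, theta = numeric(9),
                  sample_cov = S, sample_mean = fit$sample_mean, n = 800)
  fp <- fit_indices(perfect)
  expect_equal(unname(fp), c(1, 0, 0), tolerance = 1e-10)
  # baseline evaluated against itself: CFI = 0 by convention
  base <- list(sigma = diag(diag(S)), mu = fit$sample_mean,
               theta = numeric(0), sample_cov = S,
               sample_mean = fit$sample_mean, n = 800)
  # CFI = 0 whenever the model fits no better than the baseline
  base$theta <- numeric(6)
  fb <- fit_indices(base)
  expect_equal(unname(fb["cfi"]), 0, tolerance = 1e-10)
})

test_that("SRMR equals the hand-computed standardized residual RMS", {
  S <- matrix(c(4, 2, 0.5,
                2, 9, 1,
                0.5, 1, 1), 3, 3)
  Sigma <- S; Sigma[1, 2] <- Sigma[2, 1] <- 1.4
  mock <- list(sigma = Sigma, mu = c(0, 0, 0), theta = numeric(2),
               sample_cov = S, sample_mean = c(0, 0, 0), n = 500)
  # one off-diagonal residual of 0.6 standardized by sd1*sd2 = 6, over the
  # 6 unique entries: sqrt((0.6/6)^2 / 6)
  expect_equal(unname(fit_indices(mock)["srmr"]), 0.1 / sqrt(6),
               tolerance = 1e-12)
})

test_that("estimation fails informatively on impossible input", {
  expect_error(fit_measurement_model(matrix(1:3, 1, 3),
                                     measurement_spec("ar1_stationary")),
               "persons")
})

test_that("GLS estimation agrees with ML at large n on model-true data", {
  X <- sim_measurement_true(4000, 4, phi2 = 4, seed = 87)
  ml <- fit_measurement_model(X, measurement_spec())
  gls <- fit_measurement_model(X, measurement_spec(estimator = "gls"))
  expect_equal(gls$phi2, ml$phi2, tolerance = 0.2)
  expect_equal(unname(gls$theta["v0"]), unname(ml$theta["v0"]),
               tolerance = 0.3)
})

test_that("compound symmetry and toeplitz structures reproduce their shapes", {
  psi_cs <- implied_covariance(0, c(5, 1.2), measurement_spec("compound_symmetry"),
                               p = 4, what = "psi")
  expect_true(all(psi_cs[upper.tri(psi_cs)] == 1.2) && all(diag(psi_cs) == 5))
  psi_tp <- implied_covariance(0, c(5, 0.5, 0.2, 0.1),
                               measurement_spec("toeplitz"), p = 4,
                               what = "psi")
  expect_equal(psi_tp[1, 2], 2.5)
  expect_equal(psi_tp[1, 4], 0.5)
  expect_equal(psi_tp[2, 4], 1.0)
})
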