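test_that("the U transform removes blips as in the worked example", {
  sc <- make_scores(Y = rbind(c(NA, 2, 3)), A = rbind(c(1, 0.5, NA)),
                    L = rbind(c(0.2, 0.4, NA)), K = 2)
  blip <- blip_spec(2, interactions = "L")
  tau <- c(beta_1_0 = 0.3, gamma_1_0_L = 0, beta_2_0 = 0.5, gamma_2_0_L = 0,
           beta_2_1 = 1, gamma_2_1_L = 0)
  U <- transform_U(tau, sc, blip)
  expect_equal(unname(U$t1[1, "m2"]), 3 - 1 * 0.5)
  expect_equal(unname(U$t0[1, "m1"]), 2 - 0.3 * 1)
  expect_equal(unname(U$t0[1, "m2"]), 3 - 0.5 - 0.5 * 1)
  # nonzero interaction parameters engage the confounder scores
  tau2 <- tau; tau2["gamma_2_1_L"] <- 2
  U2 <- transform_U(tau2, sc, blip)
  expect_equal(unname(U2$t1[1, "m2"]), 3 - (1 + 2 * 0.4) * 0.5)
  # tau = 0 returns the raw outcomes
  U0 <- transform_U(tau * 0, sc, blip)
  expect_equal(unname(U0$t0[1, ]), c(2, 3))
})

test_that("E(U) at the true parameters matches the treatment-free regime", {
  s <- dgp_spec(N = 20000, K = 2, phi2 = 10, seed = 63)
  sc <- apply_centering(simulate_panel(s), "true_score")
  blip <- blip_spec(2)
  tau <- c(beta_1_0 = 0.4, beta_2_0 = 0.18, beta_2_1 = 0.4)
  U <- transform_U(tau, sc, blip)
  # under never-deviating treatment the within-outcome mean is zero
  expect_lt(max(abs(colMeans(U$t0))), 0.08)
})

test_that("nuisance model A recovers the assignment equation", {
  s <- dgp_spec(N = 20000, K = 4, phi2 = 10, seed = 64)
  sc <- apply_centering(simulate_panel(s), "true_score")
  nuis <- fit_nuisance_models(sc, blip_spec(4))
  cf <- nuis$model_A[["t2"]]$coef
  expect_lt(max(abs(cf[c("Y", "A_lag", "L_L")] - c(0.2, 0.4, 0.3))), 0.03)
  # white-noise scores: intercept-only structure
  set.seed(65)
  scw <- make_scores(matrix(rnorm(3000 * 5), 3000), matrix(rnorm(3000 * 4), 3000),
                     matrix(rnorm(3000 * 5), 3000), K = 4)
  nw <- fit_nuisance_models(scw, blip_spec(4))
  expect_lt(max(abs(nw$model_A[["t2"]]$coef[-1])), 0.06)
})

test_that("G-estimation recovers the benchmark parameter pattern", {
  s <- dgp_spec(N = 5000, K = 4, phi2 = 10, seed = 42)
  sc <- apply_centering(simulate_panel(s), "true_score")
  fit <- snmm(sc)
  truth <- wpscausal:::.oracle_tau(true_joint_effects(K = 4))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$tau[names(truth)] - truth)), 0.06)
  # the estimating function is solved to numerical zero
  expect_lt(fit$residual_norm, 1e-9)
})

test_that("moment conditions are mean-zero at the solution", {
  s <- dgp_spec(N = 3000, K = 3, phi2 = 30 / 7, seed = 67)
  sc <- apply_centering(simulate_panel(s), "true_score")
  blip <- blip_spec(3)
  fit <- g_estimate(sc, blip)
  # recompute the residual cross-products by hand at tau-hat
  U <- transform_U(fit$tau, sc, blip)
  for (l in blip$window) {
    a <- sc$within$A[, paste0("t", l)]
    Xa <- wpscausal:::.history_frame(sc, l)
    dA <- a - wpscausal:::.density_mean(fit$model_A[[paste0("t", l)]], Xa,
                                        length(a))
    Xb <- wpscausal:::.design_matrix(Xa, length(a))
    for (j in seq_len(ncol(U[[paste0("t", l)]]))) {
      u <- U[[paste0("t", l)]][, j]
      rU <- u - drop(Xb %*% qr.coef(qr(Xb), u))
      stat <- mean(dA * rU)
      se <- sd(dA * rU) / sqrt(length(u))
      expect_lt(abs(stat), 3 * se + 1e-8)
    }
  }
})

test_that("without confounding the G-estimate matches plain regression", {
  cf <- dgp_coefficients(alpha_A = 0, gamma_A = 0)
  s <- dgp_spec(N = 5000, K = 2, coefficients = cf, initial_cov = 0,
                phi2 = 10, seed = 68)
  sc <- apply_centering(simulate_panel(s), "true_score")
  fit <- snmm(sc)
  n <- length(sc$person_id)
  w1 <- matrix(1, n, 2, dimnames = list(NULL, c("k1", "k2")))
  ols <- fit_msm(sc, w1, horizons = 1:2, window = 0:1)
  for (p in c("beta_1_0", "beta_2_0", "beta_2_1"))
    expect_lt(abs(fit$tau[[p]] - ols$tau[[p]]), 0.06)
})

test_that("G-estimation is robust to one misspecified nuisance model", {
  s <- dgp_spec(N = 5000, K = 4, phi2 = 10, scenario = "quadratic_treatment",
                seed = 69)
  sc <- apply_centering(simulate_panel(s), "true_score")
  truth <- wpscausal:::.oracle_tau(true_joint_effects(K = 4))
  # model A misses the quadratic term; model B correct
  f1 <- g_estimate(sc, blip_spec(4), a_quadratic = FALSE, b_terms = "full")
  expect_lt(mean(abs(f1$tau[names(truth)] - truth)), 0.05)
  # model A correct; model B deliberately reduced
  f2 <- g_estimate(sc, blip_spec(4), a_quadratic = TRUE, b_terms = "reduced")
  expect_lt(mean(abs(f2$tau[names(truth)] - truth)), 0.05)
})

test_that("joint effects reduce to coefficient sums without moderation", {
  s <- dgp_spec(N = 2000, K = 2, phi2 = 10 / 9, seed = 70)
  sc <- apply_centering(simulate_panel(s), "true_score")
  fit <- snmm(sc)
  expect_equal(joint_effect(fit, 2),
               unname(fit$tau["beta_2_0"] + fit$tau["beta_2_1"]))
  expect_error(joint_effect(fit, 5), "horizon")
})

test_that("moderated joint effects evaluate the blip at supplied confounders", {
  fit <- structure(list(
    tau = c(beta_1_0 = 0.3, gamma_1_0_L = 0.1, beta_2_0 = 0.5,
            gamma_2_0_L = -0.2, beta_2_1 = 1, gamma_2_1_L = 0.4),
    blip = blip_spec(2, interactions = "L")), class = "snmm_fit")
  got <- joint_effect(fit, 2, confounder_values =
                        list(L = c("0" = 0.2, "1" = 0.4)))
  expect_equal(got, (0.5 - 0.2 * 0.2) + (1 + 0.4 * 0.4))
  expect_error(joint_effect(fit, 2, confounder_values = list(L = c("0" = 1))),
               "occasion")
})

test_that("an intervened window restricted to late occasions estimates its block", {
  s <- dgp_spec(N = 4000, K = 8, phi2 = 10, seed = 71)
  sc <- apply_centering(simulate_panel(s), "true_score")
  fit <- snmm(sc)
  truth <- wpscausal:::.oracle_tau(true_joint_effects(K = 8, window = 4:7))
  expect_equal(sort(names(fit$tau)), sort(names(truth)))
  expect_lt(max(abs(fit$tau[names(truth)] - truth)), 0.08)
})

test_that("bootstrap standard errors are returned for the SNMM", {
  s <- dgp_spec(N = 300, K = 2, phi2 = 10 / 9, seed = 72)
  sc <- apply_centering(simulate_panel(s), "true_score")
  set.seed(2)
  fit <- snmm(sc, nboot = 20)
  expect_true(all(fit$se > 0))
})
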