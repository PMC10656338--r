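test_that("within-covariance estimator subtracts the expanded trait blocks", {
  # zero trait covariance: psi equals S exactly
  set.seed(1)
  G <- matrix(rnorm(36), 6); S <- crossprod(G) + diag(6)
  psi <- estimate_within_covariance(S, matrix(0, 2, 2), c(3, 3))
  expect_equal(unname(psi), unname(S), tolerance = 1e-12,
               ignore_attr = TRUE)
  # Kronecker expansion with equal occasion counts, spot-checked by hand
  Phi <- matrix(c(10 / 9, 0.4, 0.2,
                  0.4, 10 / 9, 0.3,
                  0.2, 0.3, 10 / 9), 3, 3)
  S2 <- diag(9) * 20
  psi2 <- estimate_within_covariance(S2, Phi, c(3, 3, 3))
  Phi_plus <- attr(psi2, "phi_plus")
  expect_equal(Phi_plus[1, 2], 10 / 9)   # same variable, different occasions
  expect_equal(Phi_plus[1, 4], 0.4)      # Y block x A block
  expect_equal(Phi_plus[2, 9], 0.2)      # Y block x L block
  expect_equal(Phi_plus[5, 8], 0.3)      # A block x L block
  expect_equal(unname(psi2), unname(S2 - Phi %x% matrix(1, 3, 3)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("unequal occasion counts expand block-wise", {
  Phi <- matrix(c(2, 1, 1, 3), 2, 2)
  S <- diag(5) * 10
  psi <- estimate_within_covariance(S, Phi, c(3, 2))
  pp <- attr(psi, "phi_plus")
  expect_equal(pp[1:3, 1:3], matrix(2, 3, 3))
  expect_equal(pp[4:5, 4:5], matrix(3, 2, 2))
  expect_equal(pp[1, 4], 1)
  expect_error(estimate_within_covariance(S, Phi, c(3, 3)), "layout")
})

test_that("an indefinite difference is repaired to PSD with a warning", {
  S <- diag(2)
  Phi <- matrix(1.02, 1, 1)   # S - Phi+ has eigenvalue -0.02... scaled below
  S2 <- matrix(c(1, 0.0, 0.0, 1), 2, 2)
  expect_warning(psi <- estimate_within_covariance(S2, Phi, 2), "repaired")
  expect_gte(wpscausal:::.min_eigenvalue(psi), 0)
  expect_true(attr(psi, "repaired"))
})

test_that("correlation-preserving weights satisfy their defining identities", {
  for (seed in 1:5) {
    pair <- random_cov_pair(4, seed)
    W <- cpp_weights(pair$sigma, pair$psi)
    expect_lt(max(abs(t(W) %*% pair$sigma %*% W - pair$psi)), 1e-8)
  }
  # psi = sigma: identity weights
  pair <- random_cov_pair(3, 9)
  expect_equal(cpp_weights(pair$sigma, pair$sigma), diag(3),
               tolerance = 1e-10)
  # scalar case: w = sqrt(psi/sigma)
  expect_equal(cpp_weights(matrix(4), matrix(1))[1, 1], 0.5,
               tolerance = 1e-12)
})

test_that("weights minimize the trace MSE among covariance-preserving maps", {
  for (d in 2:3) {
    pair <- random_cov_pair(d, 20 + d)
    W <- cpp_weights(pair$sigma, pair$psi)
    W_opt <- brute_force_weights(pair$sigma, pair$psi, seed = d)
    expect_equal(W, W_opt, tolerance = 1e-4, ignore_attr = TRUE)
    mse <- function(W) sum(diag(t(W) %*% pair$sigma %*% W)) +
      sum(diag(pair$psi)) - 2 * sum(diag(t(W) %*% pair$psi))
    expect_lte(mse(W), mse(W_opt) + 1e-6)
  }
})

test_that("singular or indefinite inputs are rejected", {
  expect_error(cpp_weights(matrix(c(1, 1, 1, 1), 2), diag(2)), "singular")
  expect_error(cpp_weights(diag(2), diag(c(1, -1))), "eigenvalue")
})

test_that("stable-trait predictor matches direct evaluation of its formula", {
  Sig <- matrix(c(3, 1, 0.5,
                  1, 2.5, 0.8,
                  0.5, 0.8, 2), 3, 3)
  dev <- c(1, 0, -1)
  fit <- list(phi2 = 4, sample_cov = Sig, sample_mean = c(0, 0, 0))
  one <- rep(1, 3)
  expected <- 2 / sqrt(sum(solve(Sig) %*% one)) *
    drop(one %*% solve(Sig) %*% dev)
  got <- predict_stable_traits(matrix(dev, 1), fit)
  expect_equal(got[1], expected, tolerance = 1e-12)
  # zero trait variance: predictor identically zero, with a note
  fit0 <- list(phi2 = 0, sample_cov = Sig, sample_mean = c(0, 0, 0))
  z <- predict_stable_traits(matrix(dev, 1), fit0)
  expect_identical(z[1], 0)
  expect_match(attr(z, "note"), "zero")
})

test_that("trait predictions recover the trait covariance on model-true data", {
  set.seed(31)
  n <- 8000; p <- 4
  Phi <- matrix(c(4, 0.3 * 4, 0.3 * 4, 4), 2, 2)
  I <- matrix(rnorm(n * 2), n, 2) %*% chol(Phi)
  Psi <- 10 * 0.5^abs(outer(1:p, 1:p, "-"))
  mk <- function(i) I[, i] + matrix(rnorm(n * p), n, p) %*% chol(Psi)
  X1 <- mk(1); X2 <- mk(2)
  f1 <- fit_measurement_model(X1, measurement_spec())
  f2 <- fit_measurement_model(X2, measurement_spec())
  I1 <- predict_stable_traits(X1, f1)
  I2 <- predict_stable_traits(X2, f2)
  expect_equal(var(I1), 4, tolerance = 0.25)
  got <- stable_trait_covariance(cbind(I1, I2), c(f1$phi2, f2$phi2))
  expect_equal(unname(got), unname(Phi), tolerance = 0.3)
  # predicted trait correlation is the true correlation up to attenuation
  expect_lt(cor(I1, I2), 0.3 + 0.05)
  expect_gt(cor(I1, I2), 0.3 * 0.4)
})

test_that("predicted scores reproduce the within covariance and center at zero", {
  s <- dgp_spec(N = 8000, K = 4, phi2 = 30 / 7, seed = 17)
  pan <- simulate_panel(s)
  sc <- apply_centering(pan, "proposed")
  X <- do.call(cbind, sc$within)
  expect_lt(max(abs(colMeans(X))), 0.15)
  M2 <- crossprod(X) / nrow(X)
  expect_lt(max(abs(M2 - sc$psi_hat)) / max(abs(sc$psi_hat)), 0.05)
})

test_that("trait/within prediction cross-covariance matches its analytic value", {
  # the latent trait and scores are orthogonal; their linear predictors are
  # not at finite K -- the empirical cross-covariance must instead agree with
  # the population value w_I' Sigma W implied by the two weight formulas
  p <- 4; phi2 <- 4
  X <- sim_measurement_true(20000, p, phi2 = phi2, seed = 101)
  fit <- fit_measurement_model(X, measurement_spec())
  I_hat <- predict_stable_traits(X, fit)
  S <- fit$sample_cov * fit$n / (fit$n - 1)
  psi <- psd_repair(S - max(fit$phi2, 0))
  W <- cpp_weights(S, psi)
  scores <- sweep(X, 2, colMeans(X)) %*% W
  wI <- sqrt(max(fit$phi2, 0)) / sqrt(sum(solve(S))) * colSums(solve(S))
  pop_cross <- drop(wI %*% S %*% W)
  emp_cross <- drop(cov(I_hat, scores))
  expect_equal(emp_cross, pop_cross, tolerance = 0.02)
  expect_gt(min(pop_cross), 0)   # genuinely nonzero at small K
})

test_that("a person sitting at the occasion means scores near zero", {
  s <- dgp_spec(N = 2000, K = 3, phi2 = 10 / 9, seed = 23)
  pan <- simulate_panel(s)
  for (v in names(pan$values))
    pan$values[[v]][1, ] <- colMeans(pan$values[[v]])
  sc <- apply_centering(pan, "proposed")
  for (v in c("Y", "A", "L"))
    expect_lt(max(abs(sc$within[[v]][1, ])), 0.05)
})

test_that("vanishing trait variance reduces scoring to occasion-mean centering", {
  # on model-true data (no misattributed serial dependence) the weights tend
  # to the identity as the trait variances tend to zero
  vals <- list(Y = sim_measurement_true(4000, 4, phi2 = 1e-3, seed = 27),
               A = sim_measurement_true(4000, 4, phi2 = 1e-3, seed = 28),
               L = sim_measurement_true(4000, 4, phi2 = 1e-3, seed = 29))
  pan <- panel_data(vals, list(outcome = "Y", treatment = "A",
                               confounders = "L"), K = 3)
  sc <- apply_centering(pan, "proposed")
  for (v in c("Y", "A", "L")) {
    plain <- sweep(pan$values[[v]], 2, colMeans(pan$values[[v]]))
    expect_lt(max(abs(sc$within[[v]] - plain)), 0.35)
    expect_gt(cor(as.vector(sc$within[[v]]), as.vector(plain)), 0.999)
  }
})

test_that("persons with missing cells get pattern-specific weights", {
  s <- dgp_spec(N = 800, K = 2, phi2 = 10 / 9, treatment_waves = "all",
                seed = 29)
  pan <- simulate_panel(s)
  pan$values$Y[1:50, 3] <- NA   # 50 persons lose the last outcome wave
  pan$values$A[1:50, 3] <- NA
  pan$values$L[1:50, 3] <- NA
  sc <- apply_centering(pan, "proposed")
  expect_true(all(is.na(sc$within$Y[1:50, 3])))
  expect_true(all(!is.na(sc$within$Y[1:50, 1:2])))
  expect_true(all(!is.na(sc$within$Y[51:800, ])))
  # persons with < 2 observed values carry no scores
  pan$values$Y[51, ] <- NA; pan$values$A[51, ] <- NA
  pan$values$L[51, 2:3] <- NA
  sc2 <- suppressWarnings(apply_centering(pan, "proposed"))
  expect_true(all(is.na(do.call(cbind, lapply(sc2$within, function(m) m[51, ])))))
})

test_that("observed-mean centering sums to zero across each person's waves", {
  s <- dgp_spec(N = 300, K = 4, phi2 = 10, seed = 37)
  pan <- simulate_panel(s)
  sc <- apply_centering(pan, "observed_mean")
  for (v in c("Y", "A", "L"))
    expect_lt(max(abs(rowSums(sc$within[[v]]))), 1e-10)
})

test_that("true-score centering returns the latent truth exactly", {
  s <- dgp_spec(N = 100, K = 3, phi2 = 10, seed = 41)
  pan <- simulate_panel(s)
  sc <- apply_centering(pan, "true_score")
  expect_identical(sc$within$Y, attr(pan, "truth")$within$Y)
  expect_error(apply_centering(panel_data(pan$values, pan$roles), "true_score"),
               "truth")
})
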