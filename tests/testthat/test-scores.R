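# Conditional-expectation scores, trajectory reconstruction and bands:
# closed-form scalar case, Monte-Carlo conditional-expectation oracle,
# shrinkage and information-monotonicity properties.

# model with a single "eigenfunction" equal to 0.5 everywhere, lambda = 2,
# sigma^2 = 1 (quantities chosen for a hand-checkable scalar score)
scalar_model <- function(lambda = 2, phival = 0.5, sigma2 = 1) {
  grid <- seq(0, 42, length.out = 22)
  phi <- matrix(phival, length(grid), 1)
  structure(list(
    mean = structure(list(grid = grid, values = rep(0, length(grid)),
                          bandwidth = NA, kernel = "none"),
                     class = "gw_smooth1d"),
    covariance = structure(list(grid = grid,
                                surface = lambda * tcrossprod(phi),
                                diag_smooth = rep(lambda * phival^2,
                                                  length(grid)),
                                v_hat = rep(lambda * phival^2 + sigma2,
                                            length(grid)),
                                sigma2 = sigma2,
                                bandwidths = c(NA, NA)),
                           class = "gw_cov"),
    eigen = structure(list(values = lambda, functions = phi, fve = 1,
                           grid = grid), class = "gw_eigen"),
    K = 1L, fve_threshold = 1, n_subjects = NA, n_obs = NA),
    class = "gw_fpca")
}

test_that("a single observation gives the closed-form scalar score", {
  m <- scalar_model(lambda = 2, phival = 0.5, sigma2 = 1)
  sc <- predict_scores(list(t = 10, y = 3), m)  # residual r = 3
  # lambda * phi * r / (lambda * phi^2 + sigma^2) = 2*0.5*3 / 1.5 = 2
  expect_equal(unname(sc$scores), 2, tolerance = 1e-12)
  expect_equal(dim(sc$Omega_K), c(1L, 1L))
  # Omega = lambda - (lambda phi)^2 / (lambda phi^2 + sigma^2)
  expect_equal(sc$Omega_K[1, 1], 2 - 1 / 1.5, tolerance = 1e-12)
})

test_that("observations on the mean give zero scores and the mean curve", {
  m <- fpca_model_from_truth(make_study_truth())
  tt <- c(0, 10, 25, 39)
  sub <- list(t = tt, y = lin <- approx(m$mean$grid, m$mean$values,
                                        tt)$y)
  sc <- predict_scores(sub, m)
  expect_equal(unname(sc$scores), rep(0, m$K), tolerance = 1e-10)
  tr <- reconstruct_trajectory(sc, m)
  expect_equal(tr$values, m$mean$values, tolerance = 1e-10)
})

test_that("reconstruction is linear in the scores (K = 1)", {
  m <- scalar_model()
  sc <- predict_scores(list(t = 21, y = 6), m)
  tr <- reconstruct_trajectory(sc, m)
  expect_equal(tr$values, rep(sc$scores * 0.5, length(tr$grid)),
               tolerance = 1e-12)
})

test_that("scores match the Monte-Carlo conditional expectation", {
  # fixed toy Gaussian model: K = 2, three observation times
  truth <- toy_truth(lambda = c(4, 1), noise_sd = 0.5)
  grid <- seq(0, 42, length.out = 43)
  m <- fpca_model_from_truth(truth, grid)
  tt <- c(5, 20, 35)
  yy <- c(63.5, 64.0, 75.0)
  sc <- predict_scores(list(t = tt, y = yy), m)

  set.seed(99)
  ndraw <- 2e5
  Phi <- sapply(truth$eigenfunctions, function(f) f(tt))
  xi <- cbind(rnorm(ndraw, 0, 2), rnorm(ndraw, 0, 1))
  Y <- xi %*% t(Phi) +
    matrix(truth$mean_function(tt), ndraw, 3, byrow = TRUE) +
    matrix(rnorm(ndraw * 3, 0, 0.5), ndraw, 3)
  X <- cbind(1, Y)
  for (k in 1:2) {
    fit <- lm.fit(X, xi[, k])
    pred <- sum(coef(fit) * c(1, yy))
    # MC standard error of the regression prediction at the observed y
    s2 <- sum(fit$residuals^2) / fit$df.residual
    x0 <- c(1, yy)
    se <- sqrt(s2 * drop(x0 %*% chol2inv(qr.R(fit$qr)) %*% x0))
    expect_lt(abs(sc$scores[k] - pred), 3 * se + 1e-8)
  }
})

test_that("K = 1 pointwise and simultaneous bands coincide; zero error gives zero width", {
  m <- scalar_model()
  sc <- predict_scores(list(t = c(10, 30), y = c(2, 1)), m)
  pw <- confidence_bands(sc, m, simultaneous = FALSE)
  sb <- confidence_bands(sc, m, simultaneous = TRUE)
  expect_equal(pw$lower, sb$lower, tolerance = 1e-12)
  expect_equal(pw$upper, sb$upper, tolerance = 1e-12)

  sc0 <- sc
  sc0$Omega_K <- matrix(0, 1, 1)
  b0 <- confidence_bands(sc0, m, simultaneous = TRUE)
  expect_equal(b0$lower, b0$upper, tolerance = 1e-12)
})

test_that("simultaneous bands contain pointwise bands when K >= 2", {
  m <- fpca_model_from_truth(toy_truth(lambda = c(4, 1), noise_sd = 0.5))
  sc <- predict_scores(list(t = c(8, 22, 39), y = c(66, 70, 80)), m)
  tr <- reconstruct_trajectory(sc, m)
  expect_true(all(tr$simultaneous_lo <= tr$pointwise_lo + 1e-12))
  expect_true(all(tr$simultaneous_hi >= tr$pointwise_hi - 1e-12))
  # bands are symmetric about the estimate
  expect_equal(tr$values - tr$pointwise_lo, tr$pointwise_hi - tr$values,
               tolerance = 1e-12)
})

test_that("reconstructed gains shrink toward the mean gain", {
  truth <- recovery_truth()
  coh <- generate_cohort(truth, full_design(), n = 300, seed = 55)
  m <- fpca_model_from_truth(truth)
  trs <- reconstruct_all(coh, m)
  gain_hat <- vapply(trs, function(x) {
    diff(approx(x$grid, x$values, c(0, 40))$y)
  }, numeric(1))
  X <- true_trajectories(coh, c(0, 40))
  gain_true <- X[, 2] - X[, 1]
  slope <- coef(lm(gain_hat ~ gain_true))[[2]]
  expect_gt(slope, 0)
  expect_lt(slope, 1)
})

test_that("adding an observation never increases the score-error trace", {
  m <- fpca_model_from_truth(toy_truth(lambda = c(4, 1), noise_sd = 0.5))
  base <- c(10, 25)
  sc2 <- predict_scores(list(t = base, y = c(64, 69)), m)
  for (extra in c(3, 18, 33, 40)) {
    # Omega_K depends on the design only, not on the responses
    sc3 <- predict_scores(list(t = sort(c(base, extra)),
                               y = c(64, 69, 70)), m)
    expect_lte(sum(diag(sc3$Omega_K)), sum(diag(sc2$Omega_K)) + 1e-10)
  }
})

test_that("predicted scores are contractions: Var(xi-hat) <= lambda", {
  truth <- toy_truth(lambda = c(4, 1), noise_sd = 1)
  coh <- generate_cohort(truth, full_design(), n = 2000, seed = 66)
  m <- fpca_model_from_truth(truth)
  obs <- split(coh$observations, coh$observations$subject_id)
  S <- t(vapply(obs, function(o) {
    predict_scores(list(t = o$t, y = o$y), m)$scores
  }, numeric(2)))
  v <- apply(S, 2, var)
  slack <- 1 + 3 * sqrt(2 / nrow(S))
  expect_lt(v[1], 4 * slack)
  expect_lt(v[2], 1 * slack)
})
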