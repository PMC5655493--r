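# FPCA core: raw covariances, noise variance, eigendecomposition against
# closed forms and matrix PCA, and FVE component selection.

test_that("raw covariances count and value correctly", {
  grid <- seq(0, 42, length.out = 11)
  mean <- local_linear_1d(c(0, 10, 20, 30, 40), c(60, 60, 60, 60, 60),
                          10, grid)
  subjects <- data.frame(subject_id = "s1", ga_birth = 40, bmi_p = 22,
                         mean_caloric = 2000, mean_pa_index = 7,
                         instrument = "web", stringsAsFactors = FALSE)
  coh <- manual_cohort(list(s1 = list(t = c(5, 20, 35),
                                      y = c(62, 59, 63),
                                      label = c("WA", "WB", "WC"))),
                       subjects)
  raw <- compute_raw_covariances(coh, mean)
  # N_i = 3: exactly 6 ordered off-diagonal triples and 3 diagonal inputs
  expect_equal(nrow(raw$triples), 6L)
  expect_equal(nrow(raw$diagonal), 3L)
  # residuals (+2, -1) at (5, 20): ordered triples valued -2 both ways
  v52 <- raw$triples$value[raw$triples$s == 5 & raw$triples$t == 20]
  v25 <- raw$triples$value[raw$triples$s == 20 & raw$triples$t == 5]
  expect_equal(v52, -2)
  expect_equal(v25, -2)
  # observations exactly on the mean give all-zero raw covariances
  coh0 <- manual_cohort(list(s1 = list(t = c(5, 20, 35),
                                       y = c(60, 60, 60),
                                       label = c("WA", "WB", "WC"))),
                        subjects)
  raw0 <- compute_raw_covariances(coh0, mean)
  expect_equal(raw0$triples$value, rep(0, 6))
  expect_equal(raw0$diagonal$value, rep(0, 3))
})

test_that("sigma2 is the middle-half average of V-hat minus G-tilde", {
  grid <- seq(0, 42, length.out = 43)
  g_tilde <- 5 + sin(grid / 7)
  expect_equal(estimate_sigma2(g_tilde, g_tilde, grid), 0)
  expect_equal(estimate_sigma2(g_tilde + 2.5, g_tilde, grid), 2.5)
  expect_warning(s2 <- estimate_sigma2(g_tilde - 1, g_tilde, grid),
                 "clamped")
  expect_equal(s2, 0)
})

test_that("covariance model recovers a rank-1 covariance without noise", {
  # observation times scattered uniformly so the assembled pairs are dense
  # in the whole domain (the precondition of the surface smoother)
  set.seed(21)
  phi <- cosine_basis(2)[[2]]
  n <- 3000
  xi <- rnorm(n, 0, 4)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- sort(runif(5, 0, 42))
    data.frame(subject_id = sprintf("u%04d", i), t = tt,
               y = 70 + xi[i] * phi(tt),
               label = c("W0", "WA", "WB", "WC", "WH")[seq_along(tt)],
               stringsAsFactors = FALSE)
  }))
  obs$label <- "WB"  # labels irrelevant here
  subjects <- data.frame(subject_id = sprintf("u%04d", seq_len(n)),
                         ga_birth = 40, bmi_p = 22, mean_caloric = 2000,
                         mean_pa_index = 7, instrument = "web",
                         stringsAsFactors = FALSE)
  coh <- gwtraj:::new_cohort(obs, subjects)
  grid <- seq(0, 42, length.out = 21)
  mean <- local_linear_1d(obs$t, obs$y, 4, grid)
  raw <- compute_raw_covariances(coh, mean)
  cm <- suppressWarnings(estimate_covariance_model(raw, grid, c(3.5, 3.5)))
  truth_surface <- 16 * outer(phi(grid), phi(grid))
  interior <- grid >= 8 & grid <= 34
  rel <- abs(cm$surface[interior, interior] -
               truth_surface[interior, interior]) /
    max(abs(truth_surface))
  expect_lt(max(rel), 0.1)
  expect_identical(cm$surface, t(cm$surface))
})

test_that("too few off-diagonal covariances is an informative error", {
  grid <- seq(0, 42, length.out = 11)
  mean <- local_linear_1d(c(0, 40), c(60, 70), 20, grid)
  subjects <- data.frame(subject_id = "s1", ga_birth = 40, bmi_p = 22,
                         mean_caloric = 2000, mean_pa_index = 7,
                         instrument = "web", stringsAsFactors = FALSE)
  coh <- manual_cohort(list(s1 = list(t = c(5, 20), y = c(62, 64),
                                      label = c("WA", "WB"))), subjects)
  raw <- compute_raw_covariances(coh, mean)
  expect_error(estimate_covariance_model(raw, grid, c(5, 5)),
               "larger cohort")
})

test_that("eigendecomposition solves the rank-1 problem exactly", {
  grid <- seq(0, 42, length.out = 51)
  phi <- cosine_basis(2)[[2]]
  surface <- 4 * outer(phi(grid), phi(grid))
  eig <- eigendecompose(list(grid = grid, surface = surface))
  expect_equal(eig$values[1], 4, tolerance = 1e-8)
  expect_true(all(eig$values[-1] <= 1e-8))
  err <- min(sqrt(trapz_weights(grid) %*% (eig$functions[, 1] - phi(grid))^2),
             sqrt(trapz_weights(grid) %*% (eig$functions[, 1] + phi(grid))^2))
  expect_lt(err, 1e-6)
})

test_that("Brownian-motion covariance reproduces the Mercer expansion", {
  grid <- seq(0, 1, length.out = 201)
  surface <- outer(grid, grid, pmin)
  eig <- eigendecompose(list(grid = grid, surface = surface))
  lam_true <- 4 / ((2 * (1:3) - 1)^2 * pi^2)
  expect_equal(eig$values[1:3], lam_true, tolerance = 0.01)
  w <- trapz_weights(grid)
  for (k in 1:3) {
    f_true <- sqrt(2) * sin((k - 0.5) * pi * grid)
    err <- min(sqrt(sum(w * (eig$functions[, k] - f_true)^2)),
               sqrt(sum(w * (eig$functions[, k] + f_true)^2)))
    expect_lt(err, 0.02)
  }
})

test_that("eigenfunctions are orthonormal under trapezoid quadrature", {
  set.seed(8)
  grid <- seq(0, 42, length.out = 31)
  A <- matrix(rnorm(31 * 31), 31, 31)
  eig <- eigendecompose(list(grid = grid, surface = crossprod(A) / 31))
  w <- trapz_weights(grid)
  Gram <- crossprod(eig$functions, eig$functions * w)
  expect_lt(max(abs(Gram - diag(ncol(Gram)))), 1e-8)
  expect_true(all(diff(eig$fve) >= 0))
  expect_equal(eig$fve[length(eig$fve)], 1)
})

test_that("non-symmetric surfaces are rejected", {
  grid <- seq(0, 1, length.out = 5)
  S <- outer(grid, grid, pmin)
  S[1, 5] <- S[1, 5] + 1
  expect_error(eigendecompose(list(grid = grid, surface = S)),
               "not symmetric")
})

test_that("FVE selection matches the cumulative-sum rule", {
  expect_equal(select_K_fve(c(0.957, 0.028, 0.011, 0.004), 0.99), 3L)
  expect_equal(select_K_fve(7.3), 1L)
  expect_equal(select_K_fve(7.3, threshold = 0.5), 1L)
  expect_equal(select_K_fve(c(1, 1, 1, 1), 0.99), 4L)
  expect_error(select_K_fve(c(0, 0)), "zero")
})

test_that("dense noiseless FPCA agrees with matrix PCA after quadrature scaling", {
  tr <- make_study_truth()
  coh <- generate_cohort(tr, full_design(), n = 200, seed = 31)
  grid <- seq(0, 42, length.out = 51)
  X <- true_trajectories(coh, grid)           # fully observed, no noise
  C <- cov(X)
  eig <- eigendecompose(list(grid = grid, surface = C))
  w <- trapz_weights(grid)
  Z <- sweep(X, 2, colMeans(X)) %*% diag(sqrt(w))
  pca <- prcomp(Z, center = FALSE)
  k <- seq_len(min(5, length(eig$values)))
  expect_equal(eig$values[k], (pca$sdev^2)[k], tolerance = 1e-8)
})

test_that("total eigenvalue mass is bounded by the integrated V-hat", {
  tr <- recovery_truth()
  coh <- generate_cohort(tr, full_design(), n = 400, seed = 17)
  m <- fit_fpca(coh)
  total_var <- trapz_weights(m$mean$grid) %*% m$covariance$v_hat
  expect_lt(sum(m$eigen$values), total_var * 1.05)
})
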