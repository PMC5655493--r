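# Sparse FPCA core: raw covariances, covariance-surface and noise-variance
# estimation, eigendecomposition of the discretized covariance operator,
# and FVE-based component selection.

#' Raw covariances of centred observations
#'
#' For each subject with residuals \eqn{r_{ij} = Y_{ij} - \hat\mu(T_{ij})},
#' forms all ordered off-diagonal products \eqn{r_{ij} r_{il}}, \eqn{j \ne l}
#' (inputs to the covariance-surface smoother) and the squared residuals
#' \eqn{r_{ij}^2} (inputs to the variance-plus-noise smoother).  Same-index
#' pairs are excluded from the off-diagonal set because their expectation
#' carries the measurement-error variance \eqn{\sigma^2} in addition to the
#' covariance.  Subjects with a single observation contribute only a
#' diagonal input.
#'
#' @param cohort a \code{gw_cohort}.
#' @param mean a \code{gw_smooth1d} mean estimate covering the observation
#'   times (values are linearly interpolated between grid nodes).
#' @return an object of class \code{"gw_rawcov"}: list with data frames
#'   \code{triples} (\code{s}, \code{t}, \code{value}) and
#'   \code{diagonal} (\code{t}, \code{value}).
#' @export
compute_raw_covariances <- function(cohort, mean) {
  stopifnot(inherits(cohort, "gw_cohort"), inherits(mean, "gw_smooth1d"))
  obs <- cohort$observations
  resid <- obs$y - lin_interp(mean$grid, mean$values, obs$t)
  idx <- split(seq_len(nrow(obs)), obs$subject_id)
  trip <- lapply(idx, function(ii) {
    ni <- length(ii)
    if (ni < 2L) return(NULL)
    pairs <- expand.grid(j = seq_len(ni), l = seq_len(ni))
    pairs <- pairs[pairs$j != pairs$l, , drop = FALSE]
    data.frame(s = obs$t[ii][pairs$j], t = obs$t[ii][pairs$l],
               value = resid[ii][pairs$j] * resid[ii][pairs$l])
  })
  triples <- do.call(rbind, trip)
  rownames(triples) <- NULL
  structure(list(triples = triples,
                 diagonal = data.frame(t = obs$t, value = resid^2)),
            class = "gw_rawcov")
}

#' Smoothed covariance model with noise variance
#'
#' Estimates the covariance surface \eqn{\hat G(s,t)} by the 2D local
#' linear smoother applied to the off-diagonal raw covariances, the
#' covariance diagonal \eqn{\tilde G(t)} by a local fit with a linear term
#' along the diagonal direction and a quadratic term perpendicular to it,
#' and \eqn{\hat V(t)} (the diagonal including measurement noise,
#' \eqn{G(t,t) + \sigma^2}) by the 1D smoother applied to the squared
#' residuals; \eqn{\hat\sigma^2} is then the trapezoid-weighted average of
#' \eqn{\hat V - \tilde G} over the middle half of the domain (see
#' [estimate_sigma2()]).
#'
#' @param raw a \code{gw_rawcov}.
#' @param grid strictly increasing evaluation grid.
#' @param bandwidths length-2 bandwidths for the surface smoother.  The
#'   first is also used for the 1D smoother of the squared residuals; the
#'   rotated diagonal smoother uses \code{c(1.5 * bandwidths[1],
#'   bandwidths[2])} (longer along the diagonal, where the informative
#'   near-diagonal pairs sit at the visit-window boundaries).
#' @param kernel kernel name.
#' @return an object of class \code{"gw_cov"}: \code{grid},
#'   \code{surface}, \code{diag_smooth}, \code{v_hat}, \code{sigma2},
#'   \code{bandwidths}.
#' @export
estimate_covariance_model <- function(raw, grid, bandwidths,
                                      kernel = "gaussian") {
  stopifnot(inherits(raw, "gw_rawcov"))
  if (is.null(raw$triples) || nrow(raw$triples) < 10L) {
    stop("fewer than 10 off-diagonal raw covariances; ",
         "a larger cohort (more subjects with >= 2 observations) is needed")
  }
  sm2 <- local_linear_2d(raw$triples$s, raw$triples$t, raw$triples$value,
                         bandwidths, grid, kernel = kernel,
                         symmetric_data = TRUE)
  # Along the diagonal the informative near-diagonal pairs concentrate at
  # the visit-window boundaries, so the diagonal smoother borrows strength
  # with a longer bandwidth along the diagonal than across it.
  diag_smooth <- tryCatch(
    smooth_cov_diagonal(raw$triples$s, raw$triples$t, raw$triples$value,
                        c(1.5 * bandwidths[1L], bandwidths[2L]), grid,
                        kernel = kernel),
    error = function(e) {
      warning("diagonal smoother failed (", conditionMessage(e),
              "); falling back to the surface diagonal")
      diag(sm2$surface)
    })
  v_hat <- local_linear_1d(raw$diagonal$t, raw$diagonal$value,
                           bandwidths[1L], grid, kernel = kernel)
  sigma2 <- estimate_sigma2(v_hat$values, diag_smooth, grid)
  structure(list(grid = grid, surface = sm2$surface,
                 diag_smooth = diag_smooth, v_hat = v_hat$values,
                 sigma2 = sigma2, bandwidths = bandwidths),
            class = "gw_cov")
}

#' Measurement-error variance from the two diagonal estimates
#'
#' \eqn{\hat V(t)} targets \eqn{G(t,t) + \sigma^2} while \eqn{\tilde G(t)}
#' targets \eqn{G(t,t)}; their difference, averaged with trapezoid weights
#' over the middle half of the domain (to avoid boundary bias in the
#' smoothers), estimates \eqn{\sigma^2}.  A negative average is clamped to
#' zero with a warning.
#'
#' @param v_hat,diag_smooth numeric vectors on \code{grid}.
#' @param grid strictly increasing evaluation grid.
#' @return scalar \eqn{\hat\sigma^2 \ge 0}.
#' @export
estimate_sigma2 <- function(v_hat, diag_smooth, grid) {
  stopifnot(length(v_hat) == length(grid),
            length(diag_smooth) == length(grid))
  r <- range(grid)
  lo <- r[1L] + 0.25 * diff(r)
  hi <- r[2L] - 0.25 * diff(r)
  mid <- grid >= lo & grid <= hi
  if (sum(mid) < 2L) stop("grid too coarse for the middle-half average")
  w <- trapz_weights(grid[mid])
  s2 <- sum(w * (v_hat[mid] - diag_smooth[mid])) / sum(w)
  if (s2 < 0) {
    warning("negative noise-variance estimate clamped to 0")
    s2 <- 0
  }
  s2
}

#' Eigendecomposition of the discretized covariance operator
#'
#' Solves the quadrature-weighted eigenproblem for the integral operator
#' with kernel \eqn{\hat G}: with trapezoid weights \eqn{W} on the grid,
#' the symmetric matrix \eqn{W^{1/2} \hat G W^{1/2}} is eigendecomposed,
#' eigenvectors are mapped back by \eqn{W^{-1/2}} and rescaled to unit
#' trapezoid norm, negative eigenvalues (possible after smoothing) are
#' dropped, and each eigenfunction's sign is fixed so that its integral
#' over the domain is non-negative (ties broken by making the value at the
#' last grid point non-negative).
#'
#' @param cov a \code{gw_cov}, or any list with \code{grid} and a
#'   symmetric \code{surface}.
#' @return an object of class \code{"gw_eigen"}: \code{values}
#'   (positive eigenvalues, decreasing), \code{functions} (matrix,
#'   eigenfunctions on the grid in columns), \code{fve} (cumulative
#'   fraction of variance explained), \code{grid}.
#' @export
eigendecompose <- function(cov) {
  grid <- cov$grid
  S <- cov$surface
  stopifnot(is.matrix(S), nrow(S) == length(grid), ncol(S) == length(grid))
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8 * max(1, max(abs(S)))) {
    stop("covariance surface is not symmetric (max asymmetry ",
         signif(asym, 3), ")")
  }
  S <- (S + t(S)) / 2
  w <- trapz_weights(grid)
  sw <- sqrt(w)
  B <- S * (sw %o% sw)
  es <- eigen(B, symmetric = TRUE)
  lam <- es$values
  keep <- lam > max(lam, 0) * 1e-12 & lam > 0
  if (!any(keep)) stop("covariance surface has no positive eigenvalues")
  lam <- lam[keep]
  phi <- es$vectors[, keep, drop = FALSE] / sw
  nrm <- sqrt(colSums(w * phi^2))
  phi <- sweep(phi, 2L, nrm, "/")
  for (k in seq_along(lam)) {
    s <- sum(w * phi[, k])
    if (abs(s) < 1e-10) s <- phi[nrow(phi), k]
    if (s < 0) phi[, k] <- -phi[, k]
  }
  structure(list(values = lam, functions = phi,
                 fve = cumsum(lam) / sum(lam), grid = grid),
            class = "gw_eigen")
}

#' Number of components by fraction of variance explained
#'
#' Returns the smallest \eqn{K} such that the leading \eqn{K} eigenvalues
#' account for at least \code{threshold} of their total.
#'
#' @param eigenvalues non-negative eigenvalues in decreasing order.
#' @param threshold FVE threshold in (0, 1]; default 0.99.
#' @return integer \eqn{K}.
#' @export
select_K_fve <- function(eigenvalues, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  lam <- eigenvalues[eigenvalues > 0]
  if (length(lam) == 0L || sum(lam) <= 0) {
    stop("all eigenvalues are zero")
  }
  fve <- cumsum(lam) / sum(lam)
  as.integer(which(fve >= threshold - 1e-12)[1L])
}

#' Fit the sparse FPCA model to a cohort
#'
#' Runs the full estimation pipeline: (1) mean function by 1D local linear
#' smoothing of all observations (bandwidth by GCV unless supplied);
#' (2) raw covariances and the smoothed covariance model including the
#' measurement-error variance; (3) eigendecomposition of the discretized
#' covariance operator; (4) component count by fraction of variance
#' explained.
#'
#' @param cohort a \code{gw_cohort}.
#' @param grid_size number of equally spaced evaluation points over the
#'   cohort domain (default 51); ignored when \code{grid} is given.
#' @param grid optional explicit evaluation grid.
#' @param fve_threshold FVE threshold for selecting K (default 0.99).
#' @param mean_bandwidth optional mean-smoother bandwidth in weeks;
#'   selected by GCV over \code{bandwidth_candidates} when \code{NULL}.
#' @param cov_bandwidths optional length-2 covariance-smoother bandwidths;
#'   by default an isotropic bandwidth is selected by GCV on the
#'   off-diagonal raw covariances over \code{span/c(14, 10, 7)}.  The
#'   lower end of that range reflects the visit design (no pair support
#'   closer to the diagonal than the inter-window gap), the upper end the
#'   finest component the analysis retains (a second-vs-third-trimester
#'   contrast).
#' @param bandwidth_candidates candidates for GCV; default a log-spaced
#'   grid from span/28 to span/3.5.
#' @param kernel kernel name.
#' @return an object of class \code{"gw_fpca"} with components
#'   \code{mean}, \code{covariance}, \code{eigen}, \code{K},
#'   \code{fve_threshold}, \code{n_subjects}, \code{n_obs}.
#' @export
fit_fpca <- function(cohort, grid_size = 51L, grid = NULL,
                     fve_threshold = 0.99, mean_bandwidth = NULL,
                     cov_bandwidths = NULL, bandwidth_candidates = NULL,
                     kernel = "gaussian") {
  stopifnot(inherits(cohort, "gw_cohort"))
  obs <- cohort$observations
  if (is.null(grid)) grid <- default_grid(cohort$domain, grid_size)
  span <- diff(range(grid))
  if (is.null(bandwidth_candidates)) {
    bandwidth_candidates <- exp(seq(log(span / 28), log(span / 3.5),
                                    length.out = 6L))
  }
  if (is.null(mean_bandwidth)) {
    mean_bandwidth <- select_bandwidth_gcv(obs$t, obs$y,
                                           bandwidth_candidates,
                                           kernel = kernel)
  }
  mean <- local_linear_1d(obs$t, obs$y, mean_bandwidth, grid,
                          kernel = kernel)
  raw <- compute_raw_covariances(cohort, mean)
  # The covariance bandwidth is chosen by GCV on the off-diagonal raw
  # covariances.  The candidate range is bounded below by the visit
  # design (no pair support closer to the diagonal than the inter-window
  # gap) and above by resolution: a bandwidth beyond span/7 can no longer
  # resolve a second-vs-third-trimester contrast, the finest component
  # the analysis retains.
  if (is.null(cov_bandwidths)) {
    cov_cand <- span / c(14, 10, 7)
    h2 <- select_bandwidth_gcv_2d(raw$triples$s, raw$triples$t,
                                  raw$triples$value, cov_cand,
                                  kernel = kernel)
    cov_bandwidths <- rep(h2, 2L)
  }
  covm <- estimate_covariance_model(raw, grid, cov_bandwidths,
                                    kernel = kernel)
  eig <- eigendecompose(covm)
  K <- select_K_fve(eig$values, fve_threshold)
  structure(list(mean = mean, covariance = covm, eigen = eig, K = K,
                 fve_threshold = fve_threshold,
                 n_subjects = nrow(cohort$subjects), n_obs = nrow(obs)),
            class = "gw_fpca")
}

#' @export
print.gw_fpca <- function(x, ...) {
  cat("Sparse FPCA fit:", x$n_subjects, "subjects,", x$n_obs,
      "observations\n")
  nfr <- min(length(x$eigen$values), 5L)
  fr <- x$eigen$values[seq_len(nfr)] / sum(x$eigen$values)
  cat("  eigenvalue fractions:",
      paste(sprintf("%.1f%%", 100 * fr), collapse = ", "),
      if (length(x$eigen$values) > nfr) "..." else "", "\n")
  cat("  selected K =", x$K, sprintf("(FVE %.2f%% at threshold %.0f%%)",
      100 * x$eigen$fve[x$K], 100 * x$fve_threshold), "\n")
  cat("  noise variance:", signif(x$covariance$sigma2, 4), "kg^2\n")
  invisible(x)
}

#' FPCA model assembled from a generative truth
#'
#' Evaluates a \code{gw_truth} on a grid and packages it as a fitted-model
#' object (mean, covariance surface \eqn{\sum_k \lambda_k \phi_k \phi_k'},
#' noise variance, eigensystem) so that score prediction and confidence
#' bands can be run with the true quantities plugged in.  Useful for
#' oracle checks and coverage studies.
#'
#' @param truth a \code{gw_truth}.
#' @param grid evaluation grid; default 51 points over the truth's domain.
#' @return an object of class \code{"gw_fpca"}.
#' @export
fpca_model_from_truth <- function(truth, grid = NULL) {
  stopifnot(inherits(truth, "gw_truth"))
  if (is.null(grid)) grid <- default_grid(truth$domain, 51L)
  Phi <- vapply(truth$eigenfunctions, function(f) f(grid),
                numeric(length(grid)))
  w <- trapz_weights(grid)
  nrm <- sqrt(colSums(w * Phi^2))
  Phi <- sweep(Phi, 2L, nrm, "/")
  lam <- truth$eigenvalues * nrm^2
  surface <- Phi %*% (lam * t(Phi))
  mean <- structure(list(grid = grid,
                         values = truth$mean_function(grid),
                         bandwidth = NA_real_, kernel = "none"),
                    class = "gw_smooth1d")
  covm <- structure(list(grid = grid, surface = surface,
                         diag_smooth = diag(surface),
                         v_hat = diag(surface) + truth$noise_sd^2,
                         sigma2 = truth$noise_sd^2,
                         bandwidths = c(NA_real_, NA_real_)),
                    class = "gw_cov")
  eig <- structure(list(values = lam, functions = Phi,
                        fve = cumsum(lam) / sum(lam), grid = grid),
                   class = "gw_eigen")
  structure(list(mean = mean, covariance = covm, eigen = eig,
                 K = length(lam), fve_threshold = 1,
                 n_subjects = NA_integer_, n_obs = NA_integer_),
            class = "gw_fpca")
}
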