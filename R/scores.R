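# Conditional-expectation FPC scores, trajectory reconstruction, and
# pointwise / simultaneous confidence bands.

# Cholesky solve with an escalating ridge for nearly singular observation
# covariances (nearly coincident visit times can occur).
chol_solve <- function(Sigma, rhs) {
  scale <- mean(diag(Sigma))
  for (eps in c(0, 10^seq(-8, -4))) {
    ch <- tryCatch(chol(Sigma + diag(eps * scale, nrow(Sigma))),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      return(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
    }
  }
  stop("observation covariance matrix is numerically singular ",
       "even after ridge regularization")
}

#' Conditional-expectation FPC scores for one subject
#'
#' Computes the best linear prediction of the subject's functional
#' principal component scores given her sparse noisy observations under
#' joint normality:
#' \eqn{\hat\xi_{ik} = \hat\lambda_k \hat\phi_{ik}^T \hat\Sigma_{Y_i}^{-1}
#' (Y_i - \hat\mu_i)}, where \eqn{\hat\Sigma_{Y_i}} has entries
#' \eqn{\hat G(T_{ij}, T_{il}) + \hat\sigma^2 \delta_{jl}}.  Also returns
#' the cross-covariance \eqn{H = (\lambda_1 \phi_{i1}, \ldots,
#' \lambda_K \phi_{iK})^T} and the score-error covariance
#' \eqn{\Omega_K = \Lambda - H \Sigma_{Y_i}^{-1} H^T} used by the
#' confidence bands.
#'
#' Model quantities are evaluated at the observation times by linear
#' interpolation.  The observation covariance is assembled from the
#' positive-part eigen-reconstruction of the smoothed surface (all
#' retained components), which keeps it positive semi-definite even when
#' the raw smoothed surface is indefinite; an escalating ridge handles
#' nearly coincident visit times.
#'
#' @param subject a list with numeric vectors \code{t} and \code{y} (e.g.
#'   from [get_subject()]), at least one observation inside the model
#'   domain.
#' @param model a \code{gw_fpca}.
#' @param noise_floor_frac the measurement-error variance entering
#'   \eqn{\Sigma_{Y_i}} is floored at this fraction of the average total
#'   variance \eqn{\bar{\hat V}} (default 0.01).  A noise estimate of
#'   exactly zero would make \eqn{\Sigma_{Y_i}} rank-deficient whenever a
#'   subject has more observations than there are retained components and
#'   the conditioning would then chase measurement noise; the floor is the
#'   usual regularization of the conditional-expectation step.
#' @return an object of class \code{"gw_scores"}: \code{scores} (length
#'   K), \code{Sigma_Yi}, \code{H}, \code{Omega_K}, \code{times},
#'   \code{subject_id}.
#' @export
predict_scores <- function(subject, model, noise_floor_frac = 0.01) {
  stopifnot(inherits(model, "gw_fpca"))
  tt <- subject$t; yy <- subject$y
  stopifnot(length(tt) >= 1L, length(tt) == length(yy))
  grid <- model$mean$grid
  if (any(tt < min(grid) - 1e-8 | tt > max(grid) + 1e-8)) {
    stop("observation times outside the model domain")
  }
  K <- model$K
  N <- length(tt)
  lam <- model$eigen$values[seq_len(K)]
  mu_i <- lin_interp(grid, model$mean$values, tt)
  Phi_i <- vapply(seq_len(K), function(k) {
    lin_interp(model$eigen$grid, model$eigen$functions[, k], tt)
  }, numeric(N))
  Phi_i <- matrix(Phi_i, nrow = N, ncol = K)
  # Sigma_Yi uses the positive-part eigen-reconstruction of the smoothed
  # covariance surface (all retained components, not just K): the raw
  # smoothed surface can be indefinite, which would make the observation
  # covariance non-invertible
  K_all <- length(model$eigen$values)
  Phi_all <- vapply(seq_len(K_all), function(k) {
    lin_interp(model$eigen$grid, model$eigen$functions[, k], tt)
  }, numeric(N))
  Phi_all <- matrix(Phi_all, nrow = N, ncol = K_all)
  G_i <- Phi_all %*% (model$eigen$values * t(Phi_all))
  G_i <- (G_i + t(G_i)) / 2
  vbar <- mean(model$covariance$v_hat)
  sigma2 <- max(model$covariance$sigma2, noise_floor_frac * vbar)
  Sigma <- G_i + diag(sigma2, N)
  H <- lam * t(Phi_i)                       # K x N, rows lambda_k phi_k(T_i)
  SinvR <- chol_solve(Sigma, cbind(yy - mu_i, t(H)))
  scores <- drop(H %*% SinvR[, 1L, drop = FALSE])
  Omega <- diag(lam, K) - H %*% SinvR[, -1L, drop = FALSE]
  Omega <- (Omega + t(Omega)) / 2
  structure(list(scores = scores, Sigma_Yi = Sigma, H = H,
                 Omega_K = Omega, times = tt, K = K,
                 subject_id = subject$subject_id %||% NA_character_),
            class = "gw_scores")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confidence bands for a reconstructed trajectory
#'
#' The band half-width at time \eqn{t} is
#' \eqn{q \sqrt{\phi_{K,t}^T \hat\Omega_K \phi_{K,t}}} with
#' \eqn{q = \Phi^{-1}(1 - \alpha/2)} for pointwise bands and
#' \eqn{q = \sqrt{\chi^2_{K, 1-\alpha}}} for bands that hold
#' simultaneously over the whole trajectory.  Negative variances arising
#' from an indefinite \eqn{\hat\Omega_K} are clamped to zero with a
#' warning.
#'
#' @param scores a \code{gw_scores}.
#' @param model the \code{gw_fpca} used to produce the scores.
#' @param grid evaluation times; default the model grid.
#' @param alpha significance level in (0, 1).
#' @param simultaneous logical; simultaneous or pointwise multiplier.
#' @return list with \code{lower} and \code{upper} band values on
#'   \code{grid}.
#' @export
confidence_bands <- function(scores, model, grid = model$mean$grid,
                             alpha = 0.05, simultaneous = FALSE) {
  stopifnot(inherits(scores, "gw_scores"), alpha > 0, alpha < 1)
  K <- scores$K
  PhiG <- vapply(seq_len(K), function(k) {
    lin_interp(model$eigen$grid, model$eigen$functions[, k], grid)
  }, numeric(length(grid)))
  PhiG <- matrix(PhiG, nrow = length(grid), ncol = K)
  values <- lin_interp(model$mean$grid, model$mean$values, grid) +
    drop(PhiG %*% scores$scores)
  v <- rowSums((PhiG %*% scores$Omega_K) * PhiG)
  if (any(v < -1e-10 * max(1, max(abs(v))))) {
    warning("negative band variance clamped to 0")
  }
  v <- pmax(v, 0)
  q <- if (simultaneous) sqrt(stats::qchisq(1 - alpha, df = K)) else
    stats::qnorm(1 - alpha / 2)
  hw <- q * sqrt(v)
  list(lower = values - hw, upper = values + hw)
}

#' Reconstruct an individual trajectory with confidence bands
#'
#' \eqn{\hat X_{iK}(t) = \hat\mu(t) + \sum_{k \le K} \hat\xi_{ik}
#' \hat\phi_k(t)}, with pointwise and simultaneous bands attached.
#'
#' @param scores a \code{gw_scores}.
#' @param model the \code{gw_fpca} used to produce the scores.
#' @param grid evaluation times; default the model grid.
#' @param alpha significance level for both bands.
#' @return an object of class \code{"gw_traj"}: \code{grid},
#'   \code{values}, \code{pointwise_lo/hi}, \code{simultaneous_lo/hi},
#'   \code{alpha}, \code{subject_id}.
#' @export
reconstruct_trajectory <- function(scores, model, grid = model$mean$grid,
                                   alpha = 0.05) {
  stopifnot(inherits(scores, "gw_scores"))
  K <- scores$K
  PhiG <- vapply(seq_len(K), function(k) {
    lin_interp(model$eigen$grid, model$eigen$functions[, k], grid)
  }, numeric(length(grid)))
  PhiG <- matrix(PhiG, nrow = length(grid), ncol = K)
  values <- lin_interp(model$mean$grid, model$mean$values, grid) +
    drop(PhiG %*% scores$scores)
  pw <- confidence_bands(scores, model, grid, alpha, simultaneous = FALSE)
  sb <- confidence_bands(scores, model, grid, alpha, simultaneous = TRUE)
  structure(list(grid = grid, values = values,
                 pointwise_lo = pw$lower, pointwise_hi = pw$upper,
                 simultaneous_lo = sb$lower, simultaneous_hi = sb$upper,
                 alpha = alpha, subject_id = scores$subject_id),
            class = "gw_traj")
}

#' Reconstruct trajectories for every subject in a cohort
#'
#' @param cohort a \code{gw_cohort}.
#' @param model a \code{gw_fpca}.
#' @param alpha significance level for the bands.
#' @param grid evaluation times; default the model grid.
#' @return named list of \code{gw_traj}, keyed by subject id.
#' @export
reconstruct_all <- function(cohort, model, alpha = 0.05,
                            grid = model$mean$grid) {
  ids <- cohort$subjects$subject_id
  obs <- split(cohort$observations, cohort$observations$subject_id)
  out <- lapply(ids, function(id) {
    oi <- obs[[id]]
    sc <- predict_scores(list(subject_id = id, t = oi$t, y = oi$y), model)
    reconstruct_trajectory(sc, model, grid = grid, alpha = alpha)
  })
  names(out) <- ids
  out
}

#' @export
print.gw_traj <- function(x, ...) {
  cat("Reconstructed trajectory",
      if (!is.na(x$subject_id)) paste0("for subject ", x$subject_id),
      "on", length(x$grid), "grid points\n")
  cat(sprintf("  value range %.1f-%.1f kg; %d%% simultaneous band width %.2f kg (median)\n",
              min(x$values), max(x$values), round(100 * (1 - x$alpha)),
              stats::median(x$simultaneous_hi - x$simultaneous_lo)))
  invisible(x)
}
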