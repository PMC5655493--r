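# Logistic nonlinear mixed-effects comparator: W(t) = L / (1 + exp(-k (t -
# t0))) + c with random magnitude L and baseline c, fixed steepness k, and
# the inflection t0 fixed at week 30 by default.

#' Logistic growth mean function
#'
#' \eqn{W(t) = L / (1 + e^{-k (t - t_0)}) + c}, evaluated overflow-safely.
#' \eqn{L} acts as a magnifying factor related to the total weight gain,
#' \eqn{k} is the steepness, \eqn{t_0} the inflection point, and \eqn{c} a
#' baseline interpretable as the prepregnancy weight.
#'
#' @param t time in weeks (vectorized).
#' @param L,k,t0,c curve parameters (kg, per week, weeks, kg).
#' @return weight in kg.
#' @export
logistic_mean <- function(t, L, k, t0, c) {
  L * stats::plogis(k * (t - t0)) + c
}

#' Fit the logistic nonlinear mixed-effects model
#'
#' Maximizes the Lindstrom-Bates linearized likelihood (via
#' \code{nlme::nlme}) for the logistic curve with subject-level random
#' \eqn{(L_i, c_i)} (unstructured 2x2 covariance) and fixed steepness
#' \eqn{k}; \eqn{t_0} is held fixed (default week 30, where the mean
#' weight curve inflects).  Starting values are a population-level
#' nonlinear least-squares fit initialized at \eqn{c_0 =} mean earliest
#' weight, \eqn{L_0 =} mean observed gain, \eqn{k_0 = 0.15}/week.  If that
#' population curve already fits all observations essentially exactly
#' (residual mean square below 1e-6 kg^2) the maximum-likelihood solution
#' has zero random-effect and residual variance and is returned directly.
#'
#' @param cohort a \code{gw_cohort} with at least 20 subjects having two
#'   or more observations.
#' @param t0 fixed inflection point, weeks.
#' @param start optional named numeric starting values \code{c(L, k, c)}.
#' @return an object of class \code{"gw_nlme"}: fixed effects \code{k},
#'   \code{mu_L}, \code{mu_c}; random-effect (co)variances \code{var_L},
#'   \code{var_c}, \code{cov_Lc}; \code{sigma2_resid}; per-subject
#'   empirical Bayes estimates in \code{coef} (columns \code{subject_id},
#'   \code{L}, \code{c}); and the underlying \code{nlme} fit (when one was
#'   run).
#' @export
fit_nlme <- function(cohort, t0 = 30, start = NULL) {
  stopifnot(inherits(cohort, "gw_cohort"))
  obs <- cohort$observations
  nobs <- table(obs$subject_id)
  if (sum(nobs >= 2L) < 20L) {
    stop("need at least 20 subjects with >= 2 observations")
  }
  d <- data.frame(id = factor(obs$subject_id), t = obs$t, y = obs$y,
                  t0 = t0)
  if (is.null(start)) {
    first_y <- tapply(obs$y[order(obs$subject_id, obs$t)],
                      obs$subject_id[order(obs$subject_id, obs$t)],
                      function(v) v[1L])
    last_y <- tapply(obs$y[order(obs$subject_id, obs$t)],
                     obs$subject_id[order(obs$subject_id, obs$t)],
                     function(v) v[length(v)])
    start <- c(L = max(1, mean(last_y - first_y)), k = 0.15,
               c = mean(first_y))
  }
  pop <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ L * plogis(k * (t - t0)) + c, data = d,
                 start = as.list(start),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(pop)) {
    cf <- stats::coef(pop)
    rms <- mean(stats::residuals(pop)^2)
    if (is.finite(rms) && rms < 1e-6) {
      ids <- levels(d$id)
      return(structure(list(
        k = cf[["k"]], t0 = t0, mu_L = cf[["L"]], mu_c = cf[["c"]],
        var_L = 0, var_c = 0, cov_Lc = 0, sigma2_resid = rms,
        coef = data.frame(subject_id = ids,
                          L = rep(cf[["L"]], length(ids)),
                          c = rep(cf[["c"]], length(ids)),
                          stringsAsFactors = FALSE),
        degenerate = TRUE, fit = pop), class = "gw_nlme"))
    }
    start <- cf
  }
  fit <- tryCatch(
    nlme::nlme(y ~ L * plogis(k * (t - t0)) + c,
               fixed = L + k + c ~ 1,
               random = L + c ~ 1 | id,
               data = d,
               start = start[c("L", "k", "c")],
               control = nlme::nlmeControl(maxIter = 500, msMaxIter = 200,
                                           tolerance = 1e-8)),
    error = function(e) {
      stop("logistic NLME failed to converge: ", conditionMessage(e),
           call. = FALSE)
    })
  fe <- nlme::fixef(fit)
  vc <- as.matrix(fit$modelStruct$reStruct[[1L]]) * fit$sigma^2
  cf <- stats::coef(fit)               # per-subject L, k, c
  structure(list(
    k = fe[["k"]], t0 = t0, mu_L = fe[["L"]], mu_c = fe[["c"]],
    var_L = vc["L", "L"], var_c = vc["c", "c"], cov_Lc = vc["L", "c"],
    sigma2_resid = fit$sigma^2,
    coef = data.frame(subject_id = rownames(cf), L = cf$L, c = cf$c,
                      stringsAsFactors = FALSE),
    degenerate = FALSE, fit = fit), class = "gw_nlme")
}

#' @export
print.gw_nlme <- function(x, ...) {
  cat("Logistic NLME fit (t0 =", x$t0, "weeks)\n")
  cat(sprintf("  fixed: k = %.4f /week, mu_L = %.2f kg, mu_c = %.2f kg\n",
              x$k, x$mu_L, x$mu_c))
  cat(sprintf("  random: sd_L = %.2f, sd_c = %.2f, cor = %.2f; resid var %.3f kg^2\n",
              sqrt(x$var_L), sqrt(x$var_c),
              ifelse(x$var_L * x$var_c > 0,
                     x$cov_Lc / sqrt(x$var_L * x$var_c), 0),
              x$sigma2_resid))
  invisible(x)
}

#' Percentage reduction in residual variance
#'
#' \code{100 * (1 - resid_var_fpca / resid_var_nlme)}: how much smaller
#' the FPCA residual variance is than the comparator's.
#'
#' @param resid_var_fpca,resid_var_nlme residual variances, kg^2.
#' @return percentage (positive when FPCA fits better).
#' @export
residual_variance_reduction <- function(resid_var_fpca, resid_var_nlme) {
  100 * (1 - resid_var_fpca / resid_var_nlme)
}

#' Compare FPCA and NLME fits on observed weights
#'
#' Evaluates both models' fitted weights at every observed (subject, time)
#' pair and pools the squared residuals:
#' \deqn{MSE = \frac{1}{\sum_i N_i} \sum_i \sum_j (\hat W(T_{ij}) -
#' W(T_{ij}))^2, \qquad RMSE = \sqrt{MSE}.}
#' Residual variances are the per-model MSEs and the percentage reduction
#' is computed by [residual_variance_reduction()].  Subjects missing from
#' either fit are excluded (with a message reporting the count).
#'
#' @param cohort a \code{gw_cohort}.
#' @param fpca_model the fitted \code{gw_fpca} (recorded for reference).
#' @param fpca_trajectories named list of \code{gw_traj} keyed by subject
#'   id, e.g. from [reconstruct_all()].
#' @param nlme_fit a \code{gw_nlme}.
#' @return an object of class \code{"gw_compare"}: \code{mse_fpca},
#'   \code{mse_nlme}, \code{rmse_fpca}, \code{rmse_nlme},
#'   \code{resid_var_fpca}, \code{resid_var_nlme}, \code{pct_reduction},
#'   \code{n_obs}, \code{n_subjects}, \code{n_dropped}.
#' @export
compare_models <- function(cohort, fpca_model, fpca_trajectories,
                           nlme_fit) {
  stopifnot(inherits(cohort, "gw_cohort"), inherits(nlme_fit, "gw_nlme"))
  obs <- cohort$observations
  ids <- unique(obs$subject_id)
  have <- ids[ids %in% names(fpca_trajectories) &
                ids %in% nlme_fit$coef$subject_id]
  dropped <- length(ids) - length(have)
  if (dropped > 0L) {
    message(dropped, " subject(s) missing from one of the fits; excluded")
  }
  obs <- obs[obs$subject_id %in% have, , drop = FALSE]
  cf <- nlme_fit$coef[match(obs$subject_id, nlme_fit$coef$subject_id), ]
  yhat_nlme <- logistic_mean(obs$t, cf$L, nlme_fit$k, nlme_fit$t0, cf$c)
  yhat_fpca <- vapply(seq_len(nrow(obs)), function(i) {
    tr <- fpca_trajectories[[obs$subject_id[i]]]
    lin_interp(tr$grid, tr$values, obs$t[i])
  }, numeric(1))
  mse_f <- mean((yhat_fpca - obs$y)^2)
  mse_n <- mean((yhat_nlme - obs$y)^2)
  structure(list(mse_fpca = mse_f, mse_nlme = mse_n,
                 rmse_fpca = sqrt(mse_f), rmse_nlme = sqrt(mse_n),
                 resid_var_fpca = mse_f, resid_var_nlme = mse_n,
                 pct_reduction = residual_variance_reduction(mse_f, mse_n),
                 n_obs = nrow(obs), n_subjects = length(have),
                 n_dropped = dropped),
            class = "gw_compare")
}

#' @export
print.gw_compare <- function(x, ...) {
  cat("Model fit comparison over", x$n_obs, "observations from",
      x$n_subjects, "subjects\n")
  cat(sprintf("  FPCA: MSE %.3f kg^2 (RMSE %.3f kg)\n",
              x$mse_fpca, x$rmse_fpca))
  cat(sprintf("  NLME: MSE %.3f kg^2 (RMSE %.3f kg)\n",
              x$mse_nlme, x$rmse_nlme))
  cat(sprintf("  residual-variance reduction: %.1f%%\n", x$pct_reduction))
  invisible(x)
}
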