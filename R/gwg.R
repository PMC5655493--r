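# Inclusion filters, the four gestational weight-change outcomes (G, LG
# from the records; G', LG' from the reconstructed trajectory), and the
# linear regression stage relating weight change to prepregnancy BMI,
# average caloric intake, and average physical-activity index.

#' Apply the cohort inclusion criteria
#'
#' Retains subjects with a full-term birth (GA at birth >= 37 weeks), a
#' prepregnancy weight record (W0), at least one measured weight
#' (WA/WB/WC), at least one diet or physical-activity record, a
#' prepregnancy BMI (requires a height measurement), and internally
#' consistent gestational ages (GA at birth greater than the GA of every
#' measured weight).  Each excluded subject is logged with the first rule
#' she fails, in the order above.
#'
#' @param cohort a \code{gw_cohort}.
#' @return the filtered \code{gw_cohort}, with the exclusion log attached
#'   as attribute \code{"exclusion_log"} (see [exclusion_log()]).  Errors
#'   if no subject passes.
#' @export
apply_inclusion_criteria <- function(cohort) {
  stopifnot(inherits(cohort, "gw_cohort"))
  sub <- cohort$subjects
  obs <- split(cohort$observations, cohort$observations$subject_id)
  measured <- c("WA", "WB", "WC")
  reason <- vapply(seq_len(nrow(sub)), function(i) {
    oi <- obs[[sub$subject_id[i]]]
    labs <- if (is.null(oi)) character(0) else oi$label
    if (sub$ga_birth[i] < 37) return("preterm birth (GA < 37 weeks)")
    if (!"W0" %in% labs) return("missing prepregnancy weight (W0)")
    if (!any(labs %in% measured)) return("no measured weight (WA/WB/WC)")
    if (is.na(sub$mean_caloric[i]) && is.na(sub$mean_pa_index[i])) {
      return("no diet or physical-activity record")
    }
    if (is.na(sub$bmi_p[i])) return("missing prepregnancy BMI")
    tmax <- max(oi$t[oi$label %in% measured])
    if (tmax >= sub$ga_birth[i]) {
      return("inconsistent gestational ages (measured weight at/after birth)")
    }
    NA_character_
  }, character(1))
  keep <- is.na(reason)
  if (!any(keep)) stop("no subjects pass the inclusion criteria")
  log <- data.frame(subject_id = sub$subject_id[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  out <- new_cohort(
    cohort$observations[cohort$observations$subject_id %in%
                          sub$subject_id[keep], , drop = FALSE],
    sub[keep, , drop = FALSE], domain = cohort$domain,
    truth = if (!is.null(cohort$truth)) {
      list(model = cohort$truth$model,
           scores = cohort$truth$scores[keep, , drop = FALSE])
    },
    logistic_truth = cohort$logistic_truth)
  attr(out, "exclusion_log") <- log
  out
}

#' Exclusion log of a filtered cohort
#'
#' @param cohort a cohort returned by [apply_inclusion_criteria()].
#' @return data frame with columns \code{subject_id} and \code{reason}.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) {
    log <- data.frame(subject_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  }
  log
}

#' Gestational weight-change outcomes for one subject
#'
#' Direct outcomes from the weight records: \eqn{G = \max\{W_H, W_C\} -
#' W_0} and \eqn{LG = \log(\max\{W_H, W_C\} / W_0)} (when one of
#' \eqn{W_H, W_C} is missing the available one is used; when both are
#' missing, or \eqn{W_0} is missing, the direct outcomes are flagged
#' unusable rather than raising an error).  Trajectory-based outcomes,
#' when a reconstructed trajectory is supplied: \eqn{G'} and \eqn{LG'}
#' computed from the trajectory values at the subject's GA at birth and at
#' week 0 (linear interpolation on the trajectory grid).
#'
#' @param subject a subject record from [get_subject()].
#' @param trajectory optional \code{gw_traj} for the same subject.
#' @return one-row data frame: \code{subject_id}, \code{G}, \code{LG},
#'   \code{G_prime}, \code{LG_prime}, \code{usable_direct},
#'   \code{usable_trajectory}.
#' @export
compute_weight_change <- function(subject, trajectory = NULL) {
  pick <- function(lab) {
    v <- subject$y[subject$label == lab]
    if (length(v)) v[1L] else NA_real_
  }
  W0 <- pick("W0"); WH <- pick("WH"); WC <- pick("WC")
  top <- suppressWarnings(max(WH, WC, na.rm = TRUE))
  usable <- is.finite(W0) && W0 > 0 && is.finite(top)
  G <- if (usable) top - W0 else NA_real_
  LG <- if (usable) log(top / W0) else NA_real_
  Gp <- LGp <- NA_real_
  usable_t <- FALSE
  if (!is.null(trajectory)) {
    v0 <- lin_interp(trajectory$grid, trajectory$values, 0)
    vT <- lin_interp(trajectory$grid, trajectory$values, subject$ga_birth)
    if (is.finite(v0) && v0 > 0 && is.finite(vT)) {
      Gp <- vT - v0
      LGp <- log(vT / v0)
      usable_t <- TRUE
    }
  }
  data.frame(subject_id = subject$subject_id, G = G, LG = LG,
             G_prime = Gp, LG_prime = LGp, usable_direct = usable,
             usable_trajectory = usable_t, stringsAsFactors = FALSE)
}

#' Weight-change outcomes for every subject
#'
#' @param cohort a \code{gw_cohort}.
#' @param trajectories optional named list of \code{gw_traj} keyed by
#'   subject id (e.g. from [reconstruct_all()]); required for the
#'   trajectory-based outcomes.
#' @return data frame, one row per subject, as in
#'   [compute_weight_change()].
#' @export
compute_outcomes <- function(cohort, trajectories = NULL) {
  rows <- lapply(cohort$subjects$subject_id, function(id) {
    compute_weight_change(get_subject(cohort, id), trajectories[[id]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress a weight-change outcome on subject covariates
#'
#' Ordinary least squares with intercept.  The reported RMSE is the root
#' mean squared residual with denominator \eqn{n} (configurable to
#' \eqn{n - p}); \eqn{R^2} is unadjusted.
#'
#' @param outcomes outcome table from [compute_outcomes()].
#' @param subjects subject-level table (\code{cohort$subjects}).
#' @param response one of \code{"G"}, \code{"LG"}, \code{"G_prime"},
#'   \code{"LG_prime"}.
#' @param covariates character vector of column names in \code{subjects};
#'   default \code{"bmi_p"}.
#' @param stratum optional instrument label; when given, only subjects
#'   with that instrument enter the fit (strata are never pooled).
#' @param df_denominator \code{"n"} (default) or \code{"n-p"} for the
#'   RMSE.
#' @return list of class \code{"gw_regrow"}: \code{response},
#'   \code{covariates}, \code{stratum}, \code{n}, \code{coefficients},
#'   \code{se}, \code{r_squared}, \code{rmse}, and the underlying
#'   \code{lm} fit.
#' @export
regress_outcomes <- function(outcomes, subjects, response,
                             covariates = "bmi_p", stratum = NULL,
                             df_denominator = c("n", "n-p")) {
  df_denominator <- match.arg(df_denominator)
  stopifnot(response %in% c("G", "LG", "G_prime", "LG_prime"),
            all(covariates %in% names(subjects)))
  d <- merge(outcomes, subjects, by = "subject_id")
  if (!is.null(stratum)) d <- d[d$instrument == stratum, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c(response, covariates)]), ,
         drop = FALSE]
  if (nrow(d) < 10L) stop("fewer than 10 complete cases")
  X <- stats::model.matrix(stats::reformulate(covariates), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear covariates: ", paste(bad, collapse = ", "))
  }
  fm <- stats::lm(stats::reformulate(covariates, response), data = d)
  sm <- summary(fm)
  res <- stats::residuals(fm)
  denom <- if (df_denominator == "n") length(res) else fm$df.residual
  structure(list(response = response, covariates = covariates,
                 stratum = stratum %||% "all", n = nrow(d),
                 coefficients = stats::coef(fm),
                 se = sm$coefficients[, "Std. Error"],
                 r_squared = sm$r.squared,
                 rmse = sqrt(sum(res^2) / denom),
                 fit = fm),
            class = "gw_regrow")
}

#' @export
print.gw_regrow <- function(x, ...) {
  cat(sprintf("%s ~ %s  [%s, n = %d]\n", x$response,
              paste(x$covariates, collapse = " + "), x$stratum, x$n))
  cat(sprintf("  R^2 = %.2f, RMSE = %.3g\n", x$r_squared, x$rmse))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Table of regressions across responses, covariate sets and strata
#'
#' Fits every combination of response (\code{G}, \code{LG},
#' \code{G_prime}, \code{LG_prime}) and covariate set (prepregnancy BMI
#' alone; BMI + average caloric intake + average PA index), separately per
#' stratum.  Combinations with too few complete cases are skipped.
#'
#' @param outcomes outcome table from [compute_outcomes()].
#' @param subjects subject-level table.
#' @param strata instrument labels to fit separately; default the strata
#'   present in \code{subjects}.
#' @return data frame of class \code{"gw_regreport"} with one row per
#'   fitted model: \code{response}, \code{predictors}, \code{stratum},
#'   \code{n}, intercept and slope estimates, \code{r_squared},
#'   \code{rmse}.
#' @export
regression_report <- function(outcomes, subjects,
                              strata = unique(subjects$instrument)) {
  sets <- list(bmi = "bmi_p",
               full = c("bmi_p", "mean_caloric", "mean_pa_index"))
  rows <- list()
  for (st in strata) {
    for (resp in c("G", "LG", "G_prime", "LG_prime")) {
      for (sn in names(sets)) {
        r <- tryCatch(
          regress_outcomes(outcomes, subjects, resp, sets[[sn]],
                           stratum = st),
          error = function(e) NULL)
        if (is.null(r)) next
        cf <- r$coefficients
        rows[[length(rows) + 1L]] <- data.frame(
          response = resp,
          predictors = paste(sets[[sn]], collapse = "+"),
          stratum = st, n = r$n,
          intercept = cf[["(Intercept)"]],
          beta_bmi = cf[["bmi_p"]],
          beta_caloric = if ("mean_caloric" %in% names(cf))
            cf[["mean_caloric"]] else NA_real_,
          beta_pa = if ("mean_pa_index" %in% names(cf))
            cf[["mean_pa_index"]] else NA_real_,
          r_squared = r$r_squared, rmse = r$rmse,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gw_regreport", class(out))
  out
}

#' @export
print.gw_regreport <- function(x, ...) {
  cat("Weight-change regressions (R^2 (RMSE) by response and predictors)\n")
  for (st in unique(x$stratum)) {
    cat(" stratum:", st, "\n")
    xs <- x[x$stratum == st, , drop = FALSE]
    for (resp in unique(xs$response)) {
      xr <- xs[xs$response == resp, , drop = FALSE]
      cells <- sprintf("%s: %.2f (%.3g)", xr$predictors, xr$r_squared,
                       xr$rmse)
      cat(sprintf("  %-8s %s\n", resp, paste(cells, collapse = "   ")))
    }
  }
  invisible(x)
}
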