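# Generative truth for synthetic cohorts: a Karhunen-Loeve model
# X(t) = mu(t) + sum_k xi_k phi_k(t), observed with noise and, for the two
# self-reported weights, with reporting bias.

#' Orthonormal cosine basis on an interval
#'
#' \eqn{\phi_1 = 1/\sqrt{L}}, \eqn{\phi_k(t) = \sqrt{2/L}\cos((k-1)\pi (t-a)/L)}
#' for \eqn{k \ge 2}.  These are exactly orthonormal under the composite
#' trapezoid rule on any uniform grid, which makes them convenient
#' eigenfunctions for generative truths.
#'
#' @param K number of basis functions.
#' @param domain length-2 interval, default gestational weeks \code{c(0, 42)}.
#' @return list of \code{K} vectorized functions.
#' @export
cosine_basis <- function(K, domain = c(0, 42)) {
  L <- diff(domain)
  a <- domain[1L]
  lapply(seq_len(K), function(k) {
    if (k == 1L) {
      function(t) rep(1 / sqrt(L), length(t))
    } else {
      m <- k - 1L
      force(m)
      function(t) sqrt(2 / L) * cos(m * pi * (t - a) / L)
    }
  })
}

#' Generative truth for synthetic gestational-weight cohorts
#'
#' Bundles the components of the Karhunen-Loeve model used to simulate
#' cohorts: the mean weight function, orthonormal eigenfunctions with
#' decreasing eigenvalues, the measurement-noise standard deviation, an
#' optional linear link from prepregnancy BMI to the log relative weight
#' gain, and the reporting-bias distributions for the two self-reported
#' weights (prepregnancy weight at week 0 and highest weight at delivery).
#'
#' Eigenfunctions must be orthonormal under trapezoid quadrature on a
#' 201-point uniform grid over \code{domain} (tolerance 1e-6) and
#' eigenvalues strictly decreasing; violations are rejected.
#'
#' @param mean_function vectorized function of gestational week, kg.
#' @param eigenfunctions list of vectorized orthonormal functions.
#' @param eigenvalues strictly decreasing non-negative variances (kg^2 week).
#' @param noise_sd measurement-error standard deviation, kg.
#' @param bmi_link \code{NULL}, or \code{list(beta0, beta1, resid_sd)} so that
#'   each subject's true log relative gain is
#'   \code{beta0 + beta1 * bmi_p + N(0, resid_sd^2)}.
#' @param report_bias \code{list(w0 = c(mean, sd), wh = c(mean, sd))}:
#'   additive reporting error (kg) on the self-reported prepregnancy and
#'   highest weights.
#' @param bmi_median,bmi_sdlog log-normal prepregnancy BMI distribution.
#' @param height_mean,height_sd normal height distribution (m).
#' @param domain time domain in weeks.
#' @return an object of class \code{"gw_truth"}.
#' @seealso [make_study_truth()], [generate_cohort()]
#' @export
true_model <- function(mean_function, eigenfunctions, eigenvalues,
                       noise_sd = 0,
                       bmi_link = NULL,
                       report_bias = list(w0 = c(mean = 0, sd = 0),
                                          wh = c(mean = 0, sd = 0)),
                       bmi_median = 23, bmi_sdlog = 0.15,
                       height_mean = 1.64, height_sd = 0.06,
                       domain = c(0, 42)) {
  stopifnot(is.function(mean_function), is.list(eigenfunctions),
            length(eigenfunctions) == length(eigenvalues),
            length(eigenvalues) >= 1L)
  if (any(eigenvalues < 0)) stop("eigenvalues must be non-negative")
  if (length(eigenvalues) > 1L && any(diff(eigenvalues) >= 0)) {
    stop("eigenvalues must be strictly decreasing")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(bmi_link)) {
    stopifnot(is.list(bmi_link),
              all(c("beta0", "beta1", "resid_sd") %in% names(bmi_link)))
    if (length(eigenvalues) < 2L) {
      stop("bmi_link requires at least 2 eigenfunctions")
    }
  }
  g <- seq(domain[1L], domain[2L], length.out = 201L)
  Phi <- vapply(eigenfunctions, function(f) f(g), numeric(length(g)))
  w <- trapz_weights(g)
  Gram <- crossprod(Phi, Phi * w)
  if (max(abs(Gram - diag(length(eigenvalues)))) > 1e-6) {
    stop("eigenfunctions are not orthonormal under trapezoid quadrature ",
         "(tolerance 1e-6)")
  }
  structure(list(mean_function = mean_function,
                 eigenfunctions = eigenfunctions,
                 eigenvalues = as.numeric(eigenvalues),
                 noise_sd = noise_sd,
                 bmi_link = bmi_link,
                 report_bias = report_bias,
                 bmi_median = bmi_median, bmi_sdlog = bmi_sdlog,
                 height_mean = height_mean, height_sd = height_sd,
                 domain = domain),
            class = "gw_truth")
}

#' Default generative truth mimicking a gestational-weight cohort
#'
#' A logistic-shaped mean weight curve (baseline near 62 kg, total gain
#' near 13 kg, inflection at week 30), three cosine eigenfunctions whose
#' eigenvalue fractions are close to (0.957, 0.028, 0.011), measurement
#' noise of 1 kg by default, a negative BMI link on the log relative gain
#' (slope -0.012 per kg/m^2), and self-report bias of -1 kg (sd 1) on the
#' prepregnancy weight and +1 kg (sd 1) on the reported highest weight.
#'
#' When the BMI link is active the first two subject scores are determined
#' by the subject's baseline weight (BMI x height^2) and her linked log
#' relative gain; the stated eigenvalues for those components are the
#' (approximate) variances those constructions imply, so the truth remains
#' internally consistent.
#'
#' @param noise_sd measurement-error standard deviation in kg (default 1).
#' @return an object of class \code{"gw_truth"}.
#' @export
make_study_truth <- function(noise_sd = 1) {
  # lambda_1 and lambda_2 are the score variances the BMI-linked
  # construction implies (measured on a 60000-subject simulation): the
  # baseline weight BMI x height^2 drives the level component, the linked
  # log relative gain drives the gain-contrast component.  Fractions are
  # (0.961, 0.027, 0.011).
  true_model(
    mean_function = function(t) 62.47 + 16 * stats::plogis(0.15 * (t - 30)),
    eigenfunctions = cosine_basis(3L),
    eigenvalues = c(4600, 131, 54),
    noise_sd = noise_sd,
    bmi_link = list(beta0 = 0.462, beta1 = -0.012, resid_sd = 0.060),
    report_bias = list(w0 = c(mean = -1, sd = 1), wh = c(mean = 1, sd = 1))
  )
}

#' @export
print.gw_truth <- function(x, ...) {
  cat("Generative Karhunen-Loeve truth on [",
      x$domain[1L], ",", x$domain[2L], "] weeks\n")
  cat("  components:", length(x$eigenvalues),
      " eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  cat("  noise sd:", x$noise_sd, "kg\n")
  if (!is.null(x$bmi_link)) {
    cat("  BMI link: LG =", x$bmi_link$beta0, "+", x$bmi_link$beta1,
        "* BMI + N(0,", x$bmi_link$resid_sd, "^2)\n")
  }
  invisible(x)
}
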