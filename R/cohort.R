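# Cohort container and the synthetic-cohort generator emulating a
# trimester-based antenatal visit design: self-reported prepregnancy
# weight at week 0, up to three measured weights in trimester windows
# A/B/C, and a self-reported highest weight assigned to the gestational
# age at birth.

#' Antenatal visit design
#'
#' Trimester measurement windows, the full-term delivery window, per-visit
#' missingness probabilities, and the probability that a subject was
#' recruited after the first-trimester window (and therefore has no A
#' visit).
#'
#' @param window_A,window_B,window_C gestational-week intervals for the
#'   three measured visits; must be disjoint and increasing.
#' @param ga_birth_range gestational age at birth interval, weeks.
#' @param p_miss_A,p_miss_B,p_miss_C per-visit missingness probabilities.
#' @param p_late_recruit probability of recruitment after window A.
#' @return an object of class \code{"gw_design"}.
#' @export
visit_design <- function(window_A = c(8, 13), window_B = c(14, 27),
                         window_C = c(28, 36), ga_birth_range = c(37, 42),
                         p_miss_A = 0.1, p_miss_B = 0.1, p_miss_C = 0.1,
                         p_late_recruit = 0.25) {
  wins <- list(window_A, window_B, window_C)
  for (w in wins) stopifnot(length(w) == 2L, w[1L] < w[2L])
  if (!(window_A[2L] < window_B[1L] && window_B[2L] < window_C[1L])) {
    stop("visit windows must be pairwise disjoint and increasing")
  }
  stopifnot(length(ga_birth_range) == 2L,
            ga_birth_range[1L] < ga_birth_range[2L])
  p <- c(p_miss_A, p_miss_B, p_miss_C, p_late_recruit)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(window_A = window_A, window_B = window_B,
                 window_C = window_C, ga_birth_range = ga_birth_range,
                 p_miss_A = p_miss_A, p_miss_B = p_miss_B,
                 p_miss_C = p_miss_C, p_late_recruit = p_late_recruit),
            class = "gw_design")
}

# internal constructor + validator for the cohort container
new_cohort <- function(observations, subjects, domain = c(0, 42),
                       truth = NULL, logistic_truth = NULL) {
  stopifnot(is.data.frame(observations), is.data.frame(subjects),
            all(c("subject_id", "t", "y", "label") %in% names(observations)),
            all(c("subject_id", "ga_birth", "bmi_p", "mean_caloric",
                  "mean_pa_index", "instrument") %in% names(subjects)))
  if (anyDuplicated(subjects$subject_id)) {
    stop("subject ids must be unique")
  }
  if (!all(observations$subject_id %in% subjects$subject_id)) {
    stop("observations refer to unknown subject ids")
  }
  if (any(observations$t < domain[1L] | observations$t > domain[2L])) {
    stop("observation times outside the domain")
  }
  if (any(observations$y <= 0)) stop("weights must be positive")
  w0 <- observations$label == "W0"
  if (any(observations$t[w0] != 0)) stop("label W0 requires t = 0")
  ord <- order(match(observations$subject_id, subjects$subject_id),
               observations$t)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL
  if (anyDuplicated(observations[c("subject_id", "t")])) {
    stop("observation times must be strictly increasing within subject")
  }
  if (!is.null(truth)) {
    stopifnot(is.matrix(truth$scores),
              nrow(truth$scores) == nrow(subjects))
  }
  structure(list(observations = observations, subjects = subjects,
                 domain = domain, truth = truth,
                 logistic_truth = logistic_truth),
            class = "gw_cohort")
}

#' @export
print.gw_cohort <- function(x, ...) {
  cat("Gestational-weight cohort:", nrow(x$subjects), "subjects,",
      nrow(x$observations), "observations on [",
      x$domain[1L], ",", x$domain[2L], "] weeks\n")
  cat("  observations per subject:",
      paste(range(table(x$observations$subject_id)), collapse = "-"), "\n")
  if (!is.null(x$truth)) cat("  generative truth attached\n")
  invisible(x)
}

#' Extract one subject's record
#'
#' @param cohort a \code{gw_cohort}.
#' @param id subject identifier.
#' @return list with \code{subject_id}, observation vectors \code{t},
#'   \code{y}, \code{label}, and the subject-level covariates.
#' @export
get_subject <- function(cohort, id) {
  srow <- cohort$subjects[cohort$subjects$subject_id == id, , drop = FALSE]
  if (nrow(srow) != 1L) stop("unknown subject id: ", id)
  obs <- cohort$observations[cohort$observations$subject_id == id, ,
                             drop = FALSE]
  list(subject_id = id, t = obs$t, y = obs$y, label = obs$label,
       ga_birth = srow$ga_birth, bmi_p = srow$bmi_p,
       mean_caloric = srow$mean_caloric,
       mean_pa_index = srow$mean_pa_index,
       instrument = srow$instrument)
}

obs_block <- function(ids, keep, tt, yy, label) {
  data.frame(subject_id = ids[keep], t = tt[keep], y = yy[keep],
             label = rep(label, sum(keep)), stringsAsFactors = FALSE)
}

# Solve the first two KL scores per subject so that the trajectory passes
# through the drawn baseline weight at t = 0 and through
# baseline * exp(LG) at the subject's GA at birth, where
# LG = beta0 + beta1 * BMI + eps is the linked log relative gain.
link_scores <- function(truth, bmi, height, ga_birth) {
  n <- length(bmi)
  K <- length(truth$eigenvalues)
  mu <- truth$mean_function
  phi <- truth$eigenfunctions
  w0_true <- bmi * height^2
  lg <- truth$bmi_link$beta0 + truth$bmi_link$beta1 * bmi +
    stats::rnorm(n, 0, truth$bmi_link$resid_sd)
  wT_true <- w0_true * exp(lg)
  extra <- matrix(0, n, max(0L, K - 2L))
  if (K > 2L) {
    for (k in 3:K) {
      extra[, k - 2L] <- stats::rnorm(n, 0, sqrt(truth$eigenvalues[k]))
    }
  }
  extra0 <- 0; extraT <- 0
  if (K > 2L) {
    for (k in 3:K) {
      extra0 <- extra0 + extra[, k - 2L] * phi[[k]](0)
      extraT <- extraT + extra[, k - 2L] * phi[[k]](ga_birth)
    }
  }
  p10 <- phi[[1L]](rep(0, n)); p1T <- phi[[1L]](ga_birth)
  p20 <- phi[[2L]](rep(0, n)); p2T <- phi[[2L]](ga_birth)
  r1 <- w0_true - mu(rep(0, n)) - extra0
  r2 <- wT_true - mu(ga_birth) - extraT
  det <- p10 * p2T - p20 * p1T
  if (any(abs(det) < 1e-8)) {
    stop("degenerate eigenfunction pair in BMI-linked score construction")
  }
  xi1 <- (r1 * p2T - r2 * p20) / det
  xi2 <- (p10 * r2 - p1T * r1) / det
  cbind(xi1, xi2, extra, deparse.level = 0)
}

#' Generate a synthetic cohort under the antenatal visit design
#'
#' Simulates \code{n} subjects from the Karhunen-Loeve truth: per-subject
#' scores (independent Gaussians with the stated eigenvalues, or the
#' BMI-linked construction when \code{truth$bmi_link} is set), visit times
#' drawn uniformly inside the trimester windows, per-visit missingness,
#' measurement noise on the measured weights, and additive reporting bias
#' on the two self-reported weights.  Every subject has a W0 record at
#' week 0 and a WH record at her gestational age at birth; each of the
#' A/B/C visits is present unless missed (the A visit is also absent for
#' late-recruited subjects).
#'
#' @param truth a \code{gw_truth}.
#' @param design a \code{gw_design}.
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed; identical inputs give identical
#'   cohorts.
#' @return an object of class \code{"gw_cohort"} whose \code{truth} field
#'   stores the generative model and the realized per-subject scores.
#' @export
generate_cohort <- function(truth, design = visit_design(), n, seed = NULL) {
  stopifnot(inherits(truth, "gw_truth"), inherits(design, "gw_design"),
            n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  K <- length(truth$eigenvalues)
  bmi <- stats::rlnorm(n, log(truth$bmi_median), truth$bmi_sdlog)
  height <- stats::rnorm(n, truth$height_mean, truth$height_sd)
  ga_birth <- stats::runif(n, design$ga_birth_range[1L],
                           design$ga_birth_range[2L])
  if (is.null(truth$bmi_link)) {
    scores <- matrix(stats::rnorm(n * K), n, K) %*%
      diag(sqrt(truth$eigenvalues), K)
  } else {
    scores <- link_scores(truth, bmi, height, ga_birth)
  }
  X_at <- function(tt) {
    Phi <- vapply(truth$eigenfunctions, function(f) f(tt), numeric(n))
    truth$mean_function(tt) + rowSums(scores * Phi)
  }
  has_A <- stats::runif(n) >= design$p_late_recruit &
    stats::runif(n) >= design$p_miss_A
  has_B <- stats::runif(n) >= design$p_miss_B
  has_C <- stats::runif(n) >= design$p_miss_C
  tA <- stats::runif(n, design$window_A[1L], design$window_A[2L])
  tB <- stats::runif(n, design$window_B[1L], design$window_B[2L])
  tC <- stats::runif(n, design$window_C[1L], design$window_C[2L])
  rb <- truth$report_bias
  y0 <- X_at(rep(0, n)) + stats::rnorm(n, rb$w0[["mean"]], rb$w0[["sd"]])
  yH <- X_at(ga_birth) + stats::rnorm(n, rb$wh[["mean"]], rb$wh[["sd"]])
  yA <- X_at(tA) + stats::rnorm(n, 0, truth$noise_sd)
  yB <- X_at(tB) + stats::rnorm(n, 0, truth$noise_sd)
  yC <- X_at(tC) + stats::rnorm(n, 0, truth$noise_sd)
  ids <- sprintf("S%04d", seq_len(n))
  observations <- rbind(
    obs_block(ids, rep(TRUE, n), rep(0, n), y0, "W0"),
    obs_block(ids, has_A, tA, yA, "WA"),
    obs_block(ids, has_B, tB, yB, "WB"),
    obs_block(ids, has_C, tC, yC, "WC"),
    obs_block(ids, rep(TRUE, n), ga_birth, yH, "WH")
  )
  if (any(observations$y <= 0)) {
    stop("generated a non-positive weight; check the truth parameters")
  }
  subjects <- data.frame(
    subject_id = ids, ga_birth = ga_birth, bmi_p = bmi,
    mean_caloric = stats::rnorm(n, 2150, 350),
    mean_pa_index = stats::rnorm(n, 7.6, 1.1),
    instrument = sample(c("interviewer", "web"), n, replace = TRUE,
                        prob = c(0.477, 0.523)),
    stringsAsFactors = FALSE)
  new_cohort(observations, subjects, domain = truth$domain,
             truth = list(model = truth, scores = scores))
}

#' Evaluate the stored true trajectories of a synthetic cohort
#'
#' @param cohort a \code{gw_cohort} with generative truth attached.
#' @param grid evaluation times in weeks.
#' @return an \code{n x length(grid)} matrix of noiseless true weights.
#' @export
true_trajectories <- function(cohort, grid) {
  if (is.null(cohort$truth)) stop("cohort carries no generative truth")
  truth <- cohort$truth$model
  scores <- cohort$truth$scores
  Phi <- matrix(vapply(truth$eigenfunctions, function(f) f(grid),
                       numeric(length(grid))),
                nrow = length(grid), ncol = length(truth$eigenvalues))
  tcrossprod(scores, Phi) +
    matrix(truth$mean_function(grid), nrow(scores), length(grid),
           byrow = TRUE)
}

#' Generate a cohort from the logistic growth model
#'
#' Simulates subjects whose true curves follow the logistic comparator
#' model \eqn{W(t) = L/(1 + e^{-k(t - t_0)}) + c} with subject-level
#' random magnitude \eqn{L} and baseline \eqn{c}, under the same visit
#' design as [generate_cohort()] (all five records are noisy measurements
#' of the curve; no reporting bias).
#'
#' @param n number of subjects.
#' @param k,t0 steepness (per week) and inflection (weeks) of the curve.
#' @param mu_L,mu_c,sd_L,sd_c,cor_Lc random-effect means, standard
#'   deviations and correlation for \eqn{(L, c)}.
#' @param sigma residual standard deviation, kg.
#' @param design a \code{gw_design}.
#' @param seed optional integer seed.
#' @return a \code{gw_cohort}; the generative \eqn{(L_i, c_i)} are stored
#'   in the \code{logistic_truth} field.
#' @export
generate_logistic_cohort <- function(n, k = 0.15, t0 = 30, mu_L = 16,
                                     mu_c = 62, sd_L = 2, sd_c = 8,
                                     cor_Lc = 0, sigma = 1,
                                     design = visit_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  L <- mu_L + sd_L * z1
  c_i <- mu_c + sd_c * (cor_Lc * z1 + sqrt(1 - cor_Lc^2) * z2)
  ga_birth <- stats::runif(n, design$ga_birth_range[1L],
                           design$ga_birth_range[2L])
  has_A <- stats::runif(n) >= design$p_late_recruit &
    stats::runif(n) >= design$p_miss_A
  has_B <- stats::runif(n) >= design$p_miss_B
  has_C <- stats::runif(n) >= design$p_miss_C
  tA <- stats::runif(n, design$window_A[1L], design$window_A[2L])
  tB <- stats::runif(n, design$window_B[1L], design$window_B[2L])
  tC <- stats::runif(n, design$window_C[1L], design$window_C[2L])
  ids <- sprintf("L%04d", seq_len(n))
  obs_at <- function(tt) logistic_mean(tt, L, k, t0, c_i) +
    stats::rnorm(n, 0, sigma)
  observations <- rbind(
    obs_block(ids, rep(TRUE, n), rep(0, n), obs_at(rep(0, n)), "W0"),
    obs_block(ids, has_A, tA, obs_at(tA), "WA"),
    obs_block(ids, has_B, tB, obs_at(tB), "WB"),
    obs_block(ids, has_C, tC, obs_at(tC), "WC"),
    obs_block(ids, rep(TRUE, n), ga_birth, obs_at(ga_birth), "WH")
  )
  height <- stats::rnorm(n, 1.64, 0.06)
  subjects <- data.frame(
    subject_id = ids, ga_birth = ga_birth, bmi_p = c_i / height^2,
    mean_caloric = stats::rnorm(n, 2150, 350),
    mean_pa_index = stats::rnorm(n, 7.6, 1.1),
    instrument = sample(c("interviewer", "web"), n, replace = TRUE,
                        prob = c(0.477, 0.523)),
    stringsAsFactors = FALSE)
  new_cohort(observations, subjects,
             logistic_truth = list(k = k, t0 = t0, L = L, c = c_i,
                                   sigma = sigma))
}

#' Combine two cohorts
#'
#' Concatenates the subjects and observations of two cohorts after
#' prefixing the subject ids to keep them unique.  Generative truth is
#' dropped (the combined sample no longer follows a single truth).
#'
#' @param a,b \code{gw_cohort} objects on the same domain.
#' @return a \code{gw_cohort}.
#' @export
combine_cohorts <- function(a, b) {
  stopifnot(inherits(a, "gw_cohort"), inherits(b, "gw_cohort"),
            identical(a$domain, b$domain))
  rekey <- function(x, pre) {
    x$observations$subject_id <- paste0(pre, x$observations$subject_id)
    x$subjects$subject_id <- paste0(pre, x$subjects$subject_id)
    x
  }
  a <- rekey(a, "a."); b <- rekey(b, "b.")
  new_cohort(rbind(a$observations, b$observations),
             rbind(a$subjects, b$subjects), domain = a$domain)
}
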