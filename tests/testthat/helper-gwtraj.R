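# Shared fixtures, all built in code.

# small KL truth with independent Gaussian scores (no BMI link)
toy_truth <- function(lambda = c(9, 1), noise_sd = 0.5, ...) {
  true_model(
    mean_function = function(t) 60 + 0.3 * t,
    eigenfunctions = cosine_basis(length(lambda)),
    eigenvalues = lambda,
    noise_sd = noise_sd,
    ...)
}

# truth used for estimator-consistency checks: dominant level component
# plus two small shape components, homogeneous 1 kg error on all records
recovery_truth <- function(noise_sd = 1) {
  true_model(
    mean_function = function(t) 62 + 16 * stats::plogis(0.15 * (t - 30)),
    eigenfunctions = cosine_basis(3),
    eigenvalues = c(100, 12, 5),
    noise_sd = noise_sd,
    report_bias = list(w0 = c(mean = 0, sd = noise_sd),
                       wh = c(mean = 0, sd = noise_sd)))
}

# recovery-scale truth whose mean shows persistent early-pregnancy weight
# loss (below baseline into the third trimester) -- a shape a single
# dilated/shifted logistic cannot produce
early_loss_truth <- function(noise_sd = 1) {
  true_model(
    mean_function = function(t) {
      62 + 16 * stats::plogis(0.15 * (t - 30)) -
        7 * exp(-0.5 * ((t - 15) / 10)^2)
    },
    eigenfunctions = cosine_basis(3),
    eigenvalues = c(100, 12, 5),
    noise_sd = noise_sd,
    report_bias = list(w0 = c(mean = 0, sd = noise_sd),
                       wh = c(mean = 0, sd = noise_sd)))
}

# visit design with complete follow-up (5 records per subject)
full_design <- function() {
  visit_design(p_miss_A = 0, p_miss_B = 0, p_miss_C = 0, p_late_recruit = 0)
}

# hand-built cohort from per-subject observation lists
manual_cohort <- function(obs_list, subjects) {
  obs <- do.call(rbind, lapply(names(obs_list), function(id) {
    o <- obs_list[[id]]
    data.frame(subject_id = id, t = o$t, y = o$y, label = o$label,
               stringsAsFactors = FALSE)
  }))
  gwtraj:::new_cohort(obs, subjects)
}

l2_error_signed <- function(grid, f_hat, f_true) {
  w <- trapz_weights(grid)
  s <- sign(sum(w * f_hat * f_true))
  if (s == 0) s <- 1
  sqrt(sum(w * (s * f_hat - f_true)^2))
}
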