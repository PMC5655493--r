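# Inclusion criteria, weight-change outcomes, and the regression stage.

toy_subjects <- function(ids, ga = 40, bmi = 23, cal = 2100, pa = 7.5,
                         instr = "interviewer") {
  data.frame(subject_id = ids, ga_birth = ga, bmi_p = bmi,
             mean_caloric = cal, mean_pa_index = pa, instrument = instr,
             stringsAsFactors = FALSE)
}

std_obs <- function(w0 = 60, wb = 66, wh = 74, ga = 40) {
  list(t = c(0, 20, ga), y = c(w0, wb, wh), label = c("W0", "WB", "WH"))
}

test_that("inclusion criteria keep and log the right subjects", {
  ids <- sprintf("p%02d", 1:10)
  subs <- toy_subjects(ids)
  subs$ga_birth[1:2] <- 36.5           # preterm
  obs <- setNames(lapply(1:10, function(i) std_obs(ga = subs$ga_birth[i])),
                  ids)
  obs[["p03"]] <- list(t = c(20, 40), y = c(66, 74), label = c("WB", "WH"))
  obs[["p04"]] <- list(t = c(0, 40), y = c(60, 74), label = c("W0", "WH"))
  coh <- manual_cohort(obs, subs)
  kept <- apply_inclusion_criteria(coh)
  expect_equal(nrow(kept$subjects), 6L)
  log <- exclusion_log(kept)
  counts <- table(log$reason)
  expect_equal(unname(counts[grep("preterm", names(counts))]), 2L)
  expect_equal(unname(counts[grep("W0", names(counts))]), 1L)
  expect_equal(unname(counts[grep("measured", names(counts))]), 1L)
})

test_that("minimal subjects pass; inconsistent GA and preterm fail", {
  subs <- toy_subjects(c("q1", "q2", "q3"))
  subs$ga_birth[2] <- 36.5
  subs$mean_caloric[1] <- NA  # still has a PA record: included
  obs <- list(
    q1 = list(t = c(0, 20), y = c(60, 66), label = c("W0", "WB")),
    q2 = std_obs(ga = 36.5),
    q3 = list(t = c(0, 39, 40), y = c(60, 72, 74),
              label = c("W0", "WC", "WH")))
  subs$ga_birth[3] <- 38.5  # WC measured after the recorded birth
  coh <- manual_cohort(obs, subs)
  kept <- apply_inclusion_criteria(coh)
  expect_equal(kept$subjects$subject_id, "q1")
  expect_setequal(exclusion_log(kept)$subject_id, c("q2", "q3"))
})

test_that("weight change follows the max rule and its fallbacks", {
  subs <- toy_subjects("w1")
  coh <- manual_cohort(list(
    w1 = list(t = c(0, 35, 40), y = c(60, 75, 74),
              label = c("W0", "WC", "WH"))), subs)
  out <- compute_weight_change(get_subject(coh, "w1"))
  expect_equal(out$G, 15)                     # max{74, 75} - 60
  expect_equal(out$LG, log(75 / 60))
  expect_true(out$usable_direct)
  expect_false(out$usable_trajectory)

  # missing WH: fall back to WC, and vice versa
  coh2 <- manual_cohort(list(
    w1 = list(t = c(0, 35), y = c(60, 75), label = c("W0", "WC"))), subs)
  expect_equal(compute_weight_change(get_subject(coh2, "w1"))$G, 15)
  coh3 <- manual_cohort(list(
    w1 = list(t = c(0, 40), y = c(60, 74), label = c("W0", "WH"))), subs)
  expect_equal(compute_weight_change(get_subject(coh3, "w1"))$G, 14)

  # both missing: flagged unusable, not an error
  coh4 <- manual_cohort(list(
    w1 = list(t = c(0, 20), y = c(60, 66), label = c("W0", "WB"))), subs)
  out4 <- compute_weight_change(get_subject(coh4, "w1"))
  expect_false(out4$usable_direct)
  expect_true(is.na(out4$G))
})

test_that("trajectory-based outcomes use the endpoint values", {
  subs <- toy_subjects("w1")
  coh <- manual_cohort(list(w1 = std_obs()), subs)
  grid <- seq(0, 42, length.out = 43)
  traj <- structure(list(grid = grid, values = 60 + 14 * grid / 40,
                         pointwise_lo = NA, pointwise_hi = NA,
                         simultaneous_lo = NA, simultaneous_hi = NA,
                         alpha = 0.05, subject_id = "w1"),
                    class = "gw_traj")
  out <- compute_weight_change(get_subject(coh, "w1"), traj)
  expect_equal(out$G_prime, 14, tolerance = 1e-12)
  expect_equal(out$LG_prime, log(74 / 60), tolerance = 1e-12)
})

test_that("regression recovers exact fits, nulls, and flags collinearity", {
  set.seed(20)
  n <- 10000
  subs <- toy_subjects(sprintf("r%05d", 1:n), bmi = rlnorm(n, log(23), 0.15),
                       cal = rnorm(n, 2100, 300), pa = rnorm(n, 7.5, 1))
  out <- data.frame(subject_id = subs$subject_id,
                    G = 30 - 0.5 * subs$bmi_p,
                    LG = rnorm(n),
                    G_prime = NA_real_, LG_prime = NA_real_,
                    usable_direct = TRUE, usable_trajectory = FALSE,
                    stringsAsFactors = FALSE)
  r_exact <- suppressWarnings(regress_outcomes(out, subs, "G", "bmi_p"))
  expect_equal(r_exact$r_squared, 1, tolerance = 1e-12)
  expect_equal(r_exact$rmse, 0, tolerance = 1e-10)
  expect_equal(unname(r_exact$coefficients), c(30, -0.5),
               tolerance = 1e-10)

  r_null <- regress_outcomes(out, subs, "LG",
                             c("bmi_p", "mean_caloric", "mean_pa_index"))
  expect_lte(r_null$r_squared, 0.01)

  subs2 <- subs
  subs2$mean_pa_index <- 2 * subs2$mean_caloric
  expect_error(regress_outcomes(out, subs2, "G",
                                c("mean_caloric", "mean_pa_index")),
               "collinear")
})

test_that("in-sample R^2 never decreases when covariates are added", {
  coh <- generate_cohort(make_study_truth(), full_design(),
                         n = 200, seed = 8)
  out <- compute_outcomes(coh)
  r1 <- regress_outcomes(out, coh$subjects, "G", "bmi_p")
  r2 <- regress_outcomes(out, coh$subjects, "G",
                         c("bmi_p", "mean_caloric", "mean_pa_index"))
  expect_gte(r2$r_squared, r1$r_squared - 1e-12)
})

test_that("strata are fitted independently and never pooled", {
  coh <- generate_cohort(make_study_truth(), full_design(),
                         n = 400, seed = 9)
  out <- compute_outcomes(coh)
  ri <- regress_outcomes(out, coh$subjects, "G", "bmi_p",
                         stratum = "interviewer")
  rw <- regress_outcomes(out, coh$subjects, "G", "bmi_p", stratum = "web")
  expect_equal(ri$n + rw$n, nrow(coh$subjects))
  expect_false(isTRUE(all.equal(ri$coefficients, rw$coefficients)))
  rep <- regression_report(out, coh$subjects)
  expect_setequal(unique(rep$stratum), c("interviewer", "web"))
  expect_true(all(rep$n < nrow(coh$subjects)))
})

test_that("G-prime shrinks toward the mean relative to G", {
  truth <- make_study_truth()
  coh <- generate_cohort(truth, full_design(), n = 300, seed = 14)
  m <- fpca_model_from_truth(truth)
  trs <- reconstruct_all(coh, m)
  out <- compute_outcomes(coh, trs)
  slope <- coef(lm(G_prime ~ G, data = out))[[2]]
  expect_gt(slope, 0)
  expect_lt(slope, 1)
})
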