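# End-to-end orchestration: simulate or read a cohort, apply inclusion
# criteria, fit FPCA and the logistic NLME comparator, reconstruct
# trajectories, compare fits, compute weight-change outcomes and the
# regression report, and write all artifacts.

#' Configuration for a full analysis run
#'
#' @param n number of subjects to simulate; ignored when input files are
#'   given.
#' @param observations_csv,subjects_csv optional input files (see
#'   [read_cohort()]); when \code{NULL} a cohort is simulated from
#'   [make_study_truth()] under [visit_design()].
#' @param grid_size evaluation grid size (default 51).
#' @param fve_threshold FVE threshold for selecting K (default 0.99).
#' @param mean_bandwidth,cov_bandwidths,bandwidth_candidates smoothing
#'   controls passed to [fit_fpca()].
#' @param alpha significance level for the confidence bands.
#' @param t0 fixed inflection of the logistic comparator, weeks.
#' @param seed integer seed governing all randomness of the run.
#' @param strata instrument strata for the regression report; default all
#'   present.
#' @param out_dir output directory.
#' @return an object of class \code{"gw_config"}.
#' @export
run_config <- function(n = 500L, observations_csv = NULL,
                       subjects_csv = NULL, grid_size = 51L,
                       fve_threshold = 0.99, mean_bandwidth = NULL,
                       cov_bandwidths = NULL, bandwidth_candidates = NULL,
                       alpha = 0.05, t0 = 30, seed = 1L, strata = NULL,
                       out_dir = tempfile("gwtraj_run_")) {
  stopifnot(fve_threshold > 0, fve_threshold <= 1, alpha > 0, alpha < 1)
  structure(list(n = n, observations_csv = observations_csv,
                 subjects_csv = subjects_csv, grid_size = grid_size,
                 fve_threshold = fve_threshold,
                 mean_bandwidth = mean_bandwidth,
                 cov_bandwidths = cov_bandwidths,
                 bandwidth_candidates = bandwidth_candidates,
                 alpha = alpha, t0 = t0, seed = as.integer(seed),
                 strata = strata, out_dir = out_dir),
            class = "gw_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one cohort and writes, under
#' \code{config$out_dir}: \code{model.json} (fitted mean, eigensystem,
#' noise variance, selected K), \code{trajectories.csv} (per-subject
#' reconstructed curves with pointwise and simultaneous bands),
#' \code{comparison.csv} (FPCA vs NLME residual summaries),
#' \code{regression_report.csv}, and \code{run_log.json} (seed, sizes,
#' exclusion counts, package version).  Identical configuration and seed
#' give byte-identical numeric outputs.
#'
#' @param config a \code{gw_config}.
#' @return invisibly, a list with all intermediate objects and the output
#'   paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "gw_config"))
  cohort <- stage("input", {
    if (is.null(config$observations_csv)) {
      generate_cohort(make_study_truth(), visit_design(),
                      n = config$n, seed = config$seed)
    } else {
      read_cohort(config$observations_csv, config$subjects_csv)
    }
  })
  included <- stage("inclusion", apply_inclusion_criteria(cohort))
  model <- stage("fpca", fit_fpca(
    included, grid_size = config$grid_size,
    fve_threshold = config$fve_threshold,
    mean_bandwidth = config$mean_bandwidth,
    cov_bandwidths = config$cov_bandwidths,
    bandwidth_candidates = config$bandwidth_candidates))
  trajectories <- stage("reconstruction",
                        reconstruct_all(included, model,
                                        alpha = config$alpha))
  nlme_fit <- stage("nlme", fit_nlme(included, t0 = config$t0))
  comparison <- stage("comparison",
                      compare_models(included, model, trajectories,
                                     nlme_fit))
  outcomes <- stage("outcomes", compute_outcomes(included, trajectories))
  strata <- config$strata %||% unique(included$subjects$instrument)
  report <- stage("regression",
                  regression_report(outcomes, included$subjects,
                                    strata = strata))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage("output", {
    p_model <- file.path(config$out_dir, "model.json")
    jsonlite::write_json(list(
      grid = model$mean$grid,
      mean = model$mean$values,
      mean_bandwidth = model$mean$bandwidth,
      eigenvalues = model$eigen$values,
      fve = model$eigen$fve,
      sigma2 = model$covariance$sigma2,
      K = model$K), p_model, auto_unbox = TRUE, digits = NA)

    tr <- do.call(rbind, lapply(trajectories, function(x) {
      data.frame(subject_id = x$subject_id, t_weeks = x$grid,
                 est_kg = x$values, pw_lo = x$pointwise_lo,
                 pw_hi = x$pointwise_hi, sim_lo = x$simultaneous_lo,
                 sim_hi = x$simultaneous_hi)
    }))
    p_traj <- file.path(config$out_dir, "trajectories.csv")
    utils::write.csv(tr, p_traj, row.names = FALSE)

    p_cmp <- file.path(config$out_dir, "comparison.csv")
    utils::write.csv(data.frame(
      mse_fpca = comparison$mse_fpca, mse_nlme = comparison$mse_nlme,
      rmse_fpca = comparison$rmse_fpca, rmse_nlme = comparison$rmse_nlme,
      resid_var_fpca = comparison$resid_var_fpca,
      resid_var_nlme = comparison$resid_var_nlme,
      pct_reduction = comparison$pct_reduction,
      n_obs = comparison$n_obs), p_cmp, row.names = FALSE)

    p_reg <- file.path(config$out_dir, "regression_report.csv")
    utils::write.csv(as.data.frame(report), p_reg, row.names = FALSE)

    excl <- exclusion_log(included)
    p_log <- file.path(config$out_dir, "run_log.json")
    jsonlite::write_json(list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("gwtraj")),
      n_input = nrow(cohort$subjects),
      n_included = nrow(included$subjects),
      exclusions = as.list(table(excl$reason)),
      n_observations = nrow(included$observations),
      timestamp = format(Sys.time(), tz = "UTC")),
      p_log, auto_unbox = TRUE)
    c(model = p_model, trajectories = p_traj, comparison = p_cmp,
      regression = p_reg, log = p_log)
  })
  invisible(list(cohort = cohort, included = included, model = model,
                 trajectories = trajectories, nlme = nlme_fit,
                 comparison = comparison, outcomes = outcomes,
                 regression = report, paths = paths))
}
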