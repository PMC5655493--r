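# CSV readers/writers for cohorts.  Dialect: UTF-8, comma-separated,
# header row, times in decimal weeks.

#' Write a cohort to CSV files
#'
#' Writes \code{observations.csv} (\code{subject_id}, \code{t_weeks},
#' \code{weight_kg}, \code{label}) and \code{subjects.csv}
#' (\code{subject_id}, \code{ga_birth_weeks}, \code{bmi_p},
#' \code{mean_caloric}, \code{mean_pa_index}, \code{instrument}).  If the
#' cohort carries generative truth, a \code{truth.json} sidecar stores the
#' mean and eigenfunctions evaluated on a 201-point grid, the
#' eigenvalues, noise level, link and bias parameters, and the realized
#' per-subject scores.
#'
#' @param cohort a \code{gw_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- cohort$observations
  obs_out <- data.frame(subject_id = obs$subject_id, t_weeks = obs$t,
                        weight_kg = obs$y, label = obs$label)
  sub <- cohort$subjects
  sub_out <- data.frame(subject_id = sub$subject_id,
                        ga_birth_weeks = sub$ga_birth,
                        bmi_p = sub$bmi_p,
                        mean_caloric = sub$mean_caloric,
                        mean_pa_index = sub$mean_pa_index,
                        instrument = sub$instrument)
  p1 <- file.path(dir, "observations.csv")
  p2 <- file.path(dir, "subjects.csv")
  utils::write.csv(obs_out, p1, row.names = FALSE)
  utils::write.csv(sub_out, p2, row.names = FALSE)
  paths <- c(p1, p2)
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth$model
    g <- seq(truth$domain[1L], truth$domain[2L], length.out = 201L)
    side <- list(
      grid = g,
      mean = truth$mean_function(g),
      eigenfunctions = lapply(truth$eigenfunctions, function(f) f(g)),
      eigenvalues = truth$eigenvalues,
      noise_sd = truth$noise_sd,
      bmi_link = truth$bmi_link,
      report_bias = truth$report_bias,
      scores = cohort$truth$scores)
    p3 <- file.path(dir, "truth.json")
    jsonlite::write_json(side, p3, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Read a cohort from CSV files
#'
#' Validates and assembles a cohort from the long-format observations file
#' and the subject-level file (column layout as written by
#' [write_cohort()]).  Malformed observation rows (time outside the
#' domain, non-positive or missing weight, unknown subject, W0 not at week
#' 0) are collected into a rejects report attached as attribute
#' \code{"rejects"} rather than silently dropped; duplicate
#' (subject, time) pairs are an error listing the offenders.
#'
#' @param observations_csv,subjects_csv file paths.
#' @param domain time domain, default \code{c(0, 42)} weeks.
#' @return a \code{gw_cohort}; inspect \code{attr(x, "rejects")} for
#'   rejected rows (columns \code{row}, \code{subject_id},
#'   \code{reason}).
#' @export
read_cohort <- function(observations_csv, subjects_csv,
                        domain = c(0, 42)) {
  obs <- utils::read.csv(observations_csv, stringsAsFactors = FALSE)
  sub <- utils::read.csv(subjects_csv, stringsAsFactors = FALSE)
  need_obs <- c("subject_id", "t_weeks", "weight_kg", "label")
  need_sub <- c("subject_id", "ga_birth_weeks", "bmi_p", "mean_caloric",
                "mean_pa_index", "instrument")
  if (!all(need_obs %in% names(obs))) {
    stop("observations file must have columns ",
         paste(need_obs, collapse = ", "))
  }
  if (!all(need_sub %in% names(sub))) {
    stop("subjects file must have columns ",
         paste(need_sub, collapse = ", "))
  }
  if (anyDuplicated(sub$subject_id)) {
    stop("duplicate subject ids in subjects file")
  }
  t <- suppressWarnings(as.numeric(obs$t_weeks))
  y <- suppressWarnings(as.numeric(obs$weight_kg))
  reason <- rep(NA_character_, nrow(obs))
  bad <- function(cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- bad(is.na(t), "time not parseable")
  reason <- bad(!is.na(t) & (t < domain[1L] | t > domain[2L]),
                sprintf("time outside [%g, %g]", domain[1L], domain[2L]))
  reason <- bad(is.na(y) | y <= 0, "weight missing or non-positive")
  reason <- bad(!(obs$subject_id %in% sub$subject_id), "unknown subject id")
  reason <- bad(obs$label == "W0" & !is.na(t) & t != 0,
                "label W0 requires t = 0")
  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep),
                        subject_id = obs$subject_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  obs_ok <- data.frame(subject_id = obs$subject_id[keep], t = t[keep],
                       y = y[keep], label = obs$label[keep],
                       stringsAsFactors = FALSE)
  dup <- duplicated(obs_ok[c("subject_id", "t")]) |
    duplicated(obs_ok[c("subject_id", "t")], fromLast = TRUE)
  if (any(dup)) {
    off <- unique(paste0(obs_ok$subject_id[dup], " @ ", obs_ok$t[dup]))
    stop("duplicate (subject, time) pairs: ", paste(off, collapse = "; "))
  }
  subjects <- data.frame(subject_id = sub$subject_id,
                         ga_birth = as.numeric(sub$ga_birth_weeks),
                         bmi_p = as.numeric(sub$bmi_p),
                         mean_caloric = as.numeric(sub$mean_caloric),
                         mean_pa_index = as.numeric(sub$mean_pa_index),
                         instrument = as.character(sub$instrument),
                         stringsAsFactors = FALSE)
  out <- new_cohort(obs_ok, subjects, domain = domain)
  attr(out, "rejects") <- rejects
  out
}
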