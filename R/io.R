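# Treatment-record files, eligibility filtering and the end-to-end
# pipeline (generate -> fit -> predict -> evaluate).

.record_columns <- c("patient_id", "session_start", "session_end",
                     "pre_hgb", "post_hgb", "esa_dose", "event_kind",
                     "event_magnitude")

.parse_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S",
                                      tz = "UTC")

#' Read treatment records from CSV
#'
#' Comma-separated UTF-8 file with the header
#' `patient_id,session_start,session_end,pre_hgb,post_hgb,esa_dose,event_kind,event_magnitude`;
#' timestamps are ISO-8601 and interpreted as clinic-local (stored UTC),
#' `NA` marks missing measurements. Malformed rows are reported with their
#' line numbers; missing columns are fatal.
#'
#' @param path input file.
#' @return Data frame of treatment records sorted by session start.
#' @export
read_treatment_records <- function(path) {
  raw <- read.csv(path, colClasses = "character", na.strings = "NA")
  missing_cols <- setdiff(.record_columns, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    out <- data.frame(patient_id = character(0),
                      session_start = .parse_time(character(0)),
                      session_end = .parse_time(character(0)),
                      pre_hgb = numeric(0), post_hgb = numeric(0),
                      esa_dose = numeric(0), event_kind = character(0),
                      event_magnitude = numeric(0))
    return(out)
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    session_start = .parse_time(raw$session_start),
    session_end = .parse_time(raw$session_end),
    pre_hgb = suppressWarnings(as.numeric(raw$pre_hgb)),
    post_hgb = suppressWarnings(as.numeric(raw$post_hgb)),
    esa_dose = suppressWarnings(as.numeric(raw$esa_dose)),
    event_kind = raw$event_kind,
    event_magnitude = suppressWarnings(as.numeric(raw$event_magnitude)))
  bad <- which(is.na(out$session_start) | is.na(out$session_end) |
                 out$session_end <= out$session_start |
                 (!is.na(raw$pre_hgb) & is.na(out$pre_hgb)) |
                 (!is.na(raw$post_hgb) & is.na(out$post_hgb)) |
                 is.na(out$esa_dose))
  if (length(bad) > 0)
    stop("malformed record rows at lines: ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  out[order(out$patient_id, out$session_start), , drop = FALSE]
}

#' Write treatment records to CSV
#'
#' Inverse of [read_treatment_records()]: ISO-8601 timestamps, `NA` for
#' missing measurements, full double precision so that a write/read
#' round-trip reproduces the records.
#'
#' @param records treatment-record data frame.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_treatment_records <- function(records, path) {
  out <- records[, .record_columns]
  out$session_start <- format(records$session_start, "%Y-%m-%dT%H:%M:%S")
  out$session_end <- format(records$session_end, "%Y-%m-%dT%H:%M:%S")
  for (col in c("pre_hgb", "post_hgb", "esa_dose", "event_magnitude"))
    out[[col]] <- ifelse(is.na(records[[col]]), "NA",
                         format(records[[col]], digits = 17,
                                scientific = FALSE, trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Eligibility filter for treatment records
#'
#' Drops records whose measured pre-dialysis hemoglobin is below 5 or
#' above 20 g/dl (sensor artifacts), then checks the patient-level rules
#' on the adaptation window: strictly more than 42 eligible measurements
#' and at least 2 ESA administrations.
#'
#' @param records time-sorted records of one patient.
#' @param adaptation_days adaptation window length, days.
#' @return List: `kept` and `dropped` data frames partitioning the input
#'   (`dropped` has a `reason` column), `eligible` (logical patient
#'   status), `n_eligible_measurements`, `n_doses`, `reasons` (character,
#'   empty when eligible).
#' @export
filter_eligible <- function(records, adaptation_days = 150) {
  mf <- .model_frame(records)
  out_of_range <- !is.na(mf$pre_hgb) & (mf$pre_hgb < 5 | mf$pre_hgb > 20)
  kept <- mf[!out_of_range, , drop = FALSE]
  dropped <- mf[out_of_range, , drop = FALSE]
  if (nrow(dropped) > 0) dropped$reason <- "pre-dialysis Hgb outside [5, 20] g/dl"
  in_adapt <- kept$t < kept$t[1] + adaptation_days
  measured <- in_adapt & !is.na(kept$pre_hgb) & !is.na(kept$post_hgb)
  n_eligible <- sum(measured)
  n_doses <- sum(in_adapt & !is.na(kept$esa_dose) & kept$esa_dose > 0)
  reasons <- character(0)
  if (n_eligible <= 42)
    reasons <- c(reasons, sprintf(
      "only %d eligible measurements (needs more than 42)", n_eligible))
  if (n_doses < 2)
    reasons <- c(reasons, sprintf(
      "only %d ESA administrations (needs at least 2)", n_doses))
  list(kept = kept, dropped = dropped,
       eligible = length(reasons) == 0,
       n_eligible_measurements = n_eligible, n_doses = n_doses,
       reasons = reasons)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that
#' parse as numbers become numeric.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a cohort, fits each eligible patient on the adaptation
#' window, forecasts the prediction window with frozen parameters, and
#' evaluates adaptation and windowed prediction errors. Artifacts are
#' written to `out_dir`: the record CSV, a JSON fit summary, the windowed
#' evaluation CSV, and a plain-text log with the seed and settings.
#' Failures are isolated per patient and reported in the fit summary.
#'
#' @param out_dir output directory (created if absent).
#' @param n_patients cohort size.
#' @param seed base seed for generation and estimation.
#' @param noise_cv,missing_prob measurement model settings.
#' @param adaptation_days,prediction_days horizon layout.
#' @param config an [estimation_config()] used for every patient (its
#'   seed is derived from `seed`).
#' @param records optional pre-existing treatment records (data frame or
#'   CSV path, possibly many patients); skips generation.
#' @return Invisibly, a list with `fits` (per patient), `evaluation`
#'   (windowed prediction errors), `records`, `patients`.
#' @export
run_pipeline <- function(out_dir, n_patients = 5, seed = 1,
                         noise_cv = 0.03, missing_prob = 0.18,
                         adaptation_days = 150, prediction_days = 90,
                         config = estimation_config(), records = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  patients <- NULL
  if (is.null(records)) {
    patients <- sample_cohort(n_patients, seed = seed, noise_cv = noise_cv,
                              missing_prob = missing_prob,
                              adaptation_days = adaptation_days,
                              prediction_days = prediction_days,
                              dmu = config$dmu, dmu_ery = config$dmu_ery)
    records <- do.call(rbind, lapply(patients, `[[`, "records"))
  } else if (is.character(records)) {
    records <- read_treatment_records(records)
  }
  write_treatment_records(records, file.path(out_dir, "records.csv"))

  fits <- list()
  pred_rows <- list()
  for (pid in unique(records$patient_id)) {
    rec_i <- records[records$patient_id == pid, , drop = FALSE]
    status <- filter_eligible(rec_i, adaptation_days)
    if (!status$eligible) {
      fits[[pid]] <- list(patient_id = pid, status = "ineligible",
                          reasons = status$reasons)
      next
    }
    cfg <- config
    cfg$seed <- (seed + match(pid, unique(records$patient_id))) %% .Machine$integer.max
    cfg$adaptation_days <- adaptation_days
    fit <- tryCatch(estimate_patient(status$kept, .pipeline_profile(patients, pid),
                                     cfg),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      fits[[pid]] <- list(patient_id = pid, status = "failed",
                          reasons = conditionMessage(fit))
      next
    }
    fits[[pid]] <- list(patient_id = pid, status = "ok",
                        params = unclass(fit$params_hat)[
                          c("T_RBC", "E_endo", "t_half", "s_alpha", "s_v", "S0")],
                        cost = fit$cost,
                        mape_adaptation = fit$mape_adaptation)
    pr <- predict_patient(status$kept, .pipeline_profile(patients, pid),
                          fit$params_hat, adaptation_days,
                          dmu = config$dmu, dmu_ery = config$dmu_ery)
    if (!is.null(pr)) pred_rows[[pid]] <- pr
  }

  evaluation <- NULL
  if (length(pred_rows) > 0) {
    evaluation <- windowed_prediction_error(do.call(rbind, pred_rows))
    write.csv(evaluation, file.path(out_dir, "evaluation.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("erythrosim %s",
                       as.character(utils::packageVersion("erythrosim"))),
               sprintf("seed = %d", seed),
               sprintf("n_patients = %d", length(unique(records$patient_id))),
               sprintf("noise_cv = %g, missing_prob = %g", noise_cv,
                       missing_prob),
               sprintf("adaptation_days = %d, prediction_days = %d",
                       adaptation_days, prediction_days),
               sprintf("R %s", as.character(getRversion()))),
             file.path(out_dir, "run.log"))
  invisible(list(fits = fits, evaluation = evaluation, records = records,
                 patients = patients))
}

# profile lookup: synthetic patients carry their own profile; for external
# records a population-typical profile is assumed (anthropometrics must
# then be supplied by the caller through estimate_patient directly)
.pipeline_profile <- function(patients, pid) {
  if (!is.null(patients)) {
    for (pat in patients)
      if (pat$records$patient_id[1] == pid) return(pat$profile)
  }
  patient_profile("male", 166.5, 76)
}

#' Forecast the prediction window with frozen parameters
#'
#' Simulates the full record horizon with the fitted parameters (initial
#' steady state anchored to the first adaptation measurement, doses and
#' events as recorded) and converts the simulated post-dialysis values to
#' pre-dialysis ones through the measured pre/post ratio.
#'
#' @param records all records of one patient (adaptation + prediction).
#' @param profile a [patient_profile()].
#' @param params_hat fitted [patient_parameters()].
#' @param adaptation_days fitting-window length; only later records enter
#'   the returned frame.
#' @param dmu,dmu_ery solver resolutions.
#' @return Data frame (`patient_id`, `t_days` since adaptation end,
#'   `observed`, `simulated` pre-dialysis Hgb) for
#'   [windowed_prediction_error()], or `NULL` when there are no measured
#'   prediction records.
#' @export
predict_patient <- function(records, profile, params_hat,
                            adaptation_days = 150, dmu = 0.25,
                            dmu_ery = 1) {
  mf <- .model_frame(records)
  obs <- mf[!is.na(mf$post_hgb), , drop = FALSE]
  theta <- unlist(unclass(params_hat)[c("T_RBC", "E_endo", "t_half",
                                        "s_alpha", "s_v")])
  sim <- .fit_simulation(theta, mf, profile, params_hat$constants,
                         dmu, dmu_ery)
  conv <- pre_dialysis_hgb(sim$hgb_post, obs$post_hgb, obs$pre_hgb,
                           profile$TBV_post)
  t_pred <- obs$t - (mf$t[1] + adaptation_days)
  keep <- t_pred >= 0
  if (!any(keep)) return(NULL)
  data.frame(patient_id = obs$patient_id[keep], t_days = t_pred[keep],
             observed = obs$pre_hgb[keep],
             simulated = conv$preHgb_sim[keep])
}
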