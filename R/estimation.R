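# Parameter identification: steady-state stem-cell calibration, the
# least-squares cost on post-dialysis hemoglobin, and multi-start
# Nelder-Mead over the five patient-specific parameters.

#' Estimation settings
#'
#' @param n_starts number of Latin-hypercube initial guesses.
#' @param perturbation relative magnitude of the multiplicative restart
#'   perturbations around the incumbent optimum (default +-10%).
#' @param max_iter Nelder-Mead iteration cap per run.
#' @param reltol Nelder-Mead relative convergence tolerance on the cost.
#' @param seed RNG seed; the whole estimation is deterministic given it.
#' @param adaptation_days length of the fitting window in days.
#' @param max_restarts cap on perturbation restarts.
#' @param refine_coordinates if `TRUE`, a final pass of one-dimensional
#'   line searches over each parameter separately.
#' @param dmu,dmu_ery solver maturity resolutions used inside the cost.
#' @param check_eligibility enforce the eligibility rules (more than 42
#'   measured in-range values and at least 2 ESA administrations in the
#'   adaptation window) before fitting.
#' @param ranges 5 x 2 matrix of initial-guess ranges (rows `T_RBC` days,
#'   `E_endo` U/l, `t_half` h, `s_alpha`, `s_v`), sampled log-uniformly.
#' @return List of settings for [estimate_patient()].
#' @export
estimation_config <- function(n_starts = 8, perturbation = 0.10,
                              max_iter = 500, reltol = 1e-8, seed = 1,
                              adaptation_days = 150, max_restarts = 8,
                              refine_coordinates = FALSE,
                              dmu = 0.25, dmu_ery = 1,
                              check_eligibility = TRUE,
                              ranges = NULL) {
  stopifnot(n_starts >= 1, perturbation > 0, perturbation < 1)
  if (is.null(ranges)) {
    ranges <- rbind(T_RBC = c(35, 135), E_endo = c(2, 20),
                    t_half = c(4, 12), s_alpha = c(0.001, 0.03),
                    s_v = c(0.001, 0.2))
  }
  list(n_starts = n_starts, perturbation = perturbation,
       max_iter = max_iter, reltol = reltol, seed = seed,
       adaptation_days = adaptation_days, max_restarts = max_restarts,
       refine_coordinates = refine_coordinates, dmu = dmu,
       dmu_ery = dmu_ery, check_eligibility = check_eligibility,
       ranges = ranges)
}

#' Calibrate the stem-cell influx to a target hemoglobin
#'
#' The model is linear in the population density, so the steady-state red
#' cell count is proportional to the stem-cell influx. One reference
#' steady state at `S_ref` fixes the proportionality constant and
#' `S0 = S_ref * N_target / N_ref` is exact.
#'
#' @param p a [patient_parameters()] object (its `S0` is ignored).
#' @param profile a [patient_profile()] object (supplies the blood volume).
#' @param target_post_hgb steady-state post-dialysis hemoglobin to match,
#'   g/dl, in (2, 20).
#' @param grids optional precomputed [maturity_grids()].
#' @param dmu,dmu_ery resolutions when `grids` is absent.
#' @return Stem-cell influx `S0` in cells/day.
#' @export
#' @examples
#' p <- patient_parameters()
#' prof <- patient_profile("female", 160, 70)
#' S0 <- calibrate_stem_influx(p, prof, 11)
calibrate_stem_influx <- function(p, profile, target_post_hgb,
                                  grids = NULL, dmu = 0.25, dmu_ery = 1) {
  stopifnot(target_post_hgb > 2, target_post_hgb < 20)
  S_ref <- 1e9
  p$S0 <- S_ref
  ss <- steady_state(p, p$E_endo, grids = grids, dmu = dmu,
                     dmu_ery = dmu_ery)
  N_ref <- total_rbc(ss)
  if (N_ref <= 0) stop("reference steady state has zero erythrocyte count")
  N_target <- target_post_hgb * profile$TBV_post * 10 /
    (p$constants$MCH * 1e-12)
  S_ref * N_target / N_ref
}

# canonical fitting frame: numeric session times in days (t = 0 at the
# first session), measured pre/post Hgb, ESA doses and events
.model_frame <- function(records) {
  if (!"t" %in% names(records)) {
    if (!"session_end" %in% names(records))
      stop("records need either a numeric 't' or a 'session_end' column")
    t0 <- min(records$session_end)
    records$t <- as.numeric(difftime(records$session_end, t0, units = "days"))
  }
  records[order(records$t), , drop = FALSE]
}

# one administration per session: duplicated rows for the same session
# time carry the same treatment, not a second dose
.records_doses <- function(mf) {
  has <- !is.na(mf$esa_dose) & mf$esa_dose > 0 & !duplicated(mf$t)
  data.frame(time = mf$t[has], dose = mf$esa_dose[has])
}

.records_events <- function(mf) {
  if (!"event_kind" %in% names(mf)) return(list())
  rows <- which(!is.na(mf$event_kind) & mf$event_kind != "none" &
                  !duplicated(mf$t))
  lapply(rows, function(i) {
    if (mf$event_kind[i] == "bleed") {
      blood_event("bleed", time = mf$t[i], volume_ml = mf$event_magnitude[i])
    } else {
      blood_event("transfusion", time = mf$t[i], units = mf$event_magnitude[i])
    }
  })
}

# simulate at a parameter vector and return post-dialysis Hgb at the
# measured treatment times
.fit_simulation <- function(theta, mf, profile, constants, dmu, dmu_ery) {
  p <- patient_parameters(T_RBC = theta[1], E_endo = theta[2],
                          t_half = theta[3], s_alpha = theta[4],
                          s_v = theta[5], constants = constants)
  obs <- mf[!is.na(mf$post_hgb), , drop = FALSE]
  simulate_erythropoiesis(
    p, profile, doses = .records_doses(mf), events = .records_events(mf),
    t_end = max(mf$t, 1), record_times = obs$t,
    init_hgb = obs$post_hgb[1], dmu = dmu, dmu_ery = dmu_ery)
}

#' Least-squares cost of a parameter vector
#'
#' Sum of squared residuals between simulated and measured post-dialysis
#' hemoglobin over the adaptation records, simulating once over the window
#' with doses and blood events applied. A failed or non-finite simulation
#' maps to a large finite penalty so a simplex search can continue.
#'
#' @param theta numeric vector `(T_RBC, E_endo, t_half, s_alpha, s_v)` on
#'   the natural scale.
#' @param records adaptation-period treatment records: a data frame with
#'   columns `t` (days) or `session_end` (POSIXct), `post_hgb`, `pre_hgb`,
#'   `esa_dose`, and optionally `event_kind`/`event_magnitude`.
#' @param profile a [patient_profile()] object.
#' @param constants fixed model constants.
#' @param dmu,dmu_ery solver resolutions.
#' @return Cost in (g/dl)^2.
#' @export
hgb_fit_cost <- function(theta, records, profile,
                         constants = erythroid_defaults(),
                         dmu = 0.25, dmu_ery = 1) {
  stopifnot(all(is.finite(theta)))
  mf <- .model_frame(records)
  if (!any(!is.na(mf$post_hgb))) stop("no measured post-dialysis values")
  # keep the search numerically sane: outside the model's validity domain
  # return a sloped penalty instead of simulating
  lo <- c(12, 0.1, 0.5, 1e-6, 1e-6)
  hi <- c(190, 100, 120, 1, 10)
  if (any(theta < lo | theta > hi)) {
    excess <- sum(pmax(0, log(theta / hi)) + pmax(0, log(lo / theta)))
    return(1e8 * (1 + excess))
  }
  out <- tryCatch({
    sim <- .fit_simulation(theta, mf, profile, constants, dmu, dmu_ery)
    y <- mf$post_hgb[!is.na(mf$post_hgb)]
    sum((sim$hgb_post - y)^2)
  }, error = function(e) NA_real_)
  if (!is.finite(out)) 1e8 else out
}

#' Split records into adaptation and prediction periods
#'
#' Records earlier than `adaptation_days` after the first record belong to
#' the adaptation (fitting) window; the rest form the prediction window
#' where parameters stay frozen. The interval is half-open: a record
#' exactly at the boundary goes to the prediction set.
#'
#' @param records time-sorted treatment records (`t` or `session_end`).
#' @param adaptation_days window length in days.
#' @return List with data frames `adaptation` and `prediction`.
#' @export
split_adaptation_prediction <- function(records, adaptation_days = 150) {
  if (NROW(records) == 0) stop("empty record set")
  mf <- .model_frame(records)
  in_adapt <- mf$t < mf$t[1] + adaptation_days
  list(adaptation = mf[in_adapt, , drop = FALSE],
       prediction = mf[!in_adapt, , drop = FALSE])
}

#' Estimate the five patient-specific parameters
#'
#' Runs Nelder-Mead from `n_starts` Latin-hypercube initial guesses drawn
#' within physiological ranges, searching in log space so the parameters
#' stay positive while the optimization itself is unconstrained. The best
#' point is then restarted with +-10% multiplicative perturbations until
#' two consecutive restarts improve the cost by less than 0.1%, optionally
#' followed by coordinate-wise line searches. Deterministic given
#' `config$seed`.
#'
#' @param records treatment records covering the adaptation window (see
#'   [hgb_fit_cost()] for the expected columns). Records beyond
#'   `config$adaptation_days` are ignored here.
#' @param profile a [patient_profile()] object.
#' @param config an [estimation_config()].
#' @param constants fixed model constants.
#' @return Object of class `estimation_result`: `params_hat`
#'   (a [patient_parameters()] with calibrated `S0`), `cost`,
#'   `mape_adaptation` (%), `runs` (per-run log), `n_function_evals`.
#' @export
estimate_patient <- function(records, profile, config = estimation_config(),
                             constants = erythroid_defaults()) {
  mf <- split_adaptation_prediction(records,
                                    config$adaptation_days)$adaptation
  measured <- !is.na(mf$pre_hgb) & !is.na(mf$post_hgb)
  if (config$check_eligibility) {
    n_eligible <- sum(measured & mf$pre_hgb >= 5 & mf$pre_hgb <= 20)
    n_doses <- sum(!is.na(mf$esa_dose) & mf$esa_dose > 0)
    if (n_eligible <= 42)
      stop("ineligible: needs more than 42 eligible measurements, has ",
           n_eligible)
    if (n_doses < 2)
      stop("ineligible: needs at least 2 ESA administrations, has ", n_doses)
  }

  fn <- function(par_log) {
    hgb_fit_cost(exp(par_log), mf, profile, constants,
                 dmu = config$dmu, dmu_ery = config$dmu_ery)
  }

  set.seed(config$seed)
  lr <- log(config$ranges)
  starts <- lhs::randomLHS(config$n_starts, 5)
  starts <- sweep(sweep(starts, 2, lr[, 2] - lr[, 1], `*`), 2, lr[, 1], `+`)

  runs <- list()
  best <- NULL
  nev <- 0L
  for (i in seq_len(config$n_starts)) {
    opt <- optim(starts[i, ], fn, method = "Nelder-Mead",
                 control = list(maxit = config$max_iter,
                                reltol = config$reltol))
    nev <- nev + opt$counts[["function"]]
    runs[[length(runs) + 1]] <-
      data.frame(phase = "start", run = i,
                 start_cost = fn(starts[i, ]), cost = opt$value)
    nev <- nev + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  # restart around the incumbent with +-perturbation multiplicative noise
  stagnant <- 0L
  r <- 0L
  while (stagnant < 2L && r < config$max_restarts) {
    r <- r + 1L
    par_r <- best$par + log(runif(5, 1 - config$perturbation,
                                  1 + config$perturbation))
    opt <- optim(par_r, fn, method = "Nelder-Mead",
                 control = list(maxit = config$max_iter,
                                reltol = config$reltol))
    nev <- nev + opt$counts[["function"]]
    rel_impr <- (best$value - opt$value) / max(best$value, 1e-12)
    runs[[length(runs) + 1]] <-
      data.frame(phase = "restart", run = r, start_cost = NA_real_,
                 cost = opt$value)
    if (opt$value < best$value) best <- opt
    stagnant <- if (rel_impr > 1e-3) 0L else stagnant + 1L
  }

  if (config$refine_coordinates) {
    for (j in 1:5) {
      f1 <- function(z) { th <- best$par; th[j] <- z; fn(th) }
      o1 <- optimize(f1, interval = best$par[j] + log(c(0.75, 1.3)),
                     tol = 1e-6)
      if (o1$objective < best$value) {
        best$par[j] <- o1$minimum
        best$value <- o1$objective
      }
    }
  }

  theta <- exp(best$par)
  plaus <- config$ranges
  if (any(theta < 0.5 * plaus[, 1] | theta > 2 * plaus[, 2]))
    warning("estimated parameters far outside physiological ranges")
  p_hat <- patient_parameters(T_RBC = theta[1], E_endo = theta[2],
                              t_half = theta[3], s_alpha = theta[4],
                              s_v = theta[5], constants = constants)
  obs <- mf[!is.na(mf$post_hgb), , drop = FALSE]
  sim <- .fit_simulation(theta, mf, profile, constants,
                         config$dmu, config$dmu_ery)
  p_hat$S0 <- sim$params$S0
  structure(list(params_hat = p_hat, cost = best$value,
                 mape_adaptation = mape(obs$post_hgb, sim$hgb_post),
                 runs = do.call(rbind, runs), n_function_evals = nev,
                 config = config),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    "Parameter estimate: cost %.4g (g/dl)^2, adaptation MAPE %.2f%%, %d cost evaluations\n",
    x$cost, x$mape_adaptation, x$n_function_evals))
  print(x$params_hat)
  invisible(x)
}
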