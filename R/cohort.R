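# Synthetic hemodialysis cohort: virtual patients with known parameters,
# thrice-weekly treatment schedules, a feedback ESA titration policy, and
# Crit-Line-like measurement noise and missingness. Every stage is a pure
# function of (seed, configuration).

.rtrunc <- function(n, rfun, lo, hi, ...) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- rfun(n * 2, ...)
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

#' Cohort sampling ranges
#'
#' Distributions of the virtual-patient characteristics: anthropometrics
#' follow typical hemodialysis population statistics (height 166.5 +- 9.7
#' cm, pre-dialysis weight 78.6 +- 19.7 kg, 51.7% male), the red cell
#' lifespan is Normal(73, 20) truncated to 33-137 days, the ESA
#' half-life log-normal with median 6.3 h truncated to 3.8-13.6 h,
#' endogenous EPO Normal(8, 3) truncated to 1-20 U/l (advanced CKD),
#' and the two response slopes log-uniform over 0.0013-0.0208 and
#' 0.0007-0.1864.
#'
#' @return Named list of sampling ranges used by [sample_patient()].
#' @export
cohort_ranges <- function() {
  list(p_male = 0.5167,
       height = c(mean = 166.5, sd = 9.7, lo = 140, hi = 200),
       weight = c(mean = 78.6, sd = 19.7, lo = 40, hi = 160),
       interdialytic_gain = 2.56,
       T_RBC = c(mean = 73, sd = 20, lo = 33, hi = 137),
       t_half = c(median = 6.3, sdlog = 0.28, lo = 3.8, hi = 13.6),
       E_endo = c(mean = 8, sd = 3, lo = 1, hi = 20),
       s_alpha = c(lo = 0.0013, hi = 0.0208),
       s_v = c(lo = 0.0007, hi = 0.1864),
       # untreated (ESA-naive) steady-state hemoglobin: renal anemia
       hgb0 = c(lo = 7.5, hi = 9.5))
}

#' Draw a virtual hemodialysis patient
#'
#' Samples anthropometrics and the five true model parameters from
#' [cohort_ranges()], and lays out a thrice-weekly (Mon/Wed/Fri) treatment
#' schedule over the adaptation plus prediction horizon. The same seed
#' always yields the identical patient.
#'
#' @param seed integer seed.
#' @param ranges sampling ranges, see [cohort_ranges()].
#' @param adaptation_days,prediction_days horizon layout in days.
#' @return Object of class `synthetic_patient` with fields `profile`,
#'   `true_params`, `schedule` (session start/end in days), `hgb0`
#'   (baseline post-dialysis Hgb), `events` (empty until
#'   [inject_events()]), `seed`; `records` is filled by
#'   [synthesize_records()].
#' @export
#' @examples
#' pat <- sample_patient(42)
#' pat$true_params$T_RBC
sample_patient <- function(seed, ranges = cohort_ranges(),
                           adaptation_days = 150, prediction_days = 90) {
  set.seed(seed)
  sex <- if (runif(1) < ranges$p_male) "male" else "female"
  height <- .rtrunc(1, rnorm, ranges$height["lo"], ranges$height["hi"],
                    mean = ranges$height["mean"], sd = ranges$height["sd"])
  w_pre <- .rtrunc(1, rnorm, ranges$weight["lo"], ranges$weight["hi"],
                   mean = ranges$weight["mean"], sd = ranges$weight["sd"])
  profile <- patient_profile(sex, height,
                             max(30, w_pre - ranges$interdialytic_gain))
  true_params <- patient_parameters(
    T_RBC = .rtrunc(1, rnorm, ranges$T_RBC["lo"], ranges$T_RBC["hi"],
                    mean = ranges$T_RBC["mean"], sd = ranges$T_RBC["sd"]),
    E_endo = .rtrunc(1, rnorm, ranges$E_endo["lo"], ranges$E_endo["hi"],
                     mean = ranges$E_endo["mean"], sd = ranges$E_endo["sd"]),
    t_half = .rtrunc(1, rlnorm, ranges$t_half["lo"], ranges$t_half["hi"],
                     meanlog = log(ranges$t_half["median"]),
                     sdlog = ranges$t_half["sdlog"]),
    s_alpha = exp(runif(1, log(ranges$s_alpha["lo"]),
                        log(ranges$s_alpha["hi"]))),
    s_v = exp(runif(1, log(ranges$s_v["lo"]), log(ranges$s_v["hi"]))))

  horizon <- adaptation_days + prediction_days
  week_days <- c(0, 2, 4)                       # Mon/Wed/Fri pattern
  days <- as.vector(outer(week_days, seq(0, horizon + 7, by = 7), `+`))
  days <- sort(days[days <= horizon])
  start <- days + 8 / 24                        # morning shift
  dur <- runif(length(days), 3.5, 4.5) / 24
  schedule <- data.frame(session = seq_along(days),
                         start_day = start, end_day = start + dur)

  structure(list(profile = profile, true_params = true_params,
                 schedule = schedule,
                 hgb0 = runif(1, ranges$hgb0["lo"], ranges$hgb0["hi"]),
                 adaptation_days = adaptation_days,
                 prediction_days = prediction_days,
                 events = list(), records = NULL, seed = seed),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("Synthetic HD patient (seed %d): %d scheduled sessions over %d days\n",
              x$seed, nrow(x$schedule),
              x$adaptation_days + x$prediction_days))
  print(x$profile)
  print(x$true_params)
  invisible(x)
}

#' Default ESA titration policy settings
#'
#' @param d_base starting per-treatment dose in U/kg, on the scale at
#'   which the model's hemoglobin response equilibrates.
#' @param hgb_low,hgb_high trailing-mean hemoglobin band (g/dl) that
#'   triggers 25% dose steps up/down.
#' @param hgb_hold above this trailing mean (g/dl) the ESA is withheld
#'   entirely until hemoglobin falls back (a standard safety rule).
#' @param step_up,step_down multiplicative dose adjustments.
#' @param max_per_kg dose ceiling in U/kg.
#' @param min_per_kg below this U/kg no dose is administered.
#' @param trailing_days averaging window for the hemoglobin trend.
#' @param cooldown_days minimum spacing between dose adjustments (the
#'   slow hemoglobin response makes per-treatment stepping overshoot).
#' @return Named list of policy settings.
#' @export
dosing_config <- function(d_base = 3, hgb_low = 10, hgb_high = 11.5,
                          hgb_hold = 12.5, step_up = 1.25,
                          step_down = 0.75, max_per_kg = 100,
                          min_per_kg = 0.5, trailing_days = 14,
                          cooldown_days = 7) {
  list(d_base = d_base, hgb_low = hgb_low, hgb_high = hgb_high,
       hgb_hold = hgb_hold, step_up = step_up, step_down = step_down,
       max_per_kg = max_per_kg, min_per_kg = min_per_kg,
       trailing_days = trailing_days, cooldown_days = cooldown_days,
       day = 0, last_change = -Inf)
}

#' One step of the ESA titration policy
#'
#' A simple protocol emulating clinical anemia management: the per-kg base
#' dose steps up by 25% when the trailing two-week mean hemoglobin is
#' below the band and down by 25% when above, clipped to
#' `[0, max_per_kg]` U/kg; doses below `min_per_kg` are withheld, and
#' adjustments are spaced at least `cooldown_days` apart. The caller
#' advances `config$day` between sessions.
#'
#' @param current_hgb trailing-mean hemoglobin in g/dl (must be positive).
#' @param weight patient weight in kg.
#' @param config policy state from [dosing_config()].
#' @return List with `dose` (U for this treatment) and the updated
#'   `config` (carrying the stepped base dose).
#' @export
#' @examples
#' pol <- dosing_config()
#' dosing_policy(9.0, 80, pol)$dose
dosing_policy <- function(current_hgb, weight, config = dosing_config()) {
  stopifnot(current_hgb > 0)
  if (config$day - config$last_change >= config$cooldown_days) {
    if (current_hgb < config$hgb_low) {
      config$d_base <- config$d_base * config$step_up
      config$last_change <- config$day
    } else if (current_hgb > config$hgb_high) {
      config$d_base <- config$d_base * config$step_down
      config$last_change <- config$day
    }
  }
  config$d_base <- min(max(config$d_base, 0), config$max_per_kg)
  dose <- if (config$d_base < config$min_per_kg ||
                current_hgb > config$hgb_hold) 0 else
    config$d_base * weight
  list(dose = dose, config = config)
}

#' Apply measurement noise and missingness to simulated session values
#'
#' Emulates Crit-Line readings: the recorded post-dialysis hemoglobin is
#' the simulated value times `(1 + eps)` with `eps ~ Normal(0, noise_cv)`;
#' the pre-dialysis value divides the recorded post value by an
#' independent per-session fluid-shift ratio `Uniform(1.02, 1.12)`
#' (ultrafiltration concentrates blood, so post exceeds pre). Sessions
#' lose their measurement independently with probability `missing_prob`
#' (the treatment and any dose still happen).
#'
#' @param hgb_post simulated post-dialysis hemoglobin per session, g/dl.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param missing_prob probability a session has no usable measurement.
#' @return Data frame with `pre_hgb`, `post_hgb` (NA where missing) and
#'   the logical `missing`.
#' @export
measure_sessions <- function(hgb_post, noise_cv = 0.03,
                             missing_prob = 0.18) {
  stopifnot(noise_cv >= 0, missing_prob >= 0, missing_prob < 1)
  n <- length(hgb_post)
  post <- hgb_post * (1 + rnorm(n, 0, noise_cv))
  ratio <- runif(n, 1.02, 1.12)
  pre <- post / ratio
  missing <- runif(n) < missing_prob
  post[missing] <- NA_real_
  pre[missing] <- NA_real_
  data.frame(pre_hgb = pre, post_hgb = post, missing = missing)
}

# closed-loop first pass: step the model session to session, titrating the
# dose from the simulated hemoglobin trend; returns the dose series
.closed_loop_doses <- function(patient, policy, dmu, dmu_ery) {
  p <- patient$true_params
  profile <- patient$profile
  grids <- maturity_grids(p, dmu, dmu_ery)
  p$S0 <- calibrate_stem_influx(p, profile, patient$hgb0, grids = grids)
  state <- steady_state(p, p$E_endo, grids)
  pars <- .cpp_pars(p, grids)
  dt_base <- 0.8 * min(grids$dmu / c(1, 1, 1, p$constants$v_max, 1))

  t_sess <- patient$schedule$end_day - patient$schedule$end_day[1]
  n <- length(t_sess)
  hgb <- numeric(n)
  hgb[1] <- hgb_from_count(total_rbc(state), profile$TBV_post,
                           p$constants$MCH)
  doses <- data.frame(time = numeric(0), dose = numeric(0))
  policy$day <- 0
  step1 <- dosing_policy(hgb[1], profile$weight_kg, policy)
  doses <- rbind(doses, data.frame(time = t_sess[1], dose = step1$dose))
  policy <- step1$config

  events <- patient$events
  ev_time <- vapply(events, `[[`, numeric(1), "time")
  dens <- lapply(state$classes, `[[`, "density")
  for (i in 2:n) {
    span <- t_sess[i] - t_sess[i - 1]
    nst <- max(1L, as.integer(ceiling(span / dt_base)))
    dt <- span / nst
    tt <- t_sess[i - 1] + (0:(nst - 1)) * dt
    E <- .epo_step_avg(tt, dt, doses, p, profile)
    in_chunk <- which(ev_time > t_sess[i - 1] & ev_time <= t_sess[i])
    ev_step <- integer(0); ev_kind <- integer(0); ev_val <- numeric(0)
    for (j in in_chunk) {
      ev <- events[[j]]
      st <- max(1L, min(nst, as.integer(round((ev$time - t_sess[i - 1]) / dt)))) - 1L
      if (ev$kind == "bleed") {
        ev_kind <- c(ev_kind, 1L)
        ev_val <- c(ev_val, 1 - ev$volume_ml / (profile$TBV_post * 1000))
      } else {
        ev_kind <- c(ev_kind, 2L)
        ev_val <- c(ev_val,
                    ev$units * ev$unit_volume_ml * ev$cells_per_ml / p$T_RBC)
      }
      ev_step <- c(ev_step, st)
    }
    ord <- order(ev_step)
    out <- cpp_integrate(dens, grids$dmu, E, dt, nst, pars,
                         ev_step[ord], ev_kind[ord], ev_val[ord])
    dens <- out$density
    hgb[i] <- hgb_from_count(out$rbc[nst + 1], profile$TBV_post,
                             p$constants$MCH)
    recent <- hgb[t_sess <= t_sess[i] &
                    t_sess > t_sess[i] - policy$trailing_days &
                    seq_len(n) <= i]
    policy$day <- t_sess[i]
    stepi <- dosing_policy(mean(recent), profile$weight_kg, policy)
    doses <- rbind(doses, data.frame(time = t_sess[i], dose = stepi$dose))
    policy <- stepi$config
  }
  list(doses = doses, S0 = p$S0, t_sess = t_sess)
}

#' Generate treatment records for a virtual patient
#'
#' Two passes: a closed-loop simulation titrates the ESA dose from the
#' evolving hemoglobin via [dosing_policy()], then a single forward run
#' with the resulting dose series defines the noise-free truth at every
#' session, to which [measure_sessions()] applies noise and missingness.
#' Deterministic given the patient's seed.
#'
#' @param patient a [sample_patient()] object.
#' @param noise_cv,missing_prob see [measure_sessions()].
#' @param policy titration settings from [dosing_config()].
#' @param dmu,dmu_ery solver resolutions used for the truth simulation.
#' @return The patient with `records` (a treatment-record data frame with
#'   ISO session timestamps), `truth` (noise-free post-dialysis Hgb per
#'   session), `doses`, and the generation settings attached.
#' @export
#' @examples
#' pat <- synthesize_records(sample_patient(7), noise_cv = 0)
#' head(pat$records)
synthesize_records <- function(patient, noise_cv = 0.03,
                               missing_prob = 0.18,
                               policy = dosing_config(),
                               dmu = 0.25, dmu_ery = 1) {
  set.seed(patient$seed + 500000L)
  loop <- .closed_loop_doses(patient, policy, dmu, dmu_ery)
  p <- patient$true_params
  p$S0 <- loop$S0
  sim <- simulate_erythropoiesis(
    p, patient$profile, doses = loop$doses, events = patient$events,
    t_end = max(loop$t_sess, 1), record_times = loop$t_sess,
    dmu = dmu, dmu_ery = dmu_ery)
  meas <- measure_sessions(sim$hgb_post, noise_cv, missing_prob)
  if (meas$missing[1]) {
    # the baseline treatment that opens the adaptation window is always
    # measured (it anchors the steady-state initial condition)
    meas$missing[1] <- FALSE
    post1 <- sim$hgb_post[1] * (1 + rnorm(1, 0, noise_cv))
    meas$post_hgb[1] <- post1
    meas$pre_hgb[1] <- post1 / runif(1, 1.02, 1.12)
  }

  epoch <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
  ev_kind <- rep("none", nrow(patient$schedule))
  ev_mag <- rep(0, nrow(patient$schedule))
  for (ev in patient$events) {
    i <- which.min(abs(loop$t_sess - ev$time))
    ev_kind[i] <- ev$kind
    ev_mag[i] <- if (ev$kind == "bleed") ev$volume_ml else ev$units
  }
  records <- data.frame(
    patient_id = sprintf("SYN%04d", patient$seed %% 10000L),
    session_start = epoch + patient$schedule$start_day * 86400,
    session_end = epoch + patient$schedule$end_day * 86400,
    pre_hgb = meas$pre_hgb, post_hgb = meas$post_hgb,
    esa_dose = loop$doses$dose, event_kind = ev_kind,
    event_magnitude = ev_mag)
  patient$records <- records
  patient$truth <- sim$hgb_post
  patient$doses <- loop$doses
  patient$generation <- list(noise_cv = noise_cv,
                             missing_prob = missing_prob, policy = policy,
                             dmu = dmu, dmu_ery = dmu_ery)
  patient
}

#' Add a bleeding episode and rescue transfusion to a virtual patient
#'
#' Emulates a gastro-intestinal bleed lasting several days followed by a
#' transfusion of packed red cells. The daily blood loss is aggregated
#' onto the treatment sessions spanning the episode (so the loss between
#' two sessions is applied at the later one), keeping the event record and
#' the model forcing exactly aligned. If records were already synthesized
#' they are regenerated under the same seed.
#'
#' @param patient a [sample_patient()] object.
#' @param bleed_spec list with `start_day`, `duration_days`,
#'   `daily_volume_ml`, `transfusion_units` (transfusion given at the
#'   first session after the episode ends); `NULL` leaves the patient
#'   unchanged.
#' @return The patient with `events` set (and `records` regenerated when
#'   present).
#' @export
#' @examples
#' pat <- sample_patient(11)
#' pat <- inject_events(pat, list(start_day = 85, duration_days = 5,
#'                                daily_volume_ml = 150,
#'                                transfusion_units = 2))
#' length(pat$events)
inject_events <- function(patient, bleed_spec) {
  if (is.null(bleed_spec)) return(patient)
  t_sess <- patient$schedule$end_day - patient$schedule$end_day[1]
  t0 <- bleed_spec$start_day
  t1 <- t0 + bleed_spec$duration_days
  if (t0 < 0 || t1 > max(t_sess)) stop("event times outside the horizon")
  events <- list()
  covered <- t0
  for (i in seq_along(t_sess)) {
    if (t_sess[i] <= t0) next
    upto <- min(t_sess[i], t1)
    if (upto > covered) {
      events[[length(events) + 1]] <-
        blood_event("bleed", time = t_sess[i],
                    volume_ml = bleed_spec$daily_volume_ml * (upto - covered))
      covered <- upto
    }
    if (t_sess[i] >= t1) break
  }
  last_bleed <- max(vapply(events, `[[`, numeric(1), "time"))
  tr_i <- which(t_sess > last_bleed)[1]
  if (is.na(tr_i)) stop("no session after the bleeding episode")
  tr <- blood_event("transfusion", time = t_sess[tr_i],
                    units = bleed_spec$transfusion_units)
  if (any(vapply(events, `[[`, numeric(1), "time") == tr$time))
    stop("overlapping events at identical timestamps")
  events[[length(events) + 1]] <- tr
  patient$events <- events
  if (!is.null(patient$records)) {
    g <- patient$generation
    patient <- synthesize_records(patient, g$noise_cv, g$missing_prob,
                                  g$policy, g$dmu, g$dmu_ery)
  }
  patient
}

#' Generate a synthetic cohort
#'
#' @param n number of patients.
#' @param seed base seed; patient `i` uses `seed + i * 7919`.
#' @param noise_cv,missing_prob,policy,dmu,dmu_ery passed to
#'   [synthesize_records()].
#' @param ... passed to [sample_patient()].
#' @return List of `synthetic_patient` objects with records.
#' @export
sample_cohort <- function(n, seed = 1, noise_cv = 0.03,
                          missing_prob = 0.18, policy = dosing_config(),
                          dmu = 0.25, dmu_ery = 1, ...) {
  lapply(seq_len(n), function(i) {
    pat <- sample_patient(seed + i * 7919L, ...)
    synthesize_records(pat, noise_cv, missing_prob, policy, dmu, dmu_ery)
  })
}
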