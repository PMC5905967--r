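# Shared fixtures: small parameter sets, profiles and cached synthetic
# patients (generation is deterministic, the cache only avoids recompute).

.fixtures <- new.env(parent = emptyenv())

ref_params <- function(...) {
  patient_parameters(T_RBC = 120, E_endo = 10, t_half = 8,
                     s_alpha = 0.02, s_v = 0.08, ...)
}

ref_profile <- function() patient_profile("male", 175, 80)

# constants with every death/birth process switched off: pure transport
transport_constants <- function() {
  cst <- erythroid_defaults()
  cst$beta <- rep(0, 5)
  cst$alpha_bfu <- 0
  cst$alpha_eryb <- 0
  cst$alpha_ret <- 0
  cst$alpha_min <- 0
  cst$alpha_max <- 0
  cst$alpha_neo <- 0
  cst
}

# a state that is zero everywhere except a smooth pulse in the middle of
# the erythrocyte class
pulse_state <- function(p, dmu = 0.25, dmu_ery = 0.5, center = 60,
                        width = 5) {
  grids <- maturity_grids(p, dmu, dmu_ery)
  dens <- lapply(grids$grid, function(g) rep(0, length(g)))
  dens[[5]] <- 1e10 * exp(-((grids$grid[[5]] - center) / width)^2)
  erythrosim:::.new_state(0, grids, dens, p)
}

cached_patient <- function(seed, noise_cv, missing_prob = 0.18,
                           dmu = 0.5, dmu_ery = 2) {
  key <- paste(seed, noise_cv, missing_prob, dmu, dmu_ery, sep = "_")
  if (is.null(.fixtures[[key]])) {
    pat <- sample_patient(seed)
    .fixtures[[key]] <- synthesize_records(pat, noise_cv = noise_cv,
                                           missing_prob = missing_prob,
                                           dmu = dmu, dmu_ery = dmu_ery)
  }
  .fixtures[[key]]
}

true_theta <- function(pat) {
  unlist(unclass(pat$true_params)[c("T_RBC", "E_endo", "t_half",
                                    "s_alpha", "s_v")])
}

# hand-built treatment records around the eligibility thresholds
toy_records <- function(n = 50, pre = 10, post = 11, doses = 2,
                        start = as.POSIXct("2023-01-02 08:00:00",
                                           tz = "UTC")) {
  t_day <- seq(0, by = 2.333, length.out = n)
  dose <- rep(0, n)
  if (doses > 0) dose[seq_len(doses)] <- 2000
  data.frame(patient_id = "TOY1",
             session_start = start + t_day * 86400,
             session_end = start + (t_day + 4 / 24) * 86400,
             pre_hgb = rep_len(pre, n), post_hgb = rep_len(post, n),
             esa_dose = dose, event_kind = "none", event_magnitude = 0)
}
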