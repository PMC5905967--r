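#' Default fixed physiological constants of the erythropoiesis model
#'
#' One table holds every fixed constant of the five-class model: maturity
#' domain lengths, baseline proliferation and apoptosis rates, maturation
#' velocities, the CFU-E apoptosis range, the reticulocyte velocity range,
#' the neocytolysis parameters, the mean corpuscular hemoglobin and the ESA
#' distribution volume per kg. The values are calibrated so that a healthy
#' reference subject (slopes 0.02 and 0.08, endogenous EPO 10 U/l, red cell
#' lifespan 120 days) holds a steady-state hemoglobin near 14.5 g/dl once
#' the stem-cell influx is calibrated to that target. Every entry can be
#' overridden through the `constants` argument of [patient_parameters()].
#'
#' @return Named list of constants. Class-indexed entries are ordered
#'   BFU-E, CFU-E, erythroblast, marrow reticulocyte, erythrocyte.
#' @export
#' @examples
#' erythroid_defaults()$mu_max
erythroid_defaults <- function() {
  list(
    class_names = c("BFU_E", "CFU_E", "erythroblast",
                    "marrow_reticulocyte", "erythrocyte"),
    # maturity-domain lengths in days; the erythrocyte entry is NA because
    # it equals the patient's lifespan T_RBC
    mu_max    = c(7, 6, 5, 3, NA),
    beta      = c(0.5, 0.5, 0.7, 0, 0),      # proliferation, 1/day
    alpha_bfu = 0.02,                        # constant apoptosis, 1/day
    alpha_eryb = 0.02,
    alpha_ret = 0,
    alpha_min = 0.01,                        # CFU-E apoptosis floor, 1/day
    alpha_max = 1.2,                         # CFU-E apoptosis at E = 0
    v_min     = 0.1,                         # reticulocyte velocity floor
    v_max     = 2.5,                         # reticulocyte velocity cap
    E_neo     = 5,                           # neocytolysis threshold, U/l
    mu_neo    = 14,                          # neocyte window, days
    alpha_neo = 0.4,                         # maximal neocytolysis, 1/day
    MCH       = 29,                          # pg hemoglobin per cell
    Vd_per_kg = 0.055                        # ESA distribution volume, l/kg
  )
}

#' Patient-specific model parameters
#'
#' Bundles the five estimated quantities (red cell lifespan, endogenous EPO
#' concentration, ESA elimination half-life, CFU-E apoptosis slope,
#' reticulocyte velocity slope), the stem-cell influx `S0` set by
#' steady-state calibration, and the fixed constants.
#'
#' @param T_RBC red blood cell lifespan in days, in (10, 200).
#' @param E_endo constant endogenous erythropoietin concentration, U/l.
#' @param t_half ESA elimination half-life in hours.
#' @param s_alpha slope of the CFU-E apoptosis-prevention response, l/U.
#' @param s_v slope of the reticulocyte maturation-velocity response,
#'   maturity-days/day per U/l.
#' @param S0 stem-cell influx into BFU-E, cells/day; usually filled in by
#'   [calibrate_stem_influx()].
#' @param constants fixed constants, see [erythroid_defaults()].
#' @return Object of class `patient_parameters`.
#' @export
#' @examples
#' patient_parameters(T_RBC = 74, E_endo = 9.8, t_half = 9.6,
#'                    s_alpha = 0.0087, s_v = 0.0196)
patient_parameters <- function(T_RBC = 120, E_endo = 10, t_half = 8,
                               s_alpha = 0.02, s_v = 0.08, S0 = NA_real_,
                               constants = erythroid_defaults()) {
  stopifnot(T_RBC > 10, T_RBC < 200, t_half > 0, E_endo >= 0,
            s_alpha >= 0, s_v >= 0,
            constants$alpha_min <= constants$alpha_max,
            constants$v_min <= constants$v_max)
  structure(list(T_RBC = T_RBC, E_endo = E_endo, t_half = t_half,
                 s_alpha = s_alpha, s_v = s_v, S0 = S0,
                 constants = constants),
            class = "patient_parameters")
}

#' @export
print.patient_parameters <- function(x, ...) {
  cat("Patient parameters:\n")
  cat(sprintf("  RBC lifespan        %.1f days\n", x$T_RBC))
  cat(sprintf("  endogenous EPO      %.2f U/l\n", x$E_endo))
  cat(sprintf("  ESA half-life       %.2f h\n", x$t_half))
  cat(sprintf("  apoptosis slope     %.4g l/U\n", x$s_alpha))
  cat(sprintf("  velocity slope      %.4g\n", x$s_v))
  cat(sprintf("  stem-cell influx S0 %.4g cells/day\n", x$S0))
  invisible(x)
}

#' Patient anthropometric profile and blood volume
#'
#' Stores sex, height and post-dialytic weight and derives the
#' post-dialytic total blood volume via [nadler_tbv()] and the ESA
#' distribution volume.
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm standing height in cm, in (100, 230).
#' @param weight_kg post-dialytic body weight in kg, in (25, 300).
#' @param Vd_per_kg ESA distribution volume per kg body weight, l/kg.
#' @return Object of class `patient_profile` with fields `TBV_post`
#'   (liters) and `V_d` (liters).
#' @export
#' @examples
#' patient_profile("male", 187, 136)
patient_profile <- function(sex = c("male", "female"), height_cm, weight_kg,
                            Vd_per_kg = erythroid_defaults()$Vd_per_kg) {
  sex <- match.arg(sex)
  tbv <- nadler_tbv(sex, height_cm, weight_kg)
  structure(list(sex = sex, height_cm = height_cm, weight_kg = weight_kg,
                 TBV_post = tbv, V_d = Vd_per_kg * weight_kg),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("Patient profile: %s, %.0f cm, %.1f kg (post-dialytic)\n",
              x$sex, x$height_cm, x$weight_kg))
  cat(sprintf("  total blood volume %.2f l, ESA V_d %.2f l\n",
              x$TBV_post, x$V_d))
  invisible(x)
}

#' A bleeding or transfusion event
#'
#' @param kind `"bleed"` or `"transfusion"`.
#' @param time event time in days on the simulation clock.
#' @param volume_ml blood volume lost (bleeds only), ml.
#' @param units number of packed red cell units (transfusions only).
#' @param cells_per_ml donor red cell concentration, cells/ml.
#' @param unit_volume_ml volume of one donated unit, ml. The defaults give
#'   the standard bookkeeping of 473 ml x 5e9 cells/ml = 2.365e12 cells per
#'   unit.
#' @return Object of class `blood_event`.
#' @export
#' @examples
#' blood_event("transfusion", time = 85, units = 2)
#' blood_event("bleed", time = 80, volume_ml = 150)
blood_event <- function(kind = c("bleed", "transfusion"), time,
                        volume_ml = 0, units = 0,
                        cells_per_ml = 5e9, unit_volume_ml = 473) {
  kind <- match.arg(kind)
  stopifnot(volume_ml >= 0, units >= 0, time >= 0)
  structure(list(kind = kind, time = time, volume_ml = volume_ml,
                 units = units, cells_per_ml = cells_per_ml,
                 unit_volume_ml = unit_volume_ml),
            class = "blood_event")
}
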