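# EPO-dependent rate functions of the five erythroid classes.
#
# EPO acts at two points: it prevents apoptosis of CFU-E (decreasing
# exponential with slope s_alpha) and accelerates the maturation of marrow
# reticulocytes (linear with slope s_v, capped at v_max). A drop of total
# EPO below the neocytolysis threshold selectively removes the youngest
# circulating erythrocytes (neocytes).

.class_names <- c("BFU_E", "CFU_E", "erythroblast",
                  "marrow_reticulocyte", "erythrocyte")

.match_class <- function(class_name) {
  k <- match(class_name, .class_names)
  if (is.na(k)) stop("unknown population class: ", class_name)
  k
}

#' Apoptosis rate of an erythroid class
#'
#' CFU-E apoptosis decreases exponentially with total EPO,
#' `alpha_min + (alpha_max - alpha_min) * exp(-s_alpha * E)`; survival of
#' these progenitors is the main EPO checkpoint of erythropoiesis.
#' Erythrocytes are subject only to [neocytolysis_rate()]; the remaining
#' classes die at constant baseline rates.
#'
#' @param class_name one of `"BFU_E"`, `"CFU_E"`, `"erythroblast"`,
#'   `"marrow_reticulocyte"`, `"erythrocyte"`.
#' @param E_total total (endogenous + exogenous) EPO concentration, U/l.
#' @param mu cell maturity in days (used by the erythrocyte class, whose
#'   neocytolysis is maturity-selective).
#' @param p a [patient_parameters()] object.
#' @return Apoptosis rate in 1/day (vectorized over `E_total` or `mu`).
#' @export
#' @examples
#' p <- patient_parameters()
#' apoptosis_rate("CFU_E", E_total = c(0, 10, 1e6), p = p)
apoptosis_rate <- function(class_name, E_total, mu = 0, p) {
  stopifnot(all(E_total >= 0))
  k <- .match_class(class_name)
  cst <- p$constants
  switch(k,
         rep_len(cst$alpha_bfu, length(E_total)),
         cst$alpha_min + (cst$alpha_max - cst$alpha_min) *
           exp(-p$s_alpha * E_total),
         rep_len(cst$alpha_eryb, length(E_total)),
         rep_len(cst$alpha_ret, length(E_total)),
         neocytolysis_rate(E_total, mu, p))
}

#' Proliferation rate of an erythroid class
#'
#' Constant per class: EPO acts through apoptosis and maturation velocity,
#' not through division rates. Mature erythrocytes do not divide.
#'
#' @inheritParams apoptosis_rate
#' @return Proliferation rate in 1/day.
#' @export
proliferation_rate <- function(class_name, E_total = 0, p) {
  stopifnot(all(E_total >= 0))
  k <- .match_class(class_name)
  rep_len(p$constants$beta[k], max(1L, length(E_total)))
}

#' Maturation velocity of an erythroid class
#'
#' Marrow reticulocytes mature faster under EPO,
#' `min(v_max, v_min + s_v * E)`; all other classes advance at one
#' maturity-day per day.
#'
#' @inheritParams apoptosis_rate
#' @return Velocity in maturity-days per day; strictly positive.
#' @export
maturation_velocity <- function(class_name, E_total, p) {
  stopifnot(all(E_total >= 0))
  k <- .match_class(class_name)
  if (k == 4L) {
    pmin(p$constants$v_max, p$constants$v_min + p$s_v * E_total)
  } else {
    rep_len(1, length(E_total))
  }
}

#' Neocytolysis rate
#'
#' When total EPO falls below the threshold `E_neo`, the youngest
#' circulating erythrocytes (maturity below `mu_neo`) are removed at rate
#' `alpha_neo * (E_neo - E) / E_neo`; the rate is zero at or above the
#' threshold and outside the neocyte window.
#'
#' @param E_total total EPO concentration, U/l.
#' @param mu erythrocyte maturity in days, within `[0, T_RBC]`.
#' @param p a [patient_parameters()] object.
#' @return Rate in 1/day, vectorized over `E_total` or `mu`.
#' @export
neocytolysis_rate <- function(E_total, mu, p) {
  cst <- p$constants
  suppression <- pmax(0, (cst$E_neo - E_total) / cst$E_neo)
  cst$alpha_neo * suppression * as.numeric(mu <= cst$mu_neo)
}

#' Total EPO concentration under bolus ESA dosing
#'
#' Exogenous ESA is eliminated first-order with half-life `t_half` (hours)
#' from the distribution volume `V_d`; endogenous release is constant, so
#'
#' `E(t) = E_endo + sum over doses before t of (dose / V_d) *
#'         2^(-(t - t_dose) * 24 / t_half)`,
#'
#' the closed-form solution of the linear elimination equation with
#' intravenous bolus inputs.
#'
#' @param t evaluation times in days (vectorized).
#' @param doses data frame with columns `time` (days) and `dose` (U); may
#'   be empty.
#' @param p a [patient_parameters()] object (supplies `E_endo`, `t_half`).
#' @param profile a [patient_profile()] object (supplies `V_d`).
#' @return Total EPO concentration in U/l at each time.
#' @export
#' @examples
#' p <- patient_parameters(E_endo = 10, t_half = 8)
#' prof <- patient_profile("male", 180, 4 / erythroid_defaults()$Vd_per_kg)
#' epo_concentration(1, doses = data.frame(time = 0, dose = 8000), p, prof)
epo_concentration <- function(t, doses, p, profile) {
  if (p$t_half <= 0) stop("t_half must be positive")
  if (profile$V_d <= 0) stop("distribution volume must be positive")
  E <- rep_len(p$E_endo, length(t))
  if (NROW(doses) > 0) {
    lambda <- log(2) * 24 / p$t_half          # 1/day
    for (i in seq_len(nrow(doses))) {
      dtime <- t - doses$time[i]
      active <- dtime >= 0
      E[active] <- E[active] +
        (doses$dose[i] / profile$V_d) * exp(-lambda * dtime[active])
    }
  }
  E
}

# exact mean of the total EPO concentration over each step [t_n, t_n + dt]
# (closed-form AUC of the bolus-elimination model); using step averages
# rather than point samples makes the forcing insensitive to how dose
# times fall relative to the step grid
.epo_step_avg <- function(t_starts, dt, doses, p, profile) {
  if (NROW(doses) == 0) return(rep_len(p$E_endo, length(t_starts)))
  cpp_epo_step_avg(t_starts, dt, doses$time, doses$dose, profile$V_d,
                   log(2) * 24 / p$t_half, p$E_endo)
}

#' Apply a bleed or transfusion to a population state
#'
#' Bleeds remove circulating erythrocytes proportionally: every density
#' value of the erythrocyte class is multiplied by
#' `1 - volume_ml / (TBV * 1000)`. Transfusions add
#' `units * unit_volume_ml * cells_per_ml` cells, spread uniformly over
#' maturity `[0, T_RBC]` (the age distribution of donor cells is unknown).
#' Marrow classes are untouched in both cases.
#'
#' @param state a `population_state` (see [steady_state()]).
#' @param event a [blood_event()].
#' @param TBV total blood volume in liters (for bleeds).
#' @return The modified `population_state`.
#' @export
#' @examples
#' p <- patient_parameters(S0 = 1e9)
#' st <- steady_state(p, E_const = 10)
#' ev <- blood_event("transfusion", time = 0, units = 1)
#' total_rbc(apply_blood_event(st, ev, TBV = 5)) - total_rbc(st)
apply_blood_event <- function(state, event, TBV) {
  stopifnot(inherits(event, "blood_event"), TBV > 0)
  ery <- state$classes[[5]]
  if (event$kind == "bleed") {
    frac <- event$volume_ml / (TBV * 1000)
    if (frac > 1) stop("bleed volume exceeds total blood volume")
    ery$density <- ery$density * (1 - frac)
  } else {
    cells <- event$units * event$unit_volume_ml * event$cells_per_ml
    T_RBC <- max(ery$grid)
    ery$density <- ery$density + cells / T_RBC
  }
  state$classes[[5]] <- ery
  state$total_counts[5] <- .trapz(ery$density, ery$grid[2] - ery$grid[1])
  state
}
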