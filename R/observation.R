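# Observation model: blood volumes and the map between simulated cell
# counts and the hemoglobin values a Crit-Line monitor reports.

#' Nadler total blood volume
#'
#' Estimates total blood volume from sex, height and weight:
#' males `0.3669 h^3 + 0.03219 w + 0.6041`, females
#' `0.3561 h^3 + 0.03308 w + 0.1833`, with height `h` in meters and weight
#' `w` in kg. Applied to the post-dialytic weight this gives the
#' post-dialysis blood volume used throughout the observation model.
#'
#' @param sex `"male"` or `"female"`.
#' @param height_cm height in cm, in (100, 230).
#' @param weight_kg weight in kg, in (25, 300).
#' @return Total blood volume in liters.
#' @export
#' @examples
#' nadler_tbv("male", 187, 136)    # 7.38 l
#' nadler_tbv("female", 155, 62)   # 3.56 l
nadler_tbv <- function(sex = c("male", "female"), height_cm, weight_kg) {
  sex <- match.arg(sex)
  if (height_cm <= 100 || height_cm >= 230)
    stop("height out of the supported range (100, 230) cm")
  if (weight_kg <= 25 || weight_kg >= 300)
    stop("weight out of the supported range (25, 300) kg")
  h <- height_cm / 100
  if (sex == "male") 0.3669 * h^3 + 0.03219 * weight_kg + 0.6041
  else               0.3561 * h^3 + 0.03308 * weight_kg + 0.1833
}

#' Hemoglobin concentration from a red cell count
#'
#' `Hgb = n * MCH * 1e-12 / (TBV * 10)` g/dl: each cell carries `MCH`
#' picograms of hemoglobin, diluted in the total blood volume.
#'
#' @param n_rbc circulating red cell count (vectorized).
#' @param TBV total blood volume, liters.
#' @param MCH mean corpuscular hemoglobin, pg/cell.
#' @return Hemoglobin in g/dl.
#' @export
#' @examples
#' hgb_from_count(2.5e13, TBV = 5, MCH = 29)  # 14.5 g/dl
hgb_from_count <- function(n_rbc, TBV, MCH = erythroid_defaults()$MCH) {
  if (TBV <= 0) stop("total blood volume must be positive")
  n_rbc * MCH * 1e-12 / (TBV * 10)
}

#' Simulated pre-dialysis hemoglobin from the post-dialysis value
#'
#' Ultrafiltration removes fluid during a session, so pre- and
#' post-dialysis hemoglobin differ through blood volume alone. The measured
#' pre/post pair fixes the pre-dialysis volume,
#' `preTBV = postHgb_CLM * postTBV / preHgb_CLM`, and the simulated
#' post-dialysis value is rescaled into it,
#' `preHgb_sim = postHgb_sim * postTBV / preTBV`. Algebraically
#' `preHgb_sim / postHgb_sim = preHgb_CLM / postHgb_CLM`.
#'
#' @param postHgb_sim simulated post-dialysis hemoglobin, g/dl (vectorized).
#' @param postHgb_CLM measured post-dialysis hemoglobin, g/dl.
#' @param preHgb_CLM measured pre-dialysis hemoglobin, g/dl.
#' @param postTBV post-dialytic total blood volume, liters.
#' @return List with `preTBV` (liters) and `preHgb_sim` (g/dl).
#' @export
#' @examples
#' pre_dialysis_hgb(postHgb_sim = 11, postHgb_CLM = 11,
#'                  preHgb_CLM = 10, postTBV = 5)
pre_dialysis_hgb <- function(postHgb_sim, postHgb_CLM, preHgb_CLM, postTBV) {
  if (any(preHgb_CLM <= 0) || any(postHgb_CLM <= 0))
    stop("measured hemoglobin values must be positive")
  preTBV <- postHgb_CLM * postTBV / preHgb_CLM
  list(preTBV = preTBV, preHgb_sim = postHgb_sim * postTBV / preTBV)
}
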