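# Fit and forecast metrics: mean absolute percentage error, the
# Kantorovich (Wasserstein-1) distance between empirical samples, and the
# 30-day windowed prediction assessment.

#' Mean absolute percentage error
#'
#' `MAPE = (100 / N) * sum |y_i - g_i| / |y_i|` between measurements `y`
#' and model outputs `g` at paired time points.
#'
#' @param y measured values (nonzero).
#' @param g model outputs, same length.
#' @return MAPE in percent.
#' @export
#' @examples
#' mape(c(10, 10), c(9, 11))  # 10
mape <- function(y, g) {
  if (length(y) != length(g)) stop("y and g must have equal length")
  if (length(y) < 1) stop("at least one observation required")
  if (any(y == 0)) stop("measurements must be nonzero")
  100 * mean(abs((y - g) / y))
}

#' Kantorovich (Wasserstein-1) distance between two samples
#'
#' The minimal transport cost between the empirical distributions of `x`
#' and `y` with cost `|x - y|`. In one dimension it equals the integral of
#' the absolute difference between the empirical CDFs; for equal-size
#' samples the optimal coupling pairs order statistics, giving
#' `mean(|sort(x) - sort(y)|)`.
#'
#' @param x,y non-empty numeric samples (lengths may differ).
#' @return The distance, in the units of the samples.
#' @export
#' @examples
#' kantorovich(c(0, 1), c(1, 2))  # 1
kantorovich <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  z <- sort(c(x, y))
  if (length(z) < 2) return(abs(x - y))
  mid <- z[-length(z)]
  sum(abs(ecdf(x)(mid) - ecdf(y)(mid)) * diff(z))
}

#' Windowed prediction error over 30-day horizons
#'
#' Computes the MAPE separately over consecutive half-open windows
#' `[k*30, (k+1)*30)` days after the end of the adaptation period, using
#' pre-dialysis hemoglobin. Patients contribute only to windows in which
#' they have measurements, so the patient count decreases with the
#' horizon. The summary per window is the median of the per-patient MAPEs.
#'
#' @param pred data frame with columns `patient_id`, `t_days` (days since
#'   the adaptation end), `observed` (measured pre-dialysis Hgb, g/dl) and
#'   `simulated` (simulated pre-dialysis Hgb, g/dl).
#' @param window_days window length, days.
#' @return Data frame with one row per non-empty window:
#'   `window_start_day`, `window_end_day`, `mape_median` (%),
#'   `n_patients`; per-patient rows in the `"per_patient"` attribute.
#' @export
windowed_prediction_error <- function(pred, window_days = 30) {
  if (NROW(pred) == 0) stop("prediction records are empty")
  win <- floor(pred$t_days / window_days)
  per <- do.call(rbind, lapply(split(pred, list(pred$patient_id, win),
                                     drop = TRUE), function(d) {
    data.frame(patient_id = d$patient_id[1],
               window = floor(d$t_days[1] / window_days),
               mape = mape(d$observed, d$simulated),
               n_obs = nrow(d))
  }))
  rows <- do.call(rbind, lapply(split(per, per$window), function(d) {
    data.frame(window_start_day = d$window[1] * window_days,
               window_end_day = (d$window[1] + 1) * window_days,
               mape_median = stats::median(d$mape),
               n_patients = nrow(d))
  }))
  rows <- rows[order(rows$window_start_day), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "per_patient") <- per
  rows
}
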