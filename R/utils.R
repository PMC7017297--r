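# Internal unit helpers. Canonical internal units are ng, mL, h, kg; clearance
# is reported in mL/min/kg, hence the single factor of 60 lives here and
# nowhere else.

#' Convert weight-normalised clearance to dose-normalised AUC
#'
#' For an i.v. bolus, `AUC0-inf = Dose / CL`. With dose in mg/kg (= 1e6 ng/kg
#' per mg/kg) and CL in mL/min/kg, the AUC per unit dose in h.ng/mL per
#' (mg/kg) is `1e6 / (60 * CL)`.
#'
#' @param cl_ml_min_kg clearance in mL/min/kg; must be positive.
#' @return AUC per unit dose, h.ng/mL per (mg/kg).
#' @seealso [cl_from_auc_per_dose()] for the inverse.
#' @export
#' @examples
#' auc_per_dose_from_cl(8.7)   # rat-like clearance
auc_per_dose_from_cl <- function(cl_ml_min_kg) {
  stopifnot(is.numeric(cl_ml_min_kg), all(cl_ml_min_kg > 0))
  1e6 / (60 * cl_ml_min_kg)
}

#' @rdname auc_per_dose_from_cl
#' @param auc_per_dose AUC per unit dose in h.ng/mL per (mg/kg); positive.
#' @export
cl_from_auc_per_dose <- function(auc_per_dose) {
  stopifnot(is.numeric(auc_per_dose), all(auc_per_dose > 0))
  1e6 / (60 * auc_per_dose)
}

#' Geometric mean of positive values
#'
#' `exp(mean(log(x)))`, the aggregation used to combine clearance estimates
#' from parallel allometric methods into a single human prediction.
#'
#' @param x numeric vector, all elements strictly positive.
#' @return the geometric mean (scalar).
#' @export
#' @examples
#' geometric_mean(c(2, 8))  # 4
geometric_mean <- function(x) {
  if (length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean undefined: all values must be finite and positive")
  }
  exp(mean(log(x)))
}

#' Round half away from zero
#'
#' Reporting-style rounding (0.5 always rounds up in magnitude), as used for
#' table display; distinct from base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# coefficient of variation in percent; sample SD (n-1). Single values give 0
# by convention (flagged upstream).
cv_percent <- function(x) {
  if (length(x) < 2L) return(0)
  100 * stats::sd(x) / mean(x)
}

# sample SD with the single-observation convention used in summaries
sd_or_zero <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
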