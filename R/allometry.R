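#' Species PK parameter table constructor
#'
#' Builds and validates the per-species table consumed by the scaling
#' functions: body weight, total plasma clearance, unbound fraction, the
#' derived unbound clearance `CLp_u = CLp / fu`, and an inclusion flag (the
#' mouse, whose early distribution phase is typically under-sampled, is
#' conventionally excluded from scaling).
#'
#' @param species character vector of species labels.
#' @param weight_kg body weights in kg.
#' @param cl_ml_min_kg total plasma clearance per species, mL/min/kg (NA for
#'   the target species).
#' @param fu unbound fraction in plasma, in (0, 1] (NA when unknown).
#' @param include_in_scaling logical: use this species in cross-species fits.
#' @return a `species_pk` data frame with a `clu_ml_min_kg` column added.
#' @export
species_pk <- function(species, weight_kg, cl_ml_min_kg,
                       fu = NA_real_, include_in_scaling = TRUE) {
  d <- data.frame(species = species, weight_kg = weight_kg,
                  cl_ml_min_kg = cl_ml_min_kg, fu = fu,
                  include_in_scaling = include_in_scaling,
                  stringsAsFactors = FALSE)
  stopifnot(all(d$weight_kg > 0),
            all(is.na(d$cl_ml_min_kg) | d$cl_ml_min_kg > 0),
            all(is.na(d$fu) | (d$fu > 0 & d$fu <= 1)))
  d$clu_ml_min_kg <- unbound_cl(d$cl_ml_min_kg, d$fu)
  class(d) <- c("species_pk", class(d))
  d
}

#' Unbound clearance from total clearance and fraction unbound
#'
#' `CLp_u = CLp / fu`. NA in either input propagates.
#'
#' @param clp total plasma clearance, mL/min/kg.
#' @param fu unbound fraction in (0, 1].
#' @return unbound clearance, mL/min/kg.
#' @export
unbound_cl <- function(clp, fu) {
  bad <- !is.na(fu) & fu <= 0
  if (any(bad)) stop("fully bound, unbound CL undefined (fu <= 0)")
  stopifnot(all(is.na(fu) | fu <= 1))
  clp / fu
}

#' Re-express a scaled unbound clearance on the total scale
#'
#' After scaling unbound clearance to the target species, multiplying by the
#' target-species fu returns a total-clearance prediction commensurable with
#' the direct total-clearance pipeline.
#'
#' @param clp_u_human scaled unbound clearance, mL/min/kg.
#' @param fu_human target-species unbound fraction, in (0, 1].
#' @return total-scale clearance, mL/min/kg.
#' @export
rebind_to_total <- function(clp_u_human, fu_human) {
  stopifnot(fu_human > 0, fu_human <= 1)
  clp_u_human * fu_human
}

#' Fit the allometric power law Y = a * W^b
#'
#' Least-squares regression of `log10(Y)` on `log10(W)`; with exactly two
#' species the fitted power law passes through both points. `Y` is the
#' weight-normalised clearance (mL/min/kg); because `CL_abs = Y * W =
#' a * W^(b+1)`, the same intercept `a` serves both scales and the exponent
#' conversion `b <-> b + 1` is handled internally by the predictors.
#'
#' @param weight_kg body weights, kg (at least 2 distinct).
#' @param cl_per_kg weight-normalised clearances, mL/min/kg.
#' @param basis `"total"` or `"unbound"`, recorded on the fit.
#' @param species optional labels recorded on the fit.
#' @return an `allometric_fit`: list with `a` (natural scale), `log10_a`,
#'   `b`, `basis`, `species`, `n`, `r_squared`.
#' @export
#' @examples
#' fit_allometry(c(0.25, 3.75), c(7.9, 2.958))
fit_allometry <- function(weight_kg, cl_per_kg, basis = "total",
                          species = NULL) {
  stopifnot(length(weight_kg) == length(cl_per_kg), length(weight_kg) >= 2L,
            all(weight_kg > 0), all(cl_per_kg > 0))
  if (length(unique(weight_kg)) < 2L) {
    stop("degenerate regression: need at least 2 distinct weights")
  }
  fit <- stats::lm(log10(cl_per_kg) ~ log10(weight_kg))
  structure(
    list(a = unname(10^stats::coef(fit)[1]),
         log10_a = unname(stats::coef(fit)[1]),
         b = unname(stats::coef(fit)[2]),
         basis = basis, species = species, n = length(weight_kg),
         r_squared = {
           y <- log10(cl_per_kg)
           tss <- sum((y - mean(y))^2)
           if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
         }),
    class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> Y = %.4g * W^%.5g  (log10 a = %.4f, basis %s, n = %d)\n",
              x$a, x$b, x$log10_a, x$basis, x$n))
  invisible(x)
}

new_cl_prediction <- function(method, cl_per_kg, w_target, basis) {
  structure(list(method = method, cl_per_kg = cl_per_kg,
                 cl_absolute = cl_per_kg * w_target,
                 w_target = w_target, basis = basis),
            class = "cl_prediction")
}

#' @export
print.cl_prediction <- function(x, ...) {
  cat(sprintf("<cl_prediction> %s: %.4g mL/min/kg (%.4g mL/min at %g kg, basis %s)\n",
              x$method, x$cl_per_kg, x$cl_absolute, x$w_target, x$basis))
  invisible(x)
}

#' Direct two-species allometric prediction
#'
#' Evaluates the fitted power law at the target weight:
#' `CL/kg = a * W^b`, `CL_abs = a * W^(b+1)`.
#'
#' @param fit an [fit_allometry()] result.
#' @param w_target target body weight, kg.
#' @return a `cl_prediction` (method `"direct"`).
#' @export
predict_direct <- function(fit, w_target) {
  stopifnot(inherits(fit, "allometric_fit"), w_target > 0)
  new_cl_prediction("direct", fit$a * w_target^fit$b, w_target, fit$basis)
}

#' Tang fixed-exponent prediction
#'
#' Rule-of-exponents variant for rat-monkey data: keep the fitted intercept
#' `a` but fix the exponent at 0.65 on the absolute-clearance scale,
#' `CL_abs = a * W^0.65`, then divide by the target weight for the per-kg
#' value.
#'
#' @param fit an [fit_allometry()] result (rat + monkey).
#' @param w_target target body weight, kg.
#' @param exponent fixed absolute-scale exponent (default 0.65).
#' @return a `cl_prediction` (method `"tang"`).
#' @export
predict_tang <- function(fit, w_target, exponent = 0.65) {
  stopifnot(inherits(fit, "allometric_fit"), w_target > 0)
  new_cl_prediction("tang", fit$a * w_target^exponent / w_target,
                    w_target, fit$basis)
}

#' Single-species allometric prediction
#'
#' Fixed-exponent scaling from one species:
#' `CL_abs_target = CL_abs_animal * (W_target / W_animal)^0.75`, equivalently
#' per-kg `CL * (W_animal / W_target)^(1 - 0.75)`.
#'
#' @param cl_per_kg animal weight-normalised clearance, mL/min/kg.
#' @param w_animal animal body weight, kg.
#' @param w_target target body weight, kg.
#' @param exponent absolute-scale exponent (default 0.75); values outside
#'   (0, 2) trigger a warning.
#' @param basis recorded basis label.
#' @param species optional species label appended to the method id.
#' @return a `cl_prediction` (method `"one_species"` or
#'   `"one_species_<label>"`).
#' @export
predict_one_species <- function(cl_per_kg, w_animal, w_target,
                                exponent = 0.75, basis = "total",
                                species = NULL) {
  stopifnot(cl_per_kg > 0, w_animal > 0, w_target > 0)
  if (exponent <= 0 || exponent >= 2) {
    warning("unusual allometric exponent: ", exponent)
  }
  method <- if (is.null(species)) "one_species" else
    paste0("one_species_", species)
  new_cl_prediction(method,
                    cl_per_kg * (w_animal / w_target)^(1 - exponent),
                    w_target, basis)
}

#' Human clearance predictions by all scaling methods
#'
#' Runs the four parallel methods on a [species_pk()] table: direct
#' two-species regression, the Tang fixed-0.65 rule (both on the
#' scaling-eligible species), and single-species 0.75-exponent scaling from
#' each eligible species. On the `"unbound"` basis each species' clearance is
#' first divided by its fu, scaled, and the target prediction multiplied
#' back by `fu_target` so both bases report on the total-clearance scale.
#'
#' @param species a [species_pk()] table; rows with
#'   `include_in_scaling = TRUE` and non-NA clearance are used.
#' @param w_target target body weight, kg (default 70).
#' @param basis `"total"` or `"unbound"`.
#' @param fu_target target-species unbound fraction (required for
#'   `basis = "unbound"`).
#' @return data frame with `method`, `basis`, `cl_per_kg`, `cl_absolute` and
#'   a `geometric_mean` attribute-free summary row is *not* included; use
#'   [geometric_mean()] on `cl_per_kg`.
#' @export
human_cl_predictions <- function(species, w_target = 70,
                                 basis = c("total", "unbound"),
                                 fu_target = NULL) {
  basis <- match.arg(basis)
  sp <- species[species$include_in_scaling & !is.na(species$cl_ml_min_kg), ,
                drop = FALSE]
  if (nrow(sp) < 2L) stop("need at least 2 scaling-eligible species")
  if (basis == "unbound") {
    if (is.null(fu_target) || is.na(fu_target)) {
      stop("unbound basis requires fu for the target species")
    }
    if (any(is.na(sp$fu))) stop("unbound basis requires fu for every species used")
    cl <- sp$clu_ml_min_kg
    finish <- function(x) rebind_to_total(x, fu_target)
  } else {
    cl <- sp$cl_ml_min_kg
    finish <- identity
  }
  fit <- fit_allometry(sp$weight_kg, cl, basis = basis, species = sp$species)
  preds <- c(list(predict_direct(fit, w_target),
                  predict_tang(fit, w_target)),
             lapply(seq_len(nrow(sp)), function(i) {
               predict_one_species(cl[i], sp$weight_kg[i], w_target,
                                   basis = basis, species = sp$species[i])
             }))
  out <- do.call(rbind, lapply(preds, function(p) {
    data.frame(method = p$method, basis = basis,
               cl_per_kg = finish(p$cl_per_kg),
               stringsAsFactors = FALSE)
  }))
  out$cl_absolute <- out$cl_per_kg * w_target
  attr(out, "fit") <- fit
  out
}
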