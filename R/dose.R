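#' Body-surface-area correction factor
#'
#' `(W_human / W_animal)^(1 - 0.67)`: the factor by which an animal mg/kg
#' dose is divided to obtain the human equivalent dose on a mg/m2-normalised
#' basis.
#'
#' @param w_human human body weight, kg.
#' @param w_animal animal body weight, kg.
#' @param exponent body-surface-area exponent (default 0.67).
#' @return dimensionless correction factor (>= 1 when the human is heavier).
#' @export
#' @examples
#' bsa_correction_factor(70, 0.25)  # ~6.42 (rat -> human)
bsa_correction_factor <- function(w_human, w_animal, exponent = 0.67) {
  stopifnot(w_human > 0, w_animal > 0)
  (w_human / w_animal)^(1 - exponent)
}

#' Human equivalent dose from an animal NOAEL
#'
#' Divides the animal no-observed-adverse-effect-level dose by the
#' body-surface-area correction factor. With `factor = 1` this is direct
#' mg/kg carry-over.
#'
#' @param noael animal NOAEL, mg/kg/day.
#' @param factor correction factor from [bsa_correction_factor()].
#' @return HED, mg/kg/day.
#' @export
#' @examples
#' hed_from_noael(5, bsa_correction_factor(70, 0.25))  # ~0.78
hed_from_noael <- function(noael, factor) {
  stopifnot(noael > 0, factor > 0)
  noael / factor
}

#' Scale a pharmacodynamically active dose to human
#'
#' Applies the same body-surface-area conversion to an efficacious animal
#' dose: `PAD_human = PAD_animal / (W_human / W_animal)^(1 - 0.67)`.
#'
#' @param pad_animal efficacious animal dose, mg/kg.
#' @param w_human human body weight, kg.
#' @param w_animal animal body weight, kg.
#' @param exponent body-surface-area exponent (default 0.67).
#' @return human-equivalent PAD, mg/kg.
#' @export
#' @examples
#' pad_to_human(25, 70, 0.025)  # ~1.82 (mouse -> human)
pad_to_human <- function(pad_animal, w_human, w_animal, exponent = 0.67) {
  stopifnot(pad_animal > 0)
  pad_animal / bsa_correction_factor(w_human, w_animal, exponent)
}

#' Maximum recommended starting dose
#'
#' `MRSD = HED / safety_factor` (default factor 10). When a human PAD is
#' supplied, also reports whether the PAD falls below the MRSD -- the case in
#' which a lower clinical starting dose should be considered.
#'
#' @param hed human equivalent dose, mg/kg/day.
#' @param safety_factor dimensionless divisor (default 10).
#' @param pad_human optional human-scaled PAD, mg/kg.
#' @return list with `mrsd`, `hed`, `safety_factor`, and when `pad_human`
#'   is given, `pad_human`, `pad_below_mrsd` and a human-readable `flag`.
#' @export
mrsd <- function(hed, safety_factor = 10, pad_human = NULL) {
  stopifnot(hed > 0, safety_factor > 0)
  out <- list(mrsd = hed / safety_factor, hed = hed,
              safety_factor = safety_factor)
  if (!is.null(pad_human)) {
    stopifnot(pad_human > 0)
    out$pad_human <- pad_human
    out$pad_below_mrsd <- pad_human < out$mrsd
    out$flag <- if (out$pad_below_mrsd) {
      "consider lower start dose: human PAD below MRSD"
    } else if (pad_human > hed) {
      "PAD above HED, no extra reduction"
    } else {
      "PAD between MRSD and HED"
    }
  }
  out
}

#' Exposure prediction from a clearance estimate
#'
#' Converts a human clearance prediction into dose-normalised AUC,
#' `AUC/Dose = 1e6 / (60 * CL)` in h.ng/mL per (mg/kg), and evaluates the
#' AUC at each candidate dose.
#'
#' @param cl_per_kg clearance, mL/min/kg.
#' @param doses candidate doses, mg/kg.
#' @param method optional method label recorded on the result.
#' @param basis optional basis label.
#' @return an `exposure_prediction` list: `method`, `basis`, `cl_per_kg`,
#'   `auc_per_dose`, and `auc_at_dose` (named numeric, one entry per dose).
#' @export
#' @examples
#' predict_exposure(1.02, doses = c(0.78, 1.82, 5))
predict_exposure <- function(cl_per_kg, doses, method = NA_character_,
                             basis = NA_character_) {
  stopifnot(cl_per_kg > 0, all(doses > 0))
  apd <- auc_per_dose_from_cl(cl_per_kg)
  structure(list(method = method, basis = basis, cl_per_kg = cl_per_kg,
                 auc_per_dose = apd,
                 auc_at_dose = stats::setNames(doses * apd, format(doses))),
            class = "exposure_prediction")
}

#' Assemble the total- and unbound-basis prediction tables
#'
#' End-stage aggregation: runs [human_cl_predictions()] on both bases,
#' attaches dose-normalised AUC and AUC at each candidate dose per method,
#' appends the geometric-mean row, and reports the across-method exposure
#' range at each dose.
#'
#' @param species a [species_pk()] table including a `"human"` row carrying
#'   the target weight and fu.
#' @param doses candidate human doses, mg/kg; the conventional grid is the
#'   NOAEL-derived HED, the human-scaled PAD, and the untranslated NOAEL.
#' @param w_target target weight, kg; default taken from the human row.
#' @param bases which bases to build (default both).
#' @return a `prediction_tables` list: per-basis data frame (`total`,
#'   `unbound`) with the geometric-mean row labelled `"geometric_mean"`, plus
#'   `range`, a data frame of min/max AUC per basis and dose.
#' @export
build_prediction_tables <- function(species, doses = c(0.78, 1.82, 5.0),
                                    w_target = NULL,
                                    bases = c("total", "unbound")) {
  hum <- species[species$species == "human", , drop = FALSE]
  if (is.null(w_target)) {
    if (nrow(hum) != 1L) stop("species table needs a single 'human' row or explicit w_target")
    w_target <- hum$weight_kg
  }
  fu_target <- if (nrow(hum) == 1L) hum$fu else NA_real_
  tables <- list()
  ranges <- list()
  for (basis in bases) {
    preds <- human_cl_predictions(species, w_target = w_target, basis = basis,
                                  fu_target = if (basis == "unbound") fu_target)
    gm <- geometric_mean(preds$cl_per_kg)
    tab <- rbind(preds,
                 data.frame(method = "geometric_mean", basis = basis,
                            cl_per_kg = gm, cl_absolute = gm * w_target,
                            stringsAsFactors = FALSE))
    tab$auc_per_dose <- auc_per_dose_from_cl(tab$cl_per_kg)
    for (d in doses) tab[[paste0("auc_at_", format(d))]] <- d * tab$auc_per_dose
    tables[[basis]] <- tab
    per_method <- tab[tab$method != "geometric_mean", ]
    ranges[[basis]] <- do.call(rbind, lapply(doses, function(d) {
      v <- d * per_method$auc_per_dose
      data.frame(basis = basis, dose = d, auc_min = min(v), auc_max = max(v),
                 method_min = per_method$method[which.min(v)],
                 method_max = per_method$method[which.max(v)],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(c(tables, list(range = do.call(rbind, ranges), doses = doses,
                           w_target = w_target)),
            class = "prediction_tables")
}

#' @export
print.prediction_tables <- function(x, digits = 4, ...) {
  for (basis in intersect(c("total", "unbound"), names(x))) {
    cat("==", basis, "clearance basis ==\n")
    print(format(x[[basis]], digits = digits), row.names = FALSE)
  }
  cat("== exposure range across methods ==\n")
  print(format(x$range, digits = digits), row.names = FALSE)
  invisible(x)
}
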