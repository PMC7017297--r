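# Bundled reference dataset: the LNA-i-miR-221 preclinical programme
# (i.v.-bolus PK in mouse, rat and cynomolgus monkey; ultrafiltration plasma
# protein binding; first-in-human scaling inputs). Values are stored as
# plain-text fixtures under inst/extdata and re-derived quantities are
# always computed, never stored.

ref_path <- function(file) {
  system.file("extdata", file, package = "oligopk", mustWork = TRUE)
}

#' Reference species parameter table
#'
#' Body weights, clearances and unbound fractions for the LNA-i-miR-221
#' preclinical dataset. The working clearance per species follows the
#' dataset's own conventions: dose / AUC for mouse and monkey (whose
#' published per-kg clearances are rounded), and the per-subject mean for
#' rat (the published 7.9 mL/min/kg). Mouse is excluded from scaling by
#' default: its first sample at 1.5 h misses the distribution phase, so its
#' AUC (and hence CL) is unreliable. The monkey AUC is AUC to 48 h rather
#' than infinity (terminal half-life 12.8 h makes the truncation small).
#'
#' @return a [species_pk()] table with extra provenance columns
#'   `cl_printed_ml_min_kg`, `dose_mg_per_kg`, `auc_h_ng_ml`,
#'   `cl_convention`.
#' @export
#' @examples
#' lna_species_defaults()
lna_species_defaults <- function() {
  d <- utils::read.csv(ref_path("species_parameters.csv"),
                       stringsAsFactors = FALSE)
  cl_working <- ifelse(d$cl_convention == "dose_over_auc",
                       d$dose_mg_per_kg * 1e6 / d$auc_h_ng_ml / 60,
                       d$cl_printed_ml_min_kg)
  sp <- species_pk(d$species, d$weight_kg, cl_working, fu = d$fu,
                   include_in_scaling = d$include_in_scaling == 1)
  sp$cl_printed_ml_min_kg <- d$cl_printed_ml_min_kg
  sp$dose_mg_per_kg <- d$dose_mg_per_kg
  sp$auc_h_ng_ml <- d$auc_h_ng_ml
  sp$cl_convention <- d$cl_convention
  sp
}

#' Reference individual rat NCA parameters
#'
#' Per-subject terminal rate, half-life, C0, AUC0-inf, dose-normalised AUC,
#' extrapolated percentage, Vz and CL for the six rats (three per sex) of
#' the reference 12.5 mg/kg i.v. bolus study.
#'
#' @return data frame, one row per rat.
#' @export
lna_rat_nca <- function() {
  utils::read.csv(ref_path("rat_individual_nca.csv"), stringsAsFactors = FALSE)
}

#' Reference plasma protein binding summary
#'
#' Mean and SD plasma protein binding (already recovery-corrected) per
#' species and test concentration from the reference ultrafiltration assay
#' (n = 3 replicates).
#'
#' @return data frame with `species`, `test_conc_uM`, `ppb_mean`, `ppb_sd`,
#'   `n`.
#' @export
lna_binding <- function() {
  utils::read.csv(ref_path("protein_binding.csv"), stringsAsFactors = FALSE)
}

#' Reference headline values
#'
#' The published downstream values (scaling coefficients, predicted human
#' clearances, exposure table entries, dose-translation results, binding
#' summaries) against which [reproduce_reference()] checks the package's own
#' computations. `printed_decimals` records the precision at which each
#' value was published.
#'
#' @return data frame with `name`, `value`, `units`, `printed_decimals`,
#'   `group`.
#' @export
lna_reference_values <- function() {
  utils::read.csv(ref_path("reference_values.csv"), stringsAsFactors = FALSE)
}

ref_value <- function(name, ref = lna_reference_values()) {
  i <- match(name, ref$name)
  if (is.na(i)) stop("unknown reference value: ", name)
  ref$value[i]
}
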