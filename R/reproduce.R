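#' Recompute every reference headline value from its primitive inputs
#'
#' Runs the scaling, dose-translation, exposure and binding arithmetic on
#' the bundled primitive inputs (species weights and clearance primitives,
#' per-concentration binding means, NOAEL and PAD doses, the individual rat
#' NCA rows) and compares each recomputed value with the published one.
#'
#' A target passes when the relative deviation is within its group
#' tolerance *or* the absolute deviation is within half a unit of the last
#' published decimal (values published at 2 significant figures cannot be
#' matched tighter than their own rounding).
#'
#' @param tolerances named relative tolerances per target group; defaults:
#'   exact binding/NCA arithmetic 0.5%, scaling 2%, exposure 3%, dose 1%.
#' @return a `reproduction_report` data frame (`target`, `group`,
#'   `computed`, `reference`, `rel_dev`, `tolerance`, `pass`) with an
#'   `overall_pass` attribute.
#' @export
#' @examples
#' rep <- reproduce_reference()
#' attr(rep, "overall_pass")
reproduce_reference <- function(tolerances = c(binding = 0.005, nca = 0.005,
                                               scaling = 0.02,
                                               exposure = 0.03,
                                               dose = 0.01)) {
  sp <- lna_species_defaults()
  ref <- lna_reference_values()
  hum <- sp[sp$species == "human", ]
  rows <- list()
  add <- function(target, group, computed, ref_name = target) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, group = group, computed = computed,
      reference = ref_value(ref_name, ref),
      printed_decimals = ref$printed_decimals[match(ref_name, ref$name)],
      stringsAsFactors = FALSE)
  }

  # -- scaling, total basis ---------------------------------------------
  eligible <- sp[sp$include_in_scaling, ]
  fit <- fit_allometry(eligible$weight_kg, eligible$cl_ml_min_kg,
                       species = eligible$species)
  add("direct_b", "scaling", fit$b)
  add("direct_log10_a", "scaling", fit$log10_a)
  tot <- human_cl_predictions(sp, w_target = hum$weight_kg, basis = "total")
  cl_of <- function(tab, m) tab$cl_per_kg[tab$method == m]
  add("direct_cl_per_kg", "scaling", cl_of(tot, "direct"))
  add("direct_cl_abs", "scaling", cl_of(tot, "direct") * hum$weight_kg)
  add("tang_cl_per_kg", "scaling", cl_of(tot, "tang"))
  add("tang_cl_abs", "scaling", cl_of(tot, "tang") * hum$weight_kg)
  add("one_rat_cl_per_kg", "scaling", cl_of(tot, "one_species_rat"))
  add("one_rat_cl_abs", "scaling", cl_of(tot, "one_species_rat") * hum$weight_kg)
  add("one_monkey_cl_per_kg", "scaling", cl_of(tot, "one_species_monkey"))
  add("one_monkey_cl_abs", "scaling",
      cl_of(tot, "one_species_monkey") * hum$weight_kg)
  add("gm_cl_total", "scaling", geometric_mean(tot$cl_per_kg))

  # -- scaling, unbound basis -------------------------------------------
  unb <- human_cl_predictions(sp, w_target = hum$weight_kg,
                              basis = "unbound", fu_target = hum$fu)
  add("unbound_direct_cl_per_kg", "scaling", cl_of(unb, "direct"))
  add("unbound_tang_cl_per_kg", "scaling", cl_of(unb, "tang"))
  add("unbound_one_rat_cl_per_kg", "scaling", cl_of(unb, "one_species_rat"))
  add("unbound_one_monkey_cl_per_kg", "scaling",
      cl_of(unb, "one_species_monkey"))
  add("gm_cl_unbound", "scaling", geometric_mean(unb$cl_per_kg))

  # -- dose translation --------------------------------------------------
  w_rat <- sp$weight_kg[sp$species == "rat"]
  w_mouse <- sp$weight_kg[sp$species == "mouse"]
  hed <- hed_from_noael(ref_value("noael_rat", ref),
                        bsa_correction_factor(hum$weight_kg, w_rat))
  pad <- pad_to_human(ref_value("pad_mouse", ref), hum$weight_kg, w_mouse)
  add("hed", "dose", hed)
  add("pad_human", "dose", pad)

  # -- exposure tables ---------------------------------------------------
  auc_hed <- function(cl) hed_ref * auc_per_dose_from_cl(cl)
  hed_ref <- ref_value("hed", ref)  # exposures are published at the rounded HED
  add("gm_auc_per_dose_total", "exposure",
      auc_per_dose_from_cl(geometric_mean(tot$cl_per_kg)))
  add("auc_hed_direct_total", "exposure", auc_hed(cl_of(tot, "direct")))
  add("auc_hed_tang_total", "exposure", auc_hed(cl_of(tot, "tang")))
  add("auc_hed_one_rat_total", "exposure", auc_hed(cl_of(tot, "one_species_rat")))
  add("auc_hed_one_monkey_total", "exposure",
      auc_hed(cl_of(tot, "one_species_monkey")))
  add("gm_auc_hed_total", "exposure", auc_hed(geometric_mean(tot$cl_per_kg)))
  add("gm_auc_noael_total", "exposure",
      ref_value("noael_rat", ref) *
        auc_per_dose_from_cl(geometric_mean(tot$cl_per_kg)))
  add("auc_hed_direct_unbound", "exposure", auc_hed(cl_of(unb, "direct")))
  add("auc_hed_tang_unbound", "exposure", auc_hed(cl_of(unb, "tang")))
  add("auc_hed_one_rat_unbound", "exposure",
      auc_hed(cl_of(unb, "one_species_rat")))
  add("auc_hed_one_monkey_unbound", "exposure",
      auc_hed(cl_of(unb, "one_species_monkey")))
  add("gm_auc_hed_unbound", "exposure", auc_hed(geometric_mean(unb$cl_per_kg)))
  add("range_hed_total_min", "exposure", min(auc_hed(tot$cl_per_kg)))
  add("range_hed_total_max", "exposure", max(auc_hed(tot$cl_per_kg)))
  add("range_hed_unbound_min", "exposure", min(auc_hed(unb$cl_per_kg)))
  add("range_hed_unbound_max", "exposure", max(auc_hed(unb$cl_per_kg)))

  # -- protein binding ---------------------------------------------------
  bind <- lna_binding()
  for (spc in unique(bind$species)) {
    b <- bind[bind$species == spc, ]
    mean_ppb <- mean(b$ppb_mean)
    add(paste0("mean_ppb_", spc), "binding", round_half_up(mean_ppb, 2))
    add(paste0("fu_", spc), "binding", round_half_up((100 - mean_ppb) / 100, 4))
  }

  # -- NCA identities on the individual rat rows ------------------------
  rat <- lna_rat_nca()
  f1 <- rat[rat$sex == "F" & rat$subject == 1, ]
  id <- data.frame(
    target = c("f1_auc_per_dose", "f1_cl", "f1_vz", "f1_t_half"),
    group = "nca",
    computed = c(f1$auc_0_inf / f1$dose_mg_per_kg,
                 clearance(f1$dose_mg_per_kg, f1$auc_0_inf),
                 terminal_volume(clearance(f1$dose_mg_per_kg, f1$auc_0_inf),
                                 f1$lambda_z),
                 half_life(f1$lambda_z)),
    reference = c(f1$auc_per_dose, f1$cl, f1$vz, f1$t_half),
    printed_decimals = c(0, 1, 0, 2), stringsAsFactors = FALSE)
  rows <- c(rows, split(id, seq_len(nrow(id))))

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report$rel_dev <- (report$computed - report$reference) / report$reference
  report$tolerance <- unname(tolerances[report$group])
  half_ulp <- 0.5 * 10^(-report$printed_decimals)
  report$pass <- abs(report$rel_dev) <= report$tolerance |
    abs(report$computed - report$reference) <= half_ulp
  report$printed_decimals <- NULL
  attr(report, "overall_pass") <- all(report$pass)
  class(report) <- c("reproduction_report", class(report))
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 6)
  df$rel_dev <- sprintf("%+.3f%%", 100 * df$rel_dev)
  print(df, row.names = FALSE)
  cat(sprintf("\n%d/%d targets pass; overall: %s\n", sum(x$pass), nrow(x),
              if (attr(x, "overall_pass")) "PASS" else "FAIL"))
  invisible(x)
}

#' Run the full preclinical-to-human pipeline
#'
#' Chains the package stages: per-subject NCA on the supplied profiles with
#' group summaries; ultrafiltration binding summary; species table assembly;
#' total- and unbound-basis allometric scaling with exposure tables; and
#' dose translation (HED, human PAD, MRSD).
#'
#' @param profiles list of [conc_time_profile()] objects (or a CSV path for
#'   [read_profiles()]); may be `NULL` to skip the NCA stage and use the
#'   clearances already in `species`.
#' @param binding_measurements optional data frame in the
#'   [binding_summary()] input format; when supplied, its per-species fu
#'   replaces the fu column of `species`.
#' @param species a [species_pk()] table (default the bundled reference
#'   table).
#' @param noael animal NOAEL, mg/kg/day.
#' @param noael_species species whose weight converts the NOAEL (default
#'   rat).
#' @param pad efficacious animal dose, mg/kg (optional).
#' @param pad_species species for the PAD conversion (default mouse).
#' @param safety_factor MRSD divisor (default 10).
#' @param auc_method passed to [run_nca()].
#' @param doses candidate human doses for the exposure tables; default
#'   `c(HED, PAD_human, NOAEL)`.
#' @return list with stages `nca`, `nca_summary`, `binding`, `species`,
#'   `prediction_tables`, `dose_translation`.
#' @export
run_pipeline <- function(profiles = NULL, binding_measurements = NULL,
                         species = lna_species_defaults(),
                         noael = 5, noael_species = "rat",
                         pad = 25, pad_species = "mouse",
                         safety_factor = 10,
                         auc_method = "linuplogdown", doses = NULL) {
  if (is.character(profiles)) profiles <- read_profiles(profiles)
  nca <- nca_sum <- NULL
  if (!is.null(profiles)) {
    nca <- do.call(rbind, lapply(profiles, run_nca, auc_method = auc_method))
    nca_sum <- summarize_nca(nca, grouping = "sex")
    # fold per-species mean CL back into the species table
    for (spc in unique(nca$species)) {
      if (spc %in% species$species) {
        species$cl_ml_min_kg[species$species == spc] <-
          mean(nca$cl[nca$species == spc])
      }
    }
  }
  binding <- NULL
  if (!is.null(binding_measurements)) {
    binding <- binding_summary(binding_measurements)
    i <- match(species$species, binding$species)
    species$fu <- ifelse(is.na(i), species$fu, binding$mean_fu[i])
  }
  species$clu_ml_min_kg <- unbound_cl(species$cl_ml_min_kg, species$fu)

  hum <- species[species$species == "human", ]
  if (nrow(hum) != 1L) stop("species table needs a single 'human' row")
  w_a <- species$weight_kg[species$species == noael_species]
  if (length(w_a) != 1L) stop("unknown NOAEL species: ", noael_species)
  hed <- hed_from_noael(noael, bsa_correction_factor(hum$weight_kg, w_a))
  dose_tr <- list(hed = hed, noael = noael)
  if (!is.null(pad)) {
    w_p <- species$weight_kg[species$species == pad_species]
    if (length(w_p) != 1L) stop("unknown PAD species: ", pad_species)
    dose_tr$pad_human <- pad_to_human(pad, hum$weight_kg, w_p)
    dose_tr <- c(dose_tr, mrsd(hed, safety_factor, dose_tr$pad_human))
  } else {
    dose_tr <- c(dose_tr, mrsd(hed, safety_factor))
  }
  if (is.null(doses)) {
    doses <- unique(c(round_half_up(hed, 2),
                      if (!is.null(dose_tr$pad_human))
                        round_half_up(dose_tr$pad_human, 2),
                      noael))
  }
  bases <- if (all(!is.na(species$fu[species$include_in_scaling])) &&
               !is.na(hum$fu)) c("total", "unbound") else "total"
  tables <- build_prediction_tables(species, doses = doses, bases = bases)
  list(nca = nca, nca_summary = nca_sum, binding = binding,
       species = species, prediction_tables = tables,
       dose_translation = dose_tr)
}
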