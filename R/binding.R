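#' Apparent percent unbound from an ultrafiltration pair
#'
#' Ratio of the analyte concentration in the filtered extract to the
#' non-filtered (100%-extraction) reference, times 100. The complement is the
#' percent bound to plasma protein.
#'
#' @param filtrate concentration in the filtrate, ng/mL.
#' @param reference concentration in the non-filtered reference, ng/mL (> 0).
#' @return percent unbound (may be vectorised).
#' @export
#' @examples
#' percent_unbound(1.45, 100)   # 1.45 -> 98.55% bound
percent_unbound <- function(filtrate, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("invalid reference: must be > 0")
  }
  stopifnot(all(filtrate >= 0))
  100 * filtrate / reference
}

#' Non-specific binding from the protein-free (buffer) arm
#'
#' The same filtrate/reference ratio measured in protein-free buffer gives
#' the device recovery; its complement is the non-specific binding (analyte
#' lost to the device surface).
#'
#' @param filtrate_pbs filtrate concentration in the buffer arm, ng/mL.
#' @param reference_pbs non-filtered buffer reference, ng/mL (> 0).
#' @return list with `recovery` (fraction) and `nsb_fraction` (1 - recovery).
#' @export
nonspecific_binding <- function(filtrate_pbs, reference_pbs) {
  rec <- percent_unbound(filtrate_pbs, reference_pbs) / 100
  list(recovery = rec, nsb_fraction = 1 - rec)
}

#' Recovery-corrected percent unbound
#'
#' Divides the apparent unbound percentage by the device recovery measured in
#' protein-free buffer at the matched concentration, compensating for
#' non-specific loss of free analyte to the device. Values exceeding 100% are
#' capped with a warning.
#'
#' @param apparent_unbound apparent percent unbound (%).
#' @param recovery device recovery as a fraction in (0, 1].
#' @return corrected percent unbound (%).
#' @export
#' @examples
#' corrected_unbound(0.725, 0.50)  # 1.45
corrected_unbound <- function(apparent_unbound, recovery) {
  if (any(!is.finite(recovery)) || any(recovery <= 0)) {
    stop("invalid recovery: must be > 0")
  }
  out <- apparent_unbound / recovery
  if (any(out > 100)) {
    warning("corrected unbound exceeds 100%; capped")
    out <- pmin(out, 100)
  }
  out
}

#' Species-level plasma protein binding summary
#'
#' Aggregates replicate ultrafiltration measurements into the reporting
#' quantities: per-concentration mean and SD of plasma protein binding (PPB),
#' the unweighted mean PPB over the tested concentrations, and the mean
#' unbound fraction `fu = (100 - mean PPB) / 100`.
#'
#' Measurements from the buffer (`matrix == "pbs"`) arm, when present, supply
#' the concentration-matched recovery used to correct the plasma-arm values;
#' without a buffer arm recovery 1 is assumed.
#'
#' @param measurements data frame with columns `species`, `test_conc_uM`,
#'   `replicate`, `conc_filtrate_ng_per_ml`, `conc_reference_ng_per_ml`,
#'   `matrix` (`"plasma"` or `"pbs"`).
#' @param digits_ppb,digits_fu decimals for the rounded reporting columns
#'   (round-half-up); unrounded values are always kept.
#' @return a `binding_result` data frame, one row per species, with
#'   per-concentration PPB mean/SD columns, `mean_ppb`, `mean_fu`, and the
#'   rounded display columns `mean_ppb_rounded`, `mean_fu_rounded`.
#' @export
binding_summary <- function(measurements, digits_ppb = 2, digits_fu = 4) {
  need <- c("species", "test_conc_uM", "replicate",
            "conc_filtrate_ng_per_ml", "conc_reference_ng_per_ml", "matrix")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  plasma <- measurements[measurements$matrix == "plasma", , drop = FALSE]
  pbs <- measurements[measurements$matrix == "pbs", , drop = FALSE]
  if (nrow(plasma) == 0L) stop("no plasma measurements")
  # concentration-matched recovery from the buffer arm (species-independent)
  recovery_at <- function(conc) {
    m <- pbs[pbs$test_conc_uM == conc, , drop = FALSE]
    if (nrow(m) == 0L) return(1)
    mean(m$conc_filtrate_ng_per_ml / m$conc_reference_ng_per_ml)
  }
  out <- do.call(rbind, lapply(split(plasma, plasma$species), function(sp) {
    concs <- sort(unique(sp$test_conc_uM))
    per_conc <- lapply(concs, function(cc) {
      m <- sp[sp$test_conc_uM == cc, , drop = FALSE]
      app <- percent_unbound(m$conc_filtrate_ng_per_ml,
                             m$conc_reference_ng_per_ml)
      corr <- corrected_unbound(app, recovery_at(cc))
      ppb <- 100 - corr
      c(mean = mean(ppb), sd = sd_or_zero(ppb), n = nrow(m))
    })
    mean_ppb <- mean(vapply(per_conc, `[[`, numeric(1), "mean"))
    row <- data.frame(species = sp$species[1], stringsAsFactors = FALSE)
    for (i in seq_along(concs)) {
      row[[paste0("ppb_mean_", concs[i], "uM")]] <- per_conc[[i]][["mean"]]
      row[[paste0("ppb_sd_", concs[i], "uM")]] <- per_conc[[i]][["sd"]]
    }
    row$n_concentrations <- length(concs)
    row$mean_ppb <- mean_ppb
    row$mean_fu <- (100 - mean_ppb) / 100
    row$mean_ppb_rounded <- round_half_up(mean_ppb, digits_ppb)
    row$mean_fu_rounded <- round_half_up((100 - mean_ppb) / 100, digits_fu)
    row
  }))
  if (any(out$n_concentrations < 2L)) {
    warning("summary computed on fewer than 2 concentration levels for: ",
            paste(out$species[out$n_concentrations < 2L], collapse = ", "))
  }
  rownames(out) <- NULL
  class(out) <- c("binding_result", class(out))
  out
}

#' Assay control check for a highly bound reference compound
#'
#' Reports mean and SD of the control's percent bound and passes when the
#' mean falls inside the expected window (default 85-95%, suitable for a
#' propranolol-type highly bound control).
#'
#' @param control_bound replicate percent-bound values for the control.
#' @param window numeric length-2 expected mean window (%).
#' @return list with `mean`, `sd`, `n`, `sd_defined`, `pass`, `window`.
#' @export
control_check <- function(control_bound, window = c(85, 95)) {
  stopifnot(length(control_bound) >= 1L, length(window) == 2L)
  m <- mean(control_bound)
  list(mean = m, sd = sd_or_zero(control_bound), n = length(control_bound),
       sd_defined = length(control_bound) > 1L,
       pass = m >= window[1] && m <= window[2], window = window)
}
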