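#' Specification for simulating i.v.-bolus concentration-time data
#'
#' Defines a multi-exponential disposition curve
#' `C(t) = sum_i A_i * exp(-alpha_i * t)` with lognormal measurement noise,
#' a lower limit of quantification, and a serial or sparse sampling design.
#' The analytic ground truth (terminal rate, C0, AUC0-inf, CL, Vz) is
#' available via [ground_truth()].
#'
#' @param coefficients macro-constant coefficients `A_i`, ng/mL (positive).
#' @param rates exponential rates `alpha_i`, 1/h (positive, distinct).
#' @param dose dose in mg/kg.
#' @param sampling_times sampling grid, h.
#' @param cv_percent lognormal noise coefficient of variation on the natural
#'   scale (0 = noise-free).
#' @param llq lower limit of quantification, ng/mL; simulated values below
#'   it are flagged BLQ (never deleted).
#' @param design `"serial"` (every subject samples the full grid) or
#'   `"sparse"` (disjoint subject subsets per time, interleaved).
#' @param species,sex labels stamped on the simulated profiles.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(coefficients, rates, dose, sampling_times,
                            cv_percent = 0, llq = 0,
                            design = c("serial", "sparse"),
                            species = "synthetic", sex = "") {
  design <- match.arg(design)
  stopifnot(length(coefficients) == length(rates),
            all(coefficients > 0), all(rates > 0),
            cv_percent >= 0, llq >= 0, dose > 0)
  if (anyDuplicated(rates)) stop("rates must be distinct")
  if (length(sampling_times) == 0L) stop("no design: empty sampling grid")
  structure(list(coefficients = coefficients, rates = rates, dose = dose,
                 sampling_times = sort(sampling_times),
                 cv_percent = cv_percent, llq = llq, design = design,
                 species = species, sex = sex),
            class = "simulation_spec")
}

#' Evaluate the noise-free disposition curve of a spec
#'
#' @param spec a [simulation_spec()].
#' @param time times (h) at which to evaluate.
#' @return concentrations, ng/mL.
#' @export
disposition_curve <- function(spec, time) {
  rowSums(vapply(seq_along(spec$rates),
                 function(i) spec$coefficients[i] * exp(-spec$rates[i] * time),
                 numeric(length(time))))
}

#' Analytic ground truth of a simulation spec
#'
#' Closed forms: `lambda_z` is the smallest rate, `C0 = sum A_i`,
#' `AUC0-inf = sum A_i / alpha_i`, `CL = dose * 1e6 / AUC / 60`,
#' `Vz = CL * 60 / lambda_z`. Self-consistency `CL * 60 / Vz = lambda_z`
#' holds by construction.
#'
#' @param spec a [simulation_spec()].
#' @return list with `lambda_z`, `t_half`, `c0`, `auc_0_inf`, `cl`, `vz`.
#' @export
ground_truth <- function(spec) {
  lz <- min(spec$rates)
  auc <- sum(spec$coefficients / spec$rates)
  cl <- spec$dose * 1e6 / auc / 60
  list(lambda_z = lz, t_half = log(2) / lz, c0 = sum(spec$coefficients),
       auc_0_inf = auc, cl = cl, vz = cl * 60 / lz)
}

#' Simulate concentration-time profiles with known ground truth
#'
#' Draws `conc = C(t) * exp(rnorm(0, sigma))` with sigma chosen so the
#' multiplicative noise has the requested CV (`sigma^2 = log(1 + CV^2)`,
#' PK-conventional lognormal error). Values below the LLQ are flagged BLQ
#' but retained; under the serial design every subject samples the whole
#' grid.
#'
#' Under the sparse design, subjects are partitioned round-robin into
#' `n_groups` cohorts and each cohort samples an interleaved subset of the
#' time grid (cohort g takes times g, g + n_groups, ...), so every nominal
#' time is covered by one disjoint cohort -- the usual rodent sparse layout.
#'
#' @param spec a [simulation_spec()].
#' @param n_subjects number of subjects.
#' @param seed integer seed; same seed gives bit-identical output.
#' @param n_groups number of sparse cohorts (default `min(3, n_subjects)`;
#'   ignored for the serial design).
#' @return list with `profiles` (list of [conc_time_profile()]) and `truth`
#'   ([ground_truth()] of the spec).
#' @export
simulate_profiles <- function(spec, n_subjects = 1, seed = 1,
                              n_groups = min(3L, n_subjects)) {
  stopifnot(inherits(spec, "simulation_spec"), n_subjects >= 1)
  set.seed(seed)
  sigma <- sqrt(log(1 + (spec$cv_percent / 100)^2))
  grid <- spec$sampling_times
  assign_times <- if (spec$design == "sparse" && n_subjects > 1) {
    time_group <- rep_len(seq_len(n_groups), length(grid))
    subj_group <- rep_len(seq_len(n_groups), n_subjects)
    lapply(seq_len(n_subjects), function(s) grid[time_group == subj_group[s]])
  } else {
    rep(list(grid), n_subjects)
  }
  profiles <- lapply(seq_len(n_subjects), function(s) {
    tt <- assign_times[[s]]
    if (length(tt) == 0L) return(NULL)
    mu <- disposition_curve(spec, tt)
    conc <- mu * exp(stats::rnorm(length(tt), 0, sigma))
    conc_time_profile(sprintf("sim%02d", s), spec$species, spec$sex,
                      spec$dose, tt, conc, blq = conc < spec$llq)
  })
  list(profiles = Filter(Negate(is.null), profiles), truth = ground_truth(spec))
}

#' Construct a spec consistent with observed NCA parameters
#'
#' Builds a bi-exponential curve with a fast distribution phase (rate
#' `alpha1`) whose terminal rate, C0 and AUC0-inf match the given values
#' exactly: the terminal coefficient is
#' `A2 = (AUC - C0/alpha1) / (1/lambda_z - 1/alpha1)` and `A1 = C0 - A2`.
#' Feasibility requires `alpha1 > C0 / AUC` (so that `A2 > 0`).
#'
#' @param lambda_z terminal rate, 1/h.
#' @param c0 concentration at time zero, ng/mL.
#' @param auc_0_inf total AUC, h.ng/mL.
#' @param dose dose, mg/kg.
#' @param alpha1 distribution rate, 1/h (default 3).
#' @param sampling_times sampling grid (default the rich serial design
#'   0.083-24 h).
#' @param ... further arguments to [simulation_spec()].
#' @return a [simulation_spec()].
#' @export
spec_from_nca <- function(lambda_z, c0, auc_0_inf, dose, alpha1 = 3,
                          sampling_times = rich_serial_design(), ...) {
  stopifnot(lambda_z > 0, c0 > 0, auc_0_inf > 0, alpha1 > lambda_z)
  if (alpha1 <= c0 / auc_0_inf) {
    stop("infeasible: need alpha1 > C0 / AUC for a positive terminal coefficient")
  }
  a2 <- (auc_0_inf - c0 / alpha1) / (1 / lambda_z - 1 / alpha1)
  simulation_spec(coefficients = c(c0 - a2, a2), rates = c(alpha1, lambda_z),
                  dose = dose, sampling_times = sampling_times, ...)
}

#' Default sampling designs
#'
#' `rich_serial_design()`: 14 points, 5 min to 24 h, the dense serial grid
#' used for rat-like simulations. `sparse_design()`: 9 points, the reduced
#' grid typical of sparse rodent sampling. `late_start_design()`: first
#' sample at 1.5 h, emulating a mouse design that misses the distribution
#' phase.
#'
#' @return numeric vector of times in hours.
#' @export
rich_serial_design <- function() {
  c(0.083, 0.167, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)
}

#' @rdname rich_serial_design
#' @export
sparse_design <- function() c(0.083, 0.25, 0.5, 1, 2, 4, 8, 12, 24)

#' @rdname rich_serial_design
#' @export
late_start_design <- function() c(1.5, 3, 6, 8, 12, 24)

#' Simulate an ultrafiltration binding assay with known truth
#'
#' Two arms per concentration: in the plasma arm the filtrate is
#' `reference * fu_true * (1 - nsb_true)`, in the protein-free buffer arm
#' `reference * (1 - nsb_true)`, each multiplied by lognormal noise. Feeding
#' the result through [binding_summary()] recovers `fu_true` exactly at
#' CV 0.
#'
#' @param fu_true true unbound fraction, (0, 1].
#' @param nsb_true named or unnamed vector of true non-specific-binding
#'   fractions, one per test concentration, each in [0, 1).
#' @param test_conc_uM test concentrations (default `c(1, 10)`).
#' @param cv_percent lognormal noise CV.
#' @param n_replicates replicates per arm and concentration (default 3).
#' @param reference reference concentration, ng/mL (scale is arbitrary).
#' @param species label stamped on the measurements.
#' @param seed integer seed.
#' @return data frame in the [binding_summary()] input format.
#' @export
simulate_binding_assay <- function(fu_true, nsb_true,
                                   test_conc_uM = c(1, 10), cv_percent = 0,
                                   n_replicates = 3, reference = 1000,
                                   species = "synthetic", seed = 1) {
  stopifnot(fu_true > 0, fu_true <= 1,
            all(nsb_true >= 0), all(nsb_true < 1),
            length(nsb_true) == length(test_conc_uM))
  set.seed(seed)
  sigma <- sqrt(log(1 + (cv_percent / 100)^2))
  noise <- function(n) exp(stats::rnorm(n, 0, sigma))
  rows <- list()
  for (i in seq_along(test_conc_uM)) {
    keep <- 1 - nsb_true[i]
    for (matrix in c("plasma", "pbs")) {
      frac <- if (matrix == "plasma") fu_true * keep else keep
      rows[[length(rows) + 1L]] <- data.frame(
        species = species, test_conc_uM = test_conc_uM[i],
        replicate = seq_len(n_replicates),
        conc_filtrate_ng_per_ml = reference * frac * noise(n_replicates),
        conc_reference_ng_per_ml = reference,
        matrix = matrix, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate species clearances from an exact power law
#'
#' `CL/kg = a * W^b` per species, optionally with lognormal jitter; used for
#' allometric-fit recovery tests.
#'
#' @param a intercept, mL/min/kg at 1 kg.
#' @param b exponent.
#' @param weights named vector of body weights, kg.
#' @param fu optional unbound fractions per species.
#' @param cv_percent lognormal jitter CV (0 = exact).
#' @param seed integer seed.
#' @return a [species_pk()] table.
#' @export
simulate_species_power_law <- function(a, b, weights, fu = NA_real_,
                                       cv_percent = 0, seed = 1) {
  stopifnot(a > 0, all(weights > 0))
  set.seed(seed)
  sigma <- sqrt(log(1 + (cv_percent / 100)^2))
  cl <- a * weights^b * exp(stats::rnorm(length(weights), 0, sigma))
  nm <- if (is.null(names(weights))) paste0("sp", seq_along(weights))
        else names(weights)
  species_pk(nm, unname(weights), unname(cl), fu = fu)
}
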