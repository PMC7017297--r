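#' Terminal slope (lambda_z) by log-linear regression
#'
#' Fits `ln C = intercept - lambda_z * t` over candidate terminal windows and
#' returns the best fit. Candidate windows are every contiguous run of at
#' least `min_points` usable samples that starts after Tmax (the time of
#' maximal observed concentration; for an i.v. bolus usually the first
#' sample) and ends at the last usable sample. The window maximising the
#' adjusted coefficient of determination wins; ties go to the window with
#' more points. This mirrors the best-fit convention of commercial
#' non-compartmental software.
#'
#' BLQ handling: BLQ samples before Tmax are dropped; from the first BLQ
#' after Tmax onward all samples are excluded. Nothing is imputed.
#'
#' @param profile a [conc_time_profile()].
#' @param min_points minimum samples in a window (default 3).
#' @return an object of class `terminal_fit`: list with `lambda_z` (1/h),
#'   `intercept_log_conc` (ln ng/mL), `n_points`, `fit_quality` (adjusted
#'   R-squared), `window` (first and last time, h).
#' @export
#' @examples
#' t <- c(1, 2, 4, 8)
#' p <- conc_time_profile("s1", dose = 12.5, time = t,
#'                        conc = 1000 * exp(-0.174 * t))
#' fit_lambda_z(p)$lambda_z   # 0.174
fit_lambda_z <- function(profile, min_points = 3) {
  stopifnot(inherits(profile, "conc_time_profile"), min_points >= 3)
  obs <- usable_samples(profile)
  i_tmax <- if (nrow(obs)) which.max(obs$conc) else 0L
  term <- obs[seq_len(nrow(obs)) >= i_tmax, , drop = FALSE]
  # windows may include Tmax itself only when it is the first sample
  if (i_tmax > 1L) term <- term[-1L, , drop = FALSE]
  n <- nrow(term)
  if (n < min_points) stop("insufficient terminal data: ", n,
                           " usable samples after Tmax, need ", min_points)
  best <- NULL
  for (start in 1:(n - min_points + 1L)) {
    idx <- start:n
    fit <- stats::lm(log(conc) ~ time, data = term[idx, ])
    slope <- unname(stats::coef(fit)[2])
    if (slope >= 0) next
    k <- length(idx)
    y <- log(term$conc[idx])
    tss <- sum((y - mean(y))^2)
    if (tss <= 0) next  # flat log-concentrations carry no decay signal
    r2 <- 1 - sum(stats::residuals(fit)^2) / tss
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$fit_quality + 1e-12 ||
        (abs(adj - best$fit_quality) <= 1e-12 && k > best$n_points)) {
      best <- list(lambda_z = -slope,
                   intercept_log_conc = unname(stats::coef(fit)[1]),
                   n_points = k, fit_quality = adj,
                   window = c(term$time[idx[1]], term$time[idx[k]]))
    }
  }
  if (is.null(best)) stop("no terminal decay: non-negative slope in every candidate window")
  structure(best, class = "terminal_fit")
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf("<terminal_fit> lambda_z = %.4g 1/h (%d points, %.2f-%.2f h, adj R2 = %.4f)\n",
              x$lambda_z, x$n_points, x$window[1], x$window[2], x$fit_quality))
  invisible(x)
}

#' Terminal half-life
#'
#' `t1/2 = ln(2) / lambda_z`, with ln 2 at full precision.
#'
#' @param fit a `terminal_fit`, or a bare positive rate (1/h).
#' @return half-life in hours.
#' @export
half_life <- function(fit) {
  lz <- if (inherits(fit, "terminal_fit")) fit$lambda_z else fit
  if (!is.numeric(lz) || any(lz <= 0)) stop("invalid rate: lambda_z must be > 0")
  log(2) / lz
}

#' Back-extrapolated concentration at time zero
#'
#' i.v.-bolus convention: log-linear extrapolation through the first two
#' positive-concentration samples back to t = 0. If the first two points are
#' non-decreasing (no initial decay to extrapolate) or only one positive
#' sample exists, falls back to the first observed concentration with a
#' warning.
#'
#' @param profile a [conc_time_profile()].
#' @return C0 in ng/mL.
#' @export
#' @examples
#' p <- conc_time_profile("s1", dose = 1, time = c(1, 2), conc = c(800, 640))
#' back_extrapolate_c0(p)  # 1000 = 800^2 / 640
back_extrapolate_c0 <- function(profile) {
  obs <- profile$samples[!profile$samples$blq, , drop = FALSE]
  if (nrow(obs) == 0L) stop("empty profile: no positive samples")
  if (obs$time[1] == 0) return(obs$conc[1])
  if (nrow(obs) == 1L || obs$conc[2] >= obs$conc[1]) {
    warning("degenerate C0: falling back to first observed concentration")
    return(obs$conc[1])
  }
  slope <- log(obs$conc[1] / obs$conc[2]) / (obs$time[2] - obs$time[1])
  obs$conc[1] * exp(slope * obs$time[1])
}

#' Area under the curve to the last sample
#'
#' Trapezoidal AUC0-t. With `method = "linuplogdown"` (default) the log
#' trapezoid `dt * (C1 - C2) / ln(C1/C2)` is used on strictly decreasing
#' intervals and the linear trapezoid elsewhere; `method = "linear"` uses the
#' linear rule throughout. When the profile has no sample at t = 0, `c0` (by
#' default the back-extrapolated C0) is prepended.
#'
#' @param profile a [conc_time_profile()].
#' @param method `"linuplogdown"` or `"linear"`.
#' @param c0 value to prepend at t = 0 when absent; `NULL` (default) uses
#'   [back_extrapolate_c0()]; `NA` disables prepending.
#' @return AUC0-t in h.ng/mL.
#' @export
auc_0_t <- function(profile, method = c("linuplogdown", "linear"), c0 = NULL) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stop("unknown AUC method"))
  obs <- usable_samples(profile)
  if (nrow(obs) < 2L) stop("need at least 2 usable samples for AUC")
  t <- obs$time; C <- obs$conc
  if (t[1] > 0) {
    if (is.null(c0)) c0 <- back_extrapolate_c0(profile)
    if (!is.na(c0)) { t <- c(0, t); C <- c(c0, C) }
  }
  s <- 0
  for (i in 2:length(t)) {
    dt <- t[i] - t[i - 1]
    if (method == "linuplogdown" && C[i] < C[i - 1] && C[i] > 0) {
      s <- s + dt * (C[i - 1] - C[i]) / log(C[i - 1] / C[i])
    } else {
      s <- s + dt * (C[i - 1] + C[i]) / 2
    }
  }
  s
}

#' Extrapolate AUC to infinity
#'
#' `AUC0-inf = AUC0-t + Clast / lambda_z`; also reports the extrapolated
#' percentage `100 * tail / AUC0-inf`.
#'
#' @param auc_0_t AUC to the last quantifiable sample, h.ng/mL.
#' @param c_last last quantifiable concentration, ng/mL.
#' @param fit a `terminal_fit` (or bare positive rate, 1/h).
#' @return list with `auc_0_inf` and `extrapolated_pct`.
#' @export
auc_0_inf <- function(auc_0_t, c_last, fit) {
  lz <- if (inherits(fit, "terminal_fit")) fit$lambda_z else fit
  if (!is.numeric(lz) || lz <= 0) stop("cannot extrapolate: lambda_z must be > 0")
  stopifnot(auc_0_t > 0, c_last >= 0)
  tail <- c_last / lz
  total <- auc_0_t + tail
  list(auc_0_inf = total, extrapolated_pct = 100 * tail / total)
}

#' Systemic clearance from dose and AUC
#'
#' `CL = Dose / AUC0-inf` with the unit chain mg/kg -> 1e6 ng/kg ->
#' divide by h.ng/mL -> mL/h/kg -> / 60 -> mL/min/kg.
#'
#' @param dose dose in mg/kg.
#' @param auc_0_inf AUC0-inf in h.ng/mL.
#' @return clearance in mL/min/kg.
#' @export
#' @examples
#' clearance(12.5, 23980)  # 8.69 mL/min/kg
clearance <- function(dose, auc_0_inf) {
  if (!is.numeric(dose) || !is.numeric(auc_0_inf) ||
      any(dose <= 0) || any(auc_0_inf <= 0)) stop("invalid: dose and AUC must be > 0")
  dose * 1e6 / auc_0_inf / 60
}

#' Terminal volume of distribution
#'
#' `Vz = CL / lambda_z` (the 60 restores mL/h/kg from mL/min/kg).
#'
#' @param cl clearance in mL/min/kg.
#' @param fit a `terminal_fit` (or bare positive rate, 1/h).
#' @return Vz in mL/kg.
#' @export
terminal_volume <- function(cl, fit) {
  lz <- if (inherits(fit, "terminal_fit")) fit$lambda_z else fit
  if (!is.numeric(lz) || lz <= 0) stop("invalid rate: lambda_z must be > 0")
  stopifnot(cl > 0)
  cl * 60 / lz
}

#' Full non-compartmental analysis of one profile
#'
#' Runs the complete i.v.-bolus NCA chain: terminal fit, half-life,
#' back-extrapolated C0, AUC0-t, AUC0-inf with extrapolated fraction,
#' clearance, terminal volume, and the dose-normalised ratios C0/Dose and
#' AUC0-inf/Dose.
#'
#' @param profile a [conc_time_profile()].
#' @param auc_method passed to [auc_0_t()].
#' @param min_points passed to [fit_lambda_z()].
#' @return an `nca_result`: one-row data frame with columns `subject_id`,
#'   `species`, `sex`, `dose`, `lambda_z`, `t_half`, `c0`, `auc_0_t`,
#'   `auc_0_inf`, `auc_extrapolated_pct`, `cl`, `vz`, `c0_per_dose`,
#'   `auc_per_dose`.
#' @export
run_nca <- function(profile, auc_method = "linuplogdown", min_points = 3) {
  fit <- fit_lambda_z(profile, min_points = min_points)
  c0 <- back_extrapolate_c0(profile)
  a0t <- auc_0_t(profile, method = auc_method, c0 = c0)
  obs <- usable_samples(profile)
  ainf <- auc_0_inf(a0t, obs$conc[nrow(obs)], fit)
  cl <- clearance(profile$dose, ainf$auc_0_inf)
  res <- data.frame(
    subject_id = profile$subject_id, species = profile$species,
    sex = profile$sex, dose = profile$dose,
    lambda_z = fit$lambda_z, t_half = half_life(fit), c0 = c0,
    auc_0_t = a0t, auc_0_inf = ainf$auc_0_inf,
    auc_extrapolated_pct = ainf$extrapolated_pct,
    cl = cl, vz = terminal_volume(cl, fit),
    c0_per_dose = c0 / profile$dose,
    auc_per_dose = ainf$auc_0_inf / profile$dose,
    stringsAsFactors = FALSE)
  class(res) <- c("nca_result", class(res))
  res
}

#' Group summary of NCA results
#'
#' Arithmetic mean, sample SD (n-1) and CV% per parameter, computed per
#' subject then averaged (dose-normalised parameters are averaged as
#' per-subject ratios). Groups of one report SD 0 with `sd_defined = FALSE`.
#'
#' @param results a data frame of stacked `nca_result` rows (e.g.
#'   `do.call(rbind, lapply(profiles, run_nca))`).
#' @param grouping `"sex"` for per-sex plus pooled summaries, `"pooled"` for
#'   a single all-subject summary.
#' @return an `nca_summary` data frame: one row per group x statistic
#'   (`mean`, `sd`, `cv_pct`) with a `sd_defined` flag.
#' @export
summarize_nca <- function(results, grouping = c("sex", "pooled")) {
  grouping <- match.arg(grouping)
  if (nrow(results) == 0L) stop("no data")
  params <- c("lambda_z", "t_half", "c0", "auc_0_inf",
              "auc_extrapolated_pct", "cl", "vz", "c0_per_dose",
              "auc_per_dose")
  params <- intersect(params, names(results))
  groups <- if (grouping == "sex") {
    g <- split(results, results$sex)
    if (length(g) > 1L) g <- c(g, list(pooled = results))
    g
  } else list(pooled = results)
  out <- do.call(rbind, lapply(names(groups), function(lbl) {
    d <- groups[[lbl]]
    m <- vapply(params, function(p) mean(d[[p]]), numeric(1))
    s <- vapply(params, function(p) sd_or_zero(d[[p]]), numeric(1))
    stat <- data.frame(group = lbl, n = nrow(d),
                       statistic = c("mean", "sd", "cv_pct"),
                       sd_defined = nrow(d) > 1L,
                       stringsAsFactors = FALSE)
    vals <- rbind(m, s, ifelse(m != 0, 100 * s / abs(m), NA_real_))
    colnames(vals) <- params
    cbind(stat, as.data.frame(vals, row.names = FALSE))
  }))
  class(out) <- c("nca_summary", class(out))
  out
}
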