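#' Concentration-time profile for one subject
#'
#' Container for a single subject's plasma concentration-time series after an
#' i.v. bolus dose. Times must be strictly increasing and non-negative;
#' concentrations not flagged below the limit of quantification (BLQ) must be
#' strictly positive.
#'
#' @param subject_id subject identifier.
#' @param species species label (e.g. "rat").
#' @param sex sex label ("M", "F", or "" when not applicable).
#' @param dose administered dose in mg/kg.
#' @param time sampling times in hours.
#' @param conc plasma concentrations in ng/mL.
#' @param blq logical (or 0/1) flag per sample: below limit of quantification.
#' @return an object of class `conc_time_profile`: a list with fields
#'   `subject_id`, `species`, `sex`, `dose` and a data frame `samples`
#'   (`time`, `conc`, `blq`).
#' @export
#' @examples
#' p <- conc_time_profile("r1", "rat", "F", 12.5,
#'                        time = c(1, 2, 4, 8),
#'                        conc = 1000 * exp(-0.174 * c(1, 2, 4, 8)))
conc_time_profile <- function(subject_id, species = "", sex = "", dose,
                              time, conc, blq = rep(FALSE, length(time))) {
  stopifnot(length(time) == length(conc), length(time) == length(blq))
  blq <- as.logical(blq)
  if (length(time) == 0L) stop("empty profile")
  if (any(time < 0)) stop("times must be >= 0")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(conc[!blq] <= 0)) stop("non-BLQ concentrations must be > 0")
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0) {
    stop("dose must be a single positive number (mg/kg)")
  }
  structure(
    list(subject_id = as.character(subject_id),
         species = as.character(species), sex = as.character(sex),
         dose = dose,
         samples = data.frame(time = time, conc = conc, blq = blq)),
    class = "conc_time_profile")
}

#' @export
print.conc_time_profile <- function(x, ...) {
  cat(sprintf("<conc_time_profile> %s (%s %s), %.4g mg/kg, %d samples (%d BLQ)\n",
              x$subject_id, x$species, x$sex, x$dose,
              nrow(x$samples), sum(x$samples$blq)))
  invisible(x)
}

# Usable (non-BLQ) samples under the BLQ policy: BLQ before Tmax dropped;
# from the first BLQ after Tmax onward, all samples dropped. Never imputes.
usable_samples <- function(profile) {
  s <- profile$samples
  obs <- s[!s$blq, , drop = FALSE]
  if (nrow(obs) == 0L) return(obs)
  tmax <- obs$time[which.max(obs$conc)]
  post_blq <- s$time[s$blq & s$time > tmax]
  if (length(post_blq)) obs <- obs[obs$time < min(post_blq), , drop = FALSE]
  obs
}

#' Read concentration-time profiles from CSV
#'
#' Expects the header
#' `subject,species,sex,dose_mg_per_kg,time_h,conc_ng_per_ml,blq`
#' with `blq` coded 0/1 and times in decimal hours.
#'
#' @param path CSV file path.
#' @return a named list of [conc_time_profile()] objects, one per subject.
#' @export
read_profiles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "species", "sex", "dose_mg_per_kg",
            "time_h", "conc_ng_per_ml", "blq")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("profile CSV missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(d, d$subject), function(g) {
    g <- g[order(g$time_h), ]
    conc_time_profile(g$subject[1], g$species[1], g$sex[1],
                      g$dose_mg_per_kg[1], g$time_h, g$conc_ng_per_ml,
                      g$blq)
  })
  out[order(names(out))]
}

#' Write profiles to the canonical CSV dialect
#'
#' @param profiles a list of [conc_time_profile()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject = p$subject_id, species = p$species, sex = p$sex,
               dose_mg_per_kg = p$dose, time_h = p$samples$time,
               conc_ng_per_ml = p$samples$conc,
               blq = as.integer(p$samples$blq))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Naive-pooled mean profile across subjects
#'
#' For sparse designs where each subject contributes a subset of nominal
#' times, pools by nominal time: per-time arithmetic mean concentration and
#' SD (for error bars). BLQ observations are excluded; times where every
#' observation is BLQ are dropped with a warning.
#'
#' @param profiles list of [conc_time_profile()] objects sharing nominal times.
#' @return a list with `profile` (a [conc_time_profile()] of the pooled means,
#'   labelled `"pooled"`) and `stats`, a data frame of `time`, `mean_conc`,
#'   `sd_conc`, `n`.
#' @export
pooled_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  rows <- do.call(rbind, lapply(profiles, function(p) p$samples))
  obs <- rows[!rows$blq, , drop = FALSE]
  all_times <- sort(unique(rows$time))
  kept <- sort(unique(obs$time))
  dropped <- setdiff(all_times, kept)
  if (length(kept) == 0L) stop("cannot pool: all observations BLQ")
  if (length(dropped)) {
    warning("dropping all-BLQ time points: ",
            paste(format(dropped), collapse = ", "))
  }
  stats_df <- do.call(rbind, lapply(kept, function(tt) {
    v <- obs$conc[obs$time == tt]
    data.frame(time = tt, mean_conc = mean(v), sd_conc = sd_or_zero(v),
               n = length(v))
  }))
  p1 <- profiles[[1]]
  list(profile = conc_time_profile("pooled", p1$species, "", p1$dose,
                                   stats_df$time, stats_df$mean_conc),
       stats = stats_df)
}
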