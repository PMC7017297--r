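# Independent oracles used across tests; deliberately simple code paths
# that do not share logic with the package internals.

# relative deviation
rel <- function(x, ref) abs(x - ref) / abs(ref)

# fine-grid numeric integral of a function on [0, upper] (composite trapezoid)
integrate_fine <- function(f, upper, n = 2e5) {
  t <- seq(0, upper, length.out = n)
  y <- f(t)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

# brute-force terminal-slope oracle: try every contiguous window of >= 3
# points anchored at the end, return the slope with the best adjusted R2
oracle_lambda_z <- function(time, conc, min_points = 3) {
  n <- length(time)
  best <- NULL
  for (start in 1:(n - min_points + 1)) {
    idx <- start:n
    f <- lm(log(conc[idx]) ~ time[idx])
    k <- length(idx)
    y <- log(conc[idx])
    r2 <- 1 - sum(residuals(f)^2) / sum((y - mean(y))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj) best <- list(adj = adj, lz = -coef(f)[2])
  }
  unname(best$lz)
}

# reference rat profile parameters (female subject 1 of the bundled dataset)
F1 <- list(lambda_z = 0.174, c0 = 43094, auc_0_inf = 23980, dose = 12.5)
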