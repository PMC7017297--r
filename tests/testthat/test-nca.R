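test_that("terminal slope is recovered exactly from log-linear data", {
  t <- c(1, 2, 4, 8)
  p <- conc_time_profile("s1", dose = 12.5, time = t,
                         conc = 1000 * exp(-0.174 * t))
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.174, tolerance = 1e-12)
  expect_equal(fit$n_points, 4L)
  expect_equal(fit$fit_quality, 1, tolerance = 1e-9)

  # reference female rat #1 terminal phase, zero noise
  tf <- c(4, 8, 12, 24)
  pf <- conc_time_profile("f1", dose = F1$dose, time = tf,
                          conc = F1$c0 * exp(-F1$lambda_z * tf))
  expect_equal(fit_lambda_z(pf)$lambda_z, 0.174, tolerance = 1e-10)
})

test_that("window search matches the brute-force oracle on bi-exponential decay", {
  t <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  conc <- 5000 * exp(-2 * t) + 500 * exp(-0.18 * t)
  p <- conc_time_profile("bi", dose = 10, time = t, conc = conc)
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, oracle_lambda_z(t, conc), tolerance = 1e-10)
  # last-4-point window alone is already within 1% of the true terminal rate
  f4 <- lm(log(conc[5:8]) ~ t[5:8])
  expect_lt(rel(-coef(f4)[2], 0.18), 0.01)
  expect_lt(rel(fit$lambda_z, 0.18), 0.01)
})

test_that("terminal fitting rejects unusable input", {
  p2 <- conc_time_profile("s", dose = 1, time = c(1, 2), conc = c(10, 5))
  expect_error(fit_lambda_z(p2), "insufficient terminal data")
  flat <- conc_time_profile("s", dose = 1, time = 1:4, conc = rep(10, 4))
  expect_error(fit_lambda_z(flat), "no terminal decay")
  # BLQ after Tmax truncates the usable window
  t <- c(1, 2, 4, 8, 12)
  pb <- conc_time_profile("s", dose = 1, time = t,
                          conc = c(100, 50, 12, 1, 1),
                          blq = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(fit_lambda_z(pb), "insufficient terminal data")
})

test_that("half-life follows ln2 / lambda_z", {
  expect_equal(half_life(log(2)), 1)
  expect_lt(rel(half_life(0.174), 3.99), 0.005)
  expect_lt(rel(half_life(0.181), 3.83), 0.005)
  expect_error(half_life(-1), "invalid rate")
  # antitone in lambda
  expect_true(half_life(0.2) < half_life(0.1))
})

test_that("C0 back-extrapolation is exact geometric extrapolation", {
  p <- conc_time_profile("s", dose = 1, time = c(1, 2), conc = c(800, 640))
  expect_equal(back_extrapolate_c0(p), 800^2 / 640)
  # mono-exponential from 0.5 h recovers the true C0
  t <- c(0.5, 1, 2, 4, 8)
  pf <- conc_time_profile("f1", dose = F1$dose, time = t,
                          conc = F1$c0 * exp(-F1$lambda_z * t))
  expect_lt(rel(back_extrapolate_c0(pf), F1$c0), 0.001)
  # degenerate fallback
  p1 <- conc_time_profile("s", dose = 1, time = 1, conc = 500)
  expect_warning(c0 <- back_extrapolate_c0(p1), "degenerate C0")
  expect_equal(c0, 500)
})

test_that("trapezoidal AUC matches closed forms", {
  flat <- conc_time_profile("s", dose = 1, time = c(0, 1), conc = c(100, 100))
  expect_equal(auc_0_t(flat, "linear"), 100)
  down <- conc_time_profile("s", dose = 1, time = c(0, 1), conc = c(1000, 500))
  expect_equal(auc_0_t(down, "linuplogdown"), 500 / log(2), tolerance = 1e-12)
  expect_error(auc_0_t(down, "simpson"), "unknown AUC method")
  # dense sampling of the reference mono-exponential vs analytic C0/lambda
  t <- seq(0, 48, by = 0.01)
  pf <- conc_time_profile("f1", dose = F1$dose, time = t,
                          conc = F1$c0 * exp(-F1$lambda_z * t))
  expect_lt(rel(auc_0_t(pf), F1$c0 / F1$lambda_z), 0.001)
})

test_that("AUC extrapolation to infinity reproduces the printed tail fraction", {
  tail <- 0.00869 * 23980
  out <- auc_0_inf(23980 - tail, c_last = tail * 0.174, fit = 0.174)
  expect_equal(out$auc_0_inf, 23980, tolerance = 1e-10)
  expect_equal(out$extrapolated_pct, 0.869, tolerance = 1e-6)
  # vanishing tail
  out0 <- auc_0_inf(1000, c_last = 0, fit = 0.2)
  expect_equal(out0$auc_0_inf, 1000)
  expect_equal(out0$extrapolated_pct, 0)
  # mono-exponential: extrapolated fraction equals exp(-lambda * t_last)
  lam <- 0.25; c0 <- 2000; t_last <- 18
  a0t_exact <- c0 / lam * (1 - exp(-lam * t_last))
  out_m <- auc_0_inf(a0t_exact, c0 * exp(-lam * t_last), lam)
  expect_equal(out_m$extrapolated_pct, 100 * exp(-lam * t_last),
               tolerance = 1e-10)
  expect_error(auc_0_inf(100, 10, -0.1), "cannot extrapolate")
})

test_that("clearance and terminal volume reproduce the reference rat identities", {
  expect_lt(rel(clearance(12.5, 23980), 8.7), 0.005)
  expect_lt(rel(clearance(25, 3226), 129), 0.005)
  expect_equal(23980 / 12.5, 1918.4)
  expect_lt(rel(terminal_volume(8.7, 0.174), 3000), 0.005)
  expect_equal(terminal_volume(0.174 / 60, 0.174), 1)
  expect_lt(rel(terminal_volume(7.9, 0.181), 2626), 0.005)
  # homogeneity: clearance(k d, k a) = clearance(d, a)
  expect_equal(clearance(3 * 12.5, 3 * 23980), clearance(12.5, 23980))
  expect_error(clearance(-1, 10), "invalid")
  expect_error(terminal_volume(5, 0), "invalid rate")
})

test_that("full NCA on noise-free mono-exponential data is exact", {
  t <- rich_serial_design()
  p <- conc_time_profile("m", "rat", "F", 12.5, t,
                         F1$c0 * exp(-F1$lambda_z * t))
  r <- run_nca(p)
  expect_equal(r$lambda_z, F1$lambda_z, tolerance = 1e-10)
  expect_equal(r$c0, F1$c0, tolerance = 1e-10)
  # the log trapezoid is exact on every mono-exponential interval
  expect_equal(r$auc_0_inf, F1$c0 / F1$lambda_z, tolerance = 1e-10)
  expect_equal(r$cl * 60 / r$vz, r$lambda_z, tolerance = 1e-10)
  # doubling concentrations doubles AUC and C0, leaves rates untouched
  p2 <- conc_time_profile("m2", "rat", "F", 12.5, t,
                          2 * F1$c0 * exp(-F1$lambda_z * t))
  r2 <- run_nca(p2)
  expect_equal(r2$auc_0_inf, 2 * r$auc_0_inf, tolerance = 1e-10)
  expect_equal(r2$c0, 2 * r$c0, tolerance = 1e-10)
  expect_equal(r2$lambda_z, r$lambda_z, tolerance = 1e-12)
})

test_that("NCA summary reproduces the reference rat group statistics", {
  rat <- lna_rat_nca()
  # reconstruct per-subject results directly from the individual rows
  res <- data.frame(sex = rat$sex, lambda_z = rat$lambda_z, cl = rat$cl,
                    vz = rat$vz, auc_0_inf = rat$auc_0_inf)
  s <- summarize_nca(res, grouping = "sex")
  f_mean <- s[s$group == "F" & s$statistic == "mean", ]
  expect_equal(round(f_mean$lambda_z, 3), 0.183)
  f_sd <- s[s$group == "F" & s$statistic == "sd", ]
  expect_equal(round(f_sd$lambda_z, 3), 0.008)
  all_mean <- s[s$group == "pooled" & s$statistic == "mean", ]
  expect_equal(round(all_mean$lambda_z, 3), 0.181)
  expect_equal(round(all_mean$cl, 1), 7.9)
  expect_equal(round(all_mean$vz, 0), 2626)
  f_cv <- s[s$group == "F" & s$statistic == "cv_pct", ]
  expect_equal(round(f_cv$lambda_z), 4)
  # permutation invariance and degenerate group
  perm <- summarize_nca(res[sample(nrow(res)), ], grouping = "pooled")
  expect_equal(perm$lambda_z, summarize_nca(res, "pooled")$lambda_z)
  one <- summarize_nca(res[1, ], grouping = "pooled")
  expect_false(one$sd_defined[1])
  expect_equal(one$lambda_z[one$statistic == "sd"], 0)
  expect_error(summarize_nca(res[0, ]), "no data")
})
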