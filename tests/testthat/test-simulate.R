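test_that("simulation specs validate and expose closed-form ground truth", {
  spec <- simulation_spec(coefficients = c(5000, 500), rates = c(2, 0.18),
                          dose = 10, sampling_times = sparse_design())
  gt <- ground_truth(spec)
  expect_equal(gt$lambda_z, 0.18)
  expect_equal(gt$c0, 5500)
  expect_equal(gt$auc_0_inf, 5000 / 2 + 500 / 0.18)
  # self-consistency CL * 60 / Vz = lambda_z
  expect_equal(gt$cl * 60 / gt$vz, gt$lambda_z, tolerance = 1e-12)
  # closed-form AUC agrees with numeric integration of the curve
  num <- integrate_fine(function(t) disposition_curve(spec, t), 400)
  expect_lt(rel(gt$auc_0_inf, num), 1e-4)
  expect_error(simulation_spec(c(1, 1), c(2, 2), 1, 1:3), "distinct")
  expect_error(simulation_spec(1000, 0.2, 1, numeric(0)), "no design")
})

test_that("simulation is deterministic under a seed and varies across seeds", {
  spec <- simulation_spec(coefficients = 1000, rates = 0.2, dose = 5,
                          sampling_times = c(1, 2, 4, 8), cv_percent = 20)
  a <- simulate_profiles(spec, n_subjects = 3, seed = 11)
  b <- simulate_profiles(spec, n_subjects = 3, seed = 11)
  c <- simulate_profiles(spec, n_subjects = 3, seed = 12)
  expect_identical(a$profiles[[2]]$samples, b$profiles[[2]]$samples)
  expect_false(identical(a$profiles[[1]]$samples$conc,
                         c$profiles[[1]]$samples$conc))
})

test_that("sparse cohorts cover the grid with disjoint interleaved subsets", {
  spec <- simulation_spec(coefficients = 1000, rates = 0.2, dose = 5,
                          sampling_times = sparse_design(), design = "sparse")
  sim <- simulate_profiles(spec, n_subjects = 6, seed = 3)
  times <- lapply(sim$profiles, function(p) p$samples$time)
  expect_equal(sort(unique(unlist(times))), sparse_design())
  # subjects in different cohorts sample disjoint times
  expect_length(intersect(times[[1]], times[[2]]), 0)
  # same cohort, same times
  expect_equal(times[[1]], times[[4]])
})

test_that("BLQ flagging and the all-BLQ failure mode", {
  spec <- simulation_spec(coefficients = 1000, rates = 0.2, dose = 5,
                          sampling_times = c(1, 2, 4, 8), llq = 1e6)
  sim <- simulate_profiles(spec, seed = 1)
  expect_true(all(sim$profiles[[1]]$samples$blq))
  expect_error(fit_lambda_z(sim$profiles[[1]]), "insufficient terminal data")
})

test_that("noise-free NCA recovers every reference rat cell within 1%", {
  rat <- lna_rat_nca()
  for (i in seq_len(nrow(rat))) {
    spec <- spec_from_nca(rat$lambda_z[i], rat$c0[i], rat$auc_0_inf[i],
                          dose = rat$dose_mg_per_kg[i],
                          species = "rat", sex = rat$sex[i])
    res <- run_nca(simulate_profiles(spec, seed = 1)$profiles[[1]])
    expect_lt(rel(res$lambda_z, rat$lambda_z[i]), 0.01)
    expect_lt(rel(res$t_half, rat$t_half[i]), 0.01)
    expect_lt(rel(res$c0, rat$c0[i]), 0.01)
    expect_lt(rel(res$auc_0_inf, rat$auc_0_inf[i]), 0.01)
    expect_lt(rel(res$auc_per_dose, rat$auc_per_dose[i]), 0.01)
    expect_lt(rel(res$cl, rat$cl[i]), 0.015)
    expect_lt(rel(res$vz, rat$vz[i]), 0.015)
  }
  # infeasible fast phase is refused
  expect_error(spec_from_nca(0.174, 43094, 23980, 12.5, alpha1 = 1.5),
               "infeasible")
})

test_that("Monte-Carlo lambda_z recovery at 15% CV stays within bands", {
  spec <- simulation_spec(coefficients = c(40000, 500), rates = c(3, 0.18),
                          dose = 12.5, sampling_times = rich_serial_design(),
                          cv_percent = 15)
  n_rep <- 200
  est <- numeric(n_rep)
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    p <- simulate_profiles(spec, seed = 1000 + r)$profiles[[1]]
    fit <- fit_lambda_z(p)
    est[r] <- fit$lambda_z
    # 95% CI from the selected terminal window
    s <- p$samples[p$samples$time >= fit$window[1] &
                     p$samples$time <= fit$window[2], ]
    ci <- -rev(confint(lm(log(conc) ~ time, data = s), "time"))
    covered[r] <- ci[1] <= 0.18 && 0.18 <= ci[2]
  }
  expect_lt(rel(mean(est), 0.18), 0.05)
  expect_gte(mean(covered), 0.90)
})
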