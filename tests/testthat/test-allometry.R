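test_that("power-law fit recovers generating parameters to machine precision", {
  sp <- simulate_species_power_law(a = 3, b = -0.25,
                                   weights = c(rat = 0.25, monkey = 3.75))
  fit <- fit_allometry(sp$weight_kg, sp$cl_ml_min_kg)
  expect_equal(fit$a, 3, tolerance = 1e-12)
  expect_equal(fit$b, -0.25, tolerance = 1e-12)
  # two-point fit is an interpolant
  for (i in 1:2) {
    expect_equal(predict_direct(fit, sp$weight_kg[i])$cl_per_kg,
                 sp$cl_ml_min_kg[i], tolerance = 1e-12)
  }
  # flat law: b = 0, a = the common clearance
  flat <- fit_allometry(c(0.25, 3.75), c(5, 5))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$a, 5, tolerance = 1e-12)
  expect_equal(predict_direct(flat, 70)$cl_per_kg, 5)
  expect_error(fit_allometry(c(1, 1), c(2, 3)), "degenerate regression")
})

test_that("rat-monkey regression reproduces the reference coefficients", {
  sp <- lna_species_defaults()
  el <- sp[sp$include_in_scaling, ]
  fit <- fit_allometry(el$weight_kg, el$cl_ml_min_kg)
  expect_lt(rel(fit$b, -0.362198), 0.005)
  expect_lt(rel(fit$log10_a, 0.6789), 0.001)
  pred <- predict_direct(fit, 70)
  expect_lt(rel(pred$cl_per_kg, 1.02), 0.01)
  expect_lt(rel(pred$cl_absolute, 71.7), 0.01)
})

test_that("Tang fixed-exponent rule acts on the absolute-clearance scale", {
  sp <- lna_species_defaults()
  el <- sp[sp$include_in_scaling, ]
  fit <- fit_allometry(el$weight_kg, el$cl_ml_min_kg)
  pred <- predict_tang(fit, 70)
  expect_lt(rel(pred$cl_absolute, 76), 0.01)
  expect_lt(rel(pred$cl_per_kg, 1.1), 0.02)
  # at 1 kg the absolute prediction equals the intercept
  expect_equal(predict_tang(fit, 1)$cl_absolute, fit$a, tolerance = 1e-12)
})

test_that("single-species scaling follows the 0.75 weight-ratio rule", {
  rat <- predict_one_species(7.9, 0.25, 70)
  expect_equal(rat$cl_per_kg, 7.9 * (0.25 / 70)^0.25, tolerance = 1e-12)
  expect_lt(rel(rat$cl_absolute, 135), 0.01)
  mk <- predict_one_species(2.958, 3.75, 70)
  expect_lt(rel(mk$cl_absolute, 100), 0.01)
  # identity at equal weights, for any exponent
  expect_equal(predict_one_species(5, 3, 3, exponent = 0.6)$cl_per_kg, 5)
  # exponent 1 preserves per-kg clearance exactly
  expect_equal(predict_one_species(5, 0.25, 70, exponent = 1)$cl_per_kg, 5)
  expect_warning(predict_one_species(5, 1, 70, exponent = 2.5), "exponent")
})

test_that("per-kg/absolute duality holds for every method", {
  sp <- lna_species_defaults()
  for (basis in c("total", "unbound")) {
    tab <- human_cl_predictions(sp, w_target = 70, basis = basis,
                                fu_target = 0.0145)
    expect_equal(tab$cl_absolute, tab$cl_per_kg * 70, tolerance = 1e-12)
  }
})

test_that("unbound clearance arithmetic and re-binding", {
  expect_equal(unbound_cl(7.9, 0.013), 7.9 / 0.013)
  expect_equal(unbound_cl(4, 1), 4)
  expect_error(unbound_cl(4, 0), "fully bound")
  expect_equal(rebind_to_total(100, 0.0145), 1.45)
  expect_equal(rebind_to_total(3.7, 1), 3.7)
  # one-species rat on the unbound basis, re-bound with human fu
  v <- rebind_to_total(predict_one_species(7.9 / 0.013, 0.25, 70)$cl_per_kg,
                       0.0145)
  expect_lt(rel(v, 2.2), 0.03)
})

test_that("equal fu across species makes the unbound pipeline collapse to total", {
  sp <- species_pk(c("rat", "monkey", "human"),
                   c(0.25, 3.75, 70), c(7.9, 2.958, NA),
                   fu = 0.05, include_in_scaling = c(TRUE, TRUE, FALSE))
  tot <- human_cl_predictions(sp, 70, basis = "total")
  unb <- human_cl_predictions(sp, 70, basis = "unbound", fu_target = 0.05)
  expect_equal(unb$cl_per_kg, tot$cl_per_kg, tolerance = 1e-12)
})

test_that("geometric mean behaves and reproduces the reference aggregate", {
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(5), 5)
  expect_error(geometric_mean(c(1, -2)), "undefined")
  x <- c(1.02, 1.1, 1.9, 1.4)
  expect_lt(rel(geometric_mean(x), 1.31), 0.01)
  expect_true(geometric_mean(x) <= max(x) && geometric_mean(x) >= min(x))
  expect_equal(geometric_mean(rev(x)), geometric_mean(x))
})

test_that("jittered power-law data still yield a usable exponent", {
  b_hat <- vapply(1:500, function(s) {
    sp <- simulate_species_power_law(a = 4.8, b = -0.36,
                                     weights = c(0.025, 0.25, 3.75, 70),
                                     cv_percent = 10, seed = s)
    fit_allometry(sp$weight_kg, sp$cl_ml_min_kg)$b
  }, numeric(1))
  expect_lt(abs(median(b_hat) - (-0.36)), 0.05)
})
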