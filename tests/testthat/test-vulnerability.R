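test_that("PLC from conductance is the normalised loss, clipped to [0, 100]", {
  expect_equal(plc_from_conductance(1, 1), 0)
  expect_equal(plc_from_conductance(0, 1), 100)
  expect_equal(plc_from_conductance(0.25, 1), 75)
  expect_equal(plc_from_conductance(1.02, 1), 0)  # overshoot clipped
  expect_error(plc_from_conductance(0.5, 0), "k_max")
})

test_that("sigmoid curve has its inflexion at P50 and the right asymptotes", {
  expect_equal(sigmoid_plc(-3, -3, 40), 50)
  expect_lt(sigmoid_plc(10, -3, 40), 1e-6)
  expect_gt(sigmoid_plc(-20, -3, 40), 100 - 1e-6)
  p <- seq(0, -8, by = -0.1)
  expect_true(all(diff(sigmoid_plc(p, -3, 40)) > 0))  # rises with tension
  expect_equal(sigmoid_plc(-4.2453, -3, 40), 88, tolerance = 1e-3)
  expect_error(sigmoid_plc(-3, -3, -1), "positive")
})

test_that("analytic inversion agrees with numeric root-finding to 1e-9", {
  for (p50 in c(-2, -3, -4.5)) {
    for (s in c(20, 40, 85)) {
      for (target in c(1, 12, 50, 88, 99)) {
        p_an <- pressure_at_plc(p50, target, s = s)
        p_num <- uniroot(function(p) sigmoid_plc(p, p50, s) - target,
                         c(p50 - 30, p50 + 30), tol = 1e-12)$root
        expect_equal(p_an, p_num, tolerance = 1e-9)
        expect_equal(sigmoid_plc(p_an, p50, s), target, tolerance = 1e-9)
      }
    }
  }
  expect_equal(pressure_at_plc(-3, 50, s = 40), -3)
  expect_error(pressure_at_plc(-3, 0, s = 40), "target")
  expect_error(pressure_at_plc(-3, 100, s = 40), "target")
})

test_that("P12 and P88 are symmetric about P50 under the logistic", {
  p12 <- pressure_at_plc(-3, 12, s = 40)
  p88 <- pressure_at_plc(-3, 88, s = 40)
  expect_equal(p12, -1.7547, tolerance = 1e-4)
  expect_equal(p88, -4.2453, tolerance = 1e-4)
  expect_equal(abs(-3 - p12), abs(p88 - (-3)), tolerance = 1e-12)
})

test_that("noiseless curves are recovered to optimizer tolerance", {
  ser <- simulate_plc_series(seq(-1, -5, by = -0.25), p50 = -3, s = 40,
                             noise_sd = 0, seed = 1)
  f <- fit_vulnerability_curve(ser$pressure_mpa, ser$plc)
  expect_true(f$converged)
  expect_true(f$qc_pass)
  expect_lt(abs(f$p50 - (-3)), 1e-6)
  expect_lt(abs(f$s - 40), 1e-4)
  expect_equal(f$p12, pressure_at_plc(-3, 12, s = 40), tolerance = 1e-5)
  expect_equal(f$p88, pressure_at_plc(-3, 88, s = 40), tolerance = 1e-5)
  expect_true(f$p12 > f$p50 && f$p50 > f$p88)  # ordering on the tension axis
})

test_that("fit matches brute-force grid search on a noiseless instance", {
  ser <- simulate_plc_series(seq(-1.2, -5, by = -0.2), p50 = -3.4, s = 55,
                             noise_sd = 0, seed = 2)
  f <- fit_vulnerability_curve(ser$pressure_mpa, ser$plc)
  grid <- expand.grid(p50 = seq(-5, -2, by = 0.05), s = seq(10, 90, by = 2))
  rss <- mapply(function(p50, s) {
    sum((ser$plc - sigmoid_plc(ser$pressure_mpa, p50, s))^2)
  }, grid$p50, grid$s)
  expect_lte(f$rss, min(rss) + 1e-8)
  best <- grid[which.min(rss), ]
  expect_lt(abs(f$p50 - best$p50), 0.06)
})

test_that("degenerate and sub-quality series are flagged, not fatal", {
  # constant PLC: no curve to fit
  f <- fit_vulnerability_curve(seq(-1, -4, by = -0.5), rep(40, 7))
  expect_false(f$converged)
  expect_false(f$qc_pass)
  expect_true(is.na(f$p50))
  # curve truncated before 90% loss: fit returned but QC fails
  p <- seq(-1, -3, by = -0.25)
  f2 <- fit_vulnerability_curve(p, sigmoid_plc(p, -3, 40))
  expect_true(f2$converged)
  expect_false(f2$qc_pass)
  expect_lt(f2$max_plc_reached, 90)
  # input validation
  expect_error(fit_vulnerability_curve(c(-1, -1, -2), c(10, 20, 30)),
               "decreasing")
  expect_error(fit_vulnerability_curve(c(1, 2), c(10, 20)), "negative")
  f3 <- fit_vulnerability_curve(c(1, 1.5, 2, 3) * 1,
                                sigmoid_plc(-c(1, 1.5, 2, 3), -2, 40),
                                tension_positive = TRUE)
  expect_true(f3$converged)
})

test_that("a single noisy curve still localises P50", {
  ser <- simulate_plc_series(seq(-1, -5, by = -0.25), p50 = -3, s = 40,
                             noise_sd = 3, seed = 77)
  f <- fit_vulnerability_curve(ser$pressure_mpa, ser$plc)
  expect_true(f$converged)
  expect_lt(abs(f$p50 - (-3)), 0.3)
})

test_that("empirical conductivity normalisations", {
  hm <- empirical_conductivities(1e-6, 2e-5, NA)
  expect_equal(hm$ks_emp, 0.05)
  expect_true(is.na(hm$kl_emp))
  expect_equal(empirical_conductivities(0, 1e-5, 0.2)$ks_emp, 0)
  expect_equal(empirical_conductivities(1e-6, 1e-5, NA)$ks_emp,
               2 * empirical_conductivities(1e-6, 2e-5, NA)$ks_emp)
  expect_error(empirical_conductivities(1e-6, 0), "positive")
})
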