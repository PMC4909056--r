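spec1 <- function(mu = 10, sp = 1, sb = 0.5, se = 2) {
  list(y = list(mean = mu, sd_provenance = sp, sd_block = sb, sd_residual = se))
}

test_that("trial simulation is deterministic and honours degenerate noise", {
  t1 <- simulate_trial(spec1(), seed = 5)
  t2 <- simulate_trial(spec1(), seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_trial(spec1(), seed = 6)
  expect_false(identical(t1$y, t3$y))
  # all SDs zero: every tree exactly at the grand mean
  t0 <- simulate_trial(spec1(10, 0, 0, 0), seed = 1)
  expect_true(all(t0$y == 10))
  expect_equal(nrow(t0), 10 * 3 * 4)
  expect_equal(nlevels(t0$provenance), 10)
  expect_equal(nlevels(t0$block), 3)
  expect_error(simulate_trial(spec1(sp = -1), seed = 1), "sd_")
  expect_error(simulate_trial(spec1(), seed = 1, n_blocks = 0))
})

test_that("generated data carry the specified variance structure (moment check)", {
  # 10 x 3 x 50 with sigma = (1, 0.5, 2): the grand sample variance has
  # closed-form expectation sigmaP^2 N(1-1/P)/(N-1) + sigmaB^2 N(1-1/B)/(N-1)
  # + sigmaE^2, approached over many seeds
  n_seeds <- 200
  P <- 10; B <- 3; n <- 50; N <- P * B * n
  mom <- matrix(NA_real_, n_seeds, 3)
  sv <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    tab <- simulate_trial(spec1(10, 1, 0.5, 2), n_trees = n, seed = 1000 + i)
    sv[i] <- var(tab$y)
    mom[i, ] <- provtraits:::mom_varcomp(tab$y, tab$provenance, tab$block)
  }
  expect_sv <- (1 * N * (1 - 1 / P) + 0.25 * N * (1 - 1 / B)) / (N - 1) + 4
  mc_se <- sd(sv) / sqrt(n_seeds)
  expect_lt(abs(mean(sv) - expect_sv), 4 * mc_se)
  # method-of-moments estimates are unbiased for the generator's components
  expect_equal(colMeans(mom), c(1, 0.25, 4), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("lognormal traits exponentiate the additive model", {
  tl <- simulate_trial(list(y = list(mean = log(5), sd_provenance = 0,
                                     sd_block = 0, sd_residual = 0,
                                     lognormal = TRUE)), seed = 2)
  expect_true(all(abs(tl$y - 5) < 1e-12))
})

test_that("vessel populations are reproducible with valid geometry", {
  v1 <- simulate_vessel_population(500, seed = 9)
  v2 <- simulate_vessel_population(500, seed = 9)
  expect_identical(v1, v2)
  expect_true(all(v1$a_um > 0))
  expect_true(all(v1$b_um <= v1$a_um))
  expect_true(all(v1$d_um > 0))
  # degenerate spec: identical circular vessels
  v0 <- simulate_vessel_population(50, log(24), 0, c(1, 1), seed = 1)
  expect_equal(v0$d_um, rep(24, 50), tolerance = 1e-12)
  expect_equal(v0$a_um, v0$b_um)
  # default spec targets a mean idealized diameter near 24 um
  vbig <- simulate_vessel_population(10000, seed = 3)
  expect_lt(abs(mean(vbig$d_um) - 24) / 24, 0.05)
  expect_error(simulate_vessel_population(10, eccentricity_range = c(0, 1),
                                          seed = 1), "eccentricity")
})

test_that("PLC series sit on the sigmoid and never leave [0, 100]", {
  grid <- seq(-1, -5, by = -0.25)
  s0 <- simulate_plc_series(grid, p50 = -3, s = 40, noise_sd = 0, seed = 1)
  expect_equal(s0$plc, sigmoid_plc(grid, -3, 40), tolerance = 1e-12)
  expect_equal(s0$plc[grid == -3], 50)
  expect_identical(s0$pressure_mpa, grid)
  for (seed in 1:25) {
    s <- simulate_plc_series(grid, p50 = -2, s = 30, noise_sd = 25, seed = seed)
    expect_true(all(s$plc >= 0 & s$plc <= 100))
  }
  expect_error(simulate_plc_series(c(-1, -0.5), seed = 1), "decreasing")
})

test_that("origin climate hits its annual targets exactly", {
  mc <- simulate_origin_climate(8.3, 742, seed = 11)
  expect_equal(mean(mc$tmean_c), 8.3, tolerance = 1e-12)
  expect_equal(sum(mc$prec_mm), 742, tolerance = 1e-10)
  expect_true(all(mc$prec_mm >= 0))
  expect_error(simulate_origin_climate(8, -5, seed = 1), "positive")
  # aridity indices stay finite and positive across the generator's range
  for (seed in 1:100) {
    mat <- runif(1, 3.4, 15.3)
    map <- runif(1, 575, 1080)
    mc <- simulate_origin_climate(mat, map, seed = seed)
    fai <- forest_aridity_index(mc$tmean_c, mc$prec_mm)
    expect_true(is.finite(fai) && fai > 0)
  }
})
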