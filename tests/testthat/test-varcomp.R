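sim_y <- function(seed, sp = 1, sb = 0.5, se = 2, n_trees = 4, n_prov = 10) {
  simulate_trial(
    list(y = list(mean = 10, sd_provenance = sp, sd_block = sb,
                  sd_residual = se)),
    n_provenances = n_prov, n_trees = n_trees, seed = seed
  )
}

test_that("likelihood evaluator matches the dense-covariance oracle", {
  tab <- sim_y(3, n_prov = 4, n_trees = 2)  # 24 observations
  pts <- list(c(0.7, 0.3, 1.2), c(2, 0.01, 0.5), c(0, 1, 1), c(0, 0, 2.5))
  for (v in pts) {
    for (m in c("REML", "ML")) {
      expect_equal(
        reml_loglik(tab$y, tab$provenance, tab$block, v, m),
        dense_lmm_loglik(tab$y, tab$provenance, tab$block, v, m),
        tolerance = 1e-10
      )
    }
  }
  expect_error(reml_loglik(tab$y, tab$provenance, tab$block, c(0, 0, 0)),
               "singular")
  expect_error(reml_loglik(tab$y, tab$provenance, tab$block, c(-1, 0, 1)))
})

test_that("with no grouping variance the restricted likelihood is the iid closed form", {
  set.seed(8)
  tab <- sim_y(8, n_prov = 5, n_trees = 3)
  y <- tab$y
  n <- length(y)
  s2 <- 1.7
  # iid restricted likelihood with the mean profiled out
  ll_iid <- -0.5 * ((n - 1) * log(2 * pi * s2) + log(n) +
                      sum((y - mean(y))^2) / s2)
  expect_equal(reml_loglik(y, tab$provenance, tab$block, c(0, 0, s2)),
               ll_iid, tolerance = 1e-10)
  # translation invariance of the restricted likelihood
  expect_equal(reml_loglik(y + 100, tab$provenance, tab$block, c(0.5, 0.2, 1)),
               reml_loglik(y, tab$provenance, tab$block, c(0.5, 0.2, 1)),
               tolerance = 1e-8)
})

test_that("REML estimates equal lme4 and method-of-moments on balanced data", {
  tab <- sim_y(42, sp = 1.5, sb = 0.8, se = 1, n_trees = 10)
  fit <- fit_random_model(tab$y, tab$provenance, tab$block)
  mom <- provtraits:::mom_varcomp(tab$y, tab$provenance, tab$block)
  # interior optimum on a balanced design: REML = expected-mean-squares
  expect_true(all(mom > 0))
  expect_equal(unname(fit$sigma2), unname(mom), tolerance = 1e-5)
  lmer_fit <- lme4::lmer(y ~ 1 + (1 | provenance) + (1 | block), data = tab,
                         REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  v_lme4 <- c(vc$vcov[vc$grp == "provenance"], vc$vcov[vc$grp == "block"],
              vc$vcov[vc$grp == "Residual"])
  expect_equal(unname(fit$sigma2), v_lme4, tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lmer_fit)),
               tolerance = 1e-6)
  expect_equal(fit$mu, unname(lme4::fixef(lmer_fit)), tolerance = 1e-6)
  # row order must not matter
  perm <- sample(nrow(tab))
  fit_p <- fit_random_model(tab$y[perm], tab$provenance[perm], tab$block[perm])
  expect_equal(fit_p$sigma2, fit$sigma2, tolerance = 1e-6)
})

test_that("boundary variance components are estimated as exact zeros", {
  tab <- sim_y(7, sp = 0, sb = 0, se = 2, n_trees = 50)
  fit <- fit_random_model(tab$y, tab$provenance, tab$block)
  expect_true(fit$converged)
  expect_lte(fit$sigma2[["inter"]], 0.05)
  expect_equal(fit$sigma2[["intra"]], 4, tolerance = 0.35)
  # exactly centred group means: both components pinned at zero
  bd <- make_boundary_data(1)
  fitb <- fit_random_model(bd$y, bd$provenance, bd$block)
  expect_identical(fitb$sigma2[["inter"]], 0)
  expect_identical(fitb$sigma2[["block"]], 0)
  vc <- variance_component_percents(fitb)
  expect_equal(unname(vc), c(0, 0, 100))
})

test_that("boundary-corrected LRT: halved chi-square tail, LR clipped at zero", {
  tab <- sim_y(12, sp = 1.5, se = 1, n_trees = 10)
  full <- fit_random_model(tab$y, tab$provenance, tab$block)
  red <- fit_random_model(tab$y, tab$provenance, tab$block,
                          components = "block")
  t1 <- lrt_provenance(full, red)
  expect_gt(t1$lr, 0)
  expect_equal(t1$p_corrected,
               0.5 * pchisq(t1$lr, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(t1$delta_aic, t1$lr - 2)
  # no provenance signal at all: LR = 0 and p = 0.5 exactly
  bd <- make_boundary_data(2)
  fullb <- fit_random_model(bd$y, bd$provenance, bd$block)
  redb <- fit_random_model(bd$y, bd$provenance, bd$block,
                           components = "block")
  tb <- lrt_provenance(fullb, redb)
  expect_equal(tb$lr, 0, tolerance = 1e-7)
  expect_equal(tb$p_corrected, 0.5, tolerance = 1e-7)
  expect_error(lrt_provenance(full, fit_random_model(tab$y, tab$provenance,
                                                     tab$block, method = "ML",
                                                     components = "block")),
               "method")
})

test_that("CV decomposition: worked example, boundary and scale invariance", {
  y <- c(7, 9, 9, 11, 11, 13)  # provenance means 8, 10, 12
  pv <- factor(rep(1:3, each = 2))
  cv <- cv_components(y, pv)
  expect_equal(cv$cv_inter, 20)
  expect_equal(cv_components(rep(5, 6), pv)$cv_inter, 0)
  expect_equal(cv_components(rep(5, 6), pv)$cv_intra, 0)
  cv10 <- cv_components(10 * y, pv)
  expect_equal(cv10$cv_inter, cv$cv_inter, tolerance = 1e-12)
  expect_equal(cv10$cv_intra, cv$cv_intra, tolerance = 1e-12)
  # pooled variant uses the pooled within-provenance SD
  cvp <- cv_components(y, pv, intra = "pooled")
  expect_equal(cvp$cv_intra, sqrt(2) / 10 * 100, tolerance = 1e-10)
  expect_warning(cv_components(c(-1, 1, -2, 2, -3, 3), pv), "zero")
})

test_that("variance component percentages", {
  expect_equal(unname(variance_component_percents(c(1, 1, 2))), c(25, 25, 50))
  expect_equal(unname(variance_component_percents(c(0, 1, 3))), c(0, 25, 75))
  expect_equal(sum(variance_component_percents(c(0.3, 0.01, 5))), 100)
  expect_equal(variance_component_percents(c(2, 2, 4)),
               variance_component_percents(c(1, 1, 2)))
  expect_error(variance_component_percents(c(0, 0, 0)), "undefined")
})

test_that("climate model recovers a noiseless fixed effect exactly", {
  tab <- sim_y(5, sp = 0, sb = 0, se = 1)
  fai <- seq(2, 9.16, length.out = 10)[as.integer(tab$provenance)]
  y <- 1.5 + 0.4 * fai
  fit <- fit_climate_model(y, fai, tab$provenance, tab$block)
  expect_equal(fit$beta, 0.4, tolerance = 1e-6)
  expect_equal(fit$alpha, 1.5, tolerance = 1e-6)
  expect_error(fit_climate_model(y, rep(3, nrow(tab)), tab$provenance,
                                 tab$block), "identical")
  expect_error(fit_climate_model(y, rnorm(nrow(tab)), tab$provenance,
                                 tab$block), "constant within")
})

test_that("climate model matches lme4 ML and detects a strong signal", {
  tab <- sim_y(9, sp = 0.3, sb = 0.3, se = 1)
  fai <- seq(2, 9.16, length.out = 10)[as.integer(tab$provenance)]
  y <- tab$y + 0.8 * fai
  fit <- fit_climate_model(y, fai, tab$provenance, tab$block)
  dat <- data.frame(y = y, fai = fai, provenance = tab$provenance,
                    block = tab$block)
  m <- lme4::lmer(y ~ fai + (1 | provenance) + (1 | block), data = dat,
                  REML = FALSE,
                  control = lme4::lmerControl(calc.derivs = FALSE))
  expect_equal(fit$beta, unname(lme4::fixef(m)[2]), tolerance = 1e-4)
  expect_equal(fit$se_beta, sqrt(diag(as.matrix(stats::vcov(m))))[2],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
  expect_lt(fit$p, 0.05)
  # log-transform path requires positive data and acts on the log scale
  fitl <- fit_climate_model(exp(y / 10), fai, tab$provenance, tab$block,
                            log_transform = TRUE)
  expect_equal(fitl$beta, fit$beta / 10, tolerance = 1e-4)
})

test_that("REML recovery across seeds is approximately unbiased", {
  n_seeds <- 60
  est <- matrix(NA_real_, n_seeds, 3)
  for (i in seq_len(n_seeds)) {
    tab <- sim_y(3000 + i, sp = 1, sb = 0.5, se = sqrt(2), n_trees = 10)
    est[i, ] <- fit_random_model(tab$y, tab$provenance, tab$block)$sigma2
  }
  expect_equal(colMeans(est), c(1, 0.25, 2), tolerance = 0.2,
               ignore_attr = TRUE)
})

test_that("per-trait tables assemble complete-case results", {
  tab <- sim_y(21, sp = 1.5, sb = 0.3, se = 1)
  tab$flat <- sim_y(22, sp = 0, sb = 0, se = 1)$y
  tab$flat[1:5] <- NA  # per-trait missingness
  vt <- varcomp_table(tab, c("y", "flat"))
  expect_equal(vt$trait, c("y", "flat"))
  expect_equal(vt$n, c(120, 115))
  expect_lt(vt$p_corrected[1], 0.05)
  expect_gt(vt$p_corrected[2], 0.05)
  expect_equal(rowSums(vt[, c("vc_inter", "vc_block", "vc_intra")]),
               c(100, 100), tolerance = 1e-6, ignore_attr = TRUE)
  fai_df <- data.frame(provenance = levels(tab$provenance),
                       fai = seq(2, 9.16, length.out = 10))
  ct <- climate_model_table(tab, fai_df, c("y", "flat"))
  expect_equal(ct$n, c(120, 115))
  expect_true(all(is.finite(ct$beta)))
})
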