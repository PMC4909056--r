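# Mixed-model machinery for the two crossed random intercepts
# (provenance, block) plus residual. The covariance is
#   V = s2_inter Zp Zp' + s2_block Zb Zb' + s2_intra I,
# evaluated through the low-rank (Woodbury / determinant-lemma) identities so
# a likelihood evaluation costs O(n q^2) with q = n_provenances + n_blocks.

# Precompute the crossproducts a likelihood evaluation needs.
lmm_precompute <- function(y, X, provenance, block) {
  provenance <- droplevels(as.factor(provenance))
  block <- droplevels(as.factor(block))
  n <- length(y)
  stopifnot(length(provenance) == n, length(block) == n, nrow(X) == n)
  Zp <- stats::model.matrix(~ 0 + provenance)
  Zb <- stats::model.matrix(~ 0 + block)
  list(
    n = n, p = ncol(X),
    yty = sum(y^2), Xty = crossprod(X, y), XtX = crossprod(X),
    Zp = Zp, Zb = Zb,
    Zpty = crossprod(Zp, y), Zbty = crossprod(Zb, y),
    ZptX = crossprod(Zp, X), ZbtX = crossprod(Zb, X),
    ZptZp = crossprod(Zp), ZbtZb = crossprod(Zb), ZptZb = crossprod(Zp, Zb),
    n_prov = ncol(Zp), n_block = ncol(Zb)
  )
}

# Gaussian (restricted) log-likelihood of y under the two-intercept model,
# with the fixed effects profiled out by GLS. Returns the log-likelihood and
# the GLS pieces at the given variances.
lmm_eval <- function(pc, s2_inter, s2_block, s2_intra, method = "REML") {
  if (!all(is.finite(c(s2_inter, s2_block, s2_intra))) ||
      s2_inter < 0 || s2_block < 0 || s2_intra <= 0) {
    return(NULL)
  }
  vE <- s2_intra
  use_p <- s2_inter > 0
  use_b <- s2_block > 0

  if (!use_p && !use_b) {
    logdetV <- pc$n * log(vE)
    XtViX <- pc$XtX / vE
    XtViy <- pc$Xty / vE
    ytViy <- pc$yty / vE
  } else {
    # scaled random-effect design: Z = [sqrt(s2p) Zp, sqrt(s2b) Zb]
    sp <- sqrt(s2_inter)
    sb <- sqrt(s2_block)
    blocks_ZtZ <- list()
    blocks_Zty <- list()
    blocks_ZtX <- list()
    if (use_p && use_b) {
      ZtZ <- rbind(
        cbind(s2_inter * pc$ZptZp, sp * sb * pc$ZptZb),
        cbind(sp * sb * t(pc$ZptZb), s2_block * pc$ZbtZb)
      )
      Zty <- rbind(sp * pc$Zpty, sb * pc$Zbty)
      ZtX <- rbind(sp * pc$ZptX, sb * pc$ZbtX)
    } else if (use_p) {
      ZtZ <- s2_inter * pc$ZptZp
      Zty <- sp * pc$Zpty
      ZtX <- sp * pc$ZptX
    } else {
      ZtZ <- s2_block * pc$ZbtZb
      Zty <- sb * pc$Zbty
      ZtX <- sb * pc$ZbtX
    }
    q <- nrow(ZtZ)
    A <- ZtZ + diag(vE, q)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    # log|V| = (n - q) log vE + log|A|
    logdetV <- (pc$n - q) * log(vE) + 2 * sum(log(diag(cA)))
    Ainv_Zty <- backsolve(cA, forwardsolve(t(cA), Zty))
    Ainv_ZtX <- backsolve(cA, forwardsolve(t(cA), ZtX))
    XtViX <- (pc$XtX - crossprod(ZtX, Ainv_ZtX)) / vE
    XtViy <- (pc$Xty - crossprod(ZtX, Ainv_Zty)) / vE
    ytViy <- (pc$yty - crossprod(Zty, Ainv_Zty)[1, 1]) / vE
  }

  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  beta <- backsolve(cX, forwardsolve(t(cX), XtViy))
  rss_v <- ytViy - crossprod(XtViy, beta)[1, 1]
  rss_v <- max(rss_v, 0)

  if (method == "REML") {
    ll <- -0.5 * ((pc$n - pc$p) * log(2 * pi) + logdetV +
                    2 * sum(log(diag(cX))) + rss_v)
  } else {
    ll <- -0.5 * (pc$n * log(2 * pi) + logdetV + rss_v)
  }
  list(loglik = ll, beta = drop(beta), cov_beta = chol2inv(cX))
}

#' Restricted or full Gaussian log-likelihood of the two-intercept model
#'
#' Exact (restricted) log-likelihood of a trait vector under
#' \eqn{V = \sigma^2_{inter} Z_P Z_P' + \sigma^2_{block} Z_B Z_B' +
#' \sigma^2_{intra} I}, with the grand mean (or a supplied fixed-effect
#' design) profiled out by generalised least squares. This is the objective
#' maximised by [fit_random_model()].
#'
#' @param y Trait vector (no missing values).
#' @param provenance,block Grouping factors, same length as `y`.
#' @param variances Numeric length 3: `(sigma2_inter, sigma2_block,
#'   sigma2_intra)`; the residual variance must be positive.
#' @param method `"REML"` (default) or `"ML"`.
#' @param X Fixed-effect design matrix; defaults to an intercept column.
#' @return Log-likelihood (scalar).
#' @export
reml_loglik <- function(y, provenance, block, variances,
                        method = c("REML", "ML"), X = NULL) {
  method <- match.arg(method)
  variances <- as.numeric(variances)
  if (length(variances) != 3) stop("variances must have length 3")
  if (all(variances == 0)) stop("all variances zero: singular covariance")
  if (variances[3] <= 0) stop("residual variance must be positive")
  if (any(variances < 0)) stop("variances must be >= 0")
  if (is.null(X)) X <- matrix(1, length(y), 1)
  pc <- lmm_precompute(y, X, provenance, block)
  if (pc$n_prov < 2 || pc$n_block < 2) {
    stop("at least 2 provenances and 2 blocks are required")
  }
  ev <- lmm_eval(pc, variances[1], variances[2], variances[3], method)
  if (is.null(ev)) stop("likelihood evaluation failed (singular system)")
  ev$loglik
}

# Method-of-moments (expected-mean-squares) estimates on a balanced crossed
# design; used for starting values and as an independent oracle in tests.
mom_varcomp <- function(y, provenance, block) {
  provenance <- droplevels(as.factor(provenance))
  block <- droplevels(as.factor(block))
  n <- length(y)
  P <- nlevels(provenance)
  B <- nlevels(block)
  reps_p <- n / P
  reps_b <- n / B
  gm <- mean(y)
  ssp <- reps_p * sum((tapply(y, provenance, mean) - gm)^2)
  ssb <- reps_b * sum((tapply(y, block, mean) - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssp - ssb
  df_e <- n - P - B + 1
  mse <- sse / df_e
  c(
    inter = (ssp / (P - 1) - mse) / reps_p,
    block = (ssb / (B - 1) - mse) / reps_b,
    intra = mse
  )
}

# Maximise the (restricted) likelihood over one face of the non-negativity
# boundary: `free` flags whether (inter, block) are free; residual always is.
optimize_face <- function(pc, free, start, method) {
  idx <- c(free, TRUE)
  if (!any(free)) {
    # no random effects: the optimum is ordinary least squares in closed
    # form. An exactly deterministic fit (zero residual) makes the Gaussian
    # likelihood unbounded; report it as such so this face wins and the
    # fixed effects stay at their exact OLS values.
    rss <- pc$yty - drop(crossprod(pc$Xty, solve(pc$XtX, pc$Xty)))
    rss <- max(rss, 0)
    if (rss <= 1e-10 * max(pc$yty, 1)) {
      vE_deg <- max(rss / pc$n, 1e-12 * max(pc$yty / pc$n, 1))
      return(list(variances = c(0, 0, vE_deg),
                  loglik = Inf, converged = TRUE))
    }
    vE <- if (method == "REML") rss / (pc$n - pc$p) else rss / pc$n
    ev <- lmm_eval(pc, 0, 0, vE, method)
    return(list(variances = c(0, 0, vE), loglik = ev$loglik,
                converged = TRUE))
  }
  obj <- function(par) {
    v <- c(0, 0, 0)
    v[idx] <- exp(par)
    ev <- lmm_eval(pc, v[1], v[2], v[3], method)
    if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
    -ev$loglik
  }
  par0 <- log(pmax(start[idx], 1e-8))
  if (length(par0) == 1) {
    o <- stats::optimize(obj, lower = par0 - 25, upper = par0 + 25,
                         tol = 1e-12)
    opt <- list(par = o$minimum, value = o$objective, convergence = 0)
  } else {
    opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-13))
    pol <- tryCatch(
      stats::optim(opt$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(pol) && pol$value <= opt$value) opt <- pol
  }
  v <- c(0, 0, 0)
  v[idx] <- exp(opt$par)
  list(variances = v, loglik = -opt$value,
       converged = opt$convergence %in% c(0, 10))
}

# Full fitting engine over all boundary faces; X is the fixed-effect design.
lmm_fit <- function(y, X, provenance, block, method) {
  pc <- lmm_precompute(y, X, provenance, block)
  if (pc$n_prov < 2 || pc$n_block < 2) {
    stop("at least 2 provenances and 2 blocks are required")
  }
  # starting values: expected-mean-squares estimates, clipped positive
  mom <- mom_varcomp(y, provenance, block)
  vE0 <- max(mom["intra"], stats::var(y) / 10, 1e-8)
  start <- c(max(mom["inter"], vE0 / 10), max(mom["block"], vE0 / 10), vE0)

  faces <- list(c(TRUE, TRUE), c(FALSE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE))
  fits <- lapply(faces, function(fr) optimize_face(pc, fr, start, method))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  # prefer the face with more components pinned at zero when log-likelihoods
  # tie (a true boundary optimum): gives exact zeros rather than 1e-12s
  best_ll <- max(lls)
  n_zero <- vapply(faces, function(fr) sum(!fr), numeric(1))
  cand <- which(lls >= best_ll - 1e-7)
  best <- cand[which.max(n_zero[cand])]
  fit <- fits[[best]]

  ev <- lmm_eval(pc, fit$variances[1], fit$variances[2], fit$variances[3], method)
  list(
    variances = stats::setNames(fit$variances, c("inter", "block", "intra")),
    beta = ev$beta, cov_beta = ev$cov_beta,
    loglik = fit$loglik, method = method, converged = fit$converged,
    n = pc$n
  )
}

#' Fit the random-effects trait model
#'
#' Maximises the (restricted) likelihood of
#' \eqn{Y_{ijk} = \mu + P_i + b_j + \epsilon_{ijk}} over the variance
#' components \eqn{(\sigma^2_{inter}, \sigma^2_{block}, \sigma^2_{intra})}
#' under the non-negativity constraint. Optimisation runs on the
#' log-variance scale and every zero-variance boundary face is evaluated
#' explicitly, so boundary estimates come out as exact zeros - the situation
#' the halved-p likelihood-ratio test ([lrt_provenance()]) is designed for.
#'
#' @param y Trait vector; missing values are dropped (complete-case).
#' @param provenance,block Grouping factors.
#' @param method `"REML"` (default) or `"ML"`.
#' @param components Random intercepts to include: the default fits both;
#'   `"block"` fits the reduced model without the provenance component (the
#'   null model of the provenance LRT).
#' @return Object of class `ranmod_fit`: `mu`, `sigma2` (named length-3;
#'   excluded components are fixed at zero), `loglik`, `method`,
#'   `converged`, `n`, `components`.
#' @export
fit_random_model <- function(y, provenance, block, method = c("REML", "ML"),
                             components = c("provenance", "block")) {
  method <- match.arg(method)
  components <- match.arg(components, c("provenance", "block"),
                          several.ok = TRUE)
  keep <- is.finite(y)
  y <- y[keep]
  provenance <- droplevels(as.factor(provenance[keep]))
  block <- droplevels(as.factor(block[keep]))
  X <- matrix(1, length(y), 1)

  if (setequal(components, c("provenance", "block"))) {
    fit <- lmm_fit(y, X, provenance, block, method)
  } else {
    # reduced model: constrain the dropped component's faces to zero
    pc <- lmm_precompute(y, X, provenance, block)
    drop_prov <- !("provenance" %in% components)
    free_main <- if (drop_prov) c(FALSE, TRUE) else c(TRUE, FALSE)
    mom <- mom_varcomp(y, provenance, block)
    vE0 <- max(mom["intra"], stats::var(y) / 10, 1e-8)
    start <- c(max(mom["inter"], vE0 / 10), max(mom["block"], vE0 / 10), vE0)
    fits <- list(
      optimize_face(pc, free_main, start, method),
      optimize_face(pc, c(FALSE, FALSE), start, method)
    )
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    best <- if (lls[2] >= lls[1] - 1e-7) 2L else 1L
    f <- fits[[best]]
    ev <- lmm_eval(pc, f$variances[1], f$variances[2], f$variances[3], method)
    fit <- list(
      variances = stats::setNames(f$variances, c("inter", "block", "intra")),
      beta = ev$beta, cov_beta = ev$cov_beta, loglik = f$loglik,
      method = method, converged = f$converged, n = pc$n
    )
  }

  out <- list(
    mu = unname(fit$beta[1]), sigma2 = fit$variances, loglik = fit$loglik,
    method = method, converged = fit$converged, n = fit$n,
    components = components
  )
  class(out) <- "ranmod_fit"
  out
}

#' @export
print.ranmod_fit <- function(x, ...) {
  cat("Random-effects trait model (", x$method, ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mu = %.4f\n", x$mu))
  cat(sprintf("  sigma2: inter = %.4g, block = %.4g, intra = %.4g\n",
              x$sigma2["inter"], x$sigma2["block"], x$sigma2["intra"]))
  cat(sprintf("  logLik = %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Boundary-corrected likelihood-ratio test for provenance differentiation
#'
#' Compares the full random model (provenance + block) with the reduced
#' model lacking the provenance component. Because the null value
#' \eqn{\sigma^2_{inter} = 0} lies on the boundary of the parameter space,
#' the LRT statistic follows a 50:50 mixture of a point mass at zero and
#' \eqn{\chi^2_1}; the chi-square tail probability is therefore halved.
#' At LR = 0 the corrected p-value is exactly 0.5.
#'
#' @param full,reduced `ranmod_fit` objects fitted to the same data with the
#'   same method; `reduced` must lack the provenance component.
#' @return List of class `provenance_lrt`: `lr` (statistic, clipped at 0),
#'   `delta_aic` (LR - 2, the AIC difference for the one extra parameter),
#'   `p_corrected` (halved chi-square tail, in (0, 0.5\]).
#' @export
lrt_provenance <- function(full, reduced) {
  stopifnot(inherits(full, "ranmod_fit"), inherits(reduced, "ranmod_fit"))
  if (full$method != reduced$method) stop("fits use different methods")
  if (full$n != reduced$n) stop("fits use different data")
  if ("provenance" %in% reduced$components &&
      setequal(reduced$components, c("provenance", "block"))) {
    stop("reduced model must lack the provenance component")
  }
  lr <- max(0, 2 * (full$loglik - reduced$loglik))
  out <- list(
    lr = lr,
    delta_aic = lr - 2,
    p_corrected = 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  )
  class(out) <- "provenance_lrt"
  out
}

#' @export
print.provenance_lrt <- function(x, ...) {
  cat(sprintf("Provenance LRT: LR = %.3f, delta AIC = %.3f, P (boundary-corrected) = %.4g\n",
              x$lr, x$delta_aic, x$p_corrected))
  invisible(x)
}

#' Inter- and intra-provenance coefficients of variation
#'
#' `cv_inter` is the standard deviation of the provenance means over the
#' grand mean; `cv_intra` summarises within-provenance spread relative to
#' the same grand mean, either as the mean of the per-provenance SDs
#' (default) or as the pooled within-provenance SD. Sample (n-1) standard
#' deviations throughout.
#'
#' @param y Trait vector; missing values dropped.
#' @param provenance Provenance factor.
#' @param intra `"mean_within_sd"` (default) or `"pooled"`.
#' @return Named list `cv_inter`, `cv_intra` (percent). `NA` with a warning
#'   if the grand mean is zero.
#' @export
cv_components <- function(y, provenance, intra = c("mean_within_sd", "pooled")) {
  intra <- match.arg(intra)
  keep <- is.finite(y)
  y <- y[keep]
  provenance <- droplevels(as.factor(provenance[keep]))
  if (nlevels(provenance) < 2) stop("at least 2 provenances are required")
  gm <- mean(y)
  if (gm == 0) {
    warning("grand mean is zero: CVs undefined")
    return(list(cv_inter = NA_real_, cv_intra = NA_real_))
  }
  prov_means <- tapply(y, provenance, mean)
  cv_inter <- stats::sd(prov_means) / abs(gm) * 100
  within_sd <- tapply(y, provenance, stats::sd)
  cv_intra <- if (intra == "mean_within_sd") {
    mean(within_sd, na.rm = TRUE) / abs(gm) * 100
  } else {
    ns <- tapply(y, provenance, length)
    sqrt(sum((ns - 1) * within_sd^2, na.rm = TRUE) / sum(ns - 1)) / abs(gm) * 100
  }
  list(cv_inter = cv_inter, cv_intra = cv_intra)
}

#' Variance components as percentages of the total
#'
#' @param fit A `ranmod_fit` object (or a numeric length-3 vector of
#'   variances `(inter, block, intra)`).
#' @return Named numeric: `vc_inter`, `vc_block`, `vc_intra`, each a
#'   percentage; they sum to 100.
#' @export
variance_component_percents <- function(fit) {
  s2 <- if (inherits(fit, "ranmod_fit")) fit$sigma2 else as.numeric(fit)
  if (length(s2) != 3 || any(s2 < 0)) stop("need 3 non-negative variances")
  tot <- sum(s2)
  if (tot == 0) stop("all variance components are zero: percentages undefined")
  stats::setNames(100 * s2 / tot, c("vc_inter", "vc_block", "vc_intra"))
}

#' Climate-of-origin fixed-effect model
#'
#' Adds the forest aridity index of the provenance origin as a fixed
#' covariate to the random trait model,
#' \eqn{Y_{ijk} = \alpha + \beta\,FAI_i + P_i + b_j + \epsilon_{ijk}},
#' and tests the climate effect by a maximum-likelihood LRT against the
#' model without FAI (both keep the full random structure).
#'
#' @param y Trait vector; missing values dropped.
#' @param fai FAI value per observation (constant within provenance).
#' @param provenance,block Grouping factors.
#' @param log_transform If `TRUE`, `y` is natural-log transformed before
#'   fitting (used for right-skewed ratio traits such as leaf-specific
#'   conductivities and the Huber value).
#' @return Object of class `climate_fit`: `alpha`, `beta`, `se_alpha`,
#'   `se_beta`, `sd_prov`, `sd_block`, `sd_resid`, `loglik`,
#'   `loglik_reduced`, `lr`, `delta_aic`, `p`, `n`.
#' @export
fit_climate_model <- function(y, fai, provenance, block,
                              log_transform = FALSE) {
  keep <- is.finite(y) & is.finite(fai)
  y <- y[keep]
  fai <- fai[keep]
  provenance <- droplevels(as.factor(provenance[keep]))
  block <- droplevels(as.factor(block[keep]))
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires positive trait values")
    y <- log(y)
  }
  # the covariate must be a provenance-level quantity with some spread
  by_prov <- tapply(fai, provenance, function(v) diff(range(v)))
  if (any(by_prov > 1e-10)) stop("fai must be constant within provenance")
  if (stats::sd(tapply(fai, provenance, mean)) == 0) {
    stop("fai is identical across provenances: slope not estimable")
  }

  X_full <- cbind(1, fai)
  full <- lmm_fit(y, X_full, provenance, block, "ML")
  reduced <- lmm_fit(y, matrix(1, length(y), 1), provenance, block, "ML")
  lr <- max(0, 2 * (full$loglik - reduced$loglik))
  se <- sqrt(diag(full$cov_beta))
  out <- list(
    alpha = unname(full$beta[1]), beta = unname(full$beta[2]),
    se_alpha = se[1], se_beta = se[2],
    sd_prov = sqrt(full$variances["inter"]),
    sd_block = sqrt(full$variances["block"]),
    sd_resid = sqrt(full$variances["intra"]),
    loglik = full$loglik, loglik_reduced = reduced$loglik,
    lr = lr, delta_aic = lr - 2,
    p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
    n = full$n, converged = full$converged && reduced$converged,
    log_transform = log_transform
  )
  class(out) <- "climate_fit"
  out
}

#' @export
print.climate_fit <- function(x, ...) {
  cat("Climate-of-origin mixed model (ML, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  alpha = %.3f +/- %.3f, beta(FAI) = %.4f +/- %.4f\n",
              x$alpha, x$se_alpha, x$beta, x$se_beta))
  cat(sprintf("  SD: prov = %.3f, block = %.3f, resid = %.3f\n",
              x$sd_prov, x$sd_block, x$sd_resid))
  cat(sprintf("  LR = %.3f, P = %.4g\n", x$lr, x$p))
  invisible(x)
}

#' Per-trait variance partitioning table
#'
#' Runs the full REML variance decomposition for each trait column of a
#' tree-level trait table: CV components, variance-component percentages,
#' and the boundary-corrected provenance LRT. Missing values are dropped
#' per trait (complete-case within column).
#'
#' @param traits Data frame with `provenance` and `block` columns plus one
#'   column per trait.
#' @param trait_cols Character vector of trait column names; default all
#'   numeric columns other than the design columns.
#' @param log_traits Traits natural-log transformed before model fitting
#'   (CVs are still reported on the original scale).
#' @param intra Passed to [cv_components()].
#' @return Data frame, one row per trait: `trait`, `n`, `cv_inter`,
#'   `cv_intra`, `vc_inter`, `vc_block`, `vc_intra`, `delta_aic`, `lr`,
#'   `p_corrected`.
#' @export
varcomp_table <- function(traits, trait_cols = NULL, log_traits = character(),
                          intra = "mean_within_sd") {
  stopifnot(all(c("provenance", "block") %in% names(traits)))
  if (is.null(trait_cols)) {
    num <- vapply(traits, is.numeric, logical(1))
    trait_cols <- setdiff(names(traits)[num], c("provenance", "block"))
  }
  rows <- lapply(trait_cols, function(tc) {
    y <- traits[[tc]]
    keep <- is.finite(y)
    yk <- y[keep]
    pv <- traits$provenance[keep]
    bl <- traits$block[keep]
    ym <- if (tc %in% log_traits) log(yk) else yk
    full <- fit_random_model(ym, pv, bl, method = "REML")
    red <- fit_random_model(ym, pv, bl, method = "REML",
                            components = "block")
    test <- lrt_provenance(full, red)
    vc <- variance_component_percents(full)
    cv <- cv_components(yk, pv, intra = intra)
    data.frame(
      trait = tc, n = full$n,
      cv_inter = cv$cv_inter, cv_intra = cv$cv_intra,
      vc_inter = unname(vc["vc_inter"]), vc_block = unname(vc["vc_block"]),
      vc_intra = unname(vc["vc_intra"]),
      delta_aic = test$delta_aic, lr = test$lr,
      p_corrected = test$p_corrected
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-trait climate-of-origin model table
#'
#' Fits [fit_climate_model()] for each trait column, producing the tabular
#' summary of how strongly each trait tracks the aridity of the seed
#' source.
#'
#' @inheritParams varcomp_table
#' @param fai_by_provenance Data frame with columns `provenance` and `fai`.
#' @return Data frame, one row per trait: `trait`, `n`, `alpha`,
#'   `se_alpha`, `beta`, `se_beta`, `sd_prov`, `sd_block`, `sd_resid`,
#'   `delta_aic`, `lr`, `p`.
#' @export
climate_model_table <- function(traits, fai_by_provenance, trait_cols = NULL,
                                log_traits = character()) {
  stopifnot(all(c("provenance", "block") %in% names(traits)),
            all(c("provenance", "fai") %in% names(fai_by_provenance)))
  if (is.null(trait_cols)) {
    num <- vapply(traits, is.numeric, logical(1))
    trait_cols <- setdiff(names(traits)[num], c("provenance", "block"))
  }
  fai <- fai_by_provenance$fai[match(traits$provenance,
                                     fai_by_provenance$provenance)]
  if (any(is.na(fai))) stop("some provenances lack an FAI value")
  rows <- lapply(trait_cols, function(tc) {
    fit <- fit_climate_model(traits[[tc]], fai, traits$provenance,
                             traits$block,
                             log_transform = tc %in% log_traits)
    data.frame(
      trait = tc, n = fit$n,
      alpha = fit$alpha, se_alpha = fit$se_alpha,
      beta = fit$beta, se_beta = fit$se_beta,
      sd_prov = unname(fit$sd_prov), sd_block = unname(fit$sd_block),
      sd_resid = unname(fit$sd_resid),
      delta_aic = fit$delta_aic, lr = fit$lr, p = fit$p
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
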