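#' Percent loss of conductivity from a conductance measurement
#'
#' @param k Measured conductance at the current pressure step (same units as
#'   `k_max`). Small overshoots above `k_max` are clipped.
#' @param k_max Maximum (embolism-free) conductance, > 0.
#' @return PLC in percent, clipped to \[0, 100\].
#' @export
plc_from_conductance <- function(k, k_max) {
  if (!is.finite(k_max) || k_max <= 0) stop("k_max must be positive")
  if (any(k < 0, na.rm = TRUE)) stop("conductance must be >= 0")
  pmin(pmax(100 * (1 - k / k_max), 0), 100)
}

#' Sigmoid vulnerability curve
#'
#' The two-parameter logistic relating percent loss of conductivity to xylem
#' pressure, \eqn{PLC = 100 / (1 + \exp(s/25 \, (P - P_{50})))}. With the
#' tension sign convention (pressures negative), PLC rises towards 100 as
#' the pressure becomes more negative and passes 50 exactly at `p50`.
#'
#' @param p Xylem pressure, MPa (negative = tension). Vectorised.
#' @param p50 Pressure at 50 percent loss of conductivity, MPa.
#' @param s Slope of the curve at the inflexion point, percent per MPa (> 0).
#' @return PLC in percent, in (0, 100).
#' @export
sigmoid_plc <- function(p, p50, s) {
  if (!is.finite(s) || s <= 0) stop("slope s must be positive")
  100 / (1 + exp(s / 25 * (p - p50)))
}

#' Pressure producing a target percent loss of conductivity
#'
#' Analytic inverse of [sigmoid_plc()]:
#' \eqn{P = P_{50} + (25/s) \log((100 - t)/t)}. Used to derive the P12 and
#' P88 cavitation thresholds from a fitted curve.
#'
#' @param fit A `vuln_fit` object from [fit_vulnerability_curve()], or a
#'   numeric `p50` (then `s` must be given).
#' @param target Target PLC in percent, strictly between 0 and 100.
#' @param s Slope, percent per MPa; only when `fit` is numeric.
#' @return Pressure in MPa.
#' @export
pressure_at_plc <- function(fit, target, s = NULL) {
  if (inherits(fit, "vuln_fit")) {
    p50 <- fit$p50
    s <- fit$s
  } else {
    p50 <- fit
    if (is.null(s)) stop("s must be supplied when fit is a numeric p50")
  }
  if (any(target <= 0 | target >= 100)) stop("target PLC must be in (0, 100)")
  if (!is.finite(s) || s <= 0) stop("slope s must be positive")
  p50 + 25 / s * log((100 - target) / target)
}

#' Fit a sigmoid vulnerability curve to PLC measurements
#'
#' Least-squares fit of the two-parameter logistic vulnerability curve on
#' the PLC scale, with multi-start initialisation: the starting `p50` is
#' the measured pressure whose PLC lies nearest 50, the starting slope is
#' taken from a central finite-difference of PLC against pressure, and both
#' are perturbed over a coarse grid before local optimisation. P12 and P88
#' are filled in by analytic inversion of the fitted curve.
#'
#' Quality control follows common vulnerability-curve practice: a fit passes
#' (`qc_pass`) only if the measured points span PLC below `qc_span[1]` and
#' above `qc_span[2]` and the maximum measured PLC reaches `qc_max_plc`
#' (the measurement stopping rule).
#'
#' @param pressure Xylem pressures, MPa, strictly decreasing (tension sign
#'   convention: negative values). Use `tension_positive = TRUE` for data
#'   recorded with positive tensions.
#' @param plc Percent loss of conductivity at each pressure, in \[0, 100\].
#' @param qc_span Numeric length-2: required PLC coverage (default below 30
#'   and above 70).
#' @param qc_max_plc Minimum maximum PLC for a pass (default 90).
#' @param tension_positive Set `TRUE` if pressures are recorded as positive
#'   tensions; they are negated on input.
#' @return An object of class `vuln_fit`: list with `p50`, `s`, `p12`,
#'   `p88`, `rss`, `max_plc_reached`, `qc_pass`, `converged`, `n_points`,
#'   `fitted`.
#' @export
fit_vulnerability_curve <- function(pressure, plc, qc_span = c(30, 70),
                                    qc_max_plc = 90,
                                    tension_positive = FALSE) {
  if (tension_positive) pressure <- -pressure
  if (any(pressure > 0)) {
    stop("pressures must be negative (tension); see tension_positive")
  }
  ok <- is.finite(pressure) & is.finite(plc)
  pressure <- pressure[ok]
  plc <- plc[ok]
  if (any(diff(pressure) >= 0)) stop("pressures must be strictly decreasing")
  if (any(plc < 0 | plc > 100)) stop("PLC values must lie in [0, 100]")
  n <- length(pressure)

  qc_pass <- n >= 4 &&
    any(plc < qc_span[1]) && any(plc > qc_span[2]) &&
    max(plc) >= qc_max_plc

  out <- list(
    p50 = NA_real_, s = NA_real_, p12 = NA_real_, p88 = NA_real_,
    rss = NA_real_, max_plc_reached = max(plc), qc_pass = FALSE,
    converged = FALSE, n_points = n, fitted = rep(NA_real_, n)
  )
  class(out) <- "vuln_fit"
  if (n < 2 || stats::sd(plc) == 0) return(out)  # degenerate: flagged, no fit

  rss_fun <- function(par) {            # par = (p50, log s)
    sum((plc - sigmoid_plc(pressure, par[1], exp(par[2])))^2)
  }

  # data-driven starting values
  p50_0 <- pressure[which.min(abs(plc - 50))]
  mid <- which.min(abs(plc - 50))
  s_0 <- NA_real_
  if (mid > 1 && mid < n) {
    slope <- (plc[mid + 1] - plc[mid - 1]) / (pressure[mid + 1] - pressure[mid - 1])
    s_0 <- -slope * (25 * 4 / 100)      # invert the inflexion-point derivative
  }
  if (!is.finite(s_0) || s_0 <= 0) s_0 <- 30
  starts <- expand.grid(
    p50 = unique(c(p50_0, p50_0 - 0.5, p50_0 + 0.5, mean(range(pressure)))),
    s = unique(c(s_0, 15, 40, 90))
  )

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- try(stats::optim(
      c(starts$p50[i], log(starts$s[i])), rss_fun,
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12)
    ), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(out)

  # polish with BFGS from the best Nelder-Mead solution
  pol <- try(stats::optim(best$par, rss_fun, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
             silent = TRUE)
  if (!inherits(pol, "try-error") && pol$value <= best$value) best <- pol

  out$p50 <- best$par[1]
  out$s <- exp(best$par[2])
  out$rss <- best$value
  out$converged <- TRUE
  out$p12 <- pressure_at_plc(out$p50, 12, s = out$s)
  out$p88 <- pressure_at_plc(out$p50, 88, s = out$s)
  out$fitted <- sigmoid_plc(pressure, out$p50, out$s)
  out$qc_pass <- qc_pass
  out
}

#' @export
print.vuln_fit <- function(x, ...) {
  cat("Sigmoid vulnerability curve fit (", x$n_points, " points)\n", sep = "")
  if (x$converged) {
    cat(sprintf("  P50 = %.3f MPa, slope = %.1f %%/MPa (RSS = %.2f)\n",
                x$p50, x$s, x$rss))
    cat(sprintf("  P12 = %.3f, P88 = %.3f MPa\n", x$p12, x$p88))
  } else {
    cat("  fit did not converge (degenerate or insufficient data)\n")
  }
  cat(sprintf("  max PLC reached: %.1f%%; QC %s\n", x$max_plc_reached,
              if (isTRUE(x$qc_pass)) "pass" else "FAIL"))
  invisible(x)
}

#' Empirical specific and leaf-specific conductivity
#'
#' Normalises a measured branch hydraulic conductivity by sapwood area
#' (`KS_emp`, per the basipetal maximal sapwood area) and by distal leaf
#' area (`KL_emp`).
#'
#' @param k_h Hydraulic conductivity of the segment, kg m MPa^-1 s^-1 (>= 0).
#' @param a_xylem_m2 Sapwood area, m^2 (> 0).
#' @param a_leaf_m2 Cumulative distal leaf area, m^2, or `NA`.
#' @return One-row data frame with `ks_emp` and `kl_emp`
#'   (kg m^-1 MPa^-1 s^-1; `kl_emp` is `NA` when leaf area is absent).
#' @export
empirical_conductivities <- function(k_h, a_xylem_m2, a_leaf_m2 = NA) {
  if (!is.finite(a_xylem_m2) || a_xylem_m2 <= 0) stop("a_xylem_m2 must be positive")
  if (k_h < 0) stop("k_h must be >= 0")
  kl <- NA_real_
  if (!is.na(a_leaf_m2)) {
    if (a_leaf_m2 <= 0) stop("a_leaf_m2 must be positive when supplied")
    kl <- k_h / a_leaf_m2
  }
  data.frame(ks_emp = k_h / a_xylem_m2, kl_emp = kl)
}
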