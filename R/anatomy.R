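#' Physical constants for Hagen-Poiseuille conductivity
#'
#' Viscosity and density of water at 20 degrees C, the reference temperature
#' for theoretical conductivity calculations.
#'
#' @format A list with elements `eta` (viscosity of water, 1.002e-9 MPa s)
#'   and `rho` (density of water, 998.2 kg m^-3).
#' @export
water_constants <- list(eta = 1.002e-9, rho = 998.2)

#' Idealized vessel diameter from elliptical lumen radii
#'
#' Converts the major (`a`) and minor (`b`) radii of an elliptical vessel
#' lumen into the diameter of the circular conduit with equivalent
#' Hagen-Poiseuille conductance, \eqn{D = (32 (ab)^3 / (a^2 + b^2))^{1/4}}.
#' For a circular lumen (`a == b`) this reduces to `2 * a`.
#'
#' @param a Major radius, um. Vectorised.
#' @param b Minor radius, um. Vectorised (recycled against `a`).
#' @return Idealized diameter(s), um.
#' @details If `a < b` the radii are swapped with a warning: digitisation
#'   software does not guarantee axis ordering. Non-positive radii are an
#'   error.
#' @examples
#' ellipse_diameter(10, 10)  # 20: circle limit
#' ellipse_diameter(15, 5)
#' @export
ellipse_diameter <- function(a, b) {
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
  }
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    stop("vessel radii must be positive and finite")
  }
  swap <- a < b
  if (any(swap)) {
    warning(sum(swap), " vessel record(s) had a < b; radii swapped")
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  (32 * (a * b)^3 / (a^2 + b^2))^0.25
}

#' Hydraulically weighted vessel diameter
#'
#' \eqn{D_h = \sum D^5 / \sum D^4}: the diameter weighting each vessel by its
#' contribution to total conductance. Always at least the arithmetic mean,
#' with equality only for uniform populations.
#'
#' @param d Vector of vessel diameters, um. Must be non-empty and positive.
#' @return Hydraulically weighted diameter, um.
#' @export
hydraulic_diameter <- function(d) {
  if (length(d) == 0) stop("empty diameter list")
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameters must be positive and finite")
  sum(d^5) / sum(d^4)
}

#' Sapwood area from full cross-section area
#'
#' Species-specific linear regression for beech branch segments,
#' `A_xylem = -3.715 + 0.770 * A_cross`, used when sapwood area was not
#' delineated directly.
#'
#' @param a_cross_mm2 Full cross-section area (without bark), mm^2. Vectorised.
#' @return Sapwood (xylem) area, mm^2, guaranteed positive.
#' @export
sapwood_from_cross_section <- function(a_cross_mm2) {
  root <- 3.715 / 0.770
  if (any(!is.finite(a_cross_mm2)) || any(a_cross_mm2 <= root)) {
    stop(sprintf(
      "cross-section area must exceed %.4f mm^2 for a positive sapwood area",
      root
    ))
  }
  -3.715 + 0.770 * a_cross_mm2
}

# Hagen-Poiseuille numerator (pi * sum(D^4) / (128 eta)) * rho, with D in m.
# Returns kg m MPa^-1 s^-1; divide by an area in m^2 for a specific conductivity.
hp_numerator <- function(d_um) {
  d_m <- d_um * 1e-6
  (pi * sum(d_m^4) / (128 * water_constants$eta)) * water_constants$rho
}

#' Vessel-based anatomical traits for one branch cross-section
#'
#' Derives the standard vessel-population traits from a set of vessel
#' diameters and the sapwood area of the analysed cross-section: mean and
#' hydraulically weighted diameter, vessel density, lumen-to-sapwood area
#' ratio, theoretical specific conductivity (Hagen-Poiseuille), theoretical
#' leaf-specific conductivity, and annual sapwood area increment.
#'
#' @param vessels Data frame with columns `a_um` and `b_um` (major/minor
#'   radii, um), or a numeric vector of idealized diameters (um).
#' @param a_xylem_mm2 Sapwood area of the cross-section, mm^2 (> 0).
#' @param branch_age_yr Branch age as ring count (>= 1), or `NA` to skip
#'   `a_growth`.
#' @param a_leaf_m2 Cumulative leaf area distal to the section, m^2, or `NA`
#'   to skip `kl_theo`. A zero leaf area yields `NA` (missing), not zero.
#' @param lumen_area How to compute the lumen area of a vessel:
#'   `"idealized"` (default) uses \eqn{\pi (D/2)^2} from the idealized
#'   diameter; `"ellipse"` uses \eqn{\pi a b} and requires radii input.
#' @return One-row data frame: `n_vessels`, `d_mean_um`, `d_h_um`,
#'   `vd_n_mm2`, `lumen_fraction_pct`, `ks_theo`, `kl_theo` (both
#'   kg m^-1 MPa^-1 s^-1), `a_growth_mm2_yr`.
#' @export
cross_section_traits <- function(vessels, a_xylem_mm2, branch_age_yr = NA,
                                 a_leaf_m2 = NA,
                                 lumen_area = c("idealized", "ellipse")) {
  lumen_area <- match.arg(lumen_area)
  if (!is.finite(a_xylem_mm2) || a_xylem_mm2 <= 0) {
    stop("a_xylem_mm2 must be positive")
  }
  if (is.data.frame(vessels)) {
    stopifnot(all(c("a_um", "b_um") %in% names(vessels)))
    d <- ellipse_diameter(vessels$a_um, vessels$b_um)
    lumen_um2 <- switch(lumen_area,
      idealized = pi * (d / 2)^2,
      ellipse = pi * vessels$a_um * vessels$b_um
    )
  } else {
    d <- as.numeric(vessels)
    if (lumen_area == "ellipse") {
      stop("lumen_area = \"ellipse\" requires a data frame of radii")
    }
    lumen_um2 <- pi * (d / 2)^2
  }
  if (length(d) < 1) stop("at least one vessel is required")
  if (any(d <= 0)) stop("diameters must be positive")
  if (!is.na(branch_age_yr) && branch_age_yr < 1) {
    stop("branch_age_yr must be >= 1")
  }

  numer <- hp_numerator(d)          # kg m MPa^-1 s^-1
  a_xylem_m2 <- a_xylem_mm2 * 1e-6
  kl <- NA_real_
  if (!is.na(a_leaf_m2)) {
    if (a_leaf_m2 < 0) stop("a_leaf_m2 must be >= 0")
    if (a_leaf_m2 > 0) kl <- numer / a_leaf_m2
  }
  data.frame(
    n_vessels = length(d),
    d_mean_um = mean(d),
    d_h_um = hydraulic_diameter(d),
    vd_n_mm2 = length(d) / a_xylem_mm2,
    lumen_fraction_pct = sum(lumen_um2) / (a_xylem_mm2 * 1e6) * 100,
    ks_theo = numer / a_xylem_m2,
    kl_theo = kl,
    a_growth_mm2_yr = if (is.na(branch_age_yr)) NA_real_ else a_xylem_mm2 / branch_age_yr
  )
}

#' Foliar morphological traits
#'
#' Mean leaf size, specific leaf area and the Huber value (sapwood to leaf
#' area ratio) from branch-level leaf harvest data; measured chemistry
#' columns are passed through unchanged.
#'
#' @param total_leaf_area_cm2 Cumulative scanned leaf area, cm^2.
#' @param leaf_dry_mass_g Total leaf dry mass, g (>= 0). Zero mass gives a
#'   missing SLA rather than infinity.
#' @param n_leaves Number of leaves scanned (>= 1).
#' @param a_sapwood_m2 Branch sapwood area, m^2.
#' @param a_leaf_m2 Cumulative leaf area, m^2.
#' @param chemistry Optional named list/data.frame of measured foliar columns
#'   (e.g. `cn_ratio`, `d13c`, `ca_mass`), echoed into the result.
#' @return One-row data frame: `a_leaf_cm2`, `sla_cm2_g`, `huber_1e4`
#'   (Huber value in units of 1e-4 m^2 m^-2) plus any chemistry columns.
#' @export
foliar_traits <- function(total_leaf_area_cm2, leaf_dry_mass_g, n_leaves,
                          a_sapwood_m2, a_leaf_m2, chemistry = NULL) {
  if (n_leaves < 1) stop("n_leaves must be >= 1")
  if (leaf_dry_mass_g < 0 || total_leaf_area_cm2 < 0) {
    stop("leaf area and mass must be >= 0")
  }
  if (a_leaf_m2 <= 0 || a_sapwood_m2 <= 0) {
    stop("sapwood and leaf areas must be positive for the Huber value")
  }
  out <- data.frame(
    a_leaf_cm2 = total_leaf_area_cm2 / n_leaves,
    sla_cm2_g = if (leaf_dry_mass_g > 0) total_leaf_area_cm2 / leaf_dry_mass_g else NA_real_,
    huber_1e4 = (a_sapwood_m2 / a_leaf_m2) / 1e-4
  )
  if (!is.null(chemistry)) out <- cbind(out, as.data.frame(as.list(chemistry)))
  out
}
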