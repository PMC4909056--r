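#' Simulate a balanced provenance-trial trait table
#'
#' Generates tree-level trait values under the additive random-effects model
#' \eqn{Y_{ijk} = \mu + P_i + b_j + \epsilon_{ijk}} with independent Gaussian
#' provenance, block and residual effects - the generating model assumed by
#' the variance-partitioning machinery, so recovery can be checked exactly.
#'
#' @param specs Named list of trait specifications; each element is a list
#'   with `mean`, `sd_provenance`, `sd_block`, `sd_residual` and optional
#'   `lognormal` (if `TRUE`, the additive model operates on the log scale
#'   and the result is exponentiated).
#' @param n_provenances,n_blocks,n_trees Design: number of provenances,
#'   blocks, and trees per provenance-by-block cell. Default 10 x 3 x 4, a
#'   balanced version of a three-block replicated beech trial.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return Data frame with `tree_id`, `provenance` (factor `P01`...),
#'   `block` (factor `B1`...), and one column per trait.
#' @examples
#' tab <- simulate_trial(
#'   list(dbh = list(mean = 12, sd_provenance = 1.5,
#'                   sd_block = 0.5, sd_residual = 1.5)),
#'   seed = 1
#' )
#' head(tab)
#' @export
simulate_trial <- function(specs, n_provenances = 10, n_blocks = 3,
                           n_trees = 4, seed) {
  stopifnot(n_provenances >= 1, n_blocks >= 1, n_trees >= 1)
  if (missing(seed)) stop("seed is required")
  if (!is.list(specs) || is.null(names(specs)) || any(names(specs) == "")) {
    stop("specs must be a named list of trait specifications")
  }
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    sds <- c(sp$sd_provenance, sp$sd_block, sp$sd_residual)
    if (length(sds) != 3 || any(!is.finite(sds)) || any(sds < 0)) {
      stop("trait '", nm, "': sd_provenance, sd_block, sd_residual must be >= 0")
    }
    if (is.null(sp$mean) || !is.finite(sp$mean)) {
      stop("trait '", nm, "': mean is required")
    }
  }

  set.seed(seed)
  prov <- factor(sprintf("P%02d", rep(seq_len(n_provenances),
                                      each = n_blocks * n_trees)))
  block <- factor(sprintf("B%d", rep(rep(seq_len(n_blocks), each = n_trees),
                                     times = n_provenances)))
  n <- length(prov)
  out <- data.frame(
    tree_id = sprintf("T%04d", seq_len(n)),
    provenance = prov,
    block = block
  )
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    p_eff <- stats::rnorm(n_provenances, 0, sp$sd_provenance)
    b_eff <- stats::rnorm(n_blocks, 0, sp$sd_block)
    eps <- stats::rnorm(n, 0, sp$sd_residual)
    y <- sp$mean + p_eff[as.integer(prov)] + b_eff[as.integer(block)] + eps
    if (isTRUE(sp$lognormal)) y <- exp(y)
    out[[nm]] <- y
  }
  out
}

#' Simulate a vessel population for one branch cross-section
#'
#' Major-axis vessel diameters are drawn from a lognormal distribution
#' (strictly positive and right-skewed, like real xylem); the minor radius
#' is the major radius times a uniform eccentricity draw. Defaults target a
#' mean idealized diameter near 24 um, the scale typical of young beech
#' branch xylem.
#'
#' @param n_vessels Number of vessels (>= 1).
#' @param log_mean_diameter Mean of log major-axis diameter (log um).
#' @param log_sd_diameter SD of log major-axis diameter (>= 0).
#' @param eccentricity_range Length-2 vector, minor/major ratio bounds in
#'   (0, 1].
#' @param seed Integer seed.
#' @return Data frame with `a_um`, `b_um` (major/minor radii) and `d_um`
#'   (idealized diameter).
#' @export
simulate_vessel_population <- function(n_vessels = 200,
                                       log_mean_diameter = log(24),
                                       log_sd_diameter = 0.25,
                                       eccentricity_range = c(0.8, 1),
                                       seed) {
  stopifnot(n_vessels >= 1, log_sd_diameter >= 0)
  if (missing(seed)) stop("seed is required")
  er <- sort(eccentricity_range)
  if (length(er) != 2 || er[1] <= 0 || er[2] > 1) {
    stop("eccentricity_range must lie in (0, 1]")
  }
  set.seed(seed)
  a <- stats::rlnorm(n_vessels, log_mean_diameter, log_sd_diameter) / 2
  ecc <- stats::runif(n_vessels, er[1], er[2])
  b <- a * ecc
  data.frame(a_um = a, b_um = b, d_um = ellipse_diameter(a, b))
}

#' Simulate a PLC measurement series along a pressure ramp
#'
#' True PLC follows the sigmoid vulnerability curve ([sigmoid_plc()]);
#' additive Gaussian measurement noise is truncated to the physical
#' \[0, 100\] range.
#'
#' @param pressure_mpa Measurement pressures, MPa, strictly decreasing
#'   (more negative), e.g. `seq(-1, -5, by = -0.25)`.
#' @param p50 True P50, MPa (negative).
#' @param s True slope at the inflexion, percent per MPa (> 0).
#' @param noise_sd Measurement noise SD in PLC percent (>= 0).
#' @param seed Integer seed.
#' @return Data frame with `pressure_mpa` (echoed unchanged) and `plc`.
#' @export
simulate_plc_series <- function(pressure_mpa = seq(-1, -5, by = -0.25),
                                p50 = -3, s = 40, noise_sd = 3, seed) {
  if (missing(seed)) stop("seed is required")
  if (any(diff(pressure_mpa) >= 0)) stop("pressures must be strictly decreasing")
  if (s <= 0) stop("slope s must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  truth <- sigmoid_plc(pressure_mpa, p50, s)
  plc <- truth + stats::rnorm(length(truth), 0, noise_sd)
  data.frame(pressure_mpa = pressure_mpa, plc = pmin(pmax(plc, 0), 100))
}

#' Simulate monthly climate normals for a provenance origin
#'
#' Temperatures follow an annual sinusoid (peak in July) plus noise, then
#' are shifted so the annual mean equals `mat_target` exactly; monthly
#' precipitation is drawn from a lognormal and rescaled so the annual sum
#' equals `map_target` exactly. The defaults span the MAT/MAP range of
#' European beech origins (roughly 3-15 degrees C, 550-1100 mm).
#'
#' @param mat_target Target mean annual temperature, degrees C.
#' @param map_target Target annual precipitation, mm (> 0).
#' @param t_amplitude Half-range of the seasonal temperature cycle,
#'   degrees C.
#' @param t_noise_sd SD of month-to-month temperature irregularity,
#'   degrees C.
#' @param p_log_sd SD of log monthly precipitation before rescaling
#'   (controls seasonality strength).
#' @param seed Integer seed.
#' @return Data frame with `month` (1-12), `tmean_c`, `prec_mm`.
#' @export
simulate_origin_climate <- function(mat_target, map_target,
                                    t_amplitude = 9, t_noise_sd = 0.5,
                                    p_log_sd = 0.3, seed) {
  if (missing(seed)) stop("seed is required")
  if (map_target <= 0) stop("map_target must be positive")
  set.seed(seed)
  m <- 1:12
  tm <- mat_target - t_amplitude * cos(2 * pi * (m - 1) / 12) +
    stats::rnorm(12, 0, t_noise_sd)
  tm <- tm + (mat_target - mean(tm))          # exact annual mean
  pr <- stats::rlnorm(12, 0, p_log_sd)
  pr <- pr * map_target / sum(pr)             # exact annual sum
  data.frame(month = m, tmean_c = tm, prec_mm = pr)
}
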