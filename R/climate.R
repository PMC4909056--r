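check_monthly <- function(tmean_c, prec_mm) {
  if (length(tmean_c) != 12 || length(prec_mm) != 12) {
    stop("monthly climate requires exactly 12 temperature and 12 precipitation values")
  }
  if (any(!is.finite(tmean_c)) || any(!is.finite(prec_mm))) {
    stop("missing months in climate series")
  }
  if (any(prec_mm < 0)) stop("precipitation must be >= 0")
  invisible(TRUE)
}

#' Annual climate summaries from monthly normals
#'
#' Mean annual temperature, annual precipitation sum, and mean early
#' growing-season precipitation (April-June sum).
#'
#' @param tmean_c Twelve monthly mean temperatures, degrees C, January first.
#' @param prec_mm Twelve monthly precipitation sums, mm, January first.
#' @return Named list: `mat` (degrees C), `map` (mm/yr), `msp` (mm/yr).
#' @export
climate_summaries <- function(tmean_c, prec_mm) {
  check_monthly(tmean_c, prec_mm)
  list(
    mat = mean(tmean_c),
    map = sum(prec_mm),
    msp = sum(prec_mm[4:6])
  )
}

#' Forest aridity index
#'
#' \eqn{FAI = 100 \, T_{Jul-Aug} / (P_{May-Jul} + P_{Jul-Aug})}: the mid-summer
#' temperature over a precipitation sum in which July - the month of peak
#' evaporative demand - enters twice. Higher values indicate a drier, hotter
#' growing season (observed range across European beech origins roughly
#' 2-9).
#'
#' @inheritParams climate_summaries
#' @param interval_mean If `TRUE` (default) the July-August temperature is
#'   the arithmetic mean of the two monthly means; if `FALSE`, July alone is
#'   used.
#' @return FAI, dimensionless.
#' @export
forest_aridity_index <- function(tmean_c, prec_mm, interval_mean = TRUE) {
  check_monthly(tmean_c, prec_mm)
  t_summer <- if (interval_mean) mean(tmean_c[7:8]) else tmean_c[7]
  denom <- sum(prec_mm[5:7]) + sum(prec_mm[7:8])
  if (denom <= 0) stop("summer precipitation sum must be positive")
  100 * t_summer / denom
}

#' Ellenberg climate quotient
#'
#' \eqn{EQ = (T_{Jul} / P_{annual}) \times 1000}: July warmth per unit annual
#' precipitation, a classic continentality/aridity measure for beech
#' climates.
#'
#' @param t_jul_c Mean July temperature, degrees C.
#' @param map_mm Annual precipitation, mm (> 0).
#' @return EQ, dimensionless.
#' @export
ellenberg_quotient <- function(t_jul_c, map_mm) {
  if (any(map_mm <= 0)) stop("annual precipitation must be positive")
  t_jul_c / map_mm * 1000
}

#' Climate-of-origin indices for a set of provenances
#'
#' Summarises a long monthly-normals table into per-provenance MAT, MAP,
#' MSP, FAI and EQ. The global aridity index (GAI) is a database-derived
#' quantity: if a `gai` column is present it is echoed through, never
#' computed.
#'
#' @param climate Data frame with columns `provenance`, `month` (1-12),
#'   `tmean_c`, `prec_mm` and optionally `gai` (constant within provenance).
#' @param interval_mean Passed to [forest_aridity_index()].
#' @return Data frame, one row per provenance: `provenance`, `mat`, `map`,
#'   `msp`, `eq`, `gai`, `fai`.
#' @export
climate_indices <- function(climate, interval_mean = TRUE) {
  need <- c("provenance", "month", "tmean_c", "prec_mm")
  stopifnot(all(need %in% names(climate)))
  rows <- lapply(split(climate, climate$provenance), function(cl) {
    cl <- cl[order(cl$month), , drop = FALSE]
    if (!identical(as.integer(cl$month), 1:12)) {
      stop("provenance ", cl$provenance[1], ": months must be exactly 1..12")
    }
    s <- climate_summaries(cl$tmean_c, cl$prec_mm)
    data.frame(
      provenance = cl$provenance[1],
      mat = s$mat, map = s$map, msp = s$msp,
      eq = ellenberg_quotient(cl$tmean_c[7], s$map),
      gai = if ("gai" %in% names(cl)) cl$gai[1] else NA_real_,
      fai = forest_aridity_index(cl$tmean_c, cl$prec_mm, interval_mean)
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
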