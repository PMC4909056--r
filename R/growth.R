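#' Beech stem form factor
#'
#' Empirical form factor converting a breast-height cylinder into standing
#' timber volume, \eqn{f = 0.4039 + 0.0017335 H + 1.1267/H - 118.188/D^3 +
#' 4.2\times10^{-6} D^2}. Realistic beech trees give values near 0.5; very
#' small diameters drive the \eqn{-118.188/D^3} term below zero, which is
#' rejected.
#'
#' @param dbh_cm Diameter at breast height, cm (> 0). Vectorised.
#' @param height_m Tree height, m (> 0). Vectorised.
#' @return Form factor, dimensionless, in (0, 1) for realistic inputs.
#' @export
form_factor <- function(dbh_cm, height_m) {
  if (any(dbh_cm <= 0) || any(height_m <= 0)) stop("DBH and height must be positive")
  f <- 0.4039 + 0.0017335 * height_m + 1.1267 / height_m -
    118.188 / dbh_cm^3 + 4.2e-6 * dbh_cm^2
  if (any(f <= 0)) {
    bad <- which(f <= 0)[1]
    stop(sprintf(
      "form factor non-positive for DBH = %.2f cm, height = %.2f m",
      dbh_cm[bad], rep_len(height_m, length(f))[bad]
    ))
  }
  f
}

#' Standing timber volume
#'
#' \eqn{V = \pi ((D/100)/2)^2 \, H \, f}: a breast-height cylinder scaled by
#' the beech form factor ([form_factor()]).
#'
#' @inheritParams form_factor
#' @return Timber volume, m^3.
#' @export
timber_volume <- function(dbh_cm, height_m) {
  pi * ((dbh_cm / 100) / 2)^2 * height_m * form_factor(dbh_cm, height_m)
}

#' Aboveground biomass of a beech tree
#'
#' Power-law allometry \eqn{AGB = 0.00523 \, D^{2.12} \, H^{0.655}} (kg).
#'
#' @inheritParams form_factor
#' @return Aboveground biomass, kg.
#' @export
aboveground_biomass <- function(dbh_cm, height_m) {
  if (any(dbh_cm <= 0) || any(height_m <= 0)) stop("DBH and height must be positive")
  0.00523 * dbh_cm^2.12 * height_m^0.655
}

#' Aboveground biomass increment
#'
#' Mean annual biomass increment over the life of the plantation:
#' final aboveground biomass divided by the elapsed time since planting
#' (sapling starting biomass taken as negligible).
#'
#' @param agb_kg Final aboveground biomass, kg.
#' @param elapsed_yr Years since planting; default 19 (a trial planted with
#'   2-year saplings in 1995 and surveyed in late summer 2014).
#' @return ABI, kg per year.
#' @export
abi <- function(agb_kg, elapsed_yr = 19) {
  if (any(elapsed_yr <= 0)) stop("elapsed_yr must be positive")
  agb_kg / elapsed_yr
}

#' Basal area increment between two inventories
#'
#' \eqn{BAI = (BA_2 - BA_1)/\Delta t} with \eqn{BA = \pi (D/2)^2} in cm^2 and
#' the elapsed time computed from calendar dates as exact day counts over
#' 365.25. A shrinking DBH yields a negative increment with a warning
#' (measurement error is the usual cause).
#'
#' @param dbh1_cm,dbh2_cm DBH at the first and second inventory, cm.
#' @param date1,date2 Inventory dates (`Date` or parseable strings);
#'   `date2` must be after `date1`. Alternatively pass `delta_yr` directly.
#' @param delta_yr Elapsed time in years, overriding the dates.
#' @return BAI, cm^2 per year.
#' @export
bai <- function(dbh1_cm, dbh2_cm, date1 = NULL, date2 = NULL, delta_yr = NULL) {
  if (is.null(delta_yr)) {
    if (is.null(date1) || is.null(date2)) stop("supply dates or delta_yr")
    d1 <- as.Date(date1)
    d2 <- as.Date(date2)
    if (any(d2 <= d1)) stop("date2 must be after date1")
    delta_yr <- as.numeric(d2 - d1) / 365.25
  }
  if (any(delta_yr <= 0)) stop("elapsed time must be positive")
  if (any(dbh2_cm < dbh1_cm)) warning("DBH decreased between inventories; negative BAI")
  ba1 <- pi * (dbh1_cm / 2)^2
  ba2 <- pi * (dbh2_cm / 2)^2
  (ba2 - ba1) / delta_yr
}

#' Growth traits from a per-tree inventory series
#'
#' Computes form factor, timber volume, aboveground biomass, ABI and BAI for
#' each tree from a long inventory table (one row per tree per survey). ABI
#' uses the final survey's biomass over the time since planting; BAI uses the
#' first and last surveys only (inserting intermediate surveys does not
#' change it).
#'
#' @param inventory Data frame with columns `tree_id`, `dbh_cm`,
#'   `height_m`, `survey_date` (Date or string). Optional `provenance`,
#'   `block` columns are carried through.
#' @param planting_date Date the trial was planted (for ABI); default
#'   `"1995-05-01"`.
#' @return Data frame with one row per tree: final `dbh_cm`, `height_m`,
#'   `form_factor`, `volume_m3` (both `NA` below the 7 cm timber threshold),
#'   `agb_kg`, `abi_kg_yr`, `bai_cm2_yr` (`NA` for trees with a single
#'   survey).
#' @export
growth_increments <- function(inventory, planting_date = "1995-05-01") {
  need <- c("tree_id", "dbh_cm", "height_m", "survey_date")
  stopifnot(all(need %in% names(inventory)))
  inventory$survey_date <- as.Date(inventory$survey_date)
  planting_date <- as.Date(planting_date)
  carry <- intersect(c("provenance", "block"), names(inventory))

  rows <- lapply(split(inventory, inventory$tree_id), function(tr) {
    tr <- tr[order(tr$survey_date), , drop = FALSE]
    if (anyDuplicated(tr$survey_date)) stop("duplicate survey dates for tree ", tr$tree_id[1])
    last <- tr[nrow(tr), ]
    elapsed <- as.numeric(last$survey_date - planting_date) / 365.25
    if (elapsed <= 0) stop("survey precedes planting for tree ", tr$tree_id[1])
    agb <- aboveground_biomass(last$dbh_cm, last$height_m)
    # timber volume applies to stems of timber dimension (>= 7 cm DBH);
    # smaller trees get NA rather than an out-of-domain form factor
    ff <- vol <- NA_real_
    if (last$dbh_cm >= 7) {
      ff <- form_factor(last$dbh_cm, last$height_m)
      vol <- timber_volume(last$dbh_cm, last$height_m)
    }
    bai_val <- NA_real_
    if (nrow(tr) >= 2) {
      first <- tr[1, ]
      bai_val <- bai(first$dbh_cm, last$dbh_cm, first$survey_date, last$survey_date)
    }
    out <- data.frame(
      tree_id = last$tree_id,
      dbh_cm = last$dbh_cm,
      height_m = last$height_m,
      form_factor = ff,
      volume_m3 = vol,
      agb_kg = agb,
      abi_kg_yr = abi(agb, elapsed),
      bai_cm2_yr = bai_val
    )
    for (cc in carry) out[[cc]] <- last[[cc]]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
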