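#' Pairwise Pearson correlation matrix across traits
#'
#' Pairwise-complete Pearson correlations between all trait columns, either
#' at the tree level or between provenance means. Tree-level correlations on
#' data pooled across provenances mix several sources of variation and carry
#' inflated degrees of freedom; the returned object flags this caveat.
#'
#' @param traits Data frame with a `provenance` column (needed for the
#'   provenance-mean level) and trait columns.
#' @param trait_cols Character vector of trait columns; default all numeric
#'   columns except `provenance`/`block` identifiers.
#' @param level `"tree"` (default): raw rows; `"provenance_mean"`: traits
#'   are first averaged within provenance, so n is the number of
#'   provenances.
#' @return Object of class `trait_corr`: list with matrices `r`, `p`
#'   (two-sided t-test), `n` (pairwise-complete counts), plus `level` and
#'   `inflated_df` (TRUE at tree level). Pairs with fewer than 3 complete
#'   observations or a zero-variance member get `NA`.
#' @export
pearson_matrix <- function(traits, trait_cols = NULL,
                           level = c("tree", "provenance_mean")) {
  level <- match.arg(level)
  if (is.null(trait_cols)) {
    num <- vapply(traits, is.numeric, logical(1))
    trait_cols <- setdiff(names(traits)[num], c("provenance", "block"))
  }
  dat <- traits[trait_cols]
  if (level == "provenance_mean") {
    stopifnot("provenance" %in% names(traits))
    dat <- stats::aggregate(dat, list(provenance = traits$provenance),
                            mean, na.rm = TRUE)[trait_cols]
  }
  m <- as.matrix(dat)
  k <- ncol(m)
  obs <- !is.na(m)
  n <- crossprod(obs)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  # zero-variance columns (within the pairwise-complete subset) give NaN
  r[!is.finite(r)] <- NA
  r[n < 3] <- NA
  diag(r)[diag(n) >= 1] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[is.na(r)] <- NA
  diag(p) <- NA
  out <- list(r = r, p = p, n = n, level = level,
              inflated_df = level == "tree")
  class(out) <- "trait_corr"
  out
}

#' @export
print.trait_corr <- function(x, digits = 2, ...) {
  cat("Pearson trait correlations (level: ", x$level, ")\n", sep = "")
  if (x$inflated_df) {
    cat("  note: pooled tree-level correlations carry inflated degrees of freedom\n")
  }
  print(round(x$r, digits))
  invisible(x)
}

#' Long-format correlation table with significance stars
#'
#' @param x A `trait_corr` object.
#' @param holm Apply a Holm correction to the p-values before starring
#'   (off by default, matching common reporting practice for exploratory
#'   trait matrices).
#' @param ... Unused.
#' @return Data frame with `trait1`, `trait2`, `r`, `p`, `n`, `stars`
#'   (`***` < 0.001, `**` < 0.01, `*` < 0.05) for each unordered pair.
#' @export
as.data.frame.trait_corr <- function(x, holm = FALSE, ...) {
  traits <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  out <- data.frame(
    trait1 = traits[idx[, 1]],
    trait2 = traits[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    n = x$n[idx]
  )
  if (holm) out$p <- stats::p.adjust(out$p, method = "holm")
  out$stars <- ifelse(is.na(out$p), "",
               ifelse(out$p < 0.001, "***",
               ifelse(out$p < 0.01, "**",
               ifelse(out$p < 0.05, "*", ""))))
  out
}
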