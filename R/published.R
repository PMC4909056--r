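#' Published provenance-trial summary tables
#'
#' Loads the published provenance-level summaries bundled with the package:
#' climate normals and aridity indices at the ten beech seed origins
#' (`"origin_climate"`), the printed provenance-mean growth rates
#' (`"provenance_growth"`), the per-trait variance-partitioning summary
#' (`"varcomp"`), and the per-trait climate-of-origin mixed-model summary
#' (`"climate_model"`). These serve as worked-example inputs and consistency
#' fixtures; the raw tree-level field measurements behind them were never
#' deposited.
#'
#' @param name One of `"origin_climate"`, `"provenance_growth"`,
#'   `"varcomp"`, `"climate_model"`.
#' @return A data frame. In the `"varcomp"` table the `p` column is kept as
#'   printed (character, e.g. `"<0.001"`).
#' @export
published_table <- function(name = c("origin_climate", "provenance_growth",
                                     "varcomp", "climate_model")) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0(name, "_published.csv"),
                      package = "provtraits", mustWork = TRUE)
  utils::read.csv(file, check.names = FALSE,
                  colClasses = if (name == "varcomp") c(p = "character") else NA)
}
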