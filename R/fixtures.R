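#' Published Central Asia LULC areas, 1995-2035
#'
#' The packaged per-class area table for the five study epochs (1995, 2005,
#' 2015 observed; 2025, 2035 CA-Markov projections), in the published unit of
#' 10^4 ha to two decimals. The total area (40,010.48 x 10^4 ha) is constant
#' across years. Values are stored at printed precision, never re-derived.
#'
#' @return Long data.frame with columns `year`, `class`, `area_1e4_ha`.
#' @export
central_asia_areas <- function() {
  utils::read.csv(
    system.file("extdata", "central_asia_areas.csv", package = "landesv"),
    stringsAsFactors = FALSE
  )
}

#' Extract one year's per-class area row
#'
#' @param area_table Long data.frame with `year`, `class`, and one of
#'   `area_1e4_ha` or `area_ha` (explicit unit tags; the literature mixes
#'   both).
#' @param year Year to extract.
#' @param unit Output unit, `"ha"` (default) or `"1e4_ha"`.
#' @return Named numeric vector in canonical class order.
#' @export
area_row <- function(area_table, year, unit = c("ha", "1e4_ha")) {
  unit <- match.arg(unit)
  sub <- area_table[area_table$year == year, ]
  if (!nrow(sub)) stop("year ", year, " not present in area table")
  if ("area_ha" %in% names(sub)) {
    a <- sub$area_ha
    scale <- if (unit == "ha") 1 else 1e-4
  } else if ("area_1e4_ha" %in% names(sub)) {
    a <- sub$area_1e4_ha
    scale <- if (unit == "ha") 1e4 else 1
  } else {
    stop("area table needs an `area_ha` or `area_1e4_ha` column")
  }
  names(a) <- sub$class
  if (!setequal(names(a), lulc_classes())) {
    stop("area table year ", year, " does not cover the 7 classes")
  }
  a[lulc_classes()] * scale
}

#' Packaged study fixtures
#'
#' Convenience accessor bundling the published area table and
#' value-coefficient matrix.
#'
#' @return List with `areas` ([central_asia_areas()]) and `vc`
#'   ([value_coefficients()]).
#' @export
paper_fixture <- function() {
  list(areas = central_asia_areas(), vc = value_coefficients())
}
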