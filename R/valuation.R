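#' The nine ecosystem service functions
#'
#' Canonical order of the service functions (columns of the value-coefficient
#' matrix): food production, raw material, gas regulation, climate
#' regulation, water regulation, soil formation and retention, waste
#' treatment, biodiversity, recreation/culture/tourism.
#'
#' @return Character vector of length 9.
#' @export
esv_functions <- function() {
  c("food_production", "raw_material", "gas_regulation",
    "climate_regulation", "water_regulation", "soil_formation_retention",
    "waste_treatment", "biodiversity", "recreation_culture")
}

#' Benefit-transfer value coefficients
#'
#' The packaged 7-class x 9-function matrix of per-hectare annual ecosystem
#' service values (US$ ha^-1 yr^-1) for Central Asia, derived from the global
#' benefit-transfer model. Per-class totals are 5,567 (cropland), 3,137
#' (forestland), 4,166 (grassland), 25,681 (wetland), 6,661 (urban), 0
#' (bare) and 12,512 (water). Users may supply any matrix with the same
#' layout to the valuation functions.
#'
#' @param path Optional CSV (rows = classes in canonical order, column
#'   `class` plus the nine function columns) replacing the packaged matrix.
#' @return Numeric 7 x 9 matrix with class rownames and function colnames.
#' @export
value_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "value_coefficients.csv",
                        package = "landesv")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(df$class, lulc_classes()),
            identical(names(df)[-1], esv_functions()))
  vc <- as.matrix(df[, -1])
  rownames(vc) <- df$class
  if (any(vc < 0)) stop("value coefficients must be nonnegative")
  vc
}

# Align a named area vector with the coefficient matrix's classes.
check_classes <- function(areas_ha, vc) {
  if (is.null(names(areas_ha)) ||
      !setequal(names(areas_ha), rownames(vc))) {
    stop("`areas_ha` must be named with exactly the coefficient classes")
  }
  areas_ha[rownames(vc)]
}

#' Ecosystem service value per LULC class
#'
#' `ESV_k = A_k * sum_f VC_kf`: each class's area times its total per-hectare
#' coefficient.
#'
#' @param areas_ha Named per-class areas in hectares.
#' @param vc Value-coefficient matrix from [value_coefficients()].
#' @return Named numeric vector, US$ per year.
#' @export
esv_by_class <- function(areas_ha, vc = value_coefficients()) {
  a <- check_classes(areas_ha, vc)
  a * rowSums(vc)
}

#' Ecosystem service value per service function
#'
#' `ESV_f = sum_k A_k * VC_kf`.
#'
#' @inheritParams esv_by_class
#' @return Named numeric vector over the nine functions, US$ per year.
#' @export
esv_by_function <- function(areas_ha, vc = value_coefficients()) {
  a <- check_classes(areas_ha, vc)
  as.numeric(a %*% vc)[seq_len(ncol(vc))] |>
    stats::setNames(colnames(vc))
}

#' Total ecosystem service value
#'
#' `ESV = sum_f sum_k A_k * VC_kf`; equals both the sum of the per-class and
#' the sum of the per-function values.
#'
#' @inheritParams esv_by_class
#' @return Scalar, US$ per year.
#' @export
total_esv <- function(areas_ha, vc = value_coefficients()) {
  sum(esv_by_class(areas_ha, vc))
}

#' Change rate of an ecosystem service value
#'
#' `100 * (v2 - v1) / v1`, elementwise for vectors. Zero-baseline entries are
#' flagged `NA` (attribute `"undefined"`), never silently 0 or infinite.
#'
#' @param v1,v2 Values (scalars or equally named vectors) at the initial and
#'   final year.
#' @return Percentage change(s).
#' @export
esv_change_rate <- function(v1, v2) {
  pct <- 100 * (v2 - v1) / v1
  undef <- which(v1 == 0)
  pct[undef] <- NA_real_
  attr(pct, "undefined") <- names(v1)[undef]
  pct
}

#' Zonal ecosystem service values
#'
#' Tabulates per-class areas within each zone of a co-registered integer zone
#' raster and values them; zone values sum to the global total when the zones
#' partition the landscape.
#'
#' @param raster A `lulc_raster`.
#' @param zones Integer matrix (or `lulc_raster`-like list with `$grid`) of
#'   zone ids, same shape and nodata mask as `raster`.
#' @param vc Value-coefficient matrix.
#' @return Named numeric vector of US$ per zone id.
#' @export
zonal_esv <- function(raster, zones, vc = value_coefficients()) {
  zg <- if (is.list(zones)) zones$grid else zones
  if (!identical(dim(zg), dim(raster$grid))) {
    stop("zone raster shape differs from landscape")
  }
  keep <- !is.na(raster$grid)
  if (any(is.na(zg[keep]))) {
    stop("zone raster has nodata where the landscape has data")
  }
  ca <- if (is.matrix(raster$cell_area_ha)) raster$cell_area_ha[keep] else
    rep(raster$cell_area_ha, sum(keep))
  g <- raster$grid[keep]
  z <- zg[keep]
  per_ha <- rowSums(vc)[g]            # value density of each cell
  vals <- tapply(per_ha * ca, z, sum)
  stats::setNames(as.numeric(vals), names(vals))
}

#' Full valuation report for a multi-year area table
#'
#' Computes per-class values, per-function values, totals, and change rates
#' for every consecutive pair plus first-to-last, the layout of the published
#' valuation tables.
#'
#' @param area_table Long data.frame with columns `year`, `class`,
#'   `area_1e4_ha` (the published unit) or `area_ha`.
#' @param vc Value-coefficient matrix.
#' @return List with matrices `by_class` and `by_function` (billion US$,
#'   years as columns), vector `total` (billion US$), and matrices
#'   `class_change_pct` / `area_change_pct` over year pairs.
#' @export
esv_report <- function(area_table, vc = value_coefficients()) {
  years <- sort(unique(area_table$year))
  rows <- lapply(years, function(y) area_row(area_table, y, unit = "ha"))
  names(rows) <- years
  by_class <- vapply(rows, esv_by_class, numeric(7), vc = vc) / 1e9
  by_fun <- vapply(rows, esv_by_function, numeric(9), vc = vc) / 1e9
  total <- colSums(by_class)
  pairs <- list()
  if (length(years) > 1) {
    idx <- t(utils::combn(length(years), 2))  # every ordered year pair
    pairs <- apply(idx, 1, function(p) {
      lab <- paste0(years[p[1]], "-", years[p[2]])
      list(label = lab,
           class_pct = esv_change_rate(by_class[, p[1]], by_class[, p[2]]),
           area_pct = area_change_pct(rows[[p[1]]], rows[[p[2]]]),
           total_pct = esv_change_rate(total[p[1]], total[p[2]]))
    })
  }
  class_change <- if (length(pairs)) {
    m <- vapply(pairs, function(p) as.numeric(p$class_pct), numeric(7))
    dimnames(m) <- list(lulc_classes(), vapply(pairs, `[[`, "", "label"))
    m
  } else NULL
  area_change <- if (length(pairs)) {
    m <- vapply(pairs, function(p) as.numeric(p$area_pct), numeric(7))
    dimnames(m) <- list(lulc_classes(), vapply(pairs, `[[`, "", "label"))
    m
  } else NULL
  total_change <- if (length(pairs)) {
    stats::setNames(vapply(pairs, function(p) as.numeric(p$total_pct),
                           numeric(1)),
                    vapply(pairs, `[[`, "", "label"))
  } else NULL
  list(years = years, by_class = by_class, by_function = by_fun,
       total = total, class_change_pct = class_change,
       area_change_pct = area_change, total_change_pct = total_change)
}
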