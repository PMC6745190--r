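#' Canonical land-use / land-cover classes
#'
#' The seven LULC classes used throughout the package, in the fixed canonical
#' order that every matrix, table and raster follows: cropland, forestland,
#' grassland, wetland, urban, bare, water. Class ids in rasters are integer
#' positions into this vector.
#'
#' @return Character vector of length 7.
#' @export
lulc_classes <- function() {
  c("cropland", "forestland", "grassland", "wetland", "urban", "bare", "water")
}

#' Construct a categorical land-cover raster
#'
#' A `lulc_raster` is an integer matrix of class ids (1..7, positions in
#' [lulc_classes()]) with `NA` marking nodata, plus the cell area in hectares
#' and light geo-metadata. All spatial operations in the package consume and
#' produce this container.
#'
#' @param grid Integer matrix; values in `1:7` or `NA` (nodata).
#' @param cell_area_ha Area of one cell in hectares. Either a positive scalar
#'   (equal-area grid) or a matrix of per-cell areas matching `grid`.
#' @param year Epoch year label (optional).
#' @param xll,yll Coordinates of the lower-left corner (map units).
#' @param cellsize Cell edge length in map units.
#' @param crs Free-text CRS label carried through I/O.
#' @return An object of class `lulc_raster`.
#' @export
lulc_raster <- function(grid, cell_area_ha = 9, year = NA_integer_,
                        xll = 0, yll = 0, cellsize = 300, crs = "") {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  storage.mode(grid) <- "integer"
  vals <- grid[!is.na(grid)]
  if (length(vals) && (min(vals) < 1L || max(vals) > 7L)) {
    stop("grid contains class ids outside 1..7; remap with a legend first")
  }
  if (is.matrix(cell_area_ha)) {
    if (!identical(dim(cell_area_ha), dim(grid))) {
      stop("per-cell `cell_area_ha` must match grid dimensions")
    }
    if (any(cell_area_ha <= 0, na.rm = TRUE)) stop("cell areas must be > 0")
  } else {
    if (length(cell_area_ha) != 1L || !is.finite(cell_area_ha) ||
        cell_area_ha <= 0) {
      stop("`cell_area_ha` must be a positive scalar or a matrix")
    }
  }
  structure(
    list(grid = grid, cell_area_ha = cell_area_ha, year = year,
         xll = xll, yll = yll, cellsize = cellsize, crs = crs),
    class = "lulc_raster"
  )
}

#' @export
print.lulc_raster <- function(x, ...) {
  nd <- sum(is.na(x$grid))
  cat(sprintf("<lulc_raster> %d x %d cells, %s nodata, cell area %s ha%s\n",
              nrow(x$grid), ncol(x$grid), format(nd),
              if (is.matrix(x$cell_area_ha)) "per-cell" else
                format(x$cell_area_ha),
              if (is.na(x$year)) "" else sprintf(", year %s", x$year)))
  tab <- table(factor(lulc_classes()[x$grid], levels = lulc_classes()))
  print(tab)
  invisible(x)
}

#' Read a class legend
#'
#' A legend maps raw integer raster codes to the seven canonical classes.
#' Codes mapped to the reserved name `"nodata"` become nodata. The mapping
#' must be total over the codes present in an input raster: an unmapped code
#' is an error at remap time, never silently dropped.
#'
#' @param path CSV file with columns `raw_code` and `class_name`.
#' @return A `lulc_legend`: data.frame with integer `raw_code` and validated
#'   `class_name`.
#' @export
read_legend <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_legend(df)
}

#' Coerce a data.frame to a legend
#'
#' @param df data.frame with columns `raw_code`, `class_name`.
#' @return A `lulc_legend`.
#' @export
as_legend <- function(df) {
  stopifnot(all(c("raw_code", "class_name") %in% names(df)))
  bad <- setdiff(unique(df$class_name), c(lulc_classes(), "nodata"))
  if (length(bad)) {
    stop("legend contains unknown class names: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$raw_code)) {
    stop("legend maps some raw codes more than once")
  }
  df$raw_code <- as.integer(df$raw_code)
  structure(df[c("raw_code", "class_name")],
            class = c("lulc_legend", "data.frame"))
}

#' Packaged CCI-LC-style legend
#'
#' A best-effort mapping from 300 m CCI-LC land-cover product codes to the
#' seven canonical classes. The published study's exact code table is not
#' reproduced in its main text, so this packaged legend is a documented
#' stand-in; supply your own CSV to [read_legend()] for other products.
#'
#' @return A `lulc_legend`.
#' @export
default_legend <- function() {
  read_legend(system.file("extdata", "cci_legend.csv", package = "landesv"))
}

#' Identity legend for already-classified rasters
#'
#' Maps codes 1..7 to classes 1..7; `nodata_codes` (default 0) become nodata.
#'
#' @param nodata_codes Integer codes treated as nodata.
#' @return A `lulc_legend`.
#' @export
identity_legend <- function(nodata_codes = 0L) {
  as_legend(data.frame(
    raw_code = c(1:7, nodata_codes),
    class_name = c(lulc_classes(), rep("nodata", length(nodata_codes)))
  ))
}

#' Remap raw codes to canonical class ids
#'
#' @param grid Integer matrix of raw codes (`NA` allowed and kept as nodata).
#' @param legend A `lulc_legend`.
#' @return Integer matrix of class ids 1..7 with `NA` nodata.
#' @export
remap_codes <- function(grid, legend) {
  idx <- match(grid, legend$raw_code)
  unmapped <- !is.na(grid) & is.na(idx)
  if (any(unmapped)) {
    codes <- sort(unique(grid[unmapped]))
    stop("legend does not cover raster code(s): ",
         paste(codes, collapse = ", "))
  }
  cls <- match(legend$class_name, lulc_classes())[idx]  # nodata -> NA
  out <- matrix(as.integer(cls), nrow(grid), ncol(grid))
  out
}

#' Load a categorical raster from an ESRI ASCII grid
#'
#' Reads a single-band integer raster in the plain-text ESRI ASCII grid
#' (`.asc`) format, remaps raw codes through `legend`, and attaches cell-area
#' metadata. The file's declared `NODATA_value` and any legend nodata codes
#' both become nodata.
#'
#' @param path Path to an `.asc` file.
#' @param legend A `lulc_legend` (default: identity mapping of codes 1..7).
#' @param cell_area_ha Hectares per cell; defaults to 9 ha (a 300 m cell).
#' @param year Epoch year label.
#' @return A `lulc_raster`. The count of nodata cells is available as
#'   `attr(, "n_nodata")`.
#' @export
load_raster <- function(path, legend = identity_legend(), cell_area_ha = 9,
                        year = NA_integer_) {
  asc <- read_asc(path)
  if (any(asc$grid != round(asc$grid), na.rm = TRUE)) {
    stop("raster band is not integer-valued: ", path)
  }
  grid <- remap_codes(asc$grid, legend)
  r <- lulc_raster(grid, cell_area_ha = cell_area_ha, year = year,
                   xll = asc$xll, yll = asc$yll, cellsize = asc$cellsize)
  attr(r, "n_nodata") <- sum(is.na(grid))
  r
}

#' Harmonize nodata masks across rasters
#'
#' Applies the union of the nodata masks to every raster so that any
#' two-epoch comparison (cross-tabulation, kappa) runs over a common support.
#'
#' @param ... Two or more `lulc_raster` objects of identical shape.
#' @return List of rasters sharing one mask.
#' @export
harmonize_masks <- function(...) {
  rs <- list(...)
  if (length(rs) == 1L && is.list(rs[[1]]) && !inherits(rs[[1]], "lulc_raster")) {
    rs <- rs[[1]]
  }
  stopifnot(length(rs) >= 2L)
  dims <- lapply(rs, function(r) dim(r$grid))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("rasters differ in shape; cannot harmonize masks")
  }
  mask <- Reduce(`|`, lapply(rs, function(r) is.na(r$grid)))
  if (all(mask)) stop("harmonized mask leaves no common cells")
  lapply(rs, function(r) { r$grid[mask] <- NA_integer_; r })
}

#' Tabulate per-class areas of a raster
#'
#' Area of a class is its non-nodata cell count (or the sum of per-cell
#' areas) times the cell area. Nodata cells contribute nothing, so the class
#' areas sum exactly to the masked-region area.
#'
#' @param raster A `lulc_raster`.
#' @return Named numeric vector of areas in hectares, one entry per class in
#'   canonical order.
#' @export
tabulate_areas <- function(raster) {
  g <- raster$grid
  if (is.matrix(raster$cell_area_ha)) {
    keep <- !is.na(g)
    a <- vapply(seq_len(7L), function(k) {
      sum(raster$cell_area_ha[keep & g == k])
    }, numeric(1))
  } else {
    a <- tabulate(g[!is.na(g)], nbins = 7L) * raster$cell_area_ha
  }
  stats::setNames(as.numeric(a), lulc_classes())
}

#' Percentage change of class areas between two epochs
#'
#' Computes `100 * (a2 - a1) / a1` per class. A class with zero baseline area
#' gets `NA` and is reported in the `"undefined"` attribute rather than being
#' silently set to 0 or Inf.
#'
#' @param a1,a2 Named per-class vectors (any consistent unit), e.g. from
#'   [tabulate_areas()] or a column of [central_asia_areas()].
#' @return Named numeric vector of percentages; attribute `"undefined"` lists
#'   zero-baseline classes.
#' @export
area_change_pct <- function(a1, a2) {
  stopifnot(identical(names(a1), names(a2)))
  pct <- 100 * (a2 - a1) / a1
  undef <- names(a1)[a1 == 0]
  pct[a1 == 0] <- NA_real_
  attr(pct, "undefined") <- undef
  pct
}
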