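#' Read an ESRI ASCII grid
#'
#' Minimal reader for the plain-text `.asc` raster format: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' `nrows` whitespace-separated rows, top row first.
#'
#' @param path File path.
#' @return List with `grid` (numeric matrix, `NA` for nodata), `xll`, `yll`,
#'   `cellsize`, `nodata_value`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals),
                 path))
  }
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid[grid == nodata] <- NA
  list(grid = grid, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata_value = nodata)
}

#' Write a categorical raster as an ESRI ASCII grid
#'
#' @param raster A `lulc_raster`.
#' @param path Output path.
#' @param nodata_value Integer written for nodata cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(raster, path, nodata_value = -9999L) {
  g <- raster$grid
  g[is.na(g)] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.6f", raster$xll),
    sprintf("yllcorner %.6f", raster$yll),
    sprintf("cellsize %.6f", raster$cellsize),
    sprintf("NODATA_value %d", nodata_value)
  )
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
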