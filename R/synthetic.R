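#' Specify a synthetic neutral landscape
#'
#' @param rows,cols Grid size (>= 10 x 10 when `patchiness > 0`).
#' @param proportions Named or plain per-class target fractions (length 7,
#'   nonnegative, summing to 1). Defaults to the 1995 class shares of the
#'   packaged Central Asia area table.
#' @param patchiness Box-smoothing radius in cells (>= 0); 0 gives spatially
#'   independent noise, larger values give larger contiguous patches.
#' @param cell_area_ha Hectares per cell (default 9, a 300 m cell).
#' @param seed Integer seed.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(rows = 100L, cols = 100L,
                           proportions = NULL, patchiness = 3L,
                           cell_area_ha = 9, seed = 1L) {
  if (is.null(proportions)) {
    a <- area_row(central_asia_areas(), 1995)
    proportions <- a / sum(a)
  }
  proportions <- as.numeric(proportions)
  if (length(proportions) != 7L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must be 7 nonnegative fractions summing to 1")
  }
  if (patchiness > 0 && (rows < 10L || cols < 10L)) {
    stop("patchy landscapes need a grid of at least 10 x 10")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 proportions = stats::setNames(proportions, lulc_classes()),
                 patchiness = as.integer(patchiness),
                 cell_area_ha = cell_area_ha, seed = as.integer(seed)),
            class = "landscape_spec")
}

# Box-smooth a matrix with a truncated square window of the given radius.
smooth_field <- function(m, radius) {
  if (radius <= 0) return(m)
  box_sum(m, radius) / box_sum(matrix(1, nrow(m), ncol(m)), radius)
}

#' Generate a synthetic categorical landscape
#'
#' Neutral-landscape construction: a seeded uniform random field is
#' box-smoothed by the spec's patchiness radius and cells are assigned to
#' classes by rank-quantile thresholding at the cumulative target
#' proportions. Smoothing induces spatially clustered patches; the rank-based
#' assignment keeps the realized composition exact to one cell regardless of
#' patchiness. Deterministic for a fixed seed.
#'
#' @param spec A [landscape_spec()].
#' @param year Epoch year label for the returned raster.
#' @return A `lulc_raster`.
#' @export
generate_initial <- function(spec, year = NA_integer_) {
  stopifnot(inherits(spec, "landscape_spec"))
  n <- spec$rows * spec$cols
  field <- with_seed(spec$seed, {
    matrix(stats::runif(n), spec$rows, spec$cols)
  })
  field <- smooth_field(field, spec$patchiness)
  # largest-remainder integer class counts, then assignment by field rank
  frac <- spec$proportions * n
  cnt <- floor(frac)
  rem <- n - sum(cnt)
  if (rem > 0) {
    up <- order(frac - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[up] <- cnt[up] + 1
  }
  ord <- order(field, seq_len(n))    # stable: ties broken by cell index
  cls <- rep.int(seq_len(7L), cnt)
  grid <- matrix(NA_integer_, spec$rows, spec$cols)
  grid[ord] <- as.integer(cls)
  lulc_raster(grid, cell_area_ha = spec$cell_area_ha, year = year,
              cellsize = sqrt(spec$cell_area_ha * 1e4))
}

#' Evolve a landscape one interval under a known transition matrix
#'
#' The stochastic inverse of [estimate_transition()], used for recovery
#' tests and multi-epoch scenario generation. In unclustered mode each
#' cell's next class is sampled independently from its row of `A`. In
#' clustered mode the number of i -> j flips is fixed at the expected
#' (largest-remainder rounded) multinomial counts and the cells most suitable
#' for the destination class (by neighborhood density, seeded random
#' tie-break) flip preferentially, so change aggregates along patch edges.
#' Deterministic for a fixed seed.
#'
#' @param raster A `lulc_raster`.
#' @param A A `transition_matrix` or row-stochastic 7 x 7 matrix.
#' @param seed Integer seed.
#' @param clustered Logical; spatially clustered change (default `FALSE`).
#' @param window Neighborhood size for clustered mode.
#' @return A `lulc_raster` one interval later.
#' @export
evolve <- function(raster, A, seed = 1L, clustered = FALSE, window = 5L) {
  if (inherits(A, "transition_matrix")) A <- A$A
  A <- as.matrix(A)
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-9)) {
    stop("`A` is not row-stochastic")
  }
  g <- raster$grid
  out <- g
  with_seed(seed, {
    if (!clustered) {
      for (i in 1:7) {
        idx <- which(!is.na(g) & g == i)
        if (!length(idx)) next
        out[idx] <- sample.int(7L, length(idx), replace = TRUE,
                               prob = A[i, ])
      }
    } else {
      suit <- neighborhood_suitability(raster, window)
      nrg <- nrow(g)
      for (i in 1:7) {
        idx <- which(!is.na(g) & g == i)
        ni <- length(idx)
        if (!ni) next
        frac <- A[i, ] * ni
        cnt <- floor(frac)
        rem <- ni - sum(cnt)
        if (rem > 0) {
          up <- order(frac - cnt, decreasing = TRUE)[seq_len(rem)]
          cnt[up] <- cnt[up] + 1
        }
        rr <- (idx - 1L) %% nrg + 1L
        cc <- (idx - 1L) %/% nrg + 1L
        avail <- rep(TRUE, ni)
        # assign destinations in decreasing-count order, persistence last
        dest_order <- order(cnt * (seq_len(7L) != i), decreasing = TRUE)
        for (j in dest_order) {
          if (j == i || cnt[j] == 0) next
          sc <- suit[cbind(rr, cc, j)] + stats::runif(ni) * 1e-9
          sc[!avail] <- -Inf
          take <- order(sc, decreasing = TRUE)[seq_len(cnt[j])]
          out[idx[take]] <- j
          avail[take] <- FALSE
        }
      }
    }
  })
  res <- raster
  res$grid <- out
  res
}

#' Generate a multi-epoch synthetic scenario
#'
#' Builds an initial landscape and evolves it through a list of transition
#' matrices, one epoch per interval.
#'
#' @param spec A [landscape_spec()].
#' @param years Integer vector of epoch labels (length = number of epochs).
#' @param matrices List of length `length(years) - 1` of transition matrices
#'   (objects or plain matrices), applied in order.
#' @param clustered Logical passed to [evolve()].
#' @return List of `lulc_raster` epochs, one per year.
#' @export
generate_scenario <- function(spec, years, matrices, clustered = TRUE) {
  stopifnot(length(matrices) == length(years) - 1L)
  if (is.unsorted(years, strictly = TRUE)) {
    stop("`years` must be strictly increasing")
  }
  out <- vector("list", length(years))
  names(out) <- years
  out[[1]] <- generate_initial(spec, year = years[1])
  for (k in seq_along(matrices)) {
    out[[k + 1]] <- evolve(out[[k]], matrices[[k]],
                           seed = spec$seed + k, clustered = clustered)
    out[[k + 1]]$year <- years[k + 1]
  }
  out
}
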