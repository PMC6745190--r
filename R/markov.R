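#' Construct a transition matrix object
#'
#' @param A Row-stochastic matrix of transition probabilities (row = source
#'   class, column = destination class), canonical class order.
#' @param counts Optional cross-tabulated cell counts (or area-weighted
#'   counts) underlying `A`.
#' @param interval Optional epoch pair `c(t1, t2)`.
#' @return A `transition_matrix`.
#' @export
transition_matrix <- function(A, counts = NULL, interval = c(NA, NA)) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("transition matrix must be square")
  if (any(A < 0)) stop("transition probabilities must be nonnegative")
  rs <- rowSums(A)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("every row of a transition matrix must sum to 1 (within 1e-9)")
  }
  n <- nrow(A)
  cls <- if (n == 7L) lulc_classes() else
    if (!is.null(rownames(A))) rownames(A) else paste0("class", seq_len(n))
  dimnames(A) <- list(cls, cls)
  if (!is.null(counts)) dimnames(counts) <- dimnames(A)
  structure(list(A = A, counts = counts, classes = cls, interval = interval),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, interval %s-%s\n",
              length(x$classes), x$interval[1], x$interval[2]))
  print(round(x$A, 4))
  invisible(x)
}

#' Estimate a class-transition matrix from two epochs
#'
#' Cross-tabulates cells of the two rasters over their common (harmonized)
#' support: `counts[i, j]` is the number of cells (or total cell area, for
#' per-cell area grids) that were class `i` at the first epoch and class `j`
#' at the second. Rows are normalised to probabilities; a class absent from
#' the first epoch gets the identity row, so the matrix stays row-stochastic
#' without inventing transitions.
#'
#' @param r1,r2 `lulc_raster` objects of the same shape and legend.
#' @return A `transition_matrix` with both probabilities and raw counts.
#' @export
estimate_transition <- function(r1, r2) {
  if (!identical(dim(r1$grid), dim(r2$grid))) {
    stop("rasters differ in shape")
  }
  hz <- harmonize_masks(r1, r2)
  g1 <- hz[[1]]$grid; g2 <- hz[[2]]$grid
  keep <- !is.na(g1)
  f1 <- factor(g1[keep], levels = 1:7)
  f2 <- factor(g2[keep], levels = 1:7)
  if (is.matrix(r1$cell_area_ha)) {
    w <- r1$cell_area_ha[keep]
    counts <- as.matrix(stats::xtabs(w ~ f1 + f2))
  } else {
    counts <- unclass(table(f1, f2)) * 1.0
  }
  dimnames(counts) <- list(lulc_classes(), lulc_classes())
  A <- counts / pmax(rowSums(counts), 1)
  empty <- rowSums(counts) == 0
  A[empty, ] <- diag(7)[empty, , drop = FALSE]
  transition_matrix(A, counts = counts,
                    interval = c(r1$year, r2$year))
}

#' Project class composition forward with a Markov chain
#'
#' Computes `s %*% A^steps`, where one step is one inter-epoch interval of
#' the matrix (a decade in the packaged study design). The result remains a
#' probability vector for any number of steps.
#'
#' @param s Named or plain numeric state vector (per-class landscape shares,
#'   nonnegative, summing to 1 within 1e-9).
#' @param A A `transition_matrix` or plain row-stochastic matrix.
#' @param steps Positive integer number of intervals.
#' @return Numeric state vector with class names.
#' @export
project_state <- function(s, A, steps = 1L) {
  if (inherits(A, "transition_matrix")) A <- A$A
  A <- as.matrix(A)
  rs <- rowSums(A)
  if (any(A < 0) || any(abs(rs - 1) > 1e-9)) {
    stop("`A` is not row-stochastic")
  }
  s <- as.numeric(s)
  if (length(s) != nrow(A)) stop("state vector and matrix dimensions differ")
  if (any(s < 0) || abs(sum(s) - 1) > 1e-9) {
    stop("`s` must be a probability vector")
  }
  steps <- as.integer(steps)
  if (steps < 1L) stop("`steps` must be a positive integer")
  out <- s
  for (k in seq_len(steps)) out <- as.numeric(out %*% A)
  stats::setNames(out, rownames(A))
}

#' Markov-projected target areas
#'
#' Converts a per-class area row to landscape shares, projects the shares
#' `steps` intervals forward, and converts back to areas. The total area is
#' conserved exactly.
#'
#' @param areas Named per-class area vector (ha or any unit; positive total).
#' @param A A `transition_matrix` or row-stochastic matrix.
#' @param steps Positive integer number of intervals.
#' @return Named per-class area vector in the input's unit.
#' @export
target_areas <- function(areas, A, steps = 1L) {
  total <- sum(areas)
  if (!is.finite(total) || total <= 0) stop("total area must be positive")
  s <- project_state(areas / total, A, steps)
  out <- s * total
  names(out) <- names(areas)
  out
}
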