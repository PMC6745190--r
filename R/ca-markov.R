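# Integral-image box sum with truncated windows at the grid edge.
box_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  ri <- as.vector(row(m)); ci <- as.vector(col(m))
  r1 <- pmax(ri - half, 1L); r2 <- pmin(ri + half, nr)
  c1 <- pmax(ci - half, 1L); c2 <- pmin(ci + half, nc)
  out <- P[cbind(r2 + 1L, c2 + 1L)] - P[cbind(r1, c2 + 1L)] -
    P[cbind(r2 + 1L, c1)] + P[cbind(r1, c1)]
  matrix(out, nr, nc)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Neighborhood-density suitability surfaces
#'
#' For each class, the suitability of a cell is the fraction of non-nodata
#' cells of that class within the square window centred on the cell (edge
#' cells use the truncated window). This is the local transition rule of the
#' cellular automaton: cells surrounded by a class are most suitable for it,
#' so projected change clusters along existing patch boundaries.
#'
#' @param raster A `lulc_raster`.
#' @param window Odd window edge length in cells (>= 3); default 5.
#' @return A rows x cols x 7 array with values in `[0, 1]`, `NA` at nodata
#'   cells; at every non-nodata cell the seven class suitabilities sum to 1.
#'   Attribute `"provenance"` records the rule.
#' @export
neighborhood_suitability <- function(raster, window = 5L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3")
  }
  half <- (window - 1L) %/% 2L
  g <- raster$grid
  valid <- !is.na(g)
  denom <- box_sum(valid * 1.0, half)
  suit <- array(NA_real_, c(nrow(g), ncol(g), 7L),
                dimnames = list(NULL, NULL, lulc_classes()))
  for (k in 1:7) {
    num <- box_sum((valid & g == k) * 1.0, half)
    s <- num / denom
    s[!valid] <- NA_real_
    suit[, , k] <- s
  }
  attr(suit, "provenance") <- sprintf("neighborhood-density w=%d", window)
  suit
}

#' Allocate Markov target areas in space (the CA step)
#'
#' Demand-driven greedy reassignment: the per-class difference between the
#' target areas and the current composition defines how many cells each class
#' must gain or lose; candidate cells are ranked by the suitability gained by
#' flipping (suitability of the gaining class minus suitability of the
#' current class), and the highest-ranked eligible cells flip first. Ties are
#' broken by a seeded random shuffle, then stable cell index, so the result
#' is deterministic for a fixed seed. Demand is spread evenly over the
#' iterations and suitability is recomputed from the evolving map each time
#' (unless a fixed stack is supplied), so change accretes along patch edges.
#'
#' A transition matrix, when given, defines the feasible change set: every
#' cell flips at most once, and only from its baseline class `i` to a class
#' `j` with `A[i, j] > 0`. When no surplus class can feed a deficit class
#' directly, demand is routed along the shortest feasible chain of classes
#' (e.g. water -> bare -> cropland), flipping a distinct cell per hop, so
#' multi-class circulations implied by the Markov targets still resolve.
#'
#' @param baseline A `lulc_raster` (requires scalar cell area).
#' @param targets Named per-class target areas in hectares; their total must
#'   match the baseline's masked area within 0.1%.
#' @param suitability Optional fixed suitability stack from
#'   [neighborhood_suitability()]; default recomputes per iteration.
#' @param trans Optional `transition_matrix` restricting feasible flips.
#' @param window CA neighborhood edge length (used when `suitability` is
#'   `NULL`); default 5.
#' @param max_iter Maximum CA iterations; default 10.
#' @param seed Integer seed for tie-breaking.
#' @return A `lulc_raster`; attribute `"residual_cells"` holds the remaining
#'   per-class cell imbalance (all zero on convergence). A warning reports
#'   non-convergence after `max_iter`.
#' @export
allocate <- function(baseline, targets, suitability = NULL, trans = NULL,
                     window = 5L, max_iter = 10L, seed = 1L) {
  if (is.matrix(baseline$cell_area_ha)) {
    stop("allocation requires a scalar cell area")
  }
  g <- baseline$grid
  valid <- !is.na(g)
  n <- sum(valid)
  if (n == 0L) stop("baseline raster has no data cells")
  targets <- targets[lulc_classes()]
  if (any(is.na(targets)) || any(targets < -1e-9)) {
    stop("`targets` must give a nonnegative area for each of the 7 classes")
  }
  tot <- n * baseline$cell_area_ha
  if (abs(sum(targets) - tot) > 1e-3 * tot) {
    stop(sprintf("target total (%.1f ha) differs from masked area (%.1f ha) by more than 0.1%%",
                 sum(targets), tot))
  }
  # largest-remainder rounding of target cell counts so they sum to n
  frac <- targets / baseline$cell_area_ha
  tgt <- floor(frac)
  rem <- n - sum(tgt)
  if (rem > 0) {
    give <- order(frac - tgt, decreasing = TRUE)[seq_len(rem)]
    tgt[give] <- tgt[give] + 1L
  }
  if (any(tgt > n)) stop("infeasible target: class demand exceeds masked area")
  Amat <- if (!is.null(trans)) {
    if (inherits(trans, "transition_matrix")) trans$A else as.matrix(trans)
  } else NULL

  nrg <- nrow(g)
  flipped <- logical(length(g))  # a cell changes class at most once
  feasible <- function(i, j) is.null(Amat) || Amat[i, j] > 0
  # shortest feasible class chain ending at j that starts at a class with
  # spare (unflipped, above-target) cells; backward BFS over A's support
  route_to <- function(j, give, supply) {
    parent <- rep(NA_integer_, 7L)
    seen <- rep(FALSE, 7L); seen[j] <- TRUE
    frontier <- j
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        preds <- which(if (is.null(Amat)) rep(TRUE, 7L) else Amat[, v] > 0)
        for (u in setdiff(preds[supply[preds] > 0L], which(seen))) {
          parent[u] <- v
          seen[u] <- TRUE
          if (give[u] > 0L) {        # reached a surplus class: unwind path
            path <- u
            while (path[length(path)] != j) {
              path <- c(path, parent[path[length(path)]])
            }
            return(path)
          }
          nxt <- c(nxt, u)
        }
      }
      frontier <- nxt
    }
    NULL
  }

  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      cur <- tabulate(g[valid], nbins = 7L)
      demand <- as.integer(tgt - cur)
      if (all(demand == 0L)) break
      suit <- if (is.null(suitability)) {
        rb <- baseline; rb$grid <- g
        neighborhood_suitability(rb, window)
      } else suitability
      # Flip up to k best unflipped cells of class `from` to class `to`,
      # ranked by the suitability gained; returns the number flipped.
      flip_best <- function(from, to, k) {
        cells <- which(valid & g == from & !flipped)
        if (!length(cells) || k < 1L) return(0L)
        rr <- (cells - 1L) %% nrg + 1L
        cc <- (cells - 1L) %/% nrg + 1L
        sc <- suit[cbind(rr, cc, to)] - suit[cbind(rr, cc, from)]
        k <- min(k, length(cells))
        take <- order(-sc, stats::runif(length(sc)), cells)[seq_len(k)]
        g[cells[take]] <<- to
        flipped[cells[take]] <<- TRUE
        k
      }
      # spread demand over the remaining iterations; the last takes the rest
      left <- max_iter - iter + 1L
      need <- if (left > 1L) {
        as.integer(ceiling(pmax(demand, 0L) / left))
      } else pmax(demand, 0L)
      give <- pmax(-demand, 0L)

      # direct pass: surplus classes flip straight into deficit classes
      gain <- which(need > 0L)
      lose <- which(give > 0L)
      loser_cells <- which(valid & (g %in% lose) & !flipped)
      if (length(loser_cells) && length(gain)) {
        from <- g[loser_cells]
        rr <- (loser_cells - 1L) %% nrg + 1L
        cc <- (loser_cells - 1L) %/% nrg + 1L
        s_cur <- suit[cbind(rr, cc, from)]
        cand <- vector("list", length(gain))
        for (u in seq_along(gain)) {
          j <- gain[u]
          ok <- if (is.null(Amat)) rep(TRUE, length(loser_cells)) else
            Amat[cbind(from, j)] > 0
          if (!any(ok)) next
          sc <- suit[cbind(rr[ok], cc[ok], j)] - s_cur[ok]
          keep <- order(sc, decreasing = TRUE)
          keep <- keep[seq_len(min(length(keep), 2L * need[j]))]
          cand[[u]] <- data.frame(cell = loser_cells[ok][keep],
                                  from = from[ok][keep], to = j,
                                  score = sc[keep])
        }
        cand <- do.call(rbind, cand)
        if (!is.null(cand) && nrow(cand)) {
          ord <- order(-cand$score, stats::runif(nrow(cand)), cand$cell)
          cand <- cand[ord, ]
          for (r in seq_len(nrow(cand))) {
            cl <- cand$cell[r]; fi <- cand$from[r]; tj <- cand$to[r]
            if (need[tj] > 0L && give[fi] > 0L && !flipped[cl]) {
              g[cl] <- tj
              flipped[cl] <- TRUE
              need[tj] <- need[tj] - 1L
              give[fi] <- give[fi] - 1L
            }
            if (!any(need > 0L)) break
          }
        }
      }

      # routing pass: feed remaining deficits along the shortest feasible
      # class chain from a surplus class, one distinct cell per hop, so the
      # net residual shrinks even when A blocks every direct move
      repeat {
        progress <- FALSE
        for (j in which(need > 0L)) {
          supply <- integer(7L)
          unflipped <- valid & !flipped
          for (k in 1:7) supply[k] <- sum(unflipped & g == k)
          path <- route_to(j, give, supply)
          if (is.null(path) || length(path) < 2L) next
          t <- min(need[j], give[path[1]], supply[path[-length(path)]])
          if (t < 1L) next
          # execute from the deficit end backward: each hop u -> v moves t
          # unflipped cells of class u into class v
          for (h in seq(length(path) - 1L, 1L)) {
            flip_best(path[h], path[h + 1L], t)
          }
          need[j] <- need[j] - t
          give[path[1]] <- give[path[1]] - t
          progress <- TRUE
        }
        if (!progress || !any(need > 0L)) break
      }
    }
  })
  cur <- tabulate(g[valid], nbins = 7L)
  residual <- stats::setNames(as.integer(tgt - cur), lulc_classes())
  if (any(residual != 0L)) {
    warning(sprintf("allocation stopped with residual demand of %d cells after %d iterations",
                    sum(abs(residual)), max_iter))
  }
  out <- baseline
  out$grid <- g
  attr(out, "residual_cells") <- residual
  out
}

#' Cohen's kappa agreement between two categorical maps
#'
#' Chance-corrected agreement used to validate a simulated map against the
#' observed one. With confusion counts `C` over the harmonized support,
#' observed agreement is `p0 = sum(diag(C)) / N`, chance agreement is
#' `pc = sum_i (row_i/N)(col_i/N)` from the two maps' marginals, and
#' `kappa = (p0 - pc) / (1 - pc)`.
#'
#' @param observed,simulated `lulc_raster` objects of the same shape.
#' @return A `kappa_result`: list with `kappa`, `p0`, `pc`, the 7 x 7
#'   `confusion` counts, and `degenerate` (`TRUE` with `kappa = NA` when
#'   `pc == 1`, i.e. both maps constant with identical marginals).
#' @export
cohens_kappa <- function(observed, simulated) {
  if (!identical(dim(observed$grid), dim(simulated$grid))) {
    stop("rasters differ in shape")
  }
  hz <- harmonize_masks(observed, simulated)
  g1 <- hz[[1]]$grid; g2 <- hz[[2]]$grid
  keep <- !is.na(g1)
  conf <- unclass(table(factor(g1[keep], levels = 1:7),
                        factor(g2[keep], levels = 1:7))) * 1.0
  dimnames(conf) <- list(lulc_classes(), lulc_classes())
  kappa_from_confusion(conf)
}

#' Kappa from a confusion matrix
#'
#' @param conf Square matrix of agreement counts (rows = first map, columns
#'   = second map).
#' @return A `kappa_result`; see [cohens_kappa()].
#' @export
kappa_from_confusion <- function(conf) {
  conf <- as.matrix(conf)
  N <- sum(conf)
  if (N <= 0) stop("empty confusion matrix")
  p0 <- sum(diag(conf)) / N
  pc <- sum((rowSums(conf) / N) * (colSums(conf) / N))
  degenerate <- abs(1 - pc) < .Machine$double.eps^0.5
  kappa <- if (degenerate) NA_real_ else (p0 - pc) / (1 - pc)
  structure(list(kappa = kappa, p0 = p0, pc = pc, confusion = conf,
                 degenerate = degenerate),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %s (p0 = %.4f, pc = %.4f)%s\n",
              ifelse(is.na(x$kappa), "NA", sprintf("%.4f", x$kappa)),
              x$p0, x$pc,
              if (x$degenerate) " [degenerate: pc = 1]" else ""))
  invisible(x)
}

#' Serialize a kappa result to JSON
#'
#' @param x A `kappa_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kappa_json <- function(x, path) {
  jsonlite::write_json(
    list(kappa = x$kappa, p0 = x$p0, pc = x$pc,
         confusion = x$confusion, degenerate = x$degenerate),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
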