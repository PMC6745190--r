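test_that("neighborhood suitability is the class fraction of the (truncated) window", {
  # uniform map: its class scores 1 everywhere, all others 0
  r <- mini_raster(matrix(3L, 6, 6))
  s <- neighborhood_suitability(r, 5)
  expect_true(all(s[, , 3] == 1))
  expect_true(all(s[, , -3] == 0))

  # isolated cropland cell in grassland, 3x3 window: 1/9 at the centre
  g <- matrix(3L, 5, 5); g[3, 3] <- 1L
  s <- neighborhood_suitability(mini_raster(g), 3)
  expect_equal(unname(s[3, 3, 1]), 1 / 9)
  expect_equal(unname(s[3, 3, 3]), 8 / 9)
  expect_equal(unname(s[2, 2, 1]), 1 / 9) # window touches the cropland cell
  expect_equal(unname(s[1, 1, 3]), 1)     # corner window is all grassland
  expect_equal(unname(s[1, 1, 1]), 0)

  # class suitabilities partition the window at every cell
  spec <- landscape_spec(rows = 30, cols = 30, patchiness = 2, seed = 9)
  rp <- generate_initial(spec)
  rp$grid[c(3, 100)] <- NA_integer_
  sp <- neighborhood_suitability(rp, 5)
  sums <- apply(sp, c(1, 2), sum)
  expect_equal(max(abs(sums[!is.na(rp$grid)] - 1)), 0, tolerance = 1e-12)
  expect_true(all(is.na(sums[is.na(rp$grid)])))
  expect_error(neighborhood_suitability(rp, 4), "odd")
})

test_that("allocation meets Markov demand, honors the feasible set, and is seed-deterministic", {
  spec <- landscape_spec(rows = 200, cols = 200, patchiness = 3, seed = 21)
  base <- generate_initial(spec)
  A <- drift_matrix()

  # no net demand: the map comes back untouched
  same <- allocate(base, tabulate_areas(base), seed = 5)
  expect_identical(same$grid, base$grid)

  # degenerate single-class target
  tg1 <- setNames(c(sum(tabulate_areas(base)), rep(0, 6)), lulc_classes())
  all1 <- allocate(base, tg1, seed = 5)
  expect_true(all(all1$grid[!is.na(all1$grid)] == 1L))

  # targets from the Markov projection: per-class error <= 0.5% of total,
  # total cell count conserved exactly
  tg <- target_areas(tabulate_areas(base), A, 1)
  sim <- allocate(base, tg, trans = A, seed = 5)
  got <- tabulate_areas(sim)
  expect_lt(max(abs(got - tg)), 0.005 * sum(tg))
  expect_equal(sum(!is.na(sim$grid)), sum(!is.na(base$grid)))

  # forbidden transitions never happen: every changed cell moved i -> j
  # with A[i, j] > 0
  moved <- which(sim$grid != base$grid)
  expect_gt(length(moved), 0)
  expect_true(all(A$A[cbind(base$grid[moved], sim$grid[moved])] > 0))

  # determinism: same seed bitwise-identical, different seed allowed to differ
  sim2 <- allocate(base, tg, trans = A, seed = 5)
  expect_identical(sim2$grid, sim$grid)

  # infeasible targets rejected up front
  expect_error(allocate(base, tg1 * 2, seed = 5), "0.1%")
})

test_that("allocation routes demand through an intermediate class when the direct move is forbidden", {
  # urban must grow but only grassland may become urban, and only cropland
  # may become grassland: cropland -> grassland -> urban chain required
  A <- diag(7)
  A[1, 1] <- 0.9; A[1, 3] <- 0.1
  A[3, 3] <- 0.95; A[3, 5] <- 0.05
  spec <- landscape_spec(rows = 50, cols = 50,
                         proportions = c(0.5, 0, 0.3, 0, 0.2, 0, 0),
                         patchiness = 2, seed = 31)
  base <- generate_initial(spec)
  tg <- target_areas(tabulate_areas(base), transition_matrix(A), 1)
  sim <- allocate(base, tg, trans = A, seed = 8)
  expect_lt(max(abs(tabulate_areas(sim) - tg)), 0.005 * sum(tg))
  # no cell jumped cropland -> urban directly
  moved <- which(sim$grid != base$grid)
  expect_false(any(base$grid[moved] == 1L & sim$grid[moved] == 5L))
})

test_that("kappa matches the confusion-matrix formula and a brute-force oracle", {
  # identical maps agree perfectly
  spec <- landscape_spec(rows = 40, cols = 40, patchiness = 2, seed = 13)
  r <- generate_initial(spec)
  expect_equal(cohens_kappa(r, r)$kappa, 1)

  # hand-computed 2-class confusion: p0 = 0.8, pc = 0.5, kappa = 0.6
  k <- kappa_from_confusion(matrix(c(40, 10, 10, 40), 2, 2))
  expect_equal(k$p0, 0.8)
  expect_equal(k$pc, 0.5)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$kappa, (k$p0 - k$pc) / (1 - k$pc))

  # oracle equivalence on random maps, and symmetry in the arguments
  r2 <- evolve(r, drift_matrix(), seed = 14)
  k12 <- cohens_kappa(r, r2)
  expect_equal(k12$kappa, brute_kappa(as.vector(r$grid), as.vector(r2$grid)))
  expect_equal(cohens_kappa(r2, r)$kappa, k12$kappa)
  expect_true(k12$kappa >= -1 && k12$kappa <= 1)

  # independent random labels with equal marginals: kappa ~ 0
  set.seed(99)
  g1 <- matrix(sample.int(7L, 1e4, replace = TRUE), 100, 100)
  g2 <- matrix(sample.int(7L, 1e4, replace = TRUE), 100, 100)
  k0 <- cohens_kappa(lulc_raster(g1), lulc_raster(g2))$kappa
  expect_lt(abs(k0), 0.03)

  # pc = 1 (both maps constant, same marginals) is flagged, not divided by 0
  const <- mini_raster(matrix(2L, 4, 4))
  kd <- cohens_kappa(const, const)
  expect_true(kd$degenerate)
  expect_true(is.na(kd$kappa))
})

test_that("kappa results serialize to JSON", {
  k <- kappa_from_confusion(matrix(c(40, 10, 10, 40), 2, 2))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_kappa_json(k, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$kappa, 0.6)
  expect_equal(back$p0, 0.8)
})
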