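test_that("generated landscapes hit the target composition and are seed-deterministic", {
  # defaults emulate the study region's 1995 shares
  spec <- landscape_spec(rows = 500, cols = 500, patchiness = 0, seed = 1)
  r <- generate_initial(spec)
  shares <- tabulate_areas(r) / sum(tabulate_areas(r))
  expect_lt(max(abs(shares - spec$proportions)), 0.01)

  # patchy mode stays within spec too (rank thresholding keeps it exact)
  specp <- landscape_spec(rows = 120, cols = 120, patchiness = 4, seed = 1)
  rp <- generate_initial(specp)
  sharesp <- tabulate_areas(rp) / sum(tabulate_areas(rp))
  expect_lt(max(abs(sharesp - specp$proportions)), 0.03)

  # smoothing produces spatial clustering: same-class neighbour agreement
  # well above the unsmoothed landscape's
  agree <- function(g) mean(g[, -1] == g[, -ncol(g)])
  r0 <- generate_initial(landscape_spec(rows = 120, cols = 120,
                                        patchiness = 0, seed = 1))
  expect_gt(agree(rp$grid), agree(r0$grid) + 0.2)

  # determinism: same spec + seed is bitwise identical
  expect_identical(generate_initial(specp)$grid, rp$grid)

  # degenerate single-class proportions
  one <- generate_initial(landscape_spec(rows = 12, cols = 12,
                                         proportions = c(1, rep(0, 6)),
                                         patchiness = 0, seed = 2))
  expect_true(all(one$grid == 1L))
  expect_error(landscape_spec(proportions = c(1.2, -0.2, rep(0, 5))),
               "proportions")
})

test_that("evolve realizes the transition matrix it is given", {
  A <- drift_matrix()
  spec <- landscape_spec(rows = 100, cols = 100, patchiness = 0, seed = 4)
  r1 <- generate_initial(spec)

  # identity dynamics change nothing
  expect_identical(evolve(r1, transition_matrix(diag(7)), seed = 5)$grid,
                   r1$grid)

  # composition after one step matches the Markov projection within 3 sigma
  # of the per-class binomial sampling error
  r2 <- evolve(r1, A, seed = 5, clustered = FALSE)
  n_i <- tabulate(r1$grid[!is.na(r1$grid)], nbins = 7)
  expected <- as.numeric(n_i %*% A$A)
  sd_j <- sqrt(colSums(A$A * (1 - A$A) * n_i))
  got <- tabulate(r2$grid[!is.na(r2$grid)], nbins = 7)
  expect_true(all(abs(got - expected) <= 3 * sd_j + 1e-9))

  # clustered mode fixes flip counts at the expected multinomial values
  r2c <- evolve(r1, A, seed = 5, clustered = TRUE)
  gotc <- tabulate(r2c$grid[!is.na(r2c$grid)], nbins = 7)
  expect_true(all(abs(gotc - expected) <= 1 + 7))  # rounding only
  # and aggregates change spatially relative to independent sampling
  expect_identical(evolve(r1, A, seed = 5, clustered = TRUE)$grid, r2c$grid)
})

test_that("transition recovery error shrinks as the landscape grows", {
  A <- drift_matrix()
  err_at <- function(n, seed) {
    spec <- landscape_spec(rows = n, cols = n, patchiness = 0, seed = seed)
    r1 <- generate_initial(spec)
    r2 <- evolve(r1, A, seed = seed + 1)
    max(abs(estimate_transition(r1, r2)$A - A$A))
  }
  e_small <- err_at(100, 41)   # 1e4 cells
  e_large <- err_at(320, 41)   # ~1e5 cells
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.02)
})

test_that("multi-epoch scenarios carry labels and dynamics through", {
  spec <- landscape_spec(rows = 60, cols = 60, patchiness = 2, seed = 6)
  eps <- generate_scenario(spec, c(1995, 2005, 2015),
                           list(drift_matrix(), drift_matrix()))
  expect_equal(vapply(eps, function(r) r$year, numeric(1)),
               c("1995" = 1995, "2005" = 2005, "2015" = 2015))
  expect_equal(sum(tabulate_areas(eps[[3]])), sum(tabulate_areas(eps[[1]])))
  expect_error(generate_scenario(spec, c(1995, 1995), list(drift_matrix())),
               "increasing")
})

test_that("packaged study tables have the printed totals (fixture integrity)", {
  areas <- central_asia_areas()
  for (y in unique(areas$year)) {
    # printed rows are rounded to 2 decimals, so their sum can sit up to
    # 0.005 x 7 classes off the printed constant total
    expect_equal(sum(area_row(areas, y, unit = "1e4_ha")), 40010.48,
                 tolerance = 0.035 / 40010.48)
  }
  expect_equal(area_row(areas, 1995, unit = "1e4_ha")[["urban"]], 27.57)
  vc <- value_coefficients()
  expect_equal(sum(vc["wetland", ]), 25681)
  fx <- paper_fixture()
  expect_identical(fx$areas, areas)
  expect_identical(fx$vc, vc)
})
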