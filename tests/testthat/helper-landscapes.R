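# Shared fixtures built in code.

# Raster from a small integer matrix of class ids (NA = nodata).
mini_raster <- function(m, cell_area_ha = 9, year = NA_integer_) {
  lulc_raster(matrix(as.integer(m), nrow(m), ncol(m)),
              cell_area_ha = cell_area_ha, year = year)
}

# A drifting 7-class transition matrix in the study's spirit: cropland and
# urban expand (fed by grassland and bare land), water shrinks into bare.
drift_matrix <- function() {
  A <- diag(7)
  A[1, 1] <- 0.96; A[1, 3] <- 0.04                 # some cropland abandonment
  A[3, 3] <- 0.93; A[3, 1] <- 0.05; A[3, 5] <- 0.02 # grassland -> crop/urban
  A[6, 6] <- 0.97; A[6, 1] <- 0.03                 # bare reclaimed to crop
  A[7, 7] <- 0.90; A[7, 6] <- 0.10                 # water dries to bare
  transition_matrix(A)
}

# Printed per-class ESV table (billion US$), classes x years.
printed_table3 <- function() {
  matrix(c(422.79, 478.27, 490.68, 503.87, 516.24,
           25.12, 25.13, 25.11, 25.08, 25.05,
           856.54, 825.31, 831.02, 836.40, 841.66,
           31.11, 31.25, 32.17, 32.47, 32.98,
           1.84, 4.01, 5.94, 6.45, 7.76,
           0, 0, 0, 0, 0,
           167.92, 147.02, 131.31, 117.51, 103.54),
         7, 5, byrow = TRUE,
         dimnames = list(lulc_classes(), c(1995, 2005, 2015, 2025, 2035)))
}

# Printed per-function ESV table (billion US$), functions x years.
printed_table4 <- function() {
  matrix(c(426.08, 440.12, 446.82, 453.74, 460.31,
           29.85, 31.64, 32.22, 32.80, 33.37,
           1.87, 1.80, 1.81, 1.82, 1.83,
           45.09, 49.20, 50.56, 51.59, 52.90,
           177.36, 165.34, 154.83, 145.58, 136.33,
           63.98, 70.02, 71.66, 73.23, 74.84,
           62.49, 64.37, 64.31, 64.33, 64.38,
           609.01, 601.26, 607.24, 613.05, 618.73,
           89.59, 87.25, 86.78, 84.92, 84.52),
         9, 5, byrow = TRUE,
         dimnames = list(esv_functions(), c(1995, 2005, 2015, 2025, 2035)))
}

# Printed sensitivity table: list of (pct, cs) matrices, classes x years.
printed_table5 <- function() {
  pct <- matrix(c(14.04, 15.83, 16.18, 16.56, 16.90,
                  0.83, 0.83, 0.83, 0.82, 0.82,
                  28.45, 27.31, 27.40, 27.49, 27.56,
                  1.03, 1.42, 1.79, 1.06, 1.08,
                  0.06, 0.13, 0.20, 0.20, 0.25,
                  0.00, 0.00, 0.00, 0.00, 0.00,
                  5.58, 4.87, 4.33, 3.86, 3.39),
                7, 5, byrow = TRUE,
                dimnames = list(lulc_classes(),
                                c(1995, 2005, 2015, 2025, 2035)))
  cs <- matrix(c(0.28, 0.32, 0.32, 0.33, 0.34,
                 0.02, 0.02, 0.02, 0.02, 0.02,
                 0.57, 0.55, 0.55, 0.55, 0.55,
                 0.02, 0.03, 0.04, 0.02, 0.02,
                 0.00, 0.00, 0.00, 0.00, 0.01,
                 0.00, 0.00, 0.00, 0.00, 0.00,
                 0.11, 0.10, 0.09, 0.08, 0.07),
               7, 5, byrow = TRUE, dimnames = dimnames(pct))
  list(pct = pct, cs = cs)
}

# Independent brute-force kappa: per-cell agreement and marginal products,
# computed from the raw label vectors with no confusion matrix.
brute_kappa <- function(v1, v2) {
  keep <- !is.na(v1) & !is.na(v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  p0 <- mean(v1 == v2)
  pc <- 0
  for (k in union(v1, v2)) pc <- pc + mean(v1 == k) * mean(v2 == k)
  (p0 - pc) / (1 - pc)
}
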