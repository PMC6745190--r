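#!/usr/bin/env Rscript
# Generate a three-epoch synthetic landscape standing in for the 300 m
# land-cover product: 1995 composition drawn from the packaged area table,
# patch structure from smoothed-noise thresholding, and decadal change driven
# by a known transition matrix (cropland and urban expand, water shrinks into
# bare land). The known matrix makes every downstream estimate checkable.

library(landesv)

seed <- 20260926 %% 1000003L
spec <- landscape_spec(rows = 200, cols = 200, patchiness = 3, seed = seed)

A <- diag(7)
A[1, 1] <- 0.96; A[1, 3] <- 0.04
A[3, 3] <- 0.93; A[3, 1] <- 0.05; A[3, 5] <- 0.02
A[6, 6] <- 0.97; A[6, 1] <- 0.03
A[7, 7] <- 0.90; A[7, 6] <- 0.10
A <- transition_matrix(A)

epochs <- generate_scenario(spec, c(1995, 2005, 2015), list(A, A),
                            clustered = TRUE)

dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)
for (y in names(epochs)) {
  write_asc(epochs[[y]], file.path("results/synthetic",
                                   paste0("lulc_", y, ".asc")))
}
write_transition_csv(A, "results/synthetic/true_transition.csv")
yaml::write_yaml(
  list(rows = spec$rows, cols = spec$cols, seed = spec$seed,
       patchiness = spec$patchiness, cell_area_ha = spec$cell_area_ha,
       proportions = as.list(spec$proportions),
       years = as.integer(names(epochs))),
  "results/synthetic/manifest.yaml"
)

for (y in names(epochs)) {
  sh <- tabulate_areas(epochs[[y]])
  cat(sprintf("%s: %s\n", y,
              paste(sprintf("%s %.1f%%", lulc_classes(), 100 * sh / sum(sh)),
                    collapse = ", ")))
}
cat("Epoch rasters, true matrix and manifest written under results/synthetic/\n")
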