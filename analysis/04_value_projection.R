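#!/usr/bin/env Rscript
# Value the synthetic projection: convert the tabulated and projected class
# areas from 03_project_lulc.R into ecosystem service values with the
# packaged coefficient matrix, and run the elasticity analysis on them.
# Run 02 and 03 first.

library(landesv)

areas <- utils::read.csv("results/projection/areas.csv")
res <- run_valuation(list(areas = areas,
                          out_dir = "results/projection_valuation"))

rep <- res$report
cat("\nTotal ESV of the synthetic landscape (billion US$):\n")
print(round(rep$total, 4))
cat(sprintf("\nChange 1995-2035: %+.2f%%\n",
            rep$total_change_pct[["1995-2035"]]))
cs95 <- res$sensitivity[res$sensitivity$year == min(areas$year), ]
cat("\nValue shares (CS) of the initial epoch:\n")
print(transform(cs95, pct_change = round(pct_change, 2), cs = round(cs, 2)),
      row.names = FALSE)
cat("\nReports written under results/projection_valuation/\n")
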