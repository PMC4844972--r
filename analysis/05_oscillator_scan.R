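#!/usr/bin/env Rscript
# Stage 5: phosphoform oscillator and concentration-robustness scan.
#
# Integrates the four-state KaiC phosphoform model with the explicit
# KaiA-KaiC binding equilibrium from dephosphorylated initial conditions,
# extracts the oscillation period after a 240 h transient, and scans
# dissociation constant x total-protein scale. The headline numbers: ~21 h
# at the standard 1X mixture with K_D = 1.0 uM, and a period that stays
# within a fraction of an hour across 0.5-4X when K_D = 0.1 uM, with the
# robustness metric improving monotonically as K_D decreases.

suppressPackageStartupMessages(library(kaiabc))

out <- "results/oscillator"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (kd in c(1.0, 0.1)) {
  traj <- integrate_oscillator(oscillator_params(kd = kd))
  keep <- traj$time <= 120  # plot-scale excerpt
  write.table(format(traj[keep, ], digits = 6),
              file.path(out, sprintf("trajectory_kd%.1f.tsv", kd)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  pe <- extract_period(traj)
  cat(sprintf("K_D = %.1f uM, 1X: period %.2f h, amplitude %.3f (%d cycles)\n",
              kd, pe$period, pe$amplitude, pe$n_peaks))
}

scan <- concentration_scan(oscillator_params(),
                           scales = c(0.5, 1, 2, 4),
                           kds = c(2.5, 1.0, 0.5, 0.1))
write.table(format(scan, digits = 6), file.path(out, "scan.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
rob <- attr(scan, "robustness")
write.table(format(rob, digits = 6), file.path(out, "robustness.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("\nperiod (h) by K_D (rows) x concentration scale (columns):\n")
print(round(matrix(scan$period, 4, 4, byrow = TRUE,
                   dimnames = list(paste0("KD=", c(2.5, 1.0, 0.5, 0.1)),
                                   paste0(c(0.5, 1, 2, 4), "X"))), 2))
cat("\nrobustness (period range / median across scales):\n")
print(rob, row.names = FALSE)
cat("\nsmaller K_D -> flatter period across concentrations:",
    all(diff(rob$range_over_median[order(-rob$kd)]) <= 0), "\n")
writeLines(sprintf("05_oscillator t1=%.3f t2=%.3f",
                   scan$period[scan$kd == 1.0 & scan$scale == 1],
                   scan$period[scan$kd == 0.1 & scan$scale == 4]),
           file.path(out, "MANIFEST_05"))
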