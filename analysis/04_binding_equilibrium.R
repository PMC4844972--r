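#!/usr/bin/env Rscript
# Stage 4: two-step KaiA-KaiC binding thermodynamics.
#
# The dynamic-interaction hypothesis says KaiA-KaiC binding is a two-step
# process — an encounter complex followed by conformational isomerization
# (A + C <-> A.C <-> A'.C'). When the two complex states cannot be told
# apart, the measured dissociation constant K_Dfit pools both, and mass
# action gives 1/K_Dfit = 1/K_Dapp1 + 1/K_Dapp2: there is a gamma in (0,1)
# with K_Dfit = gamma K_Dapp1 = (1-gamma) K_Dapp2, so the effective constant
# is below either apparent one. This stage tabulates the relation across
# schemes and reproduces the half-life-based estimate that turns a reported
# ~2.5 uM constant into the ~0.1 uM used in the oscillator scan.

suppressPackageStartupMessages(library(kaiabc))

out <- "results/binding"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(42)
grid <- expand.grid(k1 = c(0.1, 0.5, 1, 2.5), k2 = c(0.1, 0.5, 1, 5, 20))
tab <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  st <- solve_two_step(two_step_scheme(grid$k1[i], grid$k2[i]),
                       a_tot = 1.3, c_tot = 3.4)
  bc <- binding_constants(st)
  data.frame(k1 = grid$k1[i], k2 = grid$k2[i],
             kd_app1 = bc$kd_app1, kd_app2 = bc$kd_app2,
             kd_fit = bc$kd_fit, gamma = bc$gamma)
}))
write.table(format(tab, digits = 6), file.path(out, "two_step_constants.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("across %d schemes (KaiA 1.3, KaiC 3.4 uM):\n", nrow(tab)))
cat(sprintf("  K_Dfit < min(K_Dapp1, K_Dapp2) in %d/%d cases\n",
            sum(tab$kd_fit < pmin(tab$kd_app1, tab$kd_app2)), nrow(tab)))
cat(sprintf("  gamma range: %.4f - %.4f (always inside (0,1))\n",
            min(tab$gamma), max(tab$gamma)))

# the half-life argument: a ~20-fold slower complex decay at longer
# incubation implies a ~20-fold smaller dissociation constant
kd_est <- kd_rescale_from_halflife(2.5, 20)
cat(sprintf("reported 2.5 uM with 20-fold half-life increase -> %.3f uM\n",
            kd_est))
cat("(the oscillator scan adopts the round value 0.1 uM)\n")
writeLines(sprintf("04_binding kd_est=%.4f", kd_est),
           file.path(out, "MANIFEST_04"))
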