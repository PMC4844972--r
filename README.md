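# kaiabc

Coevolution, binding thermodynamics and phosphoform dynamics of the
cyanobacterial KaiABC circadian clock, as an R package plus a reproducible
analysis workflow.

The KaiABC oscillator is the canonical post-translational circadian clock:
KaiC autophosphorylates at T432 and S431, KaiA stimulates phosphorylation by
binding KaiC's disordered C-terminal tail, and KaiB antagonizes KaiA on
S431-phosphorylated KaiC. `kaiabc` is aimed at molecular systems biologists
studying how the *dynamics* of the KaiA–KaiC interaction shape the clock. It
implements three linked analyses:

1. **Co-varying residue clusters.** From concatenated KaiA/KaiB/KaiC
   alignments: per-column relative evolution rates (RERs; discrete-gamma
   empirical Bayes under WAG, mean-normalized to 1), and pairwise column
   correlations of side-chain volume, polarity and hydrophobicity
   (Pearson r, Student t with n−2 df, per-pair 95% level; columns filtered
   at ≤5% gaps and ≥2 residue types). Significant pairs that are also in
   side-chain contact (min heavy-atom distance ≤ 4.5 Å) form clusters as
   connected components.
2. **Two-step binding.** For A + C ⇌ A·C ⇌ A′·C′ with pooled measurement
   K_Dfit = [A][C]/([A·C]+[A′·C′]), the identity
   1/K_Dfit = 1/K_Dapp1 + 1/K_Dapp2 holds, so K_Dfit = γ·K_Dapp1 =
   (1−γ)·K_Dapp2 with γ ∈ (0,1): the combined constant is below either
   apparent constant — an equilibrium assay that cannot separate the two
   complex states over-estimates the dissociation constant.
3. **Phosphoform oscillator.** The four-state U/T/S/D model (reference rate
   constants, K_half = 0.43 µM) with an explicit KaiA–KaiC binding
   equilibrium of dissociation constant K_D: tight KaiB-mediated
   sequestration of KaiA by S-KaiC (stoichiometry 2), KaiA depletion by the
   KaiC tail pool, and stimulation anchored to the reference condition
   (KaiA 1.3 / KaiC 3.4 µM, K_D,ref = 1 µM). As K_D → 0 the stimulation
   depends on concentration ratios only, which is why a tighter KaiA–KaiC
   equilibrium makes the oscillation period robust to proportional changes
   of all protein totals.

A synthetic-data module (trees, alignments with planted property-coupled
column pairs, toy PDB structures, oscillation fixtures) makes the entire
pipeline testable offline. See the methods vignette
(`vignettes/kaiabc-methods.Rmd`) for models, assumptions and design
decisions.

## Worked example

Simulate the oscillator at the standard 1X in-vitro mixture with K_D = 1 µM
and extract the period:

```r
library(kaiabc)
p  <- oscillator_params(kd = 1.0)            # KaiA 1.3, KaiB 3.4, KaiC 3.4 uM
pe <- extract_period(integrate_oscillator(p))
pe
#> <kai_period> 20.71 h (sd 4.22e-05, 10 peaks, amplitude 0.397)
```

The phosphorylated fraction oscillates with a ~20.7 h period (circadian-range
for this parameterization) and a 0.40 amplitude. Scanning dissociation
constant × total-protein scale (ratios fixed):

```r
scan <- concentration_scan(oscillator_params(),
                           scales = c(0.5, 1, 2, 4),
                           kds = c(2.5, 1.0, 0.5, 0.1))
attr(scan, "robustness")
#>    kd range_over_median          cv n_oscillating
#> 1 2.5       0.045514447 0.019760141             4
#> 2 1.0       0.031986906 0.013951965             4
#> 3 0.5       0.020388232 0.008936598             4
#> 4 0.1       0.005118616 0.002258536             4
```

The period spread across 0.5–4X shrinks monotonically as K_D decreases; at
K_D = 0.1 µM the period varies by only ~0.1 h (range/median 0.005) across an
8-fold concentration range.

The analysis workflow runs the full study on synthetic inputs:

```sh
Rscript analysis/01_synthetic_data.R        # tree, alignments, toy structure
Rscript analysis/02_tree_and_rates.R        # NJ tree + RERs (truth recovery)
Rscript analysis/03_covariation_clusters.R  # scan + contacts -> clusters
Rscript analysis/04_binding_equilibrium.R   # two-step constants and gamma
Rscript analysis/05_oscillator_scan.R       # trajectories + robustness scan
```

Stage 2, for instance, reports `RER vs true site rates: Spearman rho = 0.947
over 240 columns`, and stage 3 recovers all three planted cross-protein
pairs as significant and assembles exactly the three planted contact
clusters. Tables land under `results/`.

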