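---
title: "Methods: coevolution, binding and phosphoform dynamics of the KaiABC clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolution, binding and phosphoform dynamics of the KaiABC clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaiabc)
```

The cyanobacterial circadian oscillator is a three-protein machine: KaiC
autophosphorylates on T432 and S431, KaiA stimulates that phosphorylation by
grabbing KaiC's intrinsically disordered C-terminal tail, and KaiB antagonizes
KaiA by capturing it on S431-phosphorylated KaiC. `kaiabc` implements three
connected analyses of the KaiA-KaiC interaction:

1. **Coevolution**: find alignment column pairs across the clock proteins
   whose physicochemical properties change together over a phylogeny, and
   group structurally contacting significant pairs into co-varying residue
   clusters.
2. **Binding thermodynamics**: the algebra of a two-step (encounter +
   isomerization) binding scheme, showing that the measurable combined
   dissociation constant is smaller than either step's apparent constant.
3. **Dynamics**: a four-state KaiC phosphoform ODE model with an explicit
   KaiA-KaiC binding equilibrium, and the resulting dependence of the
   oscillation period on total protein concentration as a function of the
   binding constant.

A synthetic-data module generates every input the pipeline needs (trees,
alignments with planted co-varying pairs, toy structures, oscillation
fixtures), so the full analysis is reproducible offline. The numbered
scripts under `analysis/` run the stages end to end at desk scale.

# Sequence handling

Alignments are read from FASTA or Clustal files (`read_alignment()`),
upper-cased, with `.` normalized to `-`. The unknown residue `X` is treated
as missing throughout — column statistics count it as a gap and it never
contributes to a distinct-residue count or a property encoding. Per-protein
alignments sharing species are concatenated (`concatenate_alignments()`)
into a block-structured alignment; under the default `intersection` policy,
species absent from any block are dropped with a warning (how the original
species sets were reconciled is unknowable from outside, so the conservative
intersection is the default). `build_ref_map()` assigns 1-based residue
numbers of a chosen reference species per block, skipping reference gaps;
all user-facing residue labels ("KaiA-259" style) come from this map, while
internal column indices are plain 1-based positions of the concatenation.

# Tree and site rates

Pairwise distances (`protein_distances()`) use pairwise deletion (only
columns where both sequences carry a standard residue) with the p,
Poisson (`-log(1-p)`) or Kimura protein (`-log(1 - p - 0.2 p^2)`)
corrections; the Kimura correction is the default choice in the analysis
scripts, matching common practice for protein NJ trees. Saturated pairs
(correction undefined) are flagged rather than silently truncated.

`nj_tree()` is the Saitou-Nei agglomeration: join the pair minimizing
`(r-2) d(i,j) - R_i - R_j`, with the standard branch-length formulas. Two
conventions are fixed so results are reproducible: ties are broken toward
the lowest original species-index pair, and a negative branch-length
estimate is clamped to zero with the deficit moved to its sister branch
(preserving the path length between the joined nodes). On additive matrices
this recovers the generating topology and branch lengths exactly (tested
against 50 random 5-8 taxon trees and against a brute-force least-squares
search over all 15 unrooted 5-taxon topologies).

Site rates use a fixed tree rather than re-optimizing branch lengths per
column: relative evolution rates are driven mainly by column patterns and
tree shape, and the acceptance surface for this package is recovery on
synthetic truth (Spearman rank correlation with generating rates), which the
fixed-tree estimator passes with a wide margin. `column_likelihood()` is
Felsenstein pruning with `exp(Q r t)` transition matrices; the WAG and JTT
matrices (with their published model frequencies, not observed +F
frequencies — the simpler canonical choice) come from phangorn's model data,
rescaled so the mean equilibrium rate is 1; gaps are fully ambiguous states.
`site_relative_rates()` is empirical Bayes over a discrete-gamma prior:
equal-weight categories with mean-1 category means (default 8 categories,
shape 1 — deliberately agnostic defaults, both configurable), posterior-mean
rate per column, then a final rescaling so the mean over scored columns is
exactly 1. That normalization is what "relative" means here: conserved
columns score well below 1. Columns that are entirely gaps are reported
missing and excluded from the normalization.

# Covariation

Columns enter the scan if they have at most 5% missing residues
("95% sequence coverage") and at least 2 distinct residue types — both
thresholds configurable. Each eligible column is encoded on a property
scale: residue volume (Zamyatnin), polarity (Grantham) or hydropathy
(Kyte-Doolittle); the values are shipped in the package and any named
20-vector can be substituted. For a column pair, `pair_correlation()`
computes the Pearson coefficient over pairwise-complete species, the t
statistic `r sqrt((n-2)/(1-r^2))` and its two-sided p-value; significance
is per pair at `alpha = 0.05` by default, with no multiple-testing
correction — the per-pair 95% level is the convention this analysis
follows; a Benjamini-Hochberg option exists but is off by default.
Correlation signs are reported; clustering uses significance only.

Two caveats are built into the interpretation rather than the code. First,
species on a shared phylogeny are not independent samples, so the scan's
background significant fraction on real or simulated alignments is far
above the nominal 5% (the analysis scripts print it; on the synthetic data
it is roughly a quarter of all pairs). The i.i.d.-null calibration of the
test statistic itself is verified separately in the test suite (5.0% +/- 1
point over 10^4 pairs). No phylogenetic correction is attempted — this is a
known limitation, and it is exactly why the structural-contact restriction
matters. Second, `assemble_clusters()` builds a graph whose edges are pairs
that are *both* significant on some scale *and* in side-chain contact
(minimum side-chain heavy-atom distance <= 4.5 Angstroms, the standard
side-chain contact definition; C-alpha fallback for glycine; intra-chain
pairs need sequence separation >= 2), and reports connected components with
at least two members. Contact restriction removes most of the
phylogenetically inflated background.

# Two-step binding

The binding scheme is `A + C <-> A.C <-> A'.C'`, an encounter complex
followed by a conformational isomerization (the primed species are the
post-change states). `solve_two_step()` finds the equilibrium by a monotone
one-dimensional root solve on the total complex concentration, bracketed in
`[0, min(A_tot, C_tot)]`; the solution is verified in tests against an
iterated grid-refinement oracle and conserves mass to 1e-9 relative across
1000 random schemes. With `K_Dapp1 = [A][C]/[A.C]`,
`K_Dapp2 = [A][C]/[A'.C']` (defined against the fully isomerized complex —
the convention that makes the decomposition below exact) and the pooled
`K_Dfit = [A][C]/([A.C]+[A'.C'])`, the definitions give identically

$$\frac{1}{K_{Dfit}} = \frac{1}{K_{Dapp1}} + \frac{1}{K_{Dapp2}},$$

so with `gamma = K_Dapp2/(K_Dapp1 + K_Dapp2)` in (0,1):
`K_Dfit = gamma K_Dapp1 = (1-gamma) K_Dapp2`, and the combined constant is
strictly below either apparent constant whenever both complexes are
populated. The practical reading: an equilibrium experiment that cannot
distinguish the encounter from the isomerized complex reports a *larger*
dissociation constant than the fully engaged interaction warrants.
`kd_rescale_from_halflife()` implements the complementary kinetic estimate:
if longer incubation increases the complex half-life `ln(2)/k_off` by some
fold with an unchanged association rate, the dissociation constant is
smaller by the same fold (2.5 uM with a 20-fold increase gives 0.125 uM,
rounded to 0.1 uM as the tight-binding operating point of the oscillator
scan).

`free_ligand()` — the 1:1 binding quadratic used throughout the oscillator —
is evaluated in the cancellation-free (citardauq) form, because the
small-`K_D` regime is precisely the operating point of interest and the
naive quadratic formula loses precision there. `K_D = 0` returns the exact
stoichiometric limit.

# The phosphoform oscillator

The dynamical state is the three phosphorylated KaiC forms T, D, S in uM
(U follows by conservation). Each of the eight transitions of the
phosphoform cycle has rate `k0 + kA * f`, with the widely used reference
parameterization of the four-state model (shipped as
`reference_rates()`, `K_half = 0.43` uM, standard totals KaiA 1.3,
KaiB 3.4, KaiC 3.4 uM); the transcription is validated behaviorally — at
the reference operating point the model oscillates at 20.7 h with the
phosphorylated fraction swinging between roughly 26% and 66%, matching that
model's published behavior. KaiB does not appear explicitly: its role is
subsumed in the sequestration term, and its total is carried only so that
"scale all totals" means what it says.

KaiA enters twice, and the distinction is the core modeling decision:

* **Sequestration** (KaiB-mediated): S-form KaiC captures KaiA with
  stoichiometry `m = 2` monomers (one dimer) per S monomer. This capture is
  treated as effectively irreversible — `active_kaia()` solves the 1:1
  quadratic at a sequestration constant `kd_seq` whose default 0 is the
  stoichiometric clamp `max(0, A_tot - m S)` of the reference model. The
  reason it must be tight is quantitative, not aesthetic: the sequestering
  site concentration never exceeds a couple of uM, so a sequestration
  constant of order 1 uM would leave >= 0.6 uM KaiA free at all times,
  the stimulation would never switch off, and the limit cycle would decay
  to a fixed point. A micromolar-scale equilibrium on *this* step is
  dynamically incompatible with sustained oscillation under the reference
  rates, for any stoichiometry whose switch point lies inside the reachable
  S range.

* **Stimulation** (the KaiA-KaiC binding equilibrium that the package
  varies): available KaiA binds the KaiC C-terminal tail pool — capacity
  `m * C_tot` in monomer equivalents, one KaiA dimer per tail, the same
  stoichiometry convention as sequestration — with dissociation constant
  `kd`. The free-KaiA signal relative to the KaiA-replete state,
  `z = A_free(A_avail)/A_free(A_tot)`, is mapped through the reference
  operating point (KaiA 1.3 uM, KaiC 3.4 uM, `kd_ref = 1.0` uM) and fed to
  the reference saturation `A_eff/(K_half + A_eff)`; the mapping is the
  analytic inverse of the binding quadratic, so no iteration is involved.
  Two exact properties pin the construction down. At `kd = kd_ref` and 1X
  totals, `A_eff` equals the available KaiA identically, so the model *is*
  the reference model — consistent with reading the reference
  parameterization as a 1 uM binding equilibrium. And as `kd -> 0`, `z`
  becomes a function of concentration *ratios* only, so scaling all totals
  leaves the dynamics (up to the overall concentration unit) unchanged —
  tight stimulatory binding makes the period robust to proportional
  concentration changes. In between, the depletion geometry of the KaiC
  pool carries the `kd` dependence smoothly.

This placement of the varied constant on the stimulatory tail interaction —
the interaction whose two-step kinetics the binding module analyzes — is a
deliberate design choice; the alternative (varying the sequestration
constant) is ruled out by the argument above. The observable consequences,
computed by `concentration_scan()` and `analysis/05_oscillator_scan.R`: at
`kd = 1.0` uM and 1X the period is 20.7 h; the period's spread across
0.5-4X shrinks monotonically as `kd` decreases through 2.5, 1.0, 0.5,
0.1 uM (range/median 0.046, 0.032, 0.020, 0.005), and at 0.1 uM the period
stays within ~0.1 h of its 1X value at every scale. The *direction* and
ordering of these effects are the scientific claim; the absolute spread at
large `kd` is modest in this formulation.

Numerics: `deSolve::lsoda` at `rtol = 1e-8`, dense output every 0.05 h,
fully dephosphorylated initial state (mirroring the in-vitro protocol),
480 h of integration with the first 240 h discarded. Mass conservation is
enforced to 1e-6 relative and the period changes by under 1e-3 h when the
tolerance is halved, the horizon doubled, the output grid halved, or the
initial state perturbed within the basin. `extract_period()` segments the
record into cycles by upward midline crossings with 10% hysteresis, takes
one local maximum per cycle, refines it by quadratic interpolation through
its three-point neighborhood, and averages peak-to-peak intervals; fewer
than five complete cycles, or a mean peak-to-trough amplitude below 1% of
total KaiC, is reported as non-oscillating. The hysteresis segmentation
(rather than raw sign changes of the derivative) is what makes the
estimator robust on noisy fixtures; an optional 1 h moving-average
pre-filter is applied by default and is inert on smooth ODE output.

# The synthetic-data generator

`simulate_tree()` draws a pure-birth topology conditioned on the taxon
count and rescales branch lengths so the mean root-to-tip path equals
`tree_height` (default 0.5; the analysis scripts use 1.0 substitutions/site
for a deep, clock-protein-like divergence). `simulate_alignment()` evolves
independent columns by drawing equilibrium root states and mutating along
branches under the chosen substitution model with mean-1 gamma site rates.

Planted co-varying pairs are *event-driven*: the driver column is simulated
by explicit substitution events, and at each event, with probability
`coupling`, the partner's state is replaced by the residue whose property
rank matches (sign +1) or mirrors (sign -1) the driver's new residue, with
a small softmax temperature for stochasticity. Two design decisions matter
for what "coupling = 0.9" delivers at the detector:

* the partner's *independent* substitution rate is scaled by
  `1 - coupling` — a strongly compensatory site substitutes mostly together
  with its partner, not on its own clock. Without this, neutral churn
  between coupling events erodes the planted signal along deep branches.
* planted columns carry the mean rate (multiplier 1) instead of a gamma
  draw: a pair planted in a near-invariant column is undetectable by any
  method, so leaving planted rates to the lottery would benchmark the draw,
  not the detector.

Under these defaults the scan recovers 85-91% of planted pairs at
coupling 0.9 with 64 taxa (pooled over five replicate simulations), zero
coupling is indistinguishable from background, and power rises with both
coupling strength and taxon count. Event-driven coupling survives the
phylogeny — which is also why the *uncoupled* background is inflated: what
passing these tests shows is that the engine detects property-coupled
evolution on a tree, not that the 5% nominal level controls errors on
phylogenetically structured data (it does not, and the package makes no
such claim). Real alignments additionally feature indels, heterotachy,
paralogy and alignment error, none of which the generator imitates.

`toy_structure()` writes minimal fixed-width ATOM records (a CA and a CB
per residue at specified coordinates) that round-trip through standard PDB
readers — a stand-in for a real complex structure in contact-map tests, and
labelled synthetic throughout. `oscillation_fixture()` produces sine,
harmonic and noisy trajectories with known periods for validating the
period extractor.

# Problem sizes

The shipped analysis runs at desk scale, chosen to exercise every code path
while keeping the full pipeline in the minutes range: 65 taxa, 80 columns
per protein block, 3 planted pairs, a 20-scheme binding grid, and a 4 x 4
oscillator scan integrated for 480 h per cell. All sizes are arguments, not
constants.

# Known limitations

* No phylogenetic correction of pair correlations (contact restriction is
  the mitigation); no mutual-information or direct-coupling alternatives.
* Site rates come from a fixed NJ tree; maximum-likelihood branch-length
  re-estimation is not performed (an acceptable simplification at the
  recovery levels tested, but a refinement hook worth adding).
* The oscillator is deterministic and hexamer-free: no stochastic
  single-molecule effects, no monomer exchange, no explicit KaiB kinetics,
  no temperature compensation.
* Percent-phosphorylation data of real gels (densitometry) are not fit;
  the rate constants are adopted from the reference parameterization, not
  re-estimated.
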