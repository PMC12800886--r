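---
title: "Quantifying trophic and non-trophic grazer effects on biofilm bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trophic and non-trophic grazer effects on biofilm bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazenet)
```

## The problem

Intertidal mollusk grazers affect rock-surface (epilithic) biofilm
bacteria through two distinct channels: a trophic channel — grazing
consumes biofilm — and a non-trophic channel mediated by the pedal mucus
and exudates the animal leaves behind. The two are entangled in any
grazing treatment, because a grazer cannot feed without also depositing
mucus. `grazenet` implements an experimental-algebra approach to
separating them, together with the network statistics used to describe
the resulting grazer-by-bacterium interaction structure.

The experimental design the package assumes has three treatment classes
per grazer species:

* **control** — biofilm with no grazer (13 replicates by default);
* **grazing** — one grazer feeding freely; carries the *total* effect,
  grazing plus mucus (13 replicates per species);
* **mucus** — one grazer walking on a mesh cage above the biofilm, so
  only pedal mucus and exudates reach the surface; carries the
  *non-trophic* effect (10 replicates per species).

With five grazer species this is 128 experimental units. Bacterial
communities are characterized as ASV count tables from 16S amplicon
sequencing (the motivating data rarefy at 6215 reads per sample).

## Interaction strength: the Dynamic Index on clr-transformed counts

Per-capita interaction strength is the Dynamic Index

$$DI = \frac{\ln(N / D)}{Y\,t},$$

where $N$ and $D$ are the target's relative abundance with and without
the grazer, $Y$ the grazer abundance (1 per replicate here) and $t$ the
duration (one experimental period). Amplicon counts are compositional,
so before comparing groups every sample is closed to proportions after a
uniform pseudocount (default 1) and mapped through the centered log-ratio
transform $\mathrm{clr}(x)_i = \ln(x_i / g(x))$, $g$ the geometric mean.

Two DI spaces are provided behind `analysis_config(di_space = ...)`:

* `clr_difference` (default): $DI = (\mathrm{clr}_N - \mathrm{clr}_D) /
  (Y t)$ between group means. Because clr values can be zero or negative,
  a literal $\ln(N/D)$ on them is ill-defined; the clr *difference* is the
  log-ratio of the target relative to the community geometric mean and is
  exactly the estimand the simulator plants (see below). It is also
  invariant to per-sample sequencing depth.
* `relative_ratio`: literal evaluation on group-mean proportions, for
  fidelity to the index's original definition.

The point estimate is the DI of group means, not the mean of pairwise
DIs: replicates are independent aquaria, so no natural pairing between a
treatment replicate and a control replicate exists. Uncertainty comes
from a percentile bootstrap (default 9999 draws) resampling treatment
and control replicates independently; an effect is significant when the
95% interval excludes zero. No multiple-testing correction is applied to
edge significance by default; `bh_correct = TRUE` switches to
Benjamini–Hochberg-adjusted bootstrap p-values, which trades edge
sensitivity for precision (see "Error rates" below).

The trophic effect is never observed directly; it is the difference

$$DI_{TI} = DI_{total} - DI_{NTI},$$

computed by `decompose_trophic()`. Its bootstrap distribution pairs the
total and non-trophic draws by index: both estimates share the control
bootstrap stream (the stream is seeded by (seed, grazer) only), so the
difference distribution respects the common control resampling. Point
estimates satisfy the additivity identity exactly, by construction.

## The simulator and what it does (and does not) emulate

`simulate_experiment()` generates the full design with known ground
truth. Baseline ASV log-abundances are drawn once from a normal with SD
1.5 (log-normal rank-abundance curves are typical of biofilm
communities); sparse signed effects are planted on 10% of (grazer, ASV)
pairs independently for the trophic and non-trophic channels, with
magnitudes N(0, 1) (or exactly ±1 via `effect_magnitude`, the
configuration used for recovery checks). Grazing samples carry
`delta_ti + delta_nti`, mucus samples `delta_nti` only — mirroring the
treatment semantics above. Replicate noise (SD 0.3 on the log scale),
Dirichlet overdispersion (total concentration 200, mid-range for
published Dirichlet-multinomial fits to 16S data) and negative-binomial
library sizes (mean 6215, size 50) complete the count model; each
sample's expected composition is closed to proportions before counts are
drawn.

The simulator does **not** emulate: taxonomic structure or phylogenetic
correlation among ASVs, chimeras or sequencing error (counts are
error-free draws from the true composition), grazer behaviour,
between-grazer interactions, or temporal biofilm succession. Passing
recovery tests therefore demonstrates the estimator's correctness under
the compositional log-linear model it assumes — not robustness to every
feature of real amplicon data.

## Error rates at the default design

Bootstrap CIs at 10–13 replicates are mildly anticonservative: the
zero-effect false-positive rate sits near 0.06–0.09 rather than 0.05.
With 90% of pairs null, that false-positive rate bounds the *precision*
of recovered networks near 0.7–0.8 regardless of power, while recall of
±1 effects is about 0.7 and the sign of significant edges is essentially
always correct (≥ 0.98). `bh_correct = TRUE` improves precision at the
cost of recall, but rare ASVs with large compositional noise can produce
effect-sized false estimates whose p-values sit at the bootstrap floor —
no multiplicity rule screens those, so precision near 1 is not attainable
at this replication level. These operating characteristics are
recomputed, not assumed, by the test suite and `scripts/acceptance.R`.

## Networks and metrics

`build_networks()` filters an effect table to significant edges and
splits them into four networks (trophic/non-trophic × positive/negative)
with `|DI|` weights; the sign lives in network metadata because weighted
nestedness metrics assume non-negative interaction "frequencies".
Grazer rows are retained even when empty, keeping species comparable
across networks; metric code drops empty lines internally and records
the drop.

The nestedness and specialization metrics are implemented from their
primary definitions; `inst/metrics-reference.md` freezes every formula
convention and tie rule, and the test suite pins them with brute-force
and hand-worked oracles:

* `nodf()` / NODF2 — paired overlap with strictly decreasing fill,
  evaluated exhaustively against a brute-force oracle on *all* binary
  matrices up to 4×4 and against `vegan::nestednodf`.
* `weighted_nodf()` — strict-inequality weighted terms (equal-weight
  overlaps score zero), cross-checked against vegan.
* `wnoda()` — overlap with decreasing *abundance* (marginal totals), no
  fill-sorting; hand-worked 3×3 oracle.
* `wine()` — weighted distance-to-corner packing statistic with packed
  and random calibration points and the normalized `eta`; both the raw
  and normalized forms are reported because published WINE values are
  not always on a comparable scale.
* `matrix_temperature()` — unit-square isocline construction with a
  seeded simulated-annealing packing (default 50 000 proposals,
  decreasing-fill warm start). Annealing rather than a genetic algorithm:
  only near-optimal packing matters for the statistic, and a seeded SA
  run is reproducible. Shuffled perfectly nested matrices must cool back
  below 1 temperature unit; permutation of the input changes results by
  less than 2 units at the default budget.
* `discrepancy()` — displaced presences relative to the per-row packed
  block, in the given (`fixed_order`) or totals-sorted (`fill_sorted`,
  the discrepancy2 dialect) column order. Ties in the sort are broken by
  original index and noted here deliberately: metrics that optimize over
  tied column orders (as some implementations do) can report one or two
  fewer moves.
* `h2_prime()` / `d_prime()` — two-dimensional Shannon entropy
  standardized between marginal-preserving extremes. Continuous `|DI|`
  weights are integerized to a total of K = 1000 (the published
  construction assumes integer frequencies); all three entropies are
  computed from the integerized matrix so the ordering invariant holds by
  construction. Extremal tables come from greedy starts refined by 2×2
  transfer moves with optimal integer step; exhaustive enumeration
  (totals ≤ 12) verifies the heuristic in tests.

## Community-level statistics

`rarefy_counts()` (subsampling without replacement, dropping shallow
samples), `richness()`, `shannon_diversity()` (natural log, undefined
for empty samples), `bray_curtis()`, and a one-way `permanova()`
(Anderson's pseudo-F on the distance matrix, seeded label permutations,
`p = (1 + \#\{F^* \ge F\}) / (B + 1)`) cover the community analyses of
the motivating design, which is single-factor. `pairwise_permanova()`
adds FDR-corrected post hocs. The PERMANOVA pseudo-F is cross-checked
against `vegan::adonis2` and its null type-I error is verified to sit in
[0.02, 0.10] over 200 structureless simulations.

## Numerical choices and degenerate inputs

* Quantile type 7 (R default) for bootstrap percentiles.
* Groups with fewer than two replicates yield a point estimate with CI
  marked unavailable (`NA`) and `significant = FALSE`, plus a warning —
  they are never silently dropped.
* All-zero samples: rejected by `replace_zeros()` (no composition
  exists), `NA` in `shannon_diversity()` and `bray_curtis()`.
* Degenerate metric inputs (single row/column, empty matrix) raise
  errors; completely full matrices have temperature 0 by convention.
* The H2′ extremal search clamps `H2` into `[H2_min, H2_max]` if the
  heuristic were ever beaten by the observed table (not observed in
  testing, but the invariant is guaranteed).
* All randomness — simulation, bootstrap, rarefaction, annealing,
  permutations — flows from explicit integer seeds; sub-streams are
  derived deterministically, so every pipeline stage is exactly
  reproducible.

## Problem sizes used by the test and acceptance runs

Tests and the acceptance script scale the documented defaults down to
keep runs quick while preserving the design: bootstrap draws 199–1999
(default 9999), PERMANOVA calibration 200 simulations × 99 permutations,
annealing budgets 3000–50 000 proposals, simulated experiments of 50–150
ASVs at the full 128-sample layout, and recovery means pooled over three
replicate experiments. The vignette and README show the numbers those
runs actually print.

## Known limitations

* The pseudocount strategy attenuates clr differences for very rare
  ASVs; effect estimates for ASVs with expected counts near zero are
  biased toward zero (negative effects especially, since they drive
  counts into the censored zero region). Conversely, under strong
  Dirichlet overdispersion moderately abundant ASVs *overshoot* slightly
  (log-count means follow a digamma curve, not the log of the mean). At
  the default design, planted −1 effects are recovered at about −0.8 on
  average and +1 effects at about +1.0. Because a single experiment has
  only ~65 affected pairs per direction, recovery checks pool three
  replicate experiments to estimate these means with SE ≈ 0.05. The
  pseudocount is configurable and results for rare taxa should be read
  with this in mind.
* Percentile-bootstrap significance at ≤ 13 replicates is slightly
  anticonservative (see "Error rates").
* The temperature optimizer is stochastic; across seeds the statistic
  varies by under 2 units at the default budget, which is adequate for
  comparing networks but not for chasing a third significant digit.
* `relative_ratio` mode depends on the pseudocount through group-mean
  proportions and is provided for comparability, not as the default
  inferential path.
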