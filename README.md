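# grazenet

Quantifying trophic and non-trophic interactions between intertidal
mollusk grazers and epilithic biofilm bacteria from 16S amplicon count
tables.

## The problem

Grazing mollusks shape rock-surface biofilm communities through two
channels at once: consumption (trophic) and the pedal mucus and exudates
they deposit (non-trophic). An experiment can separate them with three
treatment classes per grazer species — an ungrazed control, a free
grazing treatment (total effect = trophic + non-trophic), and a caged
"mucus only" treatment (non-trophic effect). `grazenet` implements the
full analysis for such designs, aimed at microbial ecologists working
with ASV count tables:

* **Interaction strength.** Per-capita, per-time effects via the Dynamic
  Index, `DI = ln(N/D) / (Y t)`, computed by default as a difference of
  group-mean centered log-ratio (clr) values (well-defined for
  compositional counts), with percentile-bootstrap confidence intervals
  and the exact decomposition `DI_trophic = DI_total - DI_non-trophic`.
* **Networks.** Significant effects become four signed, weighted
  grazer-by-ASV bipartite networks (trophic/non-trophic ×
  positive/negative), exportable as edge-list TSV and GraphML.
* **Network architecture.** From-scratch, oracle-tested implementations
  of NODF/NODF2, weighted NODF, WNODA, WINE, matrix temperature
  (seeded simulated-annealing packing), discrepancy/discrepancy2, and
  the Blüthgen specialization indices H2′ and d′
  (see `inst/metrics-reference.md` for frozen conventions).
* **Community statistics.** Rarefaction, richness, Shannon diversity,
  Bray–Curtis dissimilarity, one-way PERMANOVA with seeded permutations
  and FDR-corrected pairwise post hocs.
* **Simulation.** A Dirichlet-multinomial generator reproducing the
  experimental layout (1 control + 5 grazing + 5 mucus treatments;
  13/13/10 replicates; 128 samples; depths near 6215 reads) with known
  sparse signed effects, for end-to-end estimator validation.

## Worked example

```r
library(grazenet)

# simulate the full design with known ground truth (+/-1 log-effects on
# 10% of grazer-ASV pairs)
sim <- simulate_experiment(simulation_config(effect_magnitude = 1, seed = 11))
sim
#> simulated grazer-biofilm experiment: 128 samples x 150 ASVs
#>   grazers: C_granosus, E_peruviana, F_crassa, S_araucana, S_lessonii
#>   samples: control=13, grazing=65, mucus=50
#>   seed: 11

cfg <- analysis_config(n_boot = 999, seed = 2)
tot <- estimate_effects(sim$counts, sim$metadata, cfg, mode = "total")
nti <- estimate_effects(sim$counts, sim$metadata, cfg, mode = "non_trophic")
ti  <- decompose_trophic(tot, nti)
head(ti[ti$significant, c("grazer", "target", "di_mean", "ci_low", "ci_high")], 3)
#>        grazer  target    di_mean       ci_low    ci_high
#> 1  C_granosus ASV0001  1.2641371  0.008061411  2.4180199
#> 15 C_granosus ASV0015  0.9731069  0.205936732  1.8477691
#> 26 C_granosus ASV0026 -1.1028337 -2.057081916 -0.1594999

nets <- build_networks(rbind(ti, nti))
nets$trophic_positive
#> bipartite network [trophic, positive]: 5 grazers x 55 ASVs, 63 edges

metric_report(nets$trophic_positive, seed = 1)
#> metric report (5 x 55, 63 edges, fill 0.23):
#>   nodf           4.8264
#>   nodf2          9.4752
#>   weighted_nodf  5.6436
#>   wnoda          20.6628
#>   wine_dw        18.4173
#>   wine_eta       0.3971
#>   temperature    45.6703
#>   discrepancy    48
#>   discrepancy2   42
#>   h2             4.0277
#>   h2_min         3.8302
#>   h2_max         5.4236
#>   h2_prime       0.8761
```

A `di_mean` of −1.10 means the grazer's presence lowered that ASV's
clr-scale (geometric-mean-relative) abundance by 1.10 natural-log units
per capita per experimental period; the interval excluding zero flags
the edge for the network stage. In the metric report, a sorted NODF
near 9 and temperature near 46 describe a weakly nested network, and
H2′ = 0.88 indicates strong specialization of the recovered edges
(each grazer's significant trophic gains touch largely distinct ASVs). The literal
Dynamic Index is also available directly, e.g. the per-capita effect on
biofilm cover for a treatment mean of 54% against an ungrazed 99.9%:

```r
dynamic_index(54, 99.9)
#> [1] -0.6151856
```

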