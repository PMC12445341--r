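# legacynet

Co-occurrence network analysis of soil drought legacies.

`legacynet` is an R package for asking how the **intensity of a past
drought** reshapes soil microbial communities and plant drought responses
in gradient mesocosm experiments. It takes compositional amplicon (ASV)
count tables from a two-year design — a year-1 soil-water-deficit (SWD)
gradient (20% control to 98% severe), a year-2 drought/control treatment,
two plant community strategies (fast/slow), two harvests (peak drought,
recovery) — and carries them through:

* **Compositional preprocessing** — abundance/prevalence filtering,
  centred log-ratio (CLR) transform, Aitchison distances, Shannon
  diversity, rank-level relative abundances.
* **Network inference** — Meinshausen–Bühlmann neighbourhood selection
  (node-wise L1 regressions on CLR data, "or"/"and" symmetrisation) with
  StARS stability selection of the penalty, per soil legacy group
  (control / mild / severe, split at 76% SWD) × timepoint × kingdom.
* **Network properties** — modularity (fast-greedy), transitivity,
  within:between module link ratio, and targeted-attack robustness as the
  area under the largest-component ~ node-removal curve.
* **Null-model tests** — canonical undirected binary configuration model
  (UBCM) ensembles: maximum-entropy networks with
  `p_ij = x_i x_j / (1 + x_i x_j)` matching the observed degrees, 999
  draws, and z-scores `z = (obs − null mean)/null sd` with the 1.96
  two-sided threshold.
* **Resilience indices** — drought resistance (peak) and recovery (7
  weeks post re-wetting) of aboveground biomass, each unit normalised by
  the continuous never-droughted baseline (1 = no drought effect).
* **A synthetic-data generator** — the full 112-unit design, planted
  sparse conditional-dependence graphs (band/block/scale-free precision
  matrices), logistic-normal → multinomial counts with kingdom-scaled
  legacy effects, and threshold biomass responses — so the whole pipeline
  is testable without any sequencing download.

See the methods vignette (`vignettes/drought-legacy-networks.Rmd`) for
the models, assumptions, and every tunable default.

## Worked example

Simulate an experiment, infer the severe-legacy prokaryote network at
peak drought, test it against its configuration-model ensemble, and
compute resistance indices:

```r
library(legacynet)

sim <- simulate_experiment(seed = 42, n_prokaryote = 60, n_fungal = 30,
                           depth = 10000)
sim$counts
#> asv_table: 112 samples x 90 taxa (1,120,000 reads)
#> kingdoms: fungal (30), prokaryote (60)

res <- infer_network(sim$counts, sim$design, legacy_group = "severe",
                     timepoint = "peak", kingdom = "prokaryote", seed = 42)
res$stars
#> stars_result: 30 penalties, beta = 0.05, selected lambda = 0.5026 (index 3), 50 subsamples of 16
network_metrics(res$network)
#> metrics_report (59 nodes, 51 edges): transitivity 0.000, modularity 0.738,
#>   within:between 7.5, robustness 0.070 [degree attack, recomputed]

fit <- fit_ubcm(igraph::degree(res$network))
ens <- sample_ensemble(fit, 999, seed = 43)
zscore_metrics(res$network, ens)
#> ensemble_summary (999 null networks, |z| >= 1.96 flags):
#>          metric observed null_mean null_sd        z significant n_null n_finite
#>      modularity  0.73818   0.58942 0.05411  2.74944        TRUE    999      999
#>    transitivity  0.00000   0.05307 0.03712 -1.42978       FALSE    999      999
#>  within_between  7.50000   3.66518 1.44443  2.65490        TRUE    999      999
#>      robustness  0.06952   0.06861 0.01562  0.05823       FALSE    999      999

b <- simulate_biomass(sim$design, seed = 42)
idx <- resilience_index(b, sim$design, "resistance")
aggregate(value ~ legacy_group, idx, mean)
#>   legacy_group     value
#> 1      control 0.9550111
#> 2         mild 0.9091548
#> 3       severe 0.6499382
```

Reading the output: the severe-legacy network is significantly more
modular (z = 2.75) with a higher within:between link ratio (z = 2.65)
than its degree-matched nulls — node identity, not chance, structures it
— while its transitivity and robustness are compatible with the null
ensemble. Resistance falls from ≈0.96 under a control legacy to ≈0.65
under a severe legacy: with the default generator slopes, a severe past
drought costs the community about a third of its baseline productivity
under a new drought.

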