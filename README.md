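# nitrilink

Linking microbial community diversity to nitrification performance in
activated-sludge systems.

Nitrification is a "narrow" process: a small guild of ammonia- and
nitrite-oxidizing autotrophs (AOB, AOA, comammox, NOB) does the work inside
a community of thousands of mostly heterotrophic taxa, and the diversity of
the *total* community is usually a poor predictor of process performance.
`nitrilink` implements the association-filter hypothesis test: partition the
community into **nitrifiers**, **nitrifier-associated** taxa (co-occurrence
network neighbors of the guild), and **noise**, then ask whether the alpha
diversity and Bray-Curtis/PCoA compositional dynamics of the associated
slice explain more of the variation in the nitrification rate than the total
community or the guild alone — across SparCC correlation cutoffs 0.1–0.9.

It is written for microbial ecologists and wastewater-treatment researchers
working with samples × taxa amplicon count tables, per-taxon functional
annotations (e.g. PICRUSt2-style gene predictions), and daily plant
chemistry records.

## What is inside

* **SparCC from scratch** — Dirichlet fraction draws, log-ratio variances
  `t_ij = Var log(x_i/x_j)`, the sparse basis solution
  `rho_ij = (w_i + w_j - t_ij) / 2 sqrt(w_i w_j)` with iterative strong-pair
  exclusion, and permutation p-values with the add-one estimator.
* **Subcommunity delineation** — nitrifier selection (amo/nxr gene flag AND
  known nitrifier genus), cutoff sweeps with guaranteed nestedness, and the
  cross-period core.
* **Diversity machinery** — exact multivariate-hypergeometric repeated
  rarefaction (default 100× at 36,103 reads), richness/Shannon/Simpson,
  Bray-Curtis, PCoA.
* **Statistics** — standardized MLR with adjusted
  `R2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`, time-lag models (2/4/6/8 days),
  an in-package regression random forest with out-of-bag permutation
  importance, db-RDA with forward AIC selection and exact hierarchical
  partitioning.
* **Nitrification chemistry** — nitrate production, efficiency and rate from
  influent/effluent N species and hydraulic retention time; qPCR copy-number
  normalization; Shapiro-Wilk-gated between-period tests.
* **A synthetic-community generator** (`sim_config()`, `simulate_dataset()`)
  with planted nitrifier/associate/noise structure and exported ground
  truth, so the entire chain is verifiable by parameter recovery.

## Worked example

Generate a synthetic plant campaign (two periods, 44 + 48 daily samples,
6 nitrifiers, 15 associates at planted correlations 0.3–0.9, 90 noise taxa,
50,000 reads/sample), rarefy, and run the full analysis:

```r
library(nitrilink)
ds  <- simulate_dataset(sim_config(seed = 1))
cfg <- pipeline_config(seed = 1)
rar <- rarefy_mean(ds$counts, depth = cfg$rarefaction_depth,
                   reps = 25, seed = 1)
res <- analyze_dataset(rar, ds$metadata, ds$annotation, cfg)
subset(res$composition, period == "core",
       c(slice, cutoff, n_taxa, n, adjR2, p_model))
```

```
        slice cutoff n_taxa  n adjR2  p_model
23      total     NA    111 92 0.259 1.73e-06
24  nitrifier     NA      6 92 0.332 2.09e-08
25 associated    0.1     18 92 0.256 2.12e-06
28 associated    0.4     15 92 0.301 1.47e-07
29 associated    0.5      7 92 0.482 3.37e-13
30 associated    0.6      6 92 0.483 2.98e-13
31 associated    0.7      4 92 0.412 8.46e-11
32 associated    0.8      0 NA    NA       NA
```

Reading it: the compositional dynamics of the **core nitrifier-associated
subcommunity** explain up to 48% of the variation in the nitrification rate
(adjusted R², peak at cutoff 0.6), versus 26% for the total community and
33% for the nitrifier guild — the association filter removes noise taxa, and
explanatory power rises with the cutoff until the surviving set collapses
(empty at 0.8+). Time lags confirm the synchronous coupling in this world:

```r
res$lags
#>   lag  n     R2    adjR2  p_model
#> 1   0 92 0.5003  0.48328 2.98e-13
#> 2   2 88 0.0104 -0.02490 8.29e-01
#> 3   4 84 0.0157 -0.02124 7.36e-01
```

The ground truth behind these numbers is exported (`ds$truth`: role,
planted correlation, anchor nitrifier, rate weight per taxon), which is what
the acceptance tests exploit for parameter recovery.

## Command line

```sh
Rscript inst/cli/nitrilink.R simulate --config sim.json --out run/
Rscript inst/cli/nitrilink.R link --in run/            # full analysis
Rscript inst/cli/nitrilink.R --help
```

Subcommands: `simulate`, `ktu`, `diversity`, `network`, `subcommunity`,
`link`, `performance`, `report`. Every run writes a JSON manifest with the
resolved configuration next to its outputs.

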