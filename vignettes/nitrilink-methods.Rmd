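---
title: "Linking community diversity to nitrification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking community diversity to nitrification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline answers

Nitrification in activated sludge is a "narrow" process: only a small guild
of ammonia- and nitrite-oxidizing autotrophs (AOB, AOA, comammox,
NOB) carries it out, while the surrounding community is overwhelmingly
heterotrophic. The diversity of the *total* community usually correlates
weakly with nitrification performance, plausibly because most taxa neither
participate in nor interact with the process — they are statistical noise.
This package implements the alternative hypothesis test: if the community is
partitioned into (i) nitrifiers, (ii) taxa *associated* with nitrifiers in a
co-occurrence network, and (iii) everything else, then the diversity and
compositional dynamics of slice (ii) should explain more of the variation in
the nitrification rate than either the total community or the nitrifier
guild alone — and filtering at stronger association cutoffs should sharpen
the signal until the surviving set becomes too small.

The chain is: count table → (optional KTU re-clustering) → repeated
rarefaction → per-period SparCC networks → nitrifier guild and
association-filtered subcommunities across cutoffs 0.1–0.9 → alpha diversity
and Bray-Curtis/PCoA composition per slice → standardized multiple linear
regression against the nitrification rate, plus time-lag variants,
random-forest importance, and db-RDA with hierarchical partitioning for the
environmental side.

## Core statistics

**SparCC.** Relative abundances are compositional, so ordinary correlations
are biased. SparCC works from log-ratio variances
$t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$, which are invariant to the
normalization. Under the sparsity assumption
$\sum_{j \ne i}\rho_{ij} \approx 0$, the row sums
$t_i = \sum_{j\ne i} t_{ij}$ satisfy the linear system
$t_i = (D-2)\,\omega_i + \sum_j \omega_j$ in the basis variances
$\omega$, giving
$\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clamped to $[-1, 1]$. The strongest pair exceeding an exclusion threshold
(default 0.1) is excluded from the sums and the system re-solved, up to 10
rounds; exclusion stops early if a taxon would retain fewer than two
partners or the system becomes singular. Estimates are averaged over 20
Dirichlet posterior draws (counts + 1 pseudocount). Significance uses
per-taxon permutation of samples with the add-one estimator
$p = (1 + \#\{|\rho_\text{perm}| \ge |\rho_\text{obs}|\})/(1 + n_\text{perm})$,
so $p$ is never 0 — note that with the default
significance level of 0.01 at least 100 permutations are required for any
edge to pass.

**Subcommunities.** A taxon enters a nitrifier-associated subcommunity at
cutoff $c$ if it has an edge to any nitrifier with $|\rho| > c$ and
$p < \alpha$ (absolute value by default: co-exclusion is also an
association; a flag restricts to positive only). Sets are nested across
cutoffs by construction. Networks are built per operating period on that
period's samples only; the "core" set at each cutoff is the intersection of
the two periods' sets. Nitrifier selection itself is a conjunction:
a predicted *amo* or *nxr* gene AND membership in a known nitrifier genus.

**Diversity → function.** Alpha diversity (richness, Shannon in nats,
Gini–Simpson $1-\sum p_i^2$) and the first three PCoA axes of Bray-Curtis
dissimilarity serve as predictors of the nitrification rate in ordinary
least squares with all variables standardized to zero mean and unit
variance, so coefficients are standardized. The published protocol wording
("unit mean and variance") is internally inconsistent; zero mean/unit
variance is the only reading that yields comparable coefficients, and is
what is implemented. Models report $R^2$, adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-p-1)$ (may be negative) and the overall F
p-value, flagged at 0.05.

**Nitrification chemistry.** Nitrate production is
$(\text{org-N} + \text{NH}_4\text{-N} + \text{NO}_2\text{-N})_{in} -
(\cdot)_{out}$; efficiency divides by the influent sum; rate divides by the
hydraulic retention time (days). Negative production is flagged, never
clamped — mass-balance anomalies are quality-control signal.

**db-RDA and partitioning.** All positive-eigenvalue PCoA axes (unweighted,
no negative-eigenvalue correction) are regressed on standardized
environmental variables; the constrained fraction is the fitted trace over
the total trace. Forward selection uses the Gaussian residual-trace AIC
$n\ln(\mathrm{RSS}/n) + 2k$; neither formula is prescribed by the source
protocol, so the simplest standard constructions were chosen. Hierarchical
partitioning averages each variable's marginal gain over all subsets with
Chevan–Sutherland weights $w(s) = s!(p-s-1)!/p!$; the individual effects sum
to the full-model fraction exactly (telescoping identity), which the tests
assert to $10^{-8}$.

**Random forest.** No forest library is available in the target runtime, so
a compact regression forest is implemented in-package: bootstrap resampling,
variance-reduction CART splits, `mtry` scanned over a grid and chosen by
minimum out-of-bag MSE, importance as the mean increase in out-of-bag MSE
under per-variable permutation, overall fit as out-of-bag $R^2$.

## The synthetic world

`sim_config()` states the world once; the defaults are not tuning knobs.

* **Design**: two periods of 44 and 48 daily samples separated by a 33-day
  unsampled gap; per-period environmental means/SDs for inorganic carbon,
  ammonium, temperature and salinity follow the two-period summary of a
  full-scale plant (IC 92.5→62.7 mg/L, NH4 44.4→70.7 mg-N/L, temperature
  34.4→31.8 °C, salinity 1.7‰). Each variable is a stationary AR(1) around
  its period mean with lag-1 autocorrelation 0.6 (daily plant chemistry is
  strongly autocorrelated; the value is a realism choice, not fitted).
* **Taxa**: 6 nitrifiers (Nitrosomonas/Nitrospira with amo/nxr flags), 15
  associates at planted latent correlations 0.3–0.9 with round-robin anchor
  nitrifiers, 90 noise taxa. Nitrifier latents respond weakly to
  standardized NH4 and IC but are dominated by an idiosyncratic AR(1)
  component — guild dynamics are driven by more than measured chemistry.
  Noise taxa are environmentally filtered (taxon-specific responses to NH4,
  IC, temperature) and load on three smooth community-drift factors, so the
  broad community's dominant compositional axes are real but
  rate-irrelevant, which is precisely the situation the association filter
  is supposed to overcome.
* **Composition**: softmax of the latents over log base abundances drawn
  from a log-normal rank-abundance curve spanning orders of magnitude, so
  rare taxa flicker around the detection limit and richness varies; counts
  are multinomial at 50,000 reads/sample.
* **Rate**: intercept 10 plus 80 × relative abundance of each associate
  plus N(0, 1.5) noise, landing in the realistic 8–40 mg-N/L/day band.
  Noise taxa and nitrifiers have zero rate weight: the planted truth is that
  the *associates* carry the function signal.

What a green test does establish: the full chain (rarefaction → network →
cutoff sweep → core → PCoA regression) recovers the planted ordering
(associated > total and > nitrifier) and the rise-then-fall of explanatory
power across cutoffs, from data with realistic compositional noise. What it
does not establish: anything about mechanistic interactions, about real
sequencing error/chimeras/primer bias (not modeled), or about the numeric
effect sizes of any particular plant — the generator's latent Gaussian
world is far cleaner than 16S data.

## Numerical choices and edge cases

* Rarefaction is exact multivariate-hypergeometric subsampling (sequential
  conditional draws), averaged over 100 replicates; averaged rows sum to the
  depth exactly, samples below depth are dropped with a warning.
  Subcommunity alpha diversity is computed on the subcommunity-restricted
  averaged table without re-rarefying.
* Pseudocount 0.5 for any log transform of raw counts in diagnostics;
  Dirichlet +1 inside SparCC.
* "Simpson" means the complement $1-\sum p_i^2$; the source protocol names
  the index without a formula, so this common ecology default is used and
  documented.
* Negative SparCC basis variances are clamped to a small floor with a
  warning; the warning is suppressed for permuted null tables where it is
  routine.
* PAM is classical BUILD + SWAP on Euclidean distances between
  L2-normalized k-mer profiles (k = 4; tetranucleotides are the norm for
  ~250-bp amplicons). Cluster number is selected by mean silhouette over a
  scanned range, ties toward fewer clusters, silhouette of a single cluster
  defined as 0.
* Between-period tests: Shapiro–Wilk at 0.05 in both periods gates the
  t-test (pooled vs Welch by an F test at 0.05), otherwise Wilcoxon;
  constant input falls back to Wilcoxon with a warning. Note the gate means
  truly Gaussian data route to the t-test with probability at most
  $(1-0.05)^2 \approx 0.90$ — an inherent property of pre-testing, visible
  in the calibration tests.
* Lags pair composition at day $t$ with rate at day $t+L$ (a flag reverses
  the orientation); unmatched days, including the inter-period gap, are
  dropped and $n$ is reported per lag.
* Raw (unadjusted) permutation p-values are thresholded at $\alpha$, as in
  the source protocol's fixed significance level; a multiple-testing switch
  is deliberately out of scope.

## Known limitations

* SparCC association is correlation, not interaction; the core sets inherit
  every caveat of co-occurrence inference.
* The greedy AIC forward search and the silhouette scan are heuristics; the
  acceptance suite checks their planted-signal behavior, not optimality.
* The in-package random forest is adequate for importance ranking at
  pipeline scale but is not a performance-tuned library.
* The KTU re-clustering reproduces the algorithmic idea (k-mer profiles +
  PAM + medoid representative), not any particular published partition.
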