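---
title: "Null models for community assembly across habitat scales"
author: "ecoassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models for community assembly across habitat scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

Microbial communities are shaped by a mixture of deterministic processes
(selection by the environment, mediated by organismal traits) and
stochastic ones (dispersal and ecological drift). Because most microbial
traits are unmeasured, the framework implemented here uses phylogenetic
relatedness as a trait proxy: if traits are phylogenetically conserved,
selection leaves a signature in the *phylogenetic* turnover between
communities, while dispersal and drift act on *composition* irrespective
of phylogeny. Two null-model statistics operationalize this:

1. **βNTI** (phylogenetic turnover). The abundance-weighted between-
   community mean nearest taxon distance,
   $$\beta MNTD(k,l) = \tfrac12\Big[\sum_i f_{i,k}\,\min_{j\in l} d(i,j)
     + \sum_j f_{j,l}\,\min_{i\in k} d(j,i)\Big],$$
   with $f$ relative abundances and $d$ cophenetic distances on a dated
   phylogeny, is compared to a *taxa-shuffle* null: the taxon labels of
   the distance matrix are permuted jointly (rows and columns), so every
   community keeps its abundance vector and only the phylogenetic
   placement of abundance is randomized. The z-score
   $\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD}_{null})/
   sd_{null}$ flags pairs whose phylogenetic turnover is greater
   ($> 2$) or smaller ($< -2$) than compatible with chance —
   heterogeneous and homogeneous selection respectively.
2. **RC~bray~** (compositional turnover). For pairs not assigned to
   selection, observed Bray–Curtis dissimilarity is located within a
   null distribution of dissimilarities between probabilistically
   assembled community pairs. The rescaled mid-P statistic lies in
   $[-1, 1]$; values above $0.95$ indicate more turnover than chance
   (dispersal limitation), below $-0.95$ less (homogenizing dispersal),
   and the remainder is attributed to drift.

`classifyPairs()` applies the thresholds as *strict* inequalities, so
boundary values ($|\beta NTI| = 2$, $|RC| = 0.95$) fall through to the
next rule; the five regions partition the plane and non-finite inputs
are reported as `unclassified` rather than silently dropped.

## Scale-restricted null pools

The central design idea is that both null models are *pool-relative*.
The taxa shuffled in the βNTI null, and the occupancy and abundance
weights of the RC~bray~ null, are computed from a configurable sample
pool. `partitionByScale()` restricts that pool to each unit of a habitat
scale (the whole region, a site, a plot within a site, a host-plant
species within a plot) and classifies only within-unit pairs; pairs
spanning units are not evaluated at that level because the null they
would be compared against is not defined there. Shuffling only the taxa
*present in the pool* keeps regional phylogenetic structure from leaking
into local nulls. A χ² test of homogeneity (`chiSquareAcrossScales()`,
2×S assigned-vs-not table per process, no continuity correction,
df = S−1) quantifies whether a process's share of pairs changes across
scales; an omnibus 5×S variant is available behind a flag. Cells with
expected counts below 1 set a warning flag in the output rather than
blocking the test.

## The Raup–Crick null recipe

The literature names the metric but rarely pins the null-community
recipe, so it is explicit here and recorded in the result's provenance:
for each pair, `nNull` fresh null pairs are assembled; each null
community preserves its real counterpart's richness and total read
count; species identities are drawn without replacement with probability
proportional to pool occupancy; each drawn species receives one
individual and the remainder are allocated multinomially with
probability proportional to pooled relative abundance. Both weighting
stages can be switched off. Observed dissimilarity is computed on counts
— the same scale as the null communities — with a relative-abundance
mode behind a flag. Ties between null and observed dissimilarity count
one half (mid-P). Whether a field study's counts were rarefied first is
outside this package's scope: counts are taken as given, and the
preserved totals are the observed per-sample totals.

## Degenerate nulls

A taxa-shuffle null is degenerate whenever the statistic is invariant
under relabelling: a community containing every pool taxon (NTI), or a
pair of communities with identical supports (βMNTD is then identically
zero because shared taxa sit at distance zero under every permutation).
Such samples/pairs are flagged invalid, logged, and excluded from
classification — they are never coerced to zero. The only place an
invalid pair re-enters is ordination of a βNTI matrix, where a complete
matrix is required; there the pair is entered at z = 0 ("no deviation"),
with a message. Null standard deviations use denominator n−1.

## Driver analysis

Spatial structure is decomposed by PCNM (Euclidean distances truncated
at the longest minimum-spanning-tree edge, beyond-threshold distances
replaced by four times the threshold, positive-eigenvalue principal
coordinates retained — via `vegan::pcnm`). Soil covariates, PCNM axes
and (optionally) the first two principal coordinates of the host-plant
phylogenetic distance matrix are z-scored and combined by PCA, and the
PCA axes compete in a forward selection on a distance-based RDA
(`vegan::capscale`) of the turnover response. Entry is by smallest
permutation p-value of the partial pseudo-F; selection stops when no
candidate reaches `alpha` or when the cumulative adjusted R² exceeds the
full-model adjusted R². The stopping rule needed one pinning decision:
with few samples and many candidates, the *penalized* full-model R² can
lie below that of a single strong predictor, so a step that is
alpha-significant is kept even when it crosses the ceiling, and the
ceiling then blocks all further entries — rejecting the crossing step
would return an empty model in the presence of an obvious signal. An
AIC-like criterion is reported per step for comparability but never used
to stop. βNTI is a z-score, not a distance: before any ordination it is
shifted by its minimum to non-negative values, and the shift is recorded
on the result. PCoA reports negative eigenvalues (Bray–Curtis and βNTI
are semimetric) without correction. The selection report labels each
selected axis by its dominant loading block (soil/host = measured
environment, spatial = spatially structured unmeasured environment);
this is a loading report, not a causal claim. Spearman screens use
asymptotic p-values (ties allowed) and Bonferroni families defaulting to
the number of tests performed in the call.

## The synthetic generator

`simulateMetacommunity()` produces data with the statistical structure
the inference assumes, under known regimes, and returns the ground truth
recorded before sequencing noise. Defaults mirror the emulated field
design: 2 sites × 4 plots × 3 host species × 4 replicates with 4 samples
dropped at random (92 samples), 449 OTUs on a birth–death tree
(birth 1, death 0.5 per time unit), ~70,000 reads per sample. Site
centres sit ~100 km apart, plots within ~2 km of their centre, samples
within ~30 m of their plot, so PCNM axes separate the design scales by
construction. A site-level latent environment (±2 with small plot- and
sample-level jitter) drives both the Gaussian niche filter and the soil
covariates (pH, OM, GM are deterministic functions of the latent
environment plus Gaussian noise), giving the driver analysis a planted,
recoverable signal. Niche optima evolve by Brownian motion along the
tree and are rescaled to the environment scale while keeping their
phylogenetic correlation, so conservatism is governed by tree shape.
Scenario defaults, chosen once as what the regime is meant to emulate:

* `env_filtering`: niche breadth σ = 1 against a site contrast of 4 —
  strong filtering on conserved niches;
* `dispersal_limitation`: per-taxon home locations and an exponential
  colonization kernel with decay length λ = 2000 m, between the
  within-plot (tens of metres) and between-plot (kilometres) scales, so
  decay is planted between plots and sites but not within plots;
* `homogenizing_dispersal`: mixing proportion m = 0.9 toward the
  regional mean community;
* `neutral_drift`: multinomial resampling chains (15 generations,
  population 1000) from the regional base abundances, no selection term.

All expected abundances are computed before any read is drawn, so
changing only sequencing depth leaves the latent structure untouched.
What the generator does **not** emulate: PCR/sequencing error and
chimeras, taxon-specific amplification bias, temporal dynamics,
speciation, or interactions between taxa. Passing tests on these data
therefore validate the inference machinery — not the biological
faithfulness of any particular field data set.

## Numerical and reproducibility choices

Counts are integers end to end; relative abundances are computed on
demand and never written to files. Null replicates default to 999.
Every stochastic routine takes an integer seed; one seeded stream drives
each turnover matrix with permutations drawn in fixed, pair-independent
order, so results are bit-identical for identical inputs and seed
regardless of how work might be scheduled. `partitionByScale()` derives
per-unit child seeds deterministically from the master seed. The test
and acceptance runs use a reduced configuration (2 sites × 2 plots ×
3 hosts × 2 replicates = 24 samples, 60 OTUs, 1000 reads/sample,
999-replicate nulls) — the smallest design in which all four habitat
scales retain at least two samples per unit and pair counts stay
informative (276 region pairs).

## Known limitations

* With equal-support community pairs βNTI does not exist (degenerate
  null); dense, low-richness data sets can lose many pairs this way.
* RC~bray~ values are quantized at resolution 2/n~null~; classifications
  near ±0.95 need n~null~ ≥ 999 to be stable.
* Under strong drift, observed turnover can exceed the Raup–Crick null
  and be labelled dispersal limitation — a known identifiability limit
  of the framework, visible in the neutral scenario.
* Forward selection inherits the usual caveats of stepwise procedures;
  the double stopping rule guards against inflation but not against
  correlated candidates.
* The χ² across scales treats pairs as independent observations, as the
  framework conventionally does, although pairs sharing a sample are
  not.
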