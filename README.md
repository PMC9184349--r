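# ecoassembly

Null-model inference of community assembly processes across habitat scales,
for microbial (and especially ectomycorrhizal fungal) community data:
an OTU abundance table, a dated phylogeny over the OTUs, and a nested
sampling design (region → site → plot → host plant).

## What it computes

Community assembly is partitioned into the four process classes of the
Vellend/Stegen framework by confronting two turnover metrics with null
models:

* **βMNTD / βNTI** — the abundance-weighted between-community mean
  nearest taxon distance,

  βMNTD(k,l) = ½ [ Σᵢ f_{i,k} · min_{j∈l} d(i,j) + Σⱼ f_{j,l} · min_{i∈k} d(j,i) ],

  compared against a *taxa-shuffle* null (joint row/column permutation of
  the cophenetic distance matrix, 999 replicates):
  βNTI = (βMNTD_obs − mean βMNTD_null) / sd βMNTD_null.
* **RC_bray** — the Raup–Crick metric on Bray–Curtis dissimilarity. Null
  communities are assembled probabilistically from the sample pool
  (species drawn without replacement ∝ occupancy, individuals filled
  ∝ pooled relative abundance; richness and total count of each real
  sample preserved), and the observed dissimilarity is located in the
  null distribution: RC_bray = 2·[(#{BC_null < BC_obs} + ½·#{ties})/n − ½] ∈ [−1, 1].
* **Classification** of every sample pair: βNTI > 2 heterogeneous
  selection; βNTI < −2 homogeneous selection; otherwise RC_bray > 0.95
  dispersal limitation, RC_bray < −0.95 homogenizing dispersal, else
  drift (all thresholds strict).
* **Scale restriction** — both null models draw from a configurable
  sample pool. Restricting the pool to a habitat unit (site, plot, host
  plant) re-expresses the question "different from chance?" at that
  scale; a χ² test of homogeneity compares process proportions across
  scales.
* **NTI** per sample (taxa-labels null; positive = phylogenetic
  clustering), with per-scale t tests and Tukey contrasts.
* **Driver analysis** — PCNM spatial eigenvectors, PCA of standardized
  predictors (soil + space + host-phylogeny axes), distance-based RDA
  with permutation forward selection, and Spearman/Bonferroni screens of
  turnover ordination axes.
* **Synthetic data** — a generator producing dated birth–death
  phylogenies, Brownian niche optima, a nested design with hierarchical
  coordinates, and OTU tables under known regimes (neutral drift,
  environmental filtering, dispersal limitation, homogenizing dispersal),
  so every inference stage can be validated against ground truth.

## Worked example

```r
library(ecoassembly)

cfg <- synthConfig(nTaxa = 60, sites = 2, plotsPerSite = 2, hosts = 3,
                   replicates = 2, dropout = 0, readsPerSample = 1000,
                   scenario = "env_filtering", seed = 42)
sim <- simulateMetacommunity(cfg)
sim$dataset
#> AssemblyDataset: 24 samples x 59 OTUs
#>   total reads: 24000
#>   design: 2 site(s), 4 plot(s), 3 host(s)
#>   covariates: pH, OM, GM, x, y
#>   tree depth (time units): 4.649

part <- partitionByScale(sim$dataset, levels = c("region", "site"),
                         nNull = 199, seed = 7)
tb <- processTable(part)
subset(tb, process %in% c("selection", "dispersal_limitation", "drift"))
#>   level              process   n        pct n_classified
#>  region dispersal_limitation   0  0.0000000          276
#>  region                drift   1  0.3623188          276
#>  region            selection 144 52.1739130          276
#>    site dispersal_limitation   2  1.5151515          132
#>    site                drift 105 79.5454545          132
#>    site            selection  10  7.5757576          132

chiSquareAcrossScales(part, "selection")
#>     process    chisq df            p min_expected warning
#> 1 selection 75.58272  1 3.504143e-18     49.82353   FALSE
```

The scenario plants a strong environmental filter that differs between
the two sites, acting on phylogenetically conserved niches. With the
regional null pool, the 144 cross-site pairs are recognised as selection
(52% of all pairs); restricting the null to each site absorbs the filter
and within-site turnover collapses to drift — the χ² test flags exactly
this scale dependence of the selection signal.

A thin command-line wrapper over the same functions is installed as
`exec/ecoassembly` (subcommands `validate`, `simulate`, `bnti`, `rcbray`,
`partition`, `drivers`).

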