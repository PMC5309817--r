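# soilweb

Soil communities reorganize as abandoned arable land returns to nature.
Two signals of that reorganization are measurable without ever observing an
interaction directly: **network tightening** — across succession stages, an
increasing share of taxon pairs co-vary strongly — and a shift of freshly
photosynthesized carbon into the **fungal channel** of the food web,
trackable with a ¹³C/¹⁵N pulse-chase. `soilweb` implements both analyses as
a tested, reusable pipeline for ecologists working with chronosequence
designs (stages × sites × subplots), plus a synthetic-data module so every
stage of the pipeline can be exercised against known ground truth.

## What it computes

**Networks.** Per succession stage: drop taxa occurring in fewer than two
samples, compute the Spearman rank correlation matrix over the stage's
samples (average ranks at ties, explicit `NA` for zero-variance taxa),
keep positive correlations ρ > τ (default τ = 0.9) as strong edges, and
report

```
connectance (%) = 100 · n_strong / n_possible
```

with the denominator policy (`all_pairs` or `between_only`) made explicit,
together with group-level interaction strengths (strong between-group edges
divided by |A|·|B| possible pairs). A presence–absence variant
(`binarize()`) feeds the identical pipeline for robustness checks, and
`shannon_index()` gives the community-evenness H. Because everything is
rank-based, heterogeneous abundance units (reads, counts, % cover) can
share one matrix.

**Isotopes.** Delta/ratio/atom-percent algebra (δ = (R_sample/R_ref − 1)·10³;
atom% = 100·R/(1+R)) against VPDB and air-N₂ references, least-squares IRMS
calibration against certified standards (USGS40, USGS41, NIST8542, USGS25),
excess atom % over unlabelled controls, TCD elemental-content curves,
PLFA/NLFA biomarker aggregation into bacteria / actinomycetes / fungi / AMF
pools, fungal-to-bacterial ratios, and root-scaled carbon-channel
partitioning (each pool's share of the label, scaled to total excess ¹³C in
the roots).

**Simulation.** `generate_abundance()` draws latent-Gaussian-copula
communities with a tunable within-group Spearman correlation per stage
(`rho_block`) on the 3-stage × 3-site × 3-subplot design;
`generate_tracer()` emits labelled/control atom-percent tables with known
transfer fractions.

## Worked example

```r
library(soilweb)

spec <- community_spec(rho_block = c(0.3, 0.7, 0.7))  # tightening then plateau
tab  <- generate_abundance(spec, seed = 42)
tab
#> abundance_table: 59 taxa x 27 samples
#>   stages: long (9), mid (9), recent (9)
#>   subgroups: 13; main groups: 7

for (st in c("recent", "mid", "long")) print(stage_network(tab, st))
#> stage_network [recent]: 59 taxa, 3 strong / 1711 possible pairs
#>   connectance = 0.175% (tau = 0.9, policy = all_pairs)
#> stage_network [mid]: 59 taxa, 5 strong / 1711 possible pairs
#>   connectance = 0.292% (tau = 0.9, policy = all_pairs)
#> stage_network [long]: 59 taxa, 6 strong / 1711 possible pairs
#>   connectance = 0.351% (tau = 0.9, policy = all_pairs)
```

The recent stage (block correlation 0.3) realizes 3 of 1711 possible strong
pairs; the mid and long stages (0.7) roughly double connectance — the
tightening signature, recovered from a single simulated draw. Averaged over
seeds the step is unambiguous (see `scripts/acceptance.R`).

```r
sim <- generate_tracer(tracer_spec(), seed = 42)   # sigma = 0.05, 9 replicates
tracer_budget(sim$measurements, time_point = "1d")
#> tracer_budget: 3 pools, root excess = 2.06157
#>       pool  excess floored fraction root_scaled
#> 1      AMF 0.03965   FALSE  0.09952     0.01923
#> 2 bacteria 0.15965   FALSE  0.40069     0.07744
#> 3    fungi 0.19914   FALSE  0.49979     0.09659
```

The generator's true channel fractions are bacteria 0.40, fungi 0.50,
AMF 0.10; from nine noisy replicates the pipeline recovers them to three
decimals, with each pool also expressed relative to the labelled carbon in
the roots (`root_scaled`).

Reference connectance counts for a published three-stage chronosequence
ship with the package:

```r
counts <- restoration_connectance_counts()
round(connectance(counts$n_strong, counts$n_possible), 3)
#> [1] 0.626 1.186 1.278 0.588 1.193 1.148
```

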