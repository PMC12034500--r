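# cycadcpi

Composite extinction-risk scoring and conservation prioritization for the
cycads of Veracruz, Mexico — and for any species set with the same kind of
mixed risk attributes.

Regional conservation planners rarely get one number they can rank species
by: IUCN Red List categories, national listings (Mexico's NOM-059),
endemism, range restriction, habitat loss and protected-area coverage all
live on different scales and in different databases. The **Conservation
Prioritization Index (CPI)** combines nine such attributes into a single
additive score per species:

- categorical risk levels are scored ordinally (IUCN CR = 4 … NT = 1,
  LC = 0; NOM-059 P = 2, A = 1, unlisted = 0; endemic = 1/0),
- every variable is min-max standardized, `z_i = (x_i − min x)/(max x − min x)`,
- variables where *small* raw values mean *high* risk (localities, extent of
  occurrence, municipalities) are inverted, `y_i = 1 − z_i`,
- percent variables (area inside the region, habitat loss, area outside
  protected areas) map to `[0, 1]`,
- **CPI = Σ components ∈ [0, 9]**, missing attributes omitted from the sum.

Around the index, the package implements the full analysis pipeline:
Pearson correlation screening, Multiple Factor Analysis of the mixed
variables, Gower-distance/Ward clustering with multiscale-bootstrap
approximately-unbiased (AU) cluster support, gamma log-link GLM trends of
CPI against range-centroid geography with explained deviance D², and
geospatial range metrics (convex-hull EOO, IUCN Criterion B preliminary
categories, protected-area overlays, canopy-threshold habitat loss, 1-km²
richness rasters and PA gap summaries). A seeded synthetic-data generator
emulates the study system's structure so everything is testable offline.

## Worked example

The package bundles a documented **synthetic stand-in** for the raw
21-species attribute table (`cycad_attributes_synthetic()`; the published
raw table itself is not redistributable — see `?cycad_attributes_synthetic`
for exactly which cells are fixed by published statements and which are
plausible fill-ins) and a **reconstructed** knowledge-shortfall table whose
marginals and extreme rows are exact (`cycad_knowledge_reconstructed()`).

```r
library(cycadcpi)

scored <- build_scored_table(cycad_attributes_synthetic())
head(dplyr::arrange(scored, cpi_rank)[, c("species_name", "genus", "cpi", "cpi_rank")], 5)
#> # A tibble: 5 × 4
#>   species_name               genus         cpi cpi_rank
#>   <chr>                      <chr>       <dbl>    <int>
#> 1 Zamia inermis              Zamia        8.88        1
#> 2 Zamia vazquezii            Zamia        8.84        2
#> 3 Ceratozamia subroseophylla Ceratozamia  8.65        3
#> 4 Ceratozamia decumbens      Ceratozamia  8.65        4
#> 5 Ceratozamia morettii       Ceratozamia  8.30        5
```

The two *Zamia* species known from one and two localities, with near-total
habitat loss and no protected-area coverage, saturate the index (CPI near
the ceiling of 9); widespread, lightly threatened species such as
*Dioon edule* score near 1.8. Correlation screening justifies dropping EOO
from the multivariate stages:

```r
cm <- cpi_correlations(scored)
round(cm["iucn", "eoo_inv"], 2)
#> [1] 0.75
```

Ordination and clustering run on the raw mixed variables (three categorical,
five numeric, EOO excluded):

```r
vars <- cpi_analysis_variables(cycad_attributes_synthetic())
fit <- mfa(vars)
head(tidy(fit), 2)
#> # A tibble: 2 × 4
#>     dim eigenvalue pct_variance cum_pct_variance
#>   <int>      <dbl>        <dbl>            <dbl>
#> 1     1       5.74         57.4             57.4
#> 2     2       1.56         15.6             73.0

au <- multiscale_bootstrap_au(vars, kinds = attr(vars, "kinds"),
                              B = 1000, seed = 42)
au_retained_clusters(au)        # member sets with AU >= 0.95
cut_tree(au$tree, k = 4)        # four-group partition
autoplot(au)                    # dendrogram annotated with AU support
```

Knowledge shortfalls count, per species, how many of five information fields
(individual counts, GenBank accessions, studies, population ecology,
pollinator identity) hold any data:

```r
shortfall_summary(cycad_knowledge_reconstructed())[, c("pct_popecol", "pct_pollinator", "min_score", "max_score")]
#> # A tibble: 1 × 4
#>   pct_popecol pct_pollinator min_score max_score
#>         <dbl>          <dbl>     <int>     <int>
#> 1        38.1           52.4         1         5
```

Population-ecology information exists for 38% of species and pollinators are
known for 52%; the recently described *Ceratozamia dominguezii* is the only
species at the minimum score of 1. `run_cpi_pipeline()` orchestrates every
stage from one (YAML-able) config — simulated inputs by default, file inputs
(CSV / GeoJSON / ESRI ASCII grid) otherwise — and writes per-stage outputs
plus a reproducibility manifest with seeds and checksums.

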