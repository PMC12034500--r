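---
title: "Methods: the Conservation Prioritization Index and its downstream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Conservation Prioritization Index and its downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycadcpi)
```

# The problem

Cycads are among the most threatened plant groups, and the state of Veracruz
(Mexico) holds 21 species across *Ceratozamia*, *Zamia* and *Dioon*. Neither
the IUCN Red List nor the Mexican NOM-059 listing alone captures everything a
regional conservation planner needs: the two systems use different criteria
and are weakly correlated, and neither integrates regional endemism, fine
levels of range restriction, habitat loss, or protected-area coverage into a
single ranking. The Conservation Prioritization Index (CPI) implemented here
combines nine risk attributes into one additive score per species, and the
package carries the full downstream analysis: correlation screening,
mixed-data ordination, cluster analysis with bootstrap support, geographic
trend models, and geospatial range/gap metrics.

# The index

Each species contributes nine components, every one standardized to $[0, 1]$
so larger always means more at risk:

* **Categorical attributes.** IUCN categories are scored CR = 4, EN = 3,
  VU = 2, NT = 1 (LC = 0 as the monotone extension; a species with an
  unevaluated category must first receive a preliminary Criterion B
  assessment, see below). NOM-059 scores P = 2, A = 1, unlisted = 0.
  Endemism to the focal region scores 1/0 and is used as-is. The ordinal
  scores are then min-max normalized like any other variable.
* **Min-max normalization.** $z_i = (x_i - \min x)/(\max x - \min x)$, so
  the observed minimum maps to 0 and the maximum to 1. A constant column is
  an error, not a silent 0/0.
* **Inversion.** For attributes where *small* raw values mean *high* risk —
  number of localities, extent of occurrence (EOO), number of municipalities
  — the normalized value is reflected: $y_i = 1 - z_i$. Inversion is an
  involution and is only defined on $[0, 1]$.
* **Percent attributes.** Percent of the distribution inside the region,
  percent habitat loss, and percent of the distribution outside protected
  areas are mapped to $[0,1]$ by division by 100 (`percent_mode = "div100"`,
  the default: 100% inside the region should read exactly 1, and the
  published component tables describe these columns as percentages, not
  normalized scores). A min-max alternative (`percent_mode = "minmax"`) is
  provided for sensitivity analysis because the published methods text
  describes normalizing "all variables"; both modes are exercised in the
  tests and the top of the ranking is stable across them.

The CPI is the plain sum of the non-missing components, so it lies in
$[0, 9]$. Missing attributes are omitted from the sum rather than imputed —
the same convention as the published analysis — and a per-species
`n_components` column makes the resulting incomparability visible rather
than hiding it. No weights: the index is deliberately transparent, and
sensitivity to that choice belongs to future work, not to this
implementation.

# Correlation screening

Pairwise Pearson correlations among the nine components
(`cpi_correlations()`) justify two modelling choices downstream: EOO is
excluded from the ordination and clustering because it is strongly
correlated with the locality, municipality and IUCN components, and the
remaining variables are treated as complementary rather than redundant.
Pairwise-complete observations are used when components are missing;
constant columns are an error naming the column.

# Mixed-data ordination (MFA)

`mfa()` implements Multiple Factor Analysis from first principles (no
mixed-data ordination package ships with this stack). Numeric variables are
centered and scaled by the *population* standard deviation; a categorical
variable with $K$ levels becomes $K$ centered indicator columns
$(I_k - p_k)/\sqrt{p_k}$ — the MCA weighting, contributing inertia $K - 1$.
Each group of variables is divided by the square root of the leading
eigenvalue of its separate analysis, the balancing step that stops any one
group from dominating dimension 1; the concatenated weighted matrix is then
decomposed by SVD with row weight $1/n$. Two identities pin the
implementation down and are asserted in the tests:

* with only single-variable numeric groups the eigenvalues equal those of
  the correlation-matrix PCA of the data;
* the eigenvalue sum equals the total weighted inertia
  $\sum_g \mathrm{trace}_g / \lambda_1^{(g)}$, and percent variance sums
  to 100 over all positive eigenvalues.

The default group specification is one group per variable (the analysis is
then factor analysis of mixed data); alternative thematic groupings are a
single argument away and the acceptance suite sweeps two of them. The
ordination uses every CPI ingredient except EOO, with IUCN, endemism and
NOM-059 categorical at their original values.

# Clustering with bootstrap support

Species are clustered on the same variable set using Gower's distance
(range-scaled numeric differences, 0/1 categorical mismatches, averaged over
pairwise-complete variables) and Ward linkage. The Ward.D2 variant
(Lance–Williams update on squared dissimilarities) is the default; the
legacy ward.D is a flag because the published methods do not distinguish
them. Agglomeration ties break deterministically (lowest merge first, the
`stats::hclust` convention), and the unit tests verify the whole merge
structure against an exhaustive brute-force agglomerator at small $n$.

Cluster support uses the multiscale bootstrap. The *variables* (table
columns) are resampled with replacement to $\lceil m r \rceil$ columns at
each scale $r \in \{0.5, 0.6, \dots, 1.4\}$ — when the objects being
clustered are the table's rows, the resampling axis is the attribute axis,
matching the convention of the standard implementation of this method. With
$B$ replicates per scale (5000 at study scale; 1000 in the routine runs
here, which is where Monte-Carlo noise on AU drops well below the 0.95
decision margin), $\mathrm{BP}(r)$ is the fraction of replicate trees
containing each original node's exact member set, and the normal-theory
model

$$ \Phi^{-1}(1 - \mathrm{BP}(r)) = v\sqrt{r} + c/\sqrt{r} $$

is fitted by weighted least squares (binomial weights), giving the
approximately unbiased support $\mathrm{AU} = 1 - \Phi(v - c)$. Clusters
with AU at or above 0.95 are conventionally retained
(`au_retained_clusters()`). Three numerical choices matter with as few as
eight variables and are deliberate:

* the regression uses the *achieved* scales $\lceil m r \rceil / m$, which
  differ substantially from the nominal $r$ at small $m$;
* per-scale hit rates within $3/B$ of 0 or 1 are excluded from the fit —
  the normal quantile is dominated by the $1/B$ resolution there, and a
  near-saturated node otherwise invites a degenerate two-point
  extrapolation;
* nodes at the ceiling (floor) in the median scale and at $r \approx 1$ are
  reported as AU = 1 (0) and flagged `saturated` (`never-recovered`);
  nodes with fewer than two informative scales fall back to the scale-1 BP
  and are flagged.

# Geographic trend models

`cpi_trends()` regresses the CPI on second-degree polynomials of range
centroid longitude and latitude — one gamma GLM with log link per
predictor, pooled and per genus. Centroids are area-weighted polygon
centroids computed in the equal-area plane and inverse-projected. Orthogonal
polynomial columns (`stats::poly`) keep the quadratic fit stable; fitted
values and the explained deviance are identical under the raw-power basis,
so $D^2 = 1 - D_{res}/D_{null}$ is the basis-independent quantity reported.
Significance uses the F test on scaled deviance with the Pearson dispersion
of the larger model, the standard choice when the gamma dispersion is
estimated; at the study's $n = 21$ its type-I error is calibrated within
$[0.03, 0.07]$ at $\alpha = 0.05$ over 1000 null simulations in the
acceptance suite. Genera with fewer than five species are excluded from
per-genus fits (a quadratic plus intercept on two species is saturated);
this reproduces the exclusion of *Dioon* ($n = 2$).

# Geospatial methods

All areas are computed in a Lambert azimuthal equal-area projection centered
on the data extent, on the authalic sphere (radius 6371.0088 km), so planar
shoelace areas are km². LAEA is exactly equal-area on the sphere; tests
hold hull areas within 0.5% of an independent ellipsoidal geodesic oracle.

* **EOO** is the convex-hull area of the occurrence points; fewer than three
  distinct or exactly collinear points raise a classed `DEGENERATE` error so
  callers can fall back to occupancy. Collinearity is tested in geographic
  coordinates, before projection curvature turns a line into a sliver.
* **Locations** count distinct occupied 10-km cells (the conR convention),
  on a grid anchored at the occurrence extent's corner so tight clusters
  never straddle an arbitrary boundary; AOO uses 2-km cells and is reported
  but is not a CPI input.
* **Preliminary Criterion B** combines the EOO bands (CR < 100,
  EN < 5,000, VU < 20,000 km²) with the location bands (1 / ≤5 / ≤10); the
  headline category is the less severe of the two, and only the headline
  category is produced.
* **Overlays** (percent of range in the region, percent outside the
  protected-area union, municipality counts) use Sutherland–Hodgman
  clipping, which requires *convex* clip polygons — validated, with an
  error rather than a silent mis-clip — and inclusion–exclusion over convex
  intersections for the PA union. Municipalities count only on strictly
  positive intersection area, so boundary contact is excluded.
* **Habitat loss** is operationalized as the percent of canopy-height cells
  inside the range that lie strictly below the genus threshold (15 m
  *Ceratozamia*, 5 m *Dioon*, 10 m *Zamia*, 3 m for the coastal-dune
  *Z. furfuracea*). With a single-date canopy layer, "loss" can only mean
  the below-threshold (unsuitable) fraction of current canopy; the package
  says so rather than implying change detection.
* **Rasterization** uses the cell-center-in-polygon rule on a shared 1-km
  grid; richness is the cell-wise sum of the per-species binary grids, and
  the gap summary tallies, per richness level, total area and area whose
  cell centers fall outside the PA union.

# The synthetic study system

`generate_species_table()` and its companions emulate the *structure* of
the study data so that every stage is testable without downloads: a
21-species table with 4-level IUCN, binary endemism, 2-level NOM-059,
right-skewed negative-binomial counts, beta-distributed percentages; convex
range polygons with constructed region/PA overlaps recorded as ground truth
(boundary-straddling rectangles make the inside fraction exact by
construction, within 1% after projection); canopy rasters with an *exact*
count of below-threshold cells; and knowledge tables with configurable
informedness.

Planted structure is controlled by `cluster_separation`, calibrated as a
per-variable effect size: group means sit `separation` apart on a latent
risk score whose observation noise (latent sd 0.25, categorical assignment
noise 0.25, beta concentration 40, negative-binomial size 8) is fixed so
that one separation unit shifts each variable by roughly one residual
standard deviation. At separation 3 the two planted groups are cleanly
recoverable: cutting the Gower/Ward tree at $k = 2$ matches the planted
partition (Rand index 1.0 across 100 seeds in the acceptance suite) and the
planted nodes carry AU near 1. At separation 0 the groups are exchangeable.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: real Veracruz geography and range shapes
(ranges are synthetic convex polygons), spatial autocorrelation between
attributes and geography (trend-model power on real ranges is untested
here), measurement error and taxonomic uncertainty in occurrence records,
and non-convex protected-area geometry.

# Bundled reference tables

Two tables ship with the package, with very different epistemic status:

* `cycad_knowledge_reconstructed()` — the knowledge-shortfall table is
  *reconstructable* from published summary statistics: the five field-wise
  shares (52%, 95%, 100%, 38%, 52% of 21 species), the unique minimum row
  (*C. dominguezii*, score 1, GenBank absent) and the unique maxima
  (*Z. inermis*, *C. miqueliana*, score 5) pin down the marginals and the
  extremes exactly; which *other* species hold the remaining TRUE cells is
  not determined and is documented as a free choice. Every quantity derived
  from marginals or extremes is exact.
* `cycad_attributes_synthetic()` — the raw attribute table behind the
  published index was not available for transcription, so this is a
  SYNTHETIC stand-in: the species list, genus composition and every
  prose-stated cell are honoured; all other cells are plausible
  genus-typical values fixed once. Quantities computed from it approximate
  the published ones (the two top-ranked species and the ~8.8 CPI ceiling
  are reproduced) but do not match them at printed precision, and the
  package never pretends otherwise.

# Problem sizes

The routine test and acceptance runs use: bootstrap B = 1000 per scale on
the 21 × 8 table (the study-scale setting is B = 5000 and is one argument
away), 1000 null simulations for the type-I calibration at n = 21, 100
generator seeds for the recovery property, and 5–10 km raster cells for the
synthetic gap maps (1-km cells are the analysis default for real layers).
These sizes were chosen so the full suite completes comfortably on a single
CPU while keeping Monte-Carlo error well inside every asserted margin.

# Known limitations

* The CPI is unweighted and additive; compensations between components are
  invisible (a species can reach a middling score via many moderate risks or
  a few extreme ones).
* Overlay operations require convex clip polygons (region, PAs,
  municipalities). Real municipal boundaries are not convex; rasterized
  overlay at fine resolution is the workaround until a general polygon
  clipper is warranted.
* The multiscale bootstrap resamples eight variables; its granularity is
  coarse, AU values carry visible Monte-Carlo structure at small B, and
  one flat-BP realization in twenty can sit below the 0.95 retention line
  even for a genuinely planted cluster.
* Percent-mode ambiguity is resolved by a documented default plus a flag,
  not by evidence: both modes rank the same species at the top, but
  component values differ.
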