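---
title: "Methods: facility sampling, ecological linking, and effective coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facility sampling, ecological linking, and effective coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecolink)
library(dplyr)
```

## The problem

Effective coverage asks what fraction of a population in need of a health
intervention received it *with sufficient quality to benefit*. The standard
construction multiplies care-seeking (from a household survey) by the quality
score of the provider used (from a facility assessment). When the specific
provider is unknown, individuals are linked to providers *ecologically* — to
the nearest facility of the reported provider category, or to a
caseload-weighted district average — and facility assessments such as the SPA
usually cover only a random sample of facilities, not a census. `ecolink`
implements the full simulation machinery needed to ask: **how much bias does
facility sampling add to ecologically linked effective coverage estimates?**

The package generates synthetic regions with the structure of a rural
West-African setting (a census of ~190 facilities dominated by public
first-level providers, a 44-cluster household survey), links episodes to
facilities three ways, computes coverage cascades with design-based cluster
variances, draws SPA-style facility samples, and compares every sampled
estimate against two references: the exact-match estimate (the "truth", from
stated sources of care) and the census-based ecological estimate (which
isolates the sampling effect from the linking effect).

## Estimators

For in-need episodes $i$ with survey weights $w_i$, skilled care-seeking
indicator $s_i$ and linked quality score $q_i$:

$$\widehat{EC} = \frac{\sum_i w_i \, s_i \, q_i}{\sum_i w_i}$$

with $q_i$ the structural (readiness) score for *input-adjusted* coverage,
the process (provision-of-care) score for *quality-adjusted* coverage, and
$q_i \equiv 1$ for crude coverage. Episodes whose only sources are unskilled
(pharmacies, community health workers) contribute $s_i = 0$: they count as
receiving no skilled care rather than being dropped.

**Variance.** Clusters are the primary sampling units in a single stratum.
The variance is the Taylor linearization of the weighted ratio mean: with
cluster totals $u_c = \sum_{i \in c} w_i (v_i - \widehat{EC})$,

$$\widehat{var} = \frac{n}{n-1} \, \frac{\sum_c (u_c - \bar u)^2}{(\sum_i w_i)^2},$$

the with-replacement approximation standard for cluster surveys. Facility
scores are treated as fixed constants (no facility-side sampling error), so
the linked scores simply extend the household dataset. The symmetric interval
uses a $t$ quantile with $n_{\text{clusters}} - 1$ degrees of freedom rather
than a normal quantile: with 44 PSUs the normal interval undercovers by about
a point, and the $t$ correction is the convention of design-based survey
software. Intervals are clipped to $[0, 1]$.

## Linking methods and fallback rules

All linking is restricted to the *reported provider category* — the cross of
managing authority (public / private / religious / NGO) and level of care
(first-level / referral).

* **Exact-match**: the stated facility's score. Always evaluated against the
  full census, even in sampled scenarios, because it is the study's fixed
  truth reference.
* **Euclidean**: the facility of the reported category nearest to the
  episode's *cluster centroid*, as the crow flies (haversine on the sphere,
  mean Earth radius 6371.0088 km). Equidistant ties break to the smallest
  facility id — the choice is arbitrary but determinism is required for
  reproducible simulations.
* **Administrative**: the caseload-weighted mean score over facilities of
  the category in the episode's district; zero total caseload degrades to
  the unweighted mean.

Whenever a skilled source cannot be matched — the stated id is unresolvable,
or the category is absent from the facility set in play — the episode
receives the **category-average fallback**: the caseload-weighted category
mean over the facility set, escalating to the census-wide category mean when
the sample contains no facility of the category at all. Fallback averages
are caseload-weighted to stay consistent with administrative linking; an
unweighted switch exists (`fallback_score(weighted = FALSE)`). Sick-child
episodes with several skilled sources get the unweighted mean of their
sources' scores; unskilled sources are excluded from that average.

## The synthetic region generator

The generator is first-class, tested code: it defines the conditions every
simulation in this package runs under.

* **Survey dimensions**: 44 clusters, 392 delivery episodes, 183 sick-child
  episodes, uniform weights.
* **Census composition**: 144 public first-level, 22 private and 21
  religious first-level, 5 public and 2 private referral facilities.
* **Source mixes** (marginal probabilities): delivery — 46.0% public
  first-level, 12.0% public referral, 5.0% private first-level, 2.2%
  religious first-level, 34.8% none (65.2% facility delivery overall);
  sick child — 27.0% public first-level, 3.0% public referral, 3.0% private,
  2.0% religious, 8.2% unskilled (pharmacy/CHW), 56.8% none (43.2% of
  episodes seek some care). 10% of care-seeking sick-child episodes report a
  second source; deliveries always have exactly one.
* **Care-seeking heterogeneity**: each cluster draws its care-seeking
  propensity from a Beta distribution with mean equal to the configured
  total and intra-cluster correlation `care_seeking_icc = 0.3`. This is what
  gives the design-based CIs the width of a real regional cluster survey
  (design effect ≈ 3–4; a crude delivery CI of roughly ±10 percentage
  points at n = 392). The Beta is mean-preserving, so the marginal mixes
  above are exact in expectation.
* **Geography**: clusters uniform in a 150 km square; facilities scattered
  around 10 town centers (Gaussian spread of extent/12) so that nearest-
  facility linking is nontrivial — some episodes genuinely bypass their
  nearest provider. Six districts are the Voronoi cells of uniform random
  centers, so districts partition facilities and clusters.
* **Quality scores**: Beta distributions reparameterised by (mean, sd) per
  provider category — bounded and unimodal, with referral facilities scoring
  higher (means ≈ 0.72–0.82) than first-level facilities (≈ 0.50–0.62) and
  within-category interquartile ranges under 20 percentage points, matching
  the typical spread of facility-assessment indices. `sd = 0` collapses a
  category to its mean exactly, which is the degenerate case used to verify
  that all linking methods coincide when within-category variance vanishes.
* **Provider choice**: gravity model — probability ∝ caseload ×
  exp(−d / 25 km) × exp(`quality_preference` × process score). The default
  `quality_preference = 0` makes choice quality-blind; preference scenarios
  set it positive and may switch on `caseload_quality_correlation`, which
  rank-correlates log-normal caseloads with process quality. Real surveys
  observe care-seeking behaviour rather than modelling it; the gravity form
  is this package's own convention and is documented as such.
* **Unlinkable sources**: 7% of episodes carrying a stated facility id have
  it cleared at random, reproducing assignment rates of roughly 92–94% under
  exact-match linking.

What the generator does **not** emulate: real road networks or travel time,
cluster displacement, non-uniform survey weights, seasonality, or the actual
spatial distribution of any real region's facilities. Passing tests
therefore demonstrate the internal consistency and statistical behaviour of
the estimators under a plausible synthetic world, not agreement with any
particular country's data.

## Facility sampling and the quality simulations

`draw_facility_sample()` keeps a census of referral facilities in every draw
and samples first-level facilities without replacement, allocating the
nominal n proportionally across two managing-authority strata
(public | non-public) with largest-remainder rounding; an unstratified
switch exists. The nominal n counts first-level facilities only, so a draw
of 65 from a 187 + 7 census contains 72 facilities. `spa_sample_size()`
implements the margin-of-error formula with finite-population correction
(n = 64 at N = 187 and ±10% precision); the canonical sizes 65/90/130 are
taken as design inputs.

Two quality simulations probe settings with more quality variability than a
typical census shows:

* **Random**: every score replaced by an independent uniform draw on [0, 1].
* **Preferential care-seeking**: scores shift by ±15 percentage points —
  up for facilities utilised at or above the threshold (≥1 sick-child user,
  ≥2 delivery users), down for under-utilised facilities within 10 km of a
  surveyed cluster, and by the facility's side of the pre-shift category
  median for remote under-utilised facilities (ties shift up by default;
  configurable). Scores clamp to [0, 1]. The runner records how many
  facilities moved up versus down, since the rule set is meant to roughly
  balance the two.

Both simulations re-score the census *before any linking*, including
exact-match, so each scenario is judged against its own truth.

## The scenario runner

`run_scenario()` produces, per scenario: 4 exact-match references (2 service
areas × 2 adjusted indicators), 8 census ecological references (× 2
methods), and the sampled grid — 2 methods × {65, 90, 130} × 20 draws × 2
areas × 2 indicators = **480 sampled estimates**, i.e. 160 per sample size
and 240 per method. A sampled estimate is an *outlier* when its point
estimate falls strictly outside the 95% CI of a reference (a point exactly
on a bound is not an outlier). Summaries report the median and IQR (linear
interpolation, quantile type 7) per grid cell.

```{r scenario, eval = FALSE}
region <- generate_region(generator_config(seed = 1))
res <- run_scenario(region, "preferential", sample_design(seed = 2))
res$outliers
export_report(res, "results/preferential")
```

## Numerical conventions and degenerate inputs

* Distances: haversine with mean Earth radius 6371.0088 km, fixed for
  reproducibility; one degree of latitude is 111.195 km.
* Seeds: the generator is deterministic given its config; each facility
  sample draw uses a sub-stream derived from (design seed, size, draw
  index), so any single draw is reproducible in isolation.
* Fewer than 2 clusters: variance undefined, an error. Zero between-cluster
  variance: se = 0 and a zero-width CI. Rescaling all weights by a constant
  changes nothing.
* Empty district × category cells under administrative linking (common after
  sampling) take the fallback uniformly; a category absent from both the
  sample and the census is an error.
* Episode tables keep one row per reported source; a `"none"` row marks an
  episode that sought no care and must be that episode's only row.

## Problem sizes used by the test suite

The bundled tests run the full default grid for the original and random
scenarios, 50 small regions (~30 facilities) for the brute-force linking
oracles, 50 default-size replicates for the directional property of the
preferential scenario, 1,000 replicate surveys for CI calibration, and a
5,000-cluster × 50,000-episode region for generator calibration. The whole
suite completes in a couple of minutes on one core.

## Known limitations

* The design-based $t$ interval is symmetric and clipped; survey CIs for
  proportions near the boundary are often built on a logit transform and are
  asymmetric. The symmetric interval is a documented convention here.
* Estimates are only meaningful at the survey's sample-domain level; nothing
  here supports small-area estimation below it.
* The preferential rules act on utilisation observed in a *finite* survey,
  so the induced preference signal is itself noisy at n = 183 sick-child
  episodes.
* Travel-time or road-distance linking, probability-proportional-to-size
  facility sampling, and cluster displacement are out of scope.
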