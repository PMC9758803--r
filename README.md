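# ecolink

Facility sampling and ecological linking for effective coverage estimation.

## What this package is for

*Effective coverage* measures the share of people in need of a health
intervention who receive it with sufficient quality to benefit. The common
construction links a household survey (who sought care, and where, by broad
provider category) to a facility assessment (how ready each facility is, and
how well it delivers care) and discounts crude care-seeking coverage by the
linked provider's quality score:

```
EC = Σ wᵢ sᵢ qᵢ / Σ wᵢ
```

with `sᵢ` indicating skilled care sought and `qᵢ` the structural score
(*input-adjusted* coverage), the process score (*quality-adjusted* coverage),
or 1 (*crude* coverage). When the specific provider is unknown, individuals
are linked **ecologically** — to the nearest facility of the reported
provider category (managing authority × level of care), or to the
caseload-weighted mean of the category within their district. And because
facility assessments such as the SPA sample facilities rather than
enumerating them, the facility set behind those links is usually incomplete.

`ecolink` is a simulation pipeline for quantifying the bias that facility
sampling adds to ecologically linked effective coverage estimates. It is
aimed at survey methodologists and health-systems researchers designing or
interpreting linked household/facility analyses. It provides:

* a **synthetic region generator** (44-cluster survey, ~190-facility census,
  calibrated care-seeking mixes, cluster-level care-seeking heterogeneity,
  gravity-model provider choice, unlinkable stated sources);
* three **linking methods** — exact-match, Euclidean-nearest within category,
  administrative caseload-weighted aggregation — with category-average
  fallback rules and multi-source averaging;
* **coverage cascades** with design-based variances (clusters as PSUs,
  Taylor linearization, t-based CIs clipped to [0, 1]);
* **SPA-style facility sampling** (referral census kept in every draw,
  stratified first-level samples of 65/90/130, 20 draws each) and two
  quality-score simulations (fully random scores; preferential care-seeking
  with ±15-point shifts);
* a **scenario runner** that compares every sample-derived estimate against
  its exact-match and census ecological references, counts CI outliers, and
  exports tidy tables and strip plots.

## Worked example

```r
library(ecolink)

region <- generate_region(generator_config(seed = 1))
region
#> <region> 194 facilities, 44 clusters, 575 episodes (583 source rows)
#>   facilities: private:first_level=22, private:referral=2, public:first_level=144, public:referral=5, religious:first_level=21
#>   episodes:   delivery=392, sick_child=183

crude_coverage(region, "delivery")
#> # A tibble: 1 × 10
#>   indicator service_area method dataset point     se ci_low ci_high n_episodes
#>   <chr>     <chr>        <chr>  <chr>   <dbl>  <dbl>  <dbl>   <dbl>      <int>
#> 1 crude     delivery     none   survey  0.582 0.0534  0.474   0.689        392
```

58.2% of the 392 synthetic deliveries happened in a facility (the generator's
configured marginal is 65.2%; cluster-level heterogeneity makes any single
44-cluster survey wander around that, exactly as a real survey would — hence
the wide design-based CI of 47.4–68.9%).

```r
links <- link_episodes(region, "euclidean", "delivery")
effective_coverage(region, links, "quality_adjusted")
#> # A tibble: 1 × 10
#>   indicator        service_area method    dataset point     se ci_low ci_high
#> 1 quality_adjusted delivery     euclidean census  0.313 0.0294  0.254   0.372
```

Quality-adjusted coverage of delivery care is 31.3% when every woman is
linked to the facility of her reported category nearest to her cluster
centroid: care-seeking (58.2%) discounted by the process quality (~0.5 on
average) of the putative providers.

A full scenario — here with scores re-assigned to emulate preferential
care-seeking from higher-quality providers — runs the whole grid:

```r
res <- run_scenario(region, "preferential", sample_design(seed = 2))
res
#> <scenario_result> scenario = preferential
#>   480 sampled estimates (65/90/130 sizes x 20 draws)
#>   outliers vs exact-match CI: 22 (4.6%); vs census CI: 0 (0.0%)

dplyr::filter(res$outliers, margin == "method")
#> # A tibble: 2 × 9
#>   margin level     n_estimates outliers_vs_exact outliers_vs_census pct_vs_exact
#> 1 method admin             240                 0                  0         0
#> 2 method euclidean         240                22                  0         9.17

export_report(res, "results/preferential")   # CSVs + strip plots
```

The reading: none of the 480 sample-derived estimates left the census
ecological CIs (sampling itself is benign), but under preferential
care-seeking the ecological estimates sit below the exact-match truth, and
4.6% of sampled estimates fall outside its CI — all of them produced by
Euclidean-nearest linking, none by administrative aggregation. The choice of
linking method, not the sampling, drives the bias.

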