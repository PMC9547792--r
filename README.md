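# nichevar

Quantifying trophic niche variation — how much of a population's diet
breadth comes from individuals eating broadly versus individuals eating
*differently* — from stomach-content and stable-isotope data.

`nichevar` is for ecologists comparing diet variation across fish
populations (or any consumer sampled by stomach contents). It implements
the full analysis chain used to test the **Niche Variation Hypothesis**
(populations with wider niches are composed of more specialized
individuals) and the competing prediction that within- and
between-individual niche components vary independently.

## The statistics

For a population, the total (population) niche width decomposes as

```
PNW = WIC + BIC
```

* on the **prey-size axis**, PNW_size is the variance of prey length over
  every measurable item in every stomach; WIC is the item-weighted mean of
  within-individual variances, BIC the weighted variance of individual mean
  sizes (maximum-likelihood variances, so the identity is exact);
* on the **taxonomic axis**, PNW_taxa is the Shannon–Weaver diversity of
  the pooled diet (natural log); WIC is the weighted mean individual
  diversity and BIC = PNW − WIC (non-negative by concavity).

Individual specialization is tested against Monte Carlo null models in
which generalist consumers draw their observed numbers of prey from the
shared pool (resampling items for the size axis, multinomial draws for the
taxonomic axis; add-one p-values on WIC/PNW). Araújo's

```
E    = mean pairwise (1 − PS_ij),   PS_ij = Σ_k min(p_ik, p_jk)
E_adj = max(0, (E − E_null) / (1 − E_null))
```

rescales the mean pairwise diet dissimilarity against its Monte Carlo null
mean so lakes with different sample sizes are comparable. The isotopic
niche (PNW_iso) is the area of the 95% bivariate-normal ellipse in
(δ13C, δ15N) space, `A = π · χ²₂(0.95) · √det Σ`, with a maximum-likelihood
and an exact conjugate Bayesian (normal–inverse-Wishart) estimator. Diet
composition is ordinated by NMDS (k = 3) on Bray–Curtis dissimilarities,
related to isotopes by PERMANOVA, and the lake-level regression battery
(linear models with standardized predictors, beta regression with AIC link
selection, Pearson correlations) tests the hypotheses.

A synthetic-data generator with exact ground truth (Dirichlet-multinomial
diets with a tunable specialization concentration; hierarchical log-normal
prey sizes with separate within/between variances; bivariate-normal
isotopes) backs every estimator with parameter-recovery tests.

## Worked example

```r
library(nichevar)

lk    <- simulate_lake(lake_config(n_fish = 18, lambda = 20), seed = 42)
sizes <- build_size_samples(lk$diet)
mat   <- build_diet_matrix(lk$diet)

decompose_continuous(sizes)
#> <niche_decomposition> axis: size (18 individuals, 392 items, items weighting)
#>   PNW = 23.05, WIC = 15.787, BIC = 7.2632 (BIC/PNW = 0.315)

decompose_shannon(mat)
#> <niche_decomposition> axis: taxa (18 individuals, 392 items, items weighting)
#>   PNW = 1.527, WIC = 0.81039, BIC = 0.71665 (BIC/PNW = 0.469)

null_continuous(sizes, R = 999, seed = 1)
#> <null_model> wic_over_tnw_size : observed 0.6849 vs null mean 0.9573 (R = 999), p = 0.001

e_adjusted(mat, R = 999, seed = 2)
#> <e_adjusted> E = 0.5774, E_null = 0.2500, E_adj = 0.4365, p = 0.001 (R = 999)

ellipse_area_bayes(lk$fish[, c("d13C", "d15N")], seed = 3)
#> <ellipse_posterior> 95% ellipse area: median 10.21 [6.688, 16.42] (ML 11.77, 4000 draws)
```

Reading this lake: 31.5% of the prey-size variance sits *between*
individuals, far more than a generalist null allows (observed WIC/PNW
0.68 vs null mean 0.96, p = 0.001), and diets overlap much less than
finite-stomach sampling explains (E_adj = 0.44). The isotopic niche is
about 10 ‰² with a credible interval reflecting the 18-fish sample.

For a whole study — many lakes, a regression table, ordination
coordinates, PERMANOVA — use the pipeline:

```r
cfg <- pipeline_config(
  synthetic = list(n_lakes = 13, base_config = lake_config()),
  r_null = 999, seed = 1)
run <- run_pipeline(cfg, out_dir = "run1")
run$lake_summary   # one row per lake: PNW/WIC/BIC both axes, E_adj, PNW_iso, ...
run$table1         # the regression battery, one row per slope/correlation
```

Field data enter through `read_diet_csv()`, `read_fish_csv()`,
`read_lake_csv()` (canonical column names, case-insensitive, with a
`col_map` for arbitrary headers) and then
`pipeline_config(input = list(diet = ..., fish = ..., lakes = ...))`.

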