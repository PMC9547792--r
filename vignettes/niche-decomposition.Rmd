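---
title: "Decomposing population niche width: models, defaults, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing population niche width}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichevar)
```

## The problem

A population's diet can be broad because every individual eats broadly, or
because individuals eat narrowly but *differently*. The classical
decomposition separates the two: the population niche width (PNW) is the sum
of the within-individual component (WIC, average individual niche breadth)
and the between-individual component (BIC, niche partitioning among
individuals). `nichevar` estimates this decomposition on two diet axes from
stomach contents, tests individual specialization against Monte Carlo nulls,
measures the isotopic niche, and fits the lake-level regressions used to
test the Niche Variation Hypothesis (BIC increases with PNW) and the
independence hypothesis (WIC and BIC uncorrelated).

## The decomposition

**Continuous (prey size) axis.** With individuals $i = 1..n$, items per
individual $n_i$, $N = \sum n_i$ and item weights $w_i = n_i/N$
(`weighting = "items"`, the default):

$$\mathrm{WIC} = \sum_i w_i v_i, \qquad
  \mathrm{BIC} = \sum_i w_i (m_i - \bar m)^2, \qquad
  \bar m = \sum_i w_i m_i,$$

where $m_i$ and $v_i$ are the mean and the *maximum-likelihood*
(divide-by-$n_i$) variance of individual $i$'s prey sizes. With these
definitions PNW = WIC + BIC equals the ML variance of all pooled items
*exactly*; an unbiased ($n-1$) divisor would break the identity, which is
why ML variances are used throughout and the conservation law is asserted to
1e-10 relative in the tests. With `weighting = "equal"` each individual gets
$w_i = 1/n$ and PNW is defined through the same law-of-total-variance
identity (it is then no longer the pooled item variance).

**Taxonomic axis.** PNW is the Shannon–Weaver diversity of the pooled diet
proportions $q_k = \sum_i w_i p_{ik}$, WIC the weighted mean individual
diversity, and BIC = PNW − WIC, which Jensen's inequality keeps
non-negative; it is zero exactly when every individual's proportions equal
the pooled ones. The natural logarithm is the default (`base` is exposed);
on 5–15 categories this puts PNW_taxa in roughly 0.2–2.5 nats, the range
typical of insectivorous fish diets.

Prey lengths can be analyzed raw (mm) or log-transformed
(`log_transform = TRUE`). Raw millimetres are the default — size variance is
then in mm², the scale on which prey-size niche widths are usually reported —
but every recovery test in the package runs on the log scale, where the
generator's normal theory is exact.

## Monte Carlo specialization tests

The null hypothesis is a population of generalists sampling from a shared
prey distribution. Each replicate keeps the observed $n_i$ and redraws every
individual's diet from the pooled data — with replacement from the pooled
item multiset on the size axis (no parametric assumption), multinomial with
the pooled proportions on the taxonomic axis — and recomputes WIC/PNW.
Specialized populations have low WIC/PNW, so the p-value is the lower-tail
add-one Monte Carlo probability
$p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(R+1)$, which cannot be
zero. The mean of the null BIC draws is retained: plotting it next to
observed BIC shows how much apparent specialization finite stomachs alone
would create. Default $R = 999$ for interactive use; published runs should
use $R = 9999$. A seed is required, never defaulted.

Because monophagous individuals inflate BIC_taxa, specialization on the
taxonomic axis is also summarized by Araújo's $E$ (mean pairwise diet
dissimilarity, $1 - \sum_k \min(p_{ik}, p_{jk})$ averaged over pairs) and
its null-adjusted version $E_{adj} = \max(0, (E - E_{null})/(1 - E_{null}))$
with $E_{null}$ the mean of $E$ over the same multinomial null. $E_{adj}$
is 0 when observed dissimilarity is explained by sampling and 1 for
completely disjoint diets; the clip at 0 keeps it in $[0,1]$ when sampling
noise puts $E$ below $E_{null}$. Calibration at 30 fish × 50 items puts the
null median of $E_{adj}$ at 0 (below 0.02), and both specialization tests
reject at nominal 5% rates (0.049 and 0.056 over 1000 generalist
populations at $R = 199$) with p-values uniform on the Monte Carlo grid.

## Isotopic niche

PNW_iso is the area of the ellipse containing 95% of a bivariate normal
fitted to (δ13C, δ15N): $A = \pi\,\chi^2_2(0.95)\sqrt{\det\Sigma}$ with
$\chi^2_2(0.95) = 5.991465$. Two estimators are provided. The ML plug-in
uses the unbiased sample covariance. The Bayesian estimator places a vague
conjugate normal–inverse-Wishart prior on $(\mu, \Sigma)$ — $\nu_0 = 3$
(the smallest value that keeps a 2×2 inverse-Wishart proper),
scale $10^{-3} I$, $\kappa_0 = 10^{-3}$, prior mean at the sample mean — and
samples the exact posterior, so no MCMC diagnostics are needed and the same
seed always reproduces the same draws. The posterior **median** area is the
default point estimate (a half-sample mode is available via
`point = "mode"`); posterior widths shrink with sample size, which is what
makes small-lake and large-lake areas comparable. At $n = 500$ from a known
normal both estimators land within 5% of the true area; at $n = 1000$ the
posterior median agrees with ML within 3%. No isotopic baseline correction
is applied — between-lake baseline differences pass straight into PNW_iso
and into the diet–isotope PERMANOVA, a deliberate limitation.

## Ordination and PERMANOVA

Diet counts of all individuals (across lakes) are ordinated together:
Bray–Curtis dissimilarities (`transform` offers `"none"` — the default —
`"sqrt"`, and `"wisconsin"`, since published analyses differ in whether the
common auto-transformation was applied), then NMDS with $k = 3$, 20 random
starts plus a metric-scaling start (via vegan's monoMDS engine: Kruskal
stress-1, pooled-adjacent-violators monotone regression, stress
non-increasing within a run). The best configuration is centered and
rotated to principal axes so NMDS1 carries the maximum variance. NMDS axis
signs are arbitrary, so NMDS1 is oriented to correlate non-negatively with
total prey count per individual (any published sign is recovered by
flipping); remaining axes get a deterministic largest-coordinate-positive
convention. A lake's taxonomic niche position is the mean NMDS1 of its
fish. Self-recovery of exact low-dimensional configurations achieves
stress and symmetric Procrustes error below 0.01.

PERMANOVA relates the same Bray–Curtis matrix to δ13C and δ15N: Gower
centering, sequential (Type I) sums of squares, pseudo-F per term,
p-values by raw-row permutation with the add-one rule — the simplest
exchangeability-consistent scheme for continuous predictors. On a
univariate Euclidean distance the pseudo-F reduces to the classical OLS
ANOVA F (asserted to 1e-8), and `n_perm = 0` returns statistics with p
absent. Fish lacking isotopes are dropped from this stage only and counted
in the provenance record.

## The regression battery

The lake-level table fits, exactly one row per slope:

* PNW_size, PNW_taxa, PNW_iso on **standardized** elevation + lake area
  (linear; standardization makes the two slopes comparable);
* BIC and WIC on PNW per axis (linear). Because WIC + BIC = PNW holds
  exactly, the two slopes sum to 1 with identical standard errors — an
  algebraic identity the tests assert on every dataset;
* BIC/PNW_size on PNW_size (beta, log-log link), BIC/PNW_taxa and E_adj on
  PNW_taxa (beta, logit) — the links follow AIC selection on the original
  field data; `link_selection = "aic"` re-selects among
  logit/probit/cloglog/loglog per model. Beta predictors are raw by
  default (`standardize_beta` flips this; published analyses do not state
  which was used, so both are supported);
* median prey length on PNW_size and mean NMDS1 on PNW_taxa (linear);
* Pearson correlations of WIC with BIC per axis (the independence test).

Beta regression is fit by maximizing the (μ, φ) log-likelihood — shapes
$\mu\phi$ and $(1-\mu)\phi$ — with BFGS on $(\beta, \log\phi)$, analytic
gradient, and starting values from least squares on the link scale;
standard errors come from the observed information and the pseudo-$R^2$ is
the squared correlation between the linear predictor and the
link-transformed response. Responses exactly 0 or 1 are a hard error:
silently squeezing them inside $(0,1)$ changes the estimand, so the caller
must decide (E_adj can clip to exactly 0 in near-generalist populations —
such lakes have to be excluded from the E_adj regression or the response
remodelled, and the error says so rather than deciding silently). Two-sided tests at
α = 0.05 throughout, no multiple-testing correction — matching the
analysis this package reproduces.

## The synthetic generator

`simulate_lake()` draws what the estimators assume: stomach counts
$n_i \sim$ zero-truncated Poisson(λ) (empty stomachs are excluded upstream
in the field protocol, so they are never generated); diet proportions
$p_i \sim \mathrm{Dirichlet}(\alpha q)$ around shared pooled proportions
$q$, with small α giving strong specialization and α → ∞ generalists;
item log-lengths $\sim N(\mu_i, \sigma_W^2)$ with
$\mu_i \sim N(M, \sigma_B^2)$, exponentiated to mm (simulating on the log
scale avoids the truncation bias a positive-support normal would carry);
isotopes bivariate normal. The generator returns exact truth:
$\mathrm{WIC} = \sigma_W^2$, $\mathrm{BIC} = \sigma_B^2$, and the
finite-sampling expectation of estimated BIC,
$\sigma_B^2 + \sigma_W^2 \sum_i w_i/n_i$, against which recovery is tested
(±15% at 200 fish × ~50 items).

Defaults describe a plausible Sierra Nevada brook-trout lake: 18 fish per
population (≈229/13), 8 invertebrate categories with geometrically
decaying $q$, λ = 20 identifiable items per stomach, prey around 7 mm with
log-scale SDs 0.5 within and 0.3 between individuals, Dirichlet α = 2
(moderate specialization), isotopes near (−25, 8) ‰. `simulate_gradient()`
spaces lakes evenly over 2508–3337 m and applies log-linear per-metre
slopes (default −4×10⁻⁴ on both σ's) so the size-axis niche narrows with
elevation, the field pattern being emulated; areas are log-uniform on
2–21 ha. Per-lake seeds derive from the master seed by a counter-based
integer mix, so inserting a lake never perturbs the others.

What the generator does **not** emulate — and what passing tests therefore
do not establish about field data: no prey-community structure or
availability gradients (diet categories are exchangeable labels), no
covariance between fish size and diet, no isotope–diet coupling (the
PERMANOVA null holds in synthetic data by construction), no measurement
error in prey lengths, and no digestion-biased detectability beyond the
missing-at-random unmeasured items.

## Degenerate inputs and numerical conventions

Single-category matrices and all-identical item sets make the
specialization tests degenerate: they return p = 1 with a warning rather
than an error, so multi-lake pipelines survive boring lakes. One-individual
populations, all-empty stomachs, zero-variance standardization and
boundary beta responses are errors with classed conditions. $0\log 0 = 0$
in every entropy; a tiny negative Shannon BIC from floating-point rounding
is clipped at 0; E_null = 1 is internally impossible with finite counts and
guarded as such. Configs are validated eagerly (YAML is the config format,
chosen for a readable, ubiquitously supported schema); `r_null` below 99
and missing seeds are errors, not warnings.

Category labels default to the full order × life-stage × habitat triple —
the richest partition stomach-content records support — with `"order_stage"`
and `"order"` collapses available for reproducing coarser analyses.

## Problem sizes in the test suite

The suite favours a few deep checks at sizes chosen for statistical
resolution: 1000 random datasets for the conservation law, 1000 simulated
generalist populations (30 fish × ~20 items, R = 199) for null calibration
and p-value uniformity, 5 × 200-fish lakes for recovery, 100 datasets for
the PERMANOVA/OLS identity, and 30 replicate 13-lake gradients for the
elevation-slope power check. The full run takes a couple of minutes on one
core.

## Known limitations

No small-sample-corrected standard ellipse (SEA_c), ellipse overlap or
Layman metrics; no jackknife CIs or the wider family of individual
specialization indices (IS, PS_i, V); no mixed models or spatial
autocorrelation in the regression battery; no blocked/stratified
permutations; no taxonomic validation of prey names. The diet–isotope
comparison inherits whatever isotopic baseline variation exists among
lakes.
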