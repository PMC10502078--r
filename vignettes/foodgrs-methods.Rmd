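---
title: "foodGRS: methods, conventions and simulator scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foodGRS: methods, conventions and simulator scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodGRS)
```

This vignette documents the statistical model behind foodGRS, the exact
numerical conventions the implementation follows, and what the built-in
simulator does and does not emulate. It states no empirical claims beyond
what the package's tests and acceptance script compute.

## 1. The model

### Genetic risk scores

Genotypes are stored as risk-allele dosages $g_{ij} \in \{0, 1, 2\}$
(individual $i$, SNP $j$), with `NA` for missing calls. Four scoring
schemes are available through `grsScore()`:

* **unweighted** — $s_i = \sum_j g_{ij}$ over non-missing SNPs (a pure
  risk-allele count; no averaging);
* **speliotes**, **finhit**, **ratio** — weighted averages
  $s_i = \sum_j w_j g_{ij} / n_i$, where $n_i$ is the number of
  non-missing SNPs for individual $i$ and $w_j$ is the catalogue effect
  size, the cohort effect size, or their quotient respectively. This is
  PLINK's `--score` averaging convention; pass `perAllele = TRUE` to
  divide by $2 n_i$ alleles instead of $n_i$ SNPs.

Individuals missing *all* panel SNPs are dropped with a warning.
`dichotomize()` splits a score at its median, with ties **assigned to the
low group** — for integer-valued unweighted scores this routinely makes
the low group larger than the high group.

### Phenotypes

FFQ ratings $1$–$7$ are recoded to weekly frequencies by the fixed mapping
$(0,\ 0.5,\ 1,\ 2.5,\ 5.5,\ 7,\ 14)$: the endpoints encode "never" and
"several times per day", the interior values are interval midpoints of the
usual consumption bands. `recodeFfq()` propagates `NA`s; the sweet-treat
index (`sweetTreatIndex()`, six sugary items) and plant-consumption index
(`plantConsumptionIndex()`, three plant items) are row sums that are `NA`
whenever any component is.

BMI-for-age z-scores use the LMS transformation
$$z = \frac{(\mathrm{BMI}/M)^L - 1}{L\,S}, \qquad
  z = \frac{\log(\mathrm{BMI}/M)}{S} \text{ when } L = 0,$$
with $(L, M, S)$ interpolated **linearly in age within sex** from a
reference table. A smooth synthetic reference covering ages 5–18
(`syntheticLmsReference()`) ships for simulation; users supply a published
reference via `readLmsReference()` for real data.

### Interaction model

`fitInteraction()` fits, by QR-based ordinary least squares on complete
cases,
$$y_i = \beta_0 + \beta_g g_i + \beta_e e_i + \boldsymbol\beta_c^\top
  \mathbf{c}_i + \beta_{ge}\, g_i e_i + \varepsilon_i,$$
with classical (homoskedastic) standard errors, $t$-distribution p-values
on $n - p$ degrees of freedom, and 95% confidence intervals. The reported
standardized coefficient is $\tilde\beta = b \cdot \mathrm{SD}(x) /
\mathrm{SD}(y)$, where for the interaction row $x$ is the **product term
itself** (not the product of standardized variables). Factor covariates
expand through `model.matrix()`; constant predictors and singular designs
are rejected with the offending term named.

### The two-level screen

Level 1 (`screenWholeGrs()`): for each food and each requested scheme, the
whole-panel GRS × weekly-food interaction is tested, adjusting for the
screening covariates (default `sex`, `ltpa`, `sleep`, `pc1`, `pc2`). A
food is flagged when any scheme's continuous p-value is below
$\alpha = 0.15$. When a continuous p-value is *borderline* — inside
$[\alpha, \texttt{borderline})$ with `borderline = 0.25` — the model is
refit with that **same scheme's** score dichotomized at its median, and
the food is also flagged if the dichotomized p-value falls below $\alpha$.

Level 2 (`screenSnps()`): for a flagged food, each panel SNP's dosage ×
food interaction is tested individually; a SNP is selected when its
two-sided p-value is below $\alpha_{\mathrm{snp}} = 0.2$ **and** its
interaction sign matches the food's *reference direction* (the sign of the
whole-GRS interaction, taken from the unweighted scheme by default). The
selected SNPs define a food-specific GRS (`buildFoodGrs()`), re-validated
by `validateFoodGrs()` under two covariate sets (`model1 = sex`,
`model2 = sex + ltpa + sleep`) and examined within the low/high strata of
the dichotomized food-specific score by `stratifiedEffects()`.

### Null calibration of the cascade, and the reference direction

Against a **fixed** reference direction, a SNP enters a food-specific GRS
under the global null when its two-sided p-value is below 0.2 *and* its
sign agrees with the reference — events that are independent under a
symmetric null, giving an inclusion probability of $0.2 \times 1/2 =
0.10$. The tests and acceptance script verify this rate empirically.

When the reference direction is instead **estimated from the same data**
(the default in a real analysis, where `screenWholeGrs()` supplies it),
the per-SNP estimate and the whole-GRS estimate are positively correlated
— the GRS contains the SNP — so sign agreement exceeds $1/2$ and the null
inclusion rate is inflated. At $n = 1142$ with the 30-SNP panel the
empirical rate is roughly 0.13–0.14. This is a property of any
same-sample direction filter, not an implementation artifact; it is why
the calibration checks fix the direction, and why downstream validation
(not the screen) carries the inferential weight.

## 2. The simulator

`simulateStudy(n, panel, effectSpec(...))` draws, from a single master
seed split into independent sub-seeds:

* **genotypes** — independent SNPs in Hardy–Weinberg proportions,
  $g_{ij} \sim \mathrm{Binomial}(2, f_j)$, default risk-allele frequencies
  equally spaced on $[0.25, 0.65]$; optional uniform missingness
  (`missingRate`);
* **cohort covariates** — age $\mathcal N(11.3, 0.2)$ years, sex
  Bernoulli(0.5) girl/boy, leisure-time physical activity
  $\mathcal N(6.7, 2.7)$ h/week truncated at 0 (by redrawing), sleep
  $\mathcal N(9.8, 0.7)$ h/day, two standard-normal genetic principal
  components;
* **FFQ ratings** — per item, a distribution over ratings $1$–$7$ obtained
  by exponential tilting of the recoded weekly values,
  $p_k \propto \exp(\theta w_k)$, with $\theta$ solved by `uniroot()` so
  the implied weekly mean matches a target (defaults approximating a
  school-age cohort); optional missingness;
* **outcome** — BMI z-score from the linear ground truth
  $z_i = \sum_j a_j g_{ij} + \sum_f b_f e_{if} + \sum_{j,f} \gamma_{jf}\,
  g_{ij} e_{if} + \boldsymbol\delta^\top \mathbf c_i +
  \varepsilon_i$, $\varepsilon_i \sim \mathcal N(0, \sigma^2)$, with
  missing dosages contributing zero; optionally back-transformed to raw
  BMI through the LMS reference.

Tunable parameters and defaults: `noiseSd` (required, z-score units),
`snpMainEffects` / `foodMainEffects` / `covariateEffects` (named vectors,
z-score units per dosage / per weekly serving / per covariate unit),
`interactionEffects` (data frame `rsid, food, effect`, z-score per
dosage × weekly-serving), `freqs` (per-SNP allele frequencies, strictly
inside $(0,1)$), `missingRate` $\in [0,1)$, `ffqMissingRate` (default 0),
`seed`.

**What the simulator does not emulate:** linkage disequilibrium between
SNPs (all SNPs independent), population structure (the PCs are pure noise,
unrelated to genotypes), genotype–covariate or diet–covariate dependence,
non-linear or threshold gene–diet effects, measurement error in the FFQ
beyond its discrete 7-point scale, and longitudinal structure. Stratified
step-function ground truths (distinct slopes below/above the score median)
are not expressible through `effectSpec`'s bilinear terms; the tests
generate those outcomes directly when needed.

## 3. Problem sizes and reproducibility

The default study size used throughout the tests and the acceptance script
is $n = 1142$ with the 30-SNP panel. Calibration checks use 1000 null
replicates at $n = 1000$ (type-I error), and 200 replicates at $n = 1142$
each for the cascade null inclusion rate, interaction-CI coverage (planted
effect $\gamma = 0.08$), and stratified sign recovery (planted slopes
$-0.130$ / $+0.153$, noise SD 1).

`runPipeline()` writes every intermediate artifact plus a resolved
configuration and log, with no timestamps, so identical configurations and
seeds reproduce every output file byte-for-byte. Genotypes round-trip
through dosage TSV and uncompressed VCFv4.2 (`writeGenotypesVcf()` /
`readGenotypes()`), with VCF REF/ALT orientation resolved against the
panel's risk/other alleles and strand-ambiguous A/T–C/G pairs warned
about.
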