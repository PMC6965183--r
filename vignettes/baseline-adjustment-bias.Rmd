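---
title: "Why adjusting drug-response phenotypes for baseline creates false positives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why adjusting drug-response phenotypes for baseline creates false positives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baselinebias)
```

## The problem

Pharmacogenomic GWAS of a quantitative drug response usually analyse the
change between a pretreatment (baseline) measurement X and an on-treatment
measurement Y. When the baseline trait is itself heritable — as LDL-C
strongly is — a variant that only shifts baseline can masquerade as a
"response" variant. A common attempted fix is to add the baseline value as
a regression covariate. This package exists to show, on fully synthetic
data with known truth, that the fix *creates* the false positives it is
meant to prevent, and to provide the heterogeneity (gene-drug interaction)
test that correctly arbitrates true response effects.

## The generative model

Each simulated individual carries dosages g (0-2 per variant, Hardy-
Weinberg, no LD) and

$$\ln B = \mu + \textstyle\sum_j \beta_{b,j} g_j + c'z + e, \qquad
  e \sim N(0, \sigma_{bio}^2)$$
$$\ln X = \ln B + u, \qquad
  \ln Y = \ln B + \ln(1-r) + \textstyle\sum_j \beta_{r,j} g_j + w$$

with independent measurement errors $u, w \sim N(0, \sigma_m^2)$ on the
log scale (multiplicative on mg/dL, so X and Y stay positive and the bias
algebra below is exact). The statin effect is a multiplicative reduction
$1-r$, default $r = 0.35$ (the median fractional LDL-C reduction on statin
therapy). Covariates z (age, sex, BMI, smoking, diabetes, hypertension,
statin type and dose) are drawn independent of genotype and carry small
log-scale effects by default.

Defaults are $\sigma_{bio} = 0.25$ and $\sigma_m = 0.18$, putting
$\sigma_m^2 / (\sigma_{bio}^2 + \sigma_m^2) \approx 0.34$ of the
non-genetic log-baseline variance in measurement error, matching the ~34%
measurement-error fraction reported for LDL-C in the cohort this design
emulates. That figure was published without a formula, so the variance-
fraction reading is a configurable default of this package, not a claim
about the original estimate.

The simulator wraps each (X, Y) pair in EHR-like records — dated statin
dispensings with days' supply, lipid results inside and outside the legal
window, and co-therapy dispensings — with configurable violation rates,
and keeps a ledger of the violations it injected so the cohort filters can
be audited against ground truth.

## Cohort filters and phenotypes

New users need ≥2 statin dispensings, ≥1 lipid strictly before initiation
(the first dispensing date), and ≥1 lipid inside the on-treatment window
[initiation + 21 d, initiation + first-fill days' supply + 21 d], endpoints
inclusive ("3 weeks" is taken as exactly 21 calendar days; the source
convention is not stated at day resolution). Lipids dated inside a
co-therapy coverage interval [fill, fill + days' supply] are ineligible for
either role. Date ties are broken by record order with a warning.

Seven phenotype definitions are built by the two-stage procedure —
residualize on covariates by OLS, then regress residuals on dosage:
ln Y − ln X with and without ln X as covariate, (Y−X)/X with and without X
as covariate (these two rank-normalized with the Blom offset c = 0.375,
ties averaged; normalization applied to the residuals, following the text
order of the source procedure), on-treatment ln Y adjusted for ln X, and
the two levels ln X and ln Y for the interaction test. The baseline level
omits statin type/dose from its covariates (treatment covariates cannot
affect a pretreatment value).

## The bias, in closed form

Write $D = \ln Y - \ln X$, $S_X^2 = \mathrm{Var}(\ln X) =
\beta_b^2 v + \sigma_{bio}^2 + \sigma_m^2$ with $v = 2\,\mathrm{maf}(1-\mathrm{maf})$.
The two-stage adjusted slope converges to

$$\beta_r - \gamma \beta_b, \qquad
  \gamma = \frac{\beta_r \beta_b v - \sigma_m^2}{S_X^2}.$$

For a pure baseline variant ($\beta_r = 0$) this is
$+\beta_b \sigma_m^2 / S_X^2$: a spurious "response" whose sign tracks the
baseline effect. The mechanism is regression toward the mean — $u$ enters
$\ln X$ positively and $D$ negatively, so conditioning on the observed
baseline makes any baseline-associated covariate, genotype included,
predict the observed change. Two limits matter:

* $\sigma_m = 0$: no spurious term — measurement error must be present.
  (A true response effect is still attenuated by $\sigma_{bio}^2/S_X^2$
  under the two-stage procedure; that factor cannot manufacture an effect
  where none exists. The exact-$\beta_r$ identity would require a joint
  regression on genotype and baseline, which the analysed pipelines do not
  run.)
* $\beta_b = 0$: no baseline pathway, no bias.

The unadjusted change score has slope exactly $\beta_r$ in all cases. The
percent-change definitions have no closed form after rank-normalization;
tests verify their scans agree in sign and genome-wide calls with the
log-scale counterparts. `expected_rejection_rate()` turns the slope and
the model residual variance into a noncentral-t rejection probability,
which the type-I-error simulations match.

A second, error-free distortion is worth knowing about: if some variant is
pleiotropic (affects both baseline and response), $\ln X$ and $D$ are
genuinely correlated even with $\sigma_m = 0$, and the baseline covariate
then transfers a spurious slope onto *every* baseline-associated variant
($-\gamma\beta_b$ with $\gamma = \sum_j \beta_{r,j}\beta_{b,j} v_j /
S_X^2$). The adjusted-equals-unadjusted equivalence at $\sigma_m = 0$
therefore holds only when no pleiotropic variants exist, and the test
suite checks it on such a panel.

## Scans, meta-analysis, interaction, loci

Per group, variants pass a strict MAF filter (> 1%; > 0.05% in the
designated large group) and are scanned by simple linear regression of
residuals on dosage with t (n−2) p-values; monomorphic and perfect-fit
variants are flagged, not dropped. Groups are combined by inverse-variance
fixed-effects meta-analysis restricted to variants shared by ≥ 2 groups,
with Cochran's Q and $I^2 = \max(0, (Q - df)/Q) \times 100$. The genomic
inflation factor is the median implied 1-df chi-square over 0.4549364231.

The interaction test is the k = 2 Cochran's Q of the baseline-level versus
on-treatment-level betas. Its default form assumes the two estimates are
independent; since they come from the same individuals and share the
biological signal ($\mathrm{cov} = \sigma_{bio}^2/(nv)$), the default is
*conservative* — null p-values pile up near 1. The `rho` argument
(correlation of the two residual vectors) switches to the corrected
variance $SE_b^2 + SE_o^2 - 2\rho SE_b SE_o$, which is calibrated: the
null-calibration checks of this package use the corrected form, and a
separate test documents the default's sub-nominal rejection rate.

Loci are called greedily: smallest p below the suggestive threshold leads,
absorbing everything within ±0.5 Mb on its chromosome; strict thresholds
5e-8 / 1e-5; p-ties broken by position.

## The demonstration experiment

`run_experiment()` defaults plant eight variants — two null, two
baseline-only ($\beta_b = \pm 0.10$), two response-only
($\beta_r = \mp 0.05$), two pleiotropic with agreeing directions — in two
ancestry groups of 12,000 and 8,000 (MAFs 0.2-0.4). Effect sizes were
chosen once, via `expected_rejection_rate()`, to give essentially complete
power at 5e-8 for every planted pathway at this cohort size. The designed
outcome, which the acceptance checks recompute:

* adjusted definitions (`logdiff_adj`, `pct_adj`, `ontreat_adj_baseline`)
  flag baseline-only, response-only and pleiotropic variants — the
  baseline-only hits are pure false positives;
* unadjusted definitions flag response-only and pleiotropic variants only;
* the interaction arbiter agrees with the unadjusted scans.

Problem sizes used by the automated checks: one 10^6-individual regression
for the closed-form/Monte-Carlo agreement; 500 replicates of n = 2,000 for
type-I error; 50,000 null variants at n = 2,000 (scanned in chunks) for
genomic-control and interaction-uniformity calibration. These sizes give
Monte-Carlo error comfortably inside the asserted tolerances.

## What the simulations do and do not show

The generator reproduces the statistical structure the analysis assumes —
log-normal LDL-C with additive genetic effects, independent multiplicative
measurement errors, multiplicative treatment effect, filter-relevant EHR
event patterns. It does not model LD (locus calling is distance-only
here), admixture or between-group allele-frequency structure beyond
separate MAFs, dose-response or adherence dynamics, repeated baselines,
or realistic EHR coding. Passing tests therefore demonstrate the bias
mechanism and the correctness of the pipeline's statistics, not the
numerical effect sizes of any particular real cohort.

Other numerical conventions: dosage jitter for imputation uncertainty is
uniform and clipped to [0, 2]; covariate matrices must be full rank (the
error names the collinear columns rather than silently aliasing);
rank-normalization refuses constant input; exclusions in pair selection
are values, not errors, and are tabulated per reason.
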