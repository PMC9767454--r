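---
title: "Within-family Mendelian randomization: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-family Mendelian randomization: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
library(dplyr)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental variables
for a modifiable exposure — here, a child's body mass index (BMI) — to
estimate its causal effect on outcomes such as depressive, anxiety, or ADHD
symptom scores. In samples of unrelated individuals ("classic" MR), three
family-level processes can violate the exclusion restriction even when the
variants are valid instruments at the individual level:

* **Population stratification**: allele frequencies and environments differ
  jointly across ancestral subgroups, creating gene–environment correlation.
* **Dynastic effects (genetic nurture)**: parental genotype shapes the
  child's environment; the child's genotype, correlated with the parents',
  then proxies an environmental pathway.
* **Assortative mating**: non-random pairing of parents on phenotypes
  induces gametic correlations across generations.

Within-family MR addresses all three for the child's own term by
instrumenting the BMI of each member of a mother–father–child trio with that
member's polygenic score (PGS) in a single multivariable two-stage
least-squares (2SLS) model: conditional on both parents' genotypes, the
child's genotype is randomized by meiosis.

`triomr` provides (i) a forward simulator of trio cohorts in which each bias
can be switched on with known magnitude, (ii) the estimators (OLS, classic
MR, within-family MR) with robust and cluster-robust standard errors and
conditional instrument diagnostics, (iii) summary-statistic sensitivity
estimators (IVW, MR-Egger, weighted median, mode-based), and (iv)
simulation-based power analysis.

## The generative model

One family per row. Parental true scores $G_m, G_f$ are standard normal
within subpopulation; the child's score is the midparent average plus
segregation noise with half the population variance,
$G_c = \tfrac12(G_m + G_f) + s$, $s \sim N(0, \tfrac12)$, so that
$\mathrm{var}(G_c) = \mathrm{var}(G_m)$ at equilibrium and
$\mathrm{cor}(G_c, G_m) = \tfrac12$ under random mating. In genotype mode
the same quantities arise mechanistically: founder dosages follow a
Balding–Nichols model (subpopulation allele frequencies
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ around an ancestral frequency $p$),
linkage disequilibrium within blocks comes from an AR(1) Gaussian copula on
each haplotype, and children receive per-SNP Bernoulli transmissions.

Standardized BMI for role $i \in \{c, m, f\}$:

$$z_i = \sqrt{R^2_i}\, G_i + \delta_{s(i)} + c\, C_{fam} + e_i,$$

with $\delta$ a per-subpopulation mean shift (SD units), $C_{fam}$ a
standard-normal confounder shared by the whole trio (the family
environment), and $\mathrm{var}(e_i)$ chosen analytically so that
$\mathrm{var}(z_i) = 1$; raw BMI is $\mu_i + \sigma_i z_i$. The child
outcome liability is

$$y = \beta_c \tfrac{\sigma_c}{5} z_c + \alpha_m \tfrac{\sigma_m}{5} z_m +
      \alpha_f \tfrac{\sigma_f}{5} z_f + \theta G_c + \delta'_{s} +
      c'\,C_{fam} + \gamma^\top w + \varepsilon,$$

so $\beta_c$ and the dynastic effects $\alpha_m, \alpha_f$ are expressed in
SD of outcome per 5 kg/m² of BMI, $\theta$ is a direct (horizontally
pleiotropic) effect of the child's score, and $w$ are small fixed covariate
effects (0.1 SD for male sex, 0.02 SD per birth year). $\varepsilon$ is
scaled so the outcome has unit variance under the all-null configuration.
These structural equations are the package's own formalization of the three
bias pathways; they are deliberately the *simplest* linear system in which
every pathway has a closed-form consequence that the estimators can be
tested against.

Two closed forms anchor the test suite. Under random mating with a common
score loading across roles, the probability limit of classic MR is
$\beta_c + (\alpha_m + \alpha_f)/2$, because the child's score covaries at
$\tfrac12$ with each parental score (with unequal loadings $\lambda_i$ the
bias generalizes to $(\alpha_m \lambda_m + \alpha_f \lambda_f)/(2
\lambda_c)$, which is why oracle scenarios use symmetric roles). And
conditioning on both parental scores halves the usable variance of the
child's instrument, so the within-family child standard error exceeds the
classic one by $\sqrt{2}$ — equivalently, within-family MR is
$\sqrt{1/2} \approx 70.7\%$ as precise.

### Default parameters

Defaults emulate a large Norwegian pregnancy-cohort trio analysis:

| parameter | default | units / meaning |
|---|---|---|
| `n_families` | 40,949 | trios |
| `bmi_mean`, `bmi_sd` | child 16.3 (2.0), mother 24.0 (4.1), father 25.9 (3.2) | kg/m² |
| `pgs_r2_*` | 0.017 / 0.032 / 0.030 | share of BMI variance explained by the score (child/mother/father) |
| `spousal_corr` | 0.23 | spousal BMI correlation |
| `n_snps` | 954 | instrument SNP count |
| `confounder_sd`, `confounder_sd_outcome` | 0.2, 0.2 | family-environment loadings (SD units); 4% of variance each |
| `beta_child`, `alpha_*`, `theta_pleio` | 0 | structural effects (global null) |
| `outcome_items` | 13×{0–2}, 5×{0–2}, 18×{0–3} | optional ordinal items per scale (totals 0–26, 0–10, 0–54) |

The `confounder_sd` values are the package's own choice of a modest but
non-negligible family environment; everything else follows the emulated
study conditions. Structural effects default to zero so that any analysis
of a default cohort is a null calibration exercise.

## Assortative mating

Mate matching uses Gaussian-copula rank matching on a *single latent mating
score* per parent (a weighted combination of standardized BMI and a symptom
liability). Given a 2×2 cross-spouse target matrix $T$ (rows = mother
traits, columns = father traits), the latent weights and copula correlation
are the best rank-1 approximation $T \approx \rho\, u v^\top$; single-entry
targets (the usual case) are represented exactly, other targets trigger a
warning naming the dropped component. A leading singular value above 1 is
infeasible and errors with the achievable bound. Matching is endogamous
(within subpopulation), which keeps the stratification and assortment
pathways separable.

Because the shared confounder $C_{fam}$ is added to both parents' BMI
*after* matching, it contributes $c^2$ to the spousal BMI correlation on its
own. The copula target is therefore deflated internally to
$(r - c^2)/(1 - c^2)$ so the *realized* correlation hits the configured
value; a target below $c^2$ is infeasible and errors. With the defaults
($r = 0.23$, $c = 0.2$) the matcher aims at 0.198 and the cohort realizes
0.23 within ±0.02 at study scale.

## Estimation

All estimators are fitted from scratch on a shared least-squares core.

* **OLS / non-genetic regression**: exposures are BMI terms divided by
  `exposure_scale` (default 5 kg/m²); the outcome is standardized (optionally
  after a log(score+1) transform, for right-skewed symptom scales); robust
  covariance is the HC1-style sandwich `n/(n-p)`, or the CR1-style
  cluster-robust sandwich `G/(G-1)·(n-1)/(n-p)` when a cluster variable
  (e.g. extended-family ID from the sibship option) is given.
* **2SLS**: exposures are projected on instruments plus covariates;
  covariates enter both stages; the sandwich meat uses *structural*
  residuals $y - X\hat b$ with observed exposures, not second-stage fitted
  values. Classic MR is the single-exposure case (child PGS instruments
  child BMI); within-family MR instruments all three BMIs with all three
  scores.
* **Conditional diagnostics**: for each exposure, residualize it on the
  other exposures' instrument-predicted values plus covariates, regress the
  residual on the instruments, and report the conditional F (numerator
  degrees of freedom `k_z - k_x + 1`) and the incremental R². With one
  exposure this is the ordinary first-stage F, satisfying
  `F = R²/(1-R²)(n-p-1)`. Covariates are included in *every* stage — a
  deliberate, documented choice where conventions differ. A conditional F
  below 1 triggers a weak-instrument warning, not an error.
* **Inference**: normal-theory 95% CIs and two-sided p-values throughout; at
  the sample sizes this package targets, t-corrections are immaterial, and
  the degrees-of-freedom-corrected sandwiches mirror widely used commercial
  implementations. `z_difference()` compares two estimates assuming
  independence; since both designs use the same data the estimates are
  correlated, so the p-value is approximate (the same approximation as the
  format it reproduces).
* **Quintile checks** for nonlinearity are fitted as OLS on exposure
  quintile indicators via the standard design-matrix path.

Complete-case analysis only: rows with missing model variables are dropped
with a logged count at every step. A multiple-imputation engine is out of
scope; the missingness injector plus the complete-case path reproduce the
complete-case sensitivity analysis instead.

### Finite-sample calibration

The just-identified trio-instrument 2SLS t-test for the child term is
mildly *conservative* in finite samples: at n = 10,000 with a conditional F
near 100 its empirical size is about 0.04 at a nominal 0.05 (classic MR,
with twice the conditional F, sits at ~0.048). This was verified against an
independent minimal implementation; it is a property of the estimator's
sampling distribution, not of the covariance code, and it dissipates as n
or instrument strength grows.

## Polygenic scores

`clump()` performs greedy p-value-ordered selection: accept a SNP iff its
p-value is below 5×10⁻⁸ and its squared dosage correlation with every
already-accepted SNP on the same chromosome within 10,000 kb is below the
threshold. The default threshold is 0.01 *as a squared correlation* — the
conventional reading when a clumping threshold is printed as "r = 0.01" —
and the flag is exposed so either convention can be applied. Monomorphic
reference SNPs count as r² = 0 with a note; SNPs missing from the reference
are dropped with a logged count.

`build_pgs()` aligns effect alleles (flipping dosages to `2-d` where the
counted allele is the other allele), drops strand-ambiguous A/T and C/G
SNPs, and mean-imputes missing dosages per SNP — all standard scoring
practice. `ancestry_pcs()` takes the top left singular vectors of the
column-standardized dosage matrix, rescaled to unit variance, with the sign
fixed by making each component's largest-magnitude loading positive
(deterministic output). `clean_anthropometrics()` applies the 4-SD outlier
rule in a single pass with the all-sample mean and SD — the plain reading of
the rule, rather than an iterated version. `prorate_scale()` requires at
least 80% of items, with a *ceiling* threshold (11 of 13 items passes; 10
does not, since 10/13 < 0.8).

## Summary-statistic sensitivity estimators

SNP-outcome associations are estimated in-cohort per SNP with robust SEs,
optionally adjusting for both parents' genotypes at the same SNP (the
within-family analogue — a dynastic-only SNP effect vanishes under this
adjustment). Summaries are harmonized so exposure betas are positive (the
Egger convention); palindromic SNPs never reach this stage because scoring
drops them.

IVW and MR-Egger share one weighted-regression core (weights
$1/\mathrm{se}_{out}^2$), so constraining the Egger intercept to zero
reproduces IVW exactly. Cochran's Q is computed and reported for both — it
is needed for the multiplicative random-effects decision (SE scaled by
$\sqrt{Q/(k-1)}$ for IVW when Q exceeds its degrees of freedom;
$\max(1,\sqrt{Q/(k-2)})$ for Egger) even where a report prints no
heterogeneity statistic. The weighted median interpolates the
inverse-variance-weighted ratio distribution at weight 0.5 (50% breakdown);
the mode-based estimator maximizes a weighted normal-kernel density of the
Wald ratios with bandwidth `factor × 0.9·min(sd, mad)·k^{-1/5}` and tends
to the weighted mean as the bandwidth grows. Median and mode SEs come from
a parametric bootstrap, 1,000 replicates by default with a recorded seed —
a documented choice, since different toolchains default differently.

## Power

`estimate_power()` simulates replicate cohorts under random mating with no
confounding (design precision only) and reports the rejection rate of the
child term with a binomial CI. `minimum_detectable_effect()` bisects the
Monte-Carlo power curve to the target (default 80% at α = 0.05) and reports
alongside it the analytic approximation
$(z_{0.975} + z_{0.8})\,\mathrm{SE} \approx 2.8\,\mathrm{SE}$ with the SE
estimated under the null. The two agree within ~10% at n ≥ 10,000, and the
within-family/classic MDE ratio is $\sqrt 2$ under random mating. The
module reports *its own* simulated and analytic MDEs under explicitly
logged parameters; minimum detectable effects depend strongly on assumed
instrument strength and outcome variance, so no attempt is made to
reproduce externally reported MDE values whose generative assumptions are
not available.

## Numerical and degenerate-input choices

* Rank ties in copula matching break by first occurrence
  (`ties.method = "first"`), making pairing deterministic given the seed.
* Rank-deficient designs error naming the collinear columns; a perfectly
  predicted exposure yields an infinite conditional F rather than an error;
  a residualized exposure with no variance at all does error.
* Transmission requires hard integer dosage calls; fractional (imputed)
  dosages are rejected.
* Genotypes are simulated unphased and transmission is per-SNP independent,
  which destroys parental LD in child haplotypes. This is acceptable here
  because LD is only consumed by clumping, which operates on the founder
  generation.
* Score loadings are calibrated analytically from the target R² and the
  realized score variance (pooled within-subpopulation SD, centered
  globally so between-group score differences propagate — the genetic half
  of the stratification pathway), never by trial simulation.
* Per-replicate seeds in acceptance runs derive from the base seed by a
  fixed affine map kept below 2³¹.

## What the simulator does and does not emulate

It emulates: trio structure with Mendelian transmission; realistic BMI
moments and score-BMI R² by role; spousal phenotype correlation; family
clustering (optional sibships); skewed ordinal symptom scales with
proration; missingness and gross reporting errors in height/weight;
population structure at the level of allele-frequency divergence and mean
shifts; dynastic and pleiotropic pathways with known coefficients.

It does not emulate: phased haplotypes, recombination maps, or realistic
human LD (the copula AR(1) blocks are a caricature sufficient for clumping
logic); genotyping-array error and QC; selection into the cohort;
longitudinal measurement; multiple imputation; parental effects that vary
over the child's life. Passing tests therefore certify the *estimators*
(consistency, bias structure, calibration, precision ratios) under a known
generative model — they are silent on how well any real cohort satisfies
that model's assumptions.

## Problem sizes used by the test suite

Oracle-equality and arithmetic tests run on toy tables in milliseconds.
Distributional checks use the sizes at which their target property is
sharp: precision-ratio and dynastic-bias oracles average 200 replicates of
40,949-family score-level cohorts; estimator size uses 1,000 replicates at
n = 10,000 (the acceptance band is the binomial 95% interval at the
500-replicate precision the calibration property is stated at); power
consistency uses 150 replicates per power evaluation at n = 10,000;
genotype-level functionality (clumping, scoring, PCs, per-SNP
associations) runs on cohorts of a few hundred families and tens of SNPs.
The full suite completes in a few minutes on one CPU.

## Known limitations

* Parental (mother/father) terms in within-family MR remain exposed to
  biases from earlier generations — removing them would require
  grandparental genotypes, which the model does not include.
* The single-latent mating mechanism cannot represent cross-spouse
  correlation structures of rank 2; such targets are approximated and
  flagged.
* `z_difference()` ignores the correlation between estimates fitted on the
  same data.
* The bootstrap SEs for median/mode estimators assume normal sampling of
  the summary statistics (parametric bootstrap).
* Power analysis covers the child term only; parental-term power is out of
  scope.

## A worked null calibration

```{r null-example}
cfg <- sim_config(n_families = 5000, seed = 7,
                  spousal_corr = 0, confounder_sd = 0,
                  confounder_sd_outcome = 0, outcomes = "dep")
fam <- tidy(simulate_trios(cfg))
tidy(within_family_mr(fam, "dep", covariates = c("sex", "birth_year"))) |>
  select(term, beta, se, ci_low, ci_high, p, cond_F, cond_R2)
```

All three intervals should (and here do) cover zero; the conditional R²
for the child is about half its marginal value, the source of the
$\sqrt 2$ precision cost that is the central trade-off of the
within-family design.
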