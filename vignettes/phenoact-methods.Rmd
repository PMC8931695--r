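---
title: "Latent phenotyping and neural coactivation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent phenotyping and neural coactivation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenoact` implements a complete latent-variable workflow for studies that
(1) classify children into phenotypic groups from binary symptom items,
(2) model region-level task activation as latent "coactivation networks",
and (3) compare those networks across the phenotypic groups, with the
behavioural and quality-control machinery of the ABCD-style Stop Signal
Task (SST) around it. This vignette describes the statistical models, the
tunable parameters and their defaults, the synthetic-data generator the
package is validated on, and the numerical and design choices a maintainer
would want to know about.

## 1. Latent class analysis of symptom items

Subjects answer $J = 22$ binary items (4 irritability, 18 ADHD). The
$K$-class model assumes items are independent given class:

$$P(y_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J}
  \rho_{kj}^{y_{ij}} (1-\rho_{kj})^{1-y_{ij}},$$

with mixing proportions $\pi_k$ and class-specific endorsement
probabilities $\rho_{kj}$. `fit_lca()` maximizes this likelihood by EM.

**Numerical choices.** Random starts draw $\rho \sim U(0.1, 0.9)$ and
$\pi$ from a flat Dirichlet; 50 starts are the enumeration default and 20
are used inside bootstrap refits. All starts are run short (50 iterations,
relative tolerance $10^{-4}$) and the ten best are polished to the full
tolerance ($10^{-6}$ relative change in log-likelihood, at most 500
iterations) — the standard accelerated multi-start ("emEM") scheme. The
likelihood is evaluated on unique response patterns with multiplicity
weights, which makes the E-step orders of magnitude cheaper at ABCD-scale
$n$ without changing any estimate. Estimated $\rho$ are clamped to
$[10^{-4}, 1-10^{-4}]$ so boundary patterns cannot produce $\log 0$.
Missing items are handled by evaluating each subject's likelihood over the
observed entries only. A fit records whether the best log-likelihood was
replicated by at least two polished starts (within $10^{-2}$), mirroring
the usual "best log-likelihood replicated?" diagnostic.

**Enumeration and selection.** `enumerate_lca()` fits $K = 1..K_{max}$ and
`select_model()` applies five joint criteria: decreasing AIC, BIC and ABIC
(ABIC uses $\ln((n+2)/24)$); relative entropy above 0.90; significant
likelihood-ratio tests (approximate VLMR/LMR and the parametric bootstrap)
at $\alpha = 0.05$; smallest class above 2% of the sample; and a
replicated best log-likelihood. The selected $K$ is the largest solution
passing all criteria whose successor fails at least one. The exact null
distribution of a mixture LRT is nonstandard; the VLMR/LMR values here use
a $\chi^2$ reference with the parameter-count difference as df, plus the
small-sample correction $LR / (1 + 1/(d \ln n))$, and are labelled
*approximate* in every output. The parametric bootstrap (`bootstrap_lrt()`,
$p = (1 + \#\{T_b \ge T\})/(B+1)$) is the reference test; bootstrap refits
whose alternative fit lands in a worse mode than the null are re-run once
with fresh starts.

**Standard errors.** Class-parameter SEs via observed information are not
reported because no downstream quantity uses them; a robust (MLR-style)
scaling correction is deliberately out of scope.

## 2. Coactivation networks: EFA, CFA, fit indices

Region-level beta weights $y$ are modelled with a confirmatory factor
model per task contrast: $y = \nu + \Lambda \eta + \varepsilon$, each
region loading on exactly one factor. Exploration precedes confirmation:
`fit_efa()` extracts 1–3 factors by maximum likelihood
(`stats::factanal`) and `efa_discard()` applies four discard criteria —
more factors than unit-or-larger eigenvalues; any indicator cross-loading
above 0.10 in absolute value on two or more factors; primary loadings
below 0.30 (such indicators are dropped and the structure re-estimated);
and factors left with two or fewer indicators. Among admissible structures
the most differentiated (largest factor count) is retained. The oblique
rotation is promax: it is available in base R, and on the clean simulated
structures used here oblique rotations agree to well within the discard
thresholds, so the specific oblique criterion is immaterial to any
decision the package makes.

`fit_cfa()` maximizes the multivariate-normal mean-and-covariance
structure likelihood with `nlminb` (a second short pass guards against
premature stops). Identification fixes the first loading per factor at 1
with free factor variances; standardized loadings are computed post hoc as
$\lambda \sqrt{\operatorname{Var}(\eta)} / \operatorname{sd}(y)$.
Covariates enter as exogenous predictors of the factors (a MIMIC
structure) with coefficients shared across groups; categorical covariates
are dummy-coded internally. Residual variances are left unconstrained so a
Heywood case is visible and flagged rather than hidden by a bound. The
model $\chi^2$ is $2(LL_{sat} - LL_{model})$ against the group-saturated
model; with covariates the saturated model is the unrestricted
per-group multivariate regression.

`fit_indices()` reports CFI, TLI (capped to $[0,1]$), RMSEA
$= \sqrt{G \max(\chi^2 - df, 0)/(df\,N)}$ with a 90% CI from inverting the
noncentral $\chi^2$, and SRMR as the RMS of standardized covariance
residuals (group-weighted; mean residuals are not included, and with
covariates the comparison is between conditional covariances). Standard
errors come from the numerically differentiated observed information;
cluster-robust (family) SEs replace them with a score-sandwich
(`cluster_robust_se()`), leaving point estimates untouched.

**Binary-item CFA.** For symptom scales, `fit_cfa_binary()` uses the
two-stage tetrachoric + unweighted-least-squares estimator: pairwise ML
tetrachorics with thresholds fixed at the marginal normal quantiles
(continuity-corrected and flagged when a 2x2 cell is empty; the matrix is
eigenvalue-smoothed to positive definiteness if needed), then a ULS fit of
$\Lambda \Phi \Lambda'$ to the off-diagonal correlations. Its fit
statistics derive from a heuristic $(n-1) F_{ULS}$ and are labelled
approximate everywhere; a full categorical weighted-least-squares
(WLSMV-style) weight matrix is deliberately not implemented.

## 3. Measurement invariance and latent-mean contrasts

`invariance_ladder()` fits configural (all measurement parameters
group-specific, latent means 0), metric (loadings equated) and scalar
(loadings and intercepts equated, latent means free except the reference
group) models bottom-up, and rejects a step only when **both**
$\Delta CFI > 0.01$ **and** $\Delta RMSEA > 0.015$ — the conjunctive
large-sample rule; testing stops at the first rejection.

`compare_latent_means()` forms all pairwise differences of the group
latent intercepts $\alpha_g$ under the scalar model, with delta-method SEs
from the joint observed-information covariance, two-sided Wald $z$ tests
(the large-$n$ setting makes a $t$ reference immaterial), and
Benjamini–Hochberg FDR within each factor's family of six contrasts. The
standardized difference is defined as $d = |\Delta| / \mathrm{SD}_\eta$
with the model-implied pooled latent SD
$\sqrt{\sum_g n_g \psi_g / N}$. This definition is deliberate and
documented: no standard formula reproduces the post-hoc effect sizes
sometimes printed alongside such contrasts from the estimates and SEs
alone, so the package reports a transparent, reproducible quantity
instead. Note the intercepts are estimated on the marker-indicator metric
(first loading fixed at 1): on simulated data with standardized loading
$\lambda_1$ the recovered intercept is $\lambda_1 \alpha$.

When scalar invariance fails the ladder stops; a partial-invariance
fallback is intentionally absent (the workflow targets data where full
invariance holds), and `compare_latent_means(force = TRUE)` exists only
for diagnostics, with a warning.

## 4. SST behaviour and quality control

`compute_ssrt()` implements the integration method: go omissions are
assigned the maximum observed go RT; $p(\text{respond}|\text{signal})$
counts premature stop-trial responses as failed stops (they do not enter
the go-RT distribution — the convention adopted here); the index into the
ascending adjusted go-RT list is $n = \lceil p \cdot N_{go} \rceil$
(the ceiling is the consensus-guideline convention; the rounding rule is
otherwise arbitrary); and $\mathrm{SSRT} = RT_{(n)} - \overline{SSD}$.
A session with no failed stops returns a flagged missing result.

`qc_filter()` excludes on any of: mean framewise displacement
$\ge 0.9$ mm (inclusive); degrees of freedom $\le 200$; FreeSurfer QC
fail; task performance flag fail (consumed as a provided boolean); any
sub-50 ms response on a stop trial with SSD = 50 ms; or $\ge 10\%$ of stop
trials at SSD = 0 ms. Every exclusion lists all triggering rules.

`winsorize_betas()` flags a region as extreme-outlier only under the
conjunction "at least one point outside mean $\pm$ 3 SD **and**
$|$skewness$| > 2$" (adjusted Fisher–Pearson moment coefficient), then
clips out-of-bound points to boundaries computed from the *original*
column in a single pass — no iterative recomputation, so the procedure is
idempotent on its own output and ranks among unclipped values are
preserved.

## 5. Regional mixed models

`fit_lmm()` fits `outcome ~ group + covariates + (1 | site)` by REML
(lme4), with the omnibus group test as a type-III Wald F using
Satterthwaite denominator df (lmerTest) — the conventional choice in this
workflow; with fewer than two sites it falls back to OLS with a warning,
and the two agree when the site variance is zero. The effect size is
$\eta^2 = SS_{group} / SS_{total}$ from the companion OLS decomposition
(type-III group SS, site as fixed blocks). $\eta^2$ near 0.75 alongside a
null F, as sometimes printed in applied tables, cannot arise from this (or
any conventional) definition; the package reports the conventional
quantity. `region_scan()` BH-adjusts omnibus p-values across the scanned
regions and reports BH-adjusted pairwise contrasts (emmeans) for regions
surviving FDR; `sex_by_group_scan()` adds sex-by-group interaction F
tests, skipping regions with empty cells.

## 6. The synthetic-data generator

The generator produces data with exactly the structure the analysis
assumes, so every stage is testable without restricted data. Its defaults
*are* the study conditions and are not adjusted per analysis:

* **Symptoms**: 4 classes with proportions 9781/787/901/279 out of 11,748
  (83.3%, 6.7%, 7.7%, 2.4%). Exact item-endorsement profiles are only ever
  published as figures, so the defaults are a synthetic calibration — high
  $\approx 0.9$, moderate $\approx 0.5$, low $\approx 0.02$ — chosen once
  to give well-separated classes (entropy > 0.95), qualitatively matching
  a typically-developing majority, a high-ADHD class with co-occurring
  irritability, a moderate-ADHD class, and a small high-irritability
  class. They are not estimates.
* **Beta weights**: single response-inhibition factor with standardized
  loadings (0.91, 0.86, 0.68, 0.51) over left inferior parietal,
  supramarginal, lateral occipital and pars orbitalis; two error-processing
  factors (0.84, 0.93, 0.79 on bilateral lateral orbitofrontal + pars
  orbitalis; 0.93, 0.98, 0.68 on bilateral superior parietal + lateral
  occipital), inter-factor correlation 0.4. Group latent means
  (TD, ADHD+IRR, ADHD, IRR): RI (0, 0.17, −0.17, −0.56); EP-I
  (0, −0.13, 0.06, 0.20); EP-II (0, −0.06, −0.21, −0.11). Residual
  variances default to $1-\lambda^2$ so indicators are standardized and
  $\mathrm{corr}(y_i, y_j) = \lambda_i \lambda_j$ within a factor. Site
  intercepts (default SD 0.1 in the bundled study generator, 21 sites) and
  MIMIC covariate effects are added on top when configured.
* **SST sessions**: 2 runs x 180 trials with 30 stop trials per run (300
  go / 60 stop per session). The stop-signal delay follows a one-up /
  one-down staircase with 50 ms steps floored at 0 ms, starting at 50 ms —
  the step is the ABCD task convention and the start is a configuration
  choice, since neither is derivable from summary task descriptions. Go
  RTs are lognormal (median 480 ms, $\sigma_{\log} = 0.28$): positive and
  right-skewed, the minimal realistic RT law. Stop outcomes follow an
  independent race with true SSRT 280 ms. The discrete 50 ms staircase
  with a skewed RT law equilibrates slightly above one half — about 52%
  successful stops pooled over sessions, within the tolerance any
  staircase-design check should allow.
* **Covariates**: independent standardized draws (age, caregiver
  education, family income), simple categoricals (sex, race, ethnicity,
  marital status), uniform site assignment, and sibling pairs at a
  configurable rate for family clustering.

What the generator does **not** emulate: item-level residual dependence
within symptom domains, non-normal or heteroskedastic beta weights,
site-by-region interactions beyond additive intercepts, RT autocorrelation
or post-error slowing, and violations of race-model context independence.
Passing recovery tests on these data therefore demonstrates correctness of
the estimators under the stated models, not robustness of the scientific
conclusions to real-data violations of them.

## 7. Problem sizes used in validation

The test suite and acceptance script run at sizes chosen to make
Monte-Carlo error small relative to each tolerance while keeping a full
run on one CPU comfortable: $n = 10^5$ for generator moment checks,
$n = 10{,}000$ for class-proportion recovery, $n = 5{,}000$ for
enumeration (bootstrap $B = 50$) and loading recovery, $n = 2{,}000$ per
group and 100 replicates for invariance-ladder power, 200 replicates for
type-I-error calibration of the omnibus mixed-model test and the
parametric bootstrap (with $B = 19$, whose attainable p-value grid makes
the nominal 5% level exactly representable).

## 8. Known limitations

* VLMR/LMR p-values are approximations (documented above); the bootstrap
  is authoritative.
* The binary-item CFA's fit statistics are heuristic; its loadings and
  thresholds are the reliable outputs.
* No mixture-SEM joint estimation: class labels enter the neural models as
  fixed modal assignments (the classifier is near-deterministic at the
  default separation, entropy > 0.95, so attenuation from classification
  error is negligible there, but it is a real simplification at low
  separation).
* Crossed random effects (site x family) are not modelled; family enters
  only through cluster-robust SEs.
* The EFA stage requires `factanal` to converge; structures it cannot fit
  (e.g. more factors than the indicator count supports) are reported as
  inadmissible rather than estimated by other means.
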