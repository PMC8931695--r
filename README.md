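# phenoact

Latent phenotyping and neural coactivation analysis for the Stop Signal
Task.

## The problem

Studies of childhood ADHD and irritability increasingly classify large
samples into *latent phenotypic groups* from binary symptom items, then ask
whether the groups differ in task-based brain activity. `phenoact` is a
tidyverse-native R package implementing that complete workflow for
ABCD-style Stop Signal Task (SST) data:

* **Latent class analysis** of binary symptom items (4 irritability + 18
  ADHD K-SADS-style items): EM estimation with multiple random starts,
  AIC/BIC/ABIC, relative entropy, approximate VLMR/LMR tests, a parametric
  bootstrap likelihood-ratio test, and a joint model-selection rule.
* **Neural coactivation networks**: exploratory factor analysis with the
  standard four discard criteria, then a hand-authored maximum-likelihood
  confirmatory factor engine (mean + covariance structure, single or
  multi-group, MIMIC covariates) with CFI / TLI / RMSEA / SRMR, plus a
  tetrachoric + ULS factor estimator for binary items.
* **Measurement invariance and latent means**: the configural → metric →
  scalar ladder with the conjunctive ΔCFI > 0.01 **and** ΔRMSEA > 0.015
  rejection rule, pairwise latent-intercept contrasts with BH-FDR, and
  family-cluster-robust standard errors.
* **SST behaviour and QC**: integration-method SSRT (omission and
  premature-response adjustments), the full exclusion-rule battery
  (framewise displacement, degrees of freedom, FreeSurfer QC, performance
  flag, speedy responses at SSD 50 ms, SSD-0 proportion), and
  skewness-gated ±3 SD winsorization.
* **Regional mixed models**: site random intercepts (REML, Satterthwaite
  F), η², FDR across regions, pairwise follow-ups, and sex-by-group
  interaction scans.
* A **synthetic-data generator** that emulates the full joint structure of
  the inputs — a four-class symptom mixture (83.3 / 6.7 / 7.7 / 2.4 %),
  group-shifted factor-structured beta weights at published standardized
  loadings, site intercepts, covariates, families, and staircase-driven
  SST sessions (2 runs × 180 trials, 30 stops per run) — so that every
  stage is testable without restricted data.

The core measurement model per task contrast is

```
y_i = nu + Lambda * eta_i + eps_i,   eta_i = alpha_g(i) + Gamma x_i + zeta_i
```

with each region loading on one factor, group latent means `alpha_g`
(reference 0) identified under scalar invariance, and group contrasts
`Delta = alpha_g2 - alpha_g1` tested by Wald z with BH-FDR per factor.

## Worked example

```r
library(phenoact)

# four-class symptom mixture, n = 10,000
symptoms <- simulate_symptoms(10000, seed = 1)
fit <- fit_lca(symptoms, K = 4, n_starts = 50, seed = 2)
fit
#> Latent class fit: K = 4, n = 10000, logLik = -41984.48 (converged)
#> class weights: 0.825 0.080 0.070 0.025
glance(fit)[, c("AIC", "BIC", "ABIC", "entropy", "smallest_class")]
#>      AIC   BIC  ABIC entropy smallest_class
#> 1  84151 84807 84518  0.9933        0.02506
```

The estimated weights recover the generating proportions (0.8326, 0.0767,
0.0670, 0.0237); the smallest class is estimated at 2.5%.

```r
# response-inhibition coactivation network, n = 5,000
cfg   <- ri_network(group_latent_means = matrix(0, 1, 1,
                                                dimnames = list("all", "ri")))
betas <- simulate_betas(cfg, rep("all", 5000), seed = 42)
net   <- fit_cfa(betas, cfa_spec(ri = names(betas)))
round(standardized_loadings(net), 3)
#> L_inferior_parietal     L_supramarginal L_lateral_occipital    L_pars_orbitalis
#>               0.908               0.865               0.672               0.510
fit_indices(net)
#>   chisq df     p cfi tli rmsea rmsea_lo rmsea_hi    srmr
#> 1 0.635  2 0.728   1   1     0        0   0.0199 0.00198
```

The standardized loadings recover the generating configuration
(0.91, 0.86, 0.68, 0.51) and the model fits cleanly (CFI = 1, RMSEA = 0).

```r
# pairwise latent-mean contrasts from group intercepts (reference TD = 0)
latent_contrasts(c(TD = 0, ADHD_IRR = 0.17, ADHD = -0.17, IRR = -0.56))
#>     group1   group2 estimate
#> 1       TD ADHD_IRR     0.17
#> 2       TD     ADHD    -0.17
#> 3       TD      IRR    -0.56
#> 4 ADHD_IRR     ADHD    -0.34
#> 5 ADHD_IRR      IRR    -0.73
#> 6     ADHD      IRR    -0.39
```

Each row is the difference in network activation (latent mean) between two
phenotypic groups — e.g. the high-irritability group sits 0.56 latent SD
below typically-developing peers, and 0.73 below the ADHD+irritability
group.

`run_pipeline(simulate_study(6000, seed = 1), pipeline_config(seed = 1))`
executes the whole chain — QC → winsorization → class enumeration →
network derivation → invariance ladder → latent contrasts → regional scan
→ SSRT comparison — and returns (optionally writes) every intermediate
table. `autoplot()` methods exist for class profiles, enumeration curves,
network loadings and contrast forests; fitted objects have `tidy()` /
`glance()` methods.

## Vignette

`vignettes/phenoact-methods.Rmd` documents the models and their
assumptions, all tunable parameters and defaults, what the synthetic
generator does and does not emulate, the numerical choices (tolerances,
starts, identification, tie-breaks), and known limitations.
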