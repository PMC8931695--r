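test_that("a just-identified triad reproduces the closed-form loading", {
  S <- matrix(c(1, .56, .48, .56, 1, .42, .48, .42, 1), 3, 3)
  set.seed(1)
  y <- MASS::mvrnorm(5000, rep(0, 3), S, empirical = TRUE)
  colnames(y) <- c("a", "b", "c")
  f <- fit_cfa(as.data.frame(y), cfa_spec(f = c("a", "b", "c")), se = FALSE)
  # lambda_1 (standardized) = sqrt(s12 * s13 / s23) = 0.8 by the triad rule
  expect_equal(unname(standardized_loadings(f)[["a"]]), 0.8, tolerance = 1e-3)
  expect_equal(f$df, 0)
  expect_lt(f$chi2, 1e-3)
  fi <- fit_indices(f)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
})

test_that("single-factor recovery at the published loading configuration", {
  cfg <- ri_network(group_latent_means =
                      matrix(0, 1, 1, dimnames = list("all", "ri")))
  b <- simulate_betas(cfg, rep("all", 5000), seed = 42)
  f <- fit_cfa(b, cfa_spec(ri = names(b)), se = FALSE)
  expect_true(f$converged)
  std <- standardized_loadings(f)
  truth <- c(0.91, 0.86, 0.68, 0.51)
  expect_lt(max(abs(unname(std) - truth)), 0.03)
})

test_that("maximum likelihood beats a derivative-free oracle on the same surface", {
  cfg <- network_config(list(f = c(a = 0.8, b = 0.7, c = 0.6, d = 0.5)))
  b <- simulate_betas(cfg, rep("all", 1500), seed = 13)
  spec <- cfa_spec(f = names(b))
  f <- fit_cfa(b, spec, se = FALSE)
  dat <- phenoact:::cfa_prepare_data(b, spec, NULL)
  lay <- phenoact:::cfa_layout(spec, 1L, "configural")
  negll <- function(p) phenoact:::cfa_negll(p, spec, lay, dat)
  # independent Nelder-Mead descent from a neutral start
  start <- c(rep(1, 3), colMeans(as.matrix(b)), rep(0.5, 4), 0.5)
  nm <- stats::optim(start, negll, method = "Nelder-Mead",
                     control = list(maxit = 20000, reltol = 1e-12))
  expect_lte(-f$loglik, nm$value + 1e-4)
})

test_that("adding free parameters never decreases the log-likelihood", {
  two <- sim_two_group_ri(400, seed = 77)
  f_conf <- fit_cfa(two$data, two$spec, group = two$group,
                    level = "configural", se = FALSE)
  f_met <- fit_cfa(two$data, two$spec, group = two$group,
                   level = "metric", se = FALSE)
  f_scal <- fit_cfa(two$data, two$spec, group = two$group,
                    level = "scalar", se = FALSE)
  expect_gte(f_conf$loglik + 1e-6, f_met$loglik)
  expect_gte(f_met$loglik + 1e-6, f_scal$loglik)
  expect_gt(f_scal$df, f_met$df)
  expect_gt(f_met$df, f_conf$df)
})

test_that("the standardized solution is invariant to indicator rescaling", {
  cfg <- ri_network(group_latent_means =
                      matrix(0, 1, 1, dimnames = list("all", "ri")))
  b <- simulate_betas(cfg, rep("all", 2000), seed = 6)
  spec <- cfa_spec(ri = names(b))
  f1 <- fit_cfa(b, spec, se = FALSE)
  b2 <- b
  b2[[2]] <- 7.3 * b2[[2]]
  f2 <- fit_cfa(b2, spec, se = FALSE)
  expect_equal(unname(standardized_loadings(f1)),
               unname(standardized_loadings(f2)), tolerance = 1e-3)
})

test_that("implied covariance at the optimum is symmetric positive definite", {
  two <- sim_two_group_ri(400, seed = 31)
  f <- fit_cfa(two$data, two$spec, group = two$group, level = "scalar",
               se = FALSE)
  for (g in 1:2) {
    Sig <- phenoact:::cfa_implied(f, g)$Sigma
    expect_equal(Sig, t(Sig), tolerance = 1e-10)
    expect_gt(min(eigen(Sig, symmetric = TRUE)$values), 0)
  }
})

test_that("a single-group multigroup call reduces to the plain fit", {
  cfg <- ri_network(group_latent_means =
                      matrix(0, 1, 1, dimnames = list("all", "ri")))
  b <- simulate_betas(cfg, rep("all", 800), seed = 3)
  spec <- cfa_spec(ri = names(b))
  f1 <- fit_cfa(b, spec, se = FALSE)
  f2 <- fit_cfa(b, spec, group = rep("only", 800), se = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-4)
})

test_that("near-zero uniquenesses are flagged as Heywood-adjacent", {
  cfg <- network_config(list(f = c(a = 0.8, b = 0.7, c = 0.6)),
                        residual_variances = c(a = 1e-4, b = 1e-4, c = 1e-4))
  b <- simulate_betas(cfg, rep("all", 800), seed = 4)
  f <- suppressWarnings(fit_cfa(b, cfa_spec(f = names(b)), se = FALSE))
  std <- standardized_loadings(f)
  expect_gt(min(abs(std)), 0.99)
})

test_that("fit index arithmetic matches the defining formulas", {
  core <- phenoact:::fit_indices_core(50, 25, 500, 30, 100, G = 1)
  expect_equal(core$rmsea, sqrt(25 / 2500))
  expect_equal(core$cfi, 1 - 25 / 470)
  perfect <- phenoact:::fit_indices_core(25, 25, 500, 30, 100)
  expect_equal(perfect$rmsea, 0)
  expect_equal(perfect$cfi, 1)
  saturated <- phenoact:::fit_indices_core(0, 0, 500, 30, 100)
  expect_equal(saturated$cfi, 1)
  expect_equal(saturated$rmsea, 0)
  # RMSEA CI brackets the point estimate
  wide <- phenoact:::fit_indices_core(80, 25, 900, 30, 200)
  expect_lte(wide$rmsea_lo, wide$rmsea)
  expect_gte(wide$rmsea_hi, wide$rmsea)
})

test_that("SRMR is zero for a saturated model", {
  S <- matrix(c(1, .5, .4, .5, 1, .3, .4, .3, 1), 3, 3)
  set.seed(2)
  y <- MASS::mvrnorm(800, rep(0, 3), S, empirical = TRUE)
  colnames(y) <- c("a", "b", "c")
  f <- fit_cfa(as.data.frame(y), cfa_spec(f = c("a", "b", "c")), se = FALSE)
  expect_lt(fit_indices(f)$srmr, 1e-4)
})

test_that("MIMIC covariate effects are recovered on the marker metric", {
  cfg <- ri_network(covariate_effects = c(age = 0.3),
                    group_latent_means =
                      matrix(0, 1, 1, dimnames = list("all", "ri")))
  cov <- tibble::tibble(age = rnorm(4000))
  b <- simulate_betas(cfg, rep("all", 4000), covariates = cov, seed = 10)
  d <- dplyr::bind_cols(b, cov)
  f <- fit_cfa(d, cfa_spec(ri = names(b), covariates = "age"), se = FALSE)
  gam <- f$par[grep("^gamma", f$par_names)]
  # marker loading is fixed at 1, so gamma is scaled by the true marker 0.91
  expect_equal(unname(gam), 0.91 * 0.3, tolerance = 0.05)
})
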