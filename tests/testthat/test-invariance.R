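test_that("the change-in-fit rejection rule is conjunctive", {
  expect_false(invariance_step_rejected(0.02, 0.010))
  expect_true(invariance_step_rejected(0.02, 0.020))
  expect_false(invariance_step_rejected(0.005, 0.020))
  expect_false(invariance_step_rejected(0.01, 0.015))  # strict inequalities
})

test_that("fully invariant two-group data attain scalar invariance", {
  two <- sim_two_group_ri(1500, seed = 101)
  lad <- invariance_ladder(two$data, two$spec, group = two$group, se = FALSE)
  expect_equal(lad$attained, "scalar")
  expect_false(any(lad$steps$rejected))
  # nested log-likelihood ordering along the ladder
  lls <- vapply(lad$fits, `[[`, 0, "loglik")
  expect_true(all(diff(lls[c("configural", "metric", "scalar")]) <= 1e-6))
})

test_that("an intercept shift on one indicator rejects the scalar step", {
  two <- sim_two_group_ri(2000, seed = 55, shift_region = "L_supramarginal",
                          shift = 0.5)
  lad <- invariance_ladder(two$data, two$spec, group = two$group, se = FALSE)
  expect_false(identical(lad$attained, "scalar"))
  scal <- lad$steps[lad$steps$level == "scalar", ]
  expect_true(scal$rejected)
})

test_that("latent contrasts reproduce intercept differences exactly", {
  alpha <- c(TD = 0, ADHD_IRR = 0.17, ADHD = -0.17, IRR = -0.56)
  ct <- latent_contrasts(alpha)
  get <- function(a, b) ct$estimate[ct$group1 == a & ct$group2 == b]
  expect_equal(get("TD", "IRR"), -0.56)
  expect_equal(get("ADHD_IRR", "IRR"), -0.73)
  expect_equal(get("ADHD", "IRR"), -0.39)
  # antisymmetry under reversed ordering of the pair
  expect_equal(get("TD", "ADHD_IRR"), 0.17)
  expect_equal(ct$intercept2[ct$group1 == "TD" & ct$group2 == "IRR"], -0.56)
})

test_that("identical groups give near-zero contrasts with large FDR p", {
  two <- sim_two_group_ri(1500, seed = 202)
  f <- fit_cfa(two$data, two$spec, group = two$group, level = "scalar")
  cm <- compare_latent_means(f)
  expect_lt(abs(cm$estimate), 2.5 * cm$se)
  expect_gt(cm$p_fdr, 0.01)
})

test_that("latent means require scalar invariance unless forced", {
  two <- sim_two_group_ri(300, seed = 17)
  f <- fit_cfa(two$data, two$spec, group = two$group, level = "metric")
  expect_error(compare_latent_means(f), "scalar")
  expect_warning(cm <- compare_latent_means(f, force = TRUE), "scalar")
  expect_equal(cm$estimate, 0)  # metric level fixes all latent means at 0
})

test_that("BH adjustment matches the hand step-up and brute force", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.9)
  expect_equal(fdr_adjust(p), c(0.06, 0.06, 0.06, 0.06, 0.06, 0.9))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  withr::with_seed(99, {
    for (i in 1:25) {
      pv <- runif(sample(1:40, 1))
      expect_equal(fdr_adjust(pv), bh_bruteforce(pv), tolerance = 1e-12)
    }
  })
  expect_error(fdr_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("cluster-robust machinery: singletons match the plain sandwich", {
  two <- sim_two_group_ri(400, seed = 303)
  f <- fit_cfa(two$data, two$spec, group = two$group, level = "scalar")
  fs <- sandwich_se(f)
  fc <- cluster_robust_se(f, seq_len(f$n))
  expect_equal(sqrt(diag(fs$vcov)), sqrt(diag(fc$vcov)), tolerance = 1e-8)
  expect_equal(fs$par, f$par)  # point estimates untouched
})

test_that("duplicating subjects into perfect pairs inflates SEs by sqrt(2)", {
  two <- sim_two_group_ri(300, seed = 404)
  dup <- two$data[rep(seq_len(nrow(two$data)), each = 2), ]
  gdup <- rep(two$group, each = 2)
  f <- fit_cfa(dup, two$spec, group = gdup, level = "scalar")
  f_singleton <- cluster_robust_se(f, seq_len(f$n))
  f_pairs <- cluster_robust_se(f, rep(seq_len(nrow(two$data)), each = 2))
  ratio <- sqrt(diag(f_pairs$vcov)) / sqrt(diag(f_singleton$vcov))
  expect_equal(median(ratio), sqrt(2), tolerance = 0.05)
})

test_that("scalar fits recover latent means within two standard errors", {
  # four groups at the published latent means, marker metric: truth is
  # lambda_marker * alpha
  gm <- matrix(c(0, 0.17, -0.17, -0.56), 4, 1,
               dimnames = list(c("TD", "ADHD_IRR", "ADHD", "IRR"), "ri"))
  cfg <- ri_network(group_latent_means = gm)
  hits <- 0L
  total <- 0L
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    cls <- rep(rownames(gm), each = 1000)
    b <- simulate_betas(cfg, cls, seed = 7000 + r)
    f <- fit_cfa(b, cfa_spec(ri = names(b)), group = cls, level = "scalar")
    idx <- grep("^alpha", f$par_names)
    est <- f$par[idx]
    se <- sqrt(diag(f$vcov)[idx])
    # groups sort alphabetically: ADHD, ADHD_IRR, IRR vs reference ADHD?
    groups <- sort(rownames(gm))
    ref <- groups[1]
    truth <- 0.91 * (gm[groups[-1], 1] - gm[ref, 1])
    hits <- hits + sum(abs(est - truth) < 2 * se)
    total <- total + length(est)
  }
  expect_gte(hits / total, 0.93)
})
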