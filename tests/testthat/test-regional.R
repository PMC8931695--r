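sim_lmm_data <- function(n = 600, n_sites = 12, site_sd = 0.4,
                         group_shift = c(0, 0, 0), seed = 1) {
  withr::with_seed(seed, {
    g <- factor(sample(paste0("g", seq_along(group_shift)), n, TRUE))
    site <- sample(sprintf("s%02d", seq_len(n_sites)), n, TRUE)
    u <- stats::setNames(rnorm(n_sites, 0, site_sd),
                         sprintf("s%02d", seq_len(n_sites)))
    age <- rnorm(n)
    y <- group_shift[as.integer(g)] + 0.2 * age + u[site] + rnorm(n)
    tibble::tibble(y = y, group = g, site_id = site, age = age)
  })
}

test_that("REML solution matches a dense grid over the variance ratio", {
  d <- sim_lmm_data(n = 12, n_sites = 3, site_sd = 0.8, seed = 3)
  f <- fit_lmm(d, "y", "group", covariates = "age")
  X <- stats::model.matrix(~ group + age, d)
  grid <- seq(0, 30, by = 0.002)
  vals <- vapply(grid, function(phi) reml_loglik_profile(d$y, X, d$site_id, phi), 0)
  expect_lt(abs(as.numeric(stats::logLik(f$model)) - max(vals)), 1e-4)
})

test_that("no site variance reduces the mixed model F to the OLS ANCOVA F", {
  d <- sim_lmm_data(n = 300, n_sites = 1, site_sd = 0, seed = 5)
  expect_warning(f <- fit_lmm(d, "y", "group", covariates = "age",
                              site = "site_id"), "OLS")
  ols <- lm(y ~ group + age, d)
  a <- car::Anova(ols, type = 3)
  expect_equal(f$omnibus$F, a["group", "F value"], tolerance = 1e-6)
  expect_true(f$ols_fallback)
})

test_that("omnibus type-I error is calibrated near five percent", {
  rejections <- vapply(1:200, function(r) {
    d <- sim_lmm_data(n = 240, n_sites = 8, site_sd = 0.3, seed = 5000 + r)
    f <- fit_lmm(d, "y", "group", covariates = "age")
    f$omnibus$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("eta squared lies in the unit interval and tracks the shift", {
  d0 <- sim_lmm_data(n = 800, group_shift = c(0, 0, 0), seed = 11)
  d1 <- sim_lmm_data(n = 800, group_shift = c(0, 0.8, -0.8), seed = 11)
  f0 <- fit_lmm(d0, "y", "group", covariates = "age")
  f1 <- fit_lmm(d1, "y", "group", covariates = "age")
  expect_gte(f0$omnibus$eta2, 0)
  expect_lte(f1$omnibus$eta2, 1)
  expect_gt(f1$omnibus$eta2, f0$omnibus$eta2)
})

test_that("constant outcome gives a zero F", {
  d <- sim_lmm_data(n = 100, seed = 2)
  d$y <- 5
  f <- fit_lmm(d, "y", "group")
  expect_equal(f$omnibus$F, 0)
  expect_equal(f$omnibus$eta2, 0)
})

test_that("REML estimates are invariant to site relabelling", {
  d <- sim_lmm_data(n = 300, n_sites = 6, seed = 21)
  f1 <- fit_lmm(d, "y", "group", covariates = "age")
  d2 <- d
  d2$site_id <- factor(d2$site_id,
                       labels = rev(sprintf("relab%02d", 1:6)))
  f2 <- fit_lmm(d2, "y", "group", covariates = "age")
  expect_equal(f1$omnibus$F, f2$omnibus$F, tolerance = 1e-6)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-6)
})

test_that("region scan flags an injected shift and only that region", {
  withr::with_seed(31, {
    n <- 2000
    g <- factor(sample(c("a", "b"), n, TRUE))
    site <- sample(sprintf("s%02d", 1:10), n, TRUE)
    betas <- tibble::tibble(r1 = rnorm(n), r2 = rnorm(n), r3 = rnorm(n))
    betas$r2 <- betas$r2 + 0.3 * (g == "b")
    d <- tibble::tibble(group = g, site_id = site, age = rnorm(n))
  })
  rs <- region_scan(betas, c("r1", "r2", "r3"), d, covariates = "age")
  expect_equal(rs$regions$region, c("r1", "r2", "r3"))
  expect_lt(rs$regions$p_fdr[rs$regions$region == "r2"], 0.05)
  expect_true(all(rs$pairwise$region == "r2"))
  expect_error(region_scan(betas, "missing_region", d), "absent")
})

test_that("identical outcome columns give identical statistics", {
  withr::with_seed(41, {
    n <- 400
    d <- tibble::tibble(group = factor(sample(c("a", "b", "c"), n, TRUE)),
                        site_id = sample(sprintf("s%d", 1:6), n, TRUE))
    betas <- tibble::tibble(r1 = rnorm(n))
    betas$r2 <- betas$r1
  })
  rs <- region_scan(betas, c("r1", "r2"), d)
  expect_equal(rs$regions$F[1], rs$regions$F[2], tolerance = 1e-10)
  expect_equal(rs$regions$p[1], rs$regions$p[2], tolerance = 1e-10)
})

test_that("sex-by-group scan is calibrated under the null and flags degeneracies", {
  withr::with_seed(51, {
    n <- 1200
    d <- tibble::tibble(group = factor(sample(c("a", "b"), n, TRUE)),
                        sex = sample(c("F", "M"), n, TRUE),
                        site_id = sample(sprintf("s%d", 1:8), n, TRUE))
    betas <- tibble::tibble(r1 = rnorm(n), r2 = rnorm(n))
  })
  out <- sex_by_group_scan(betas, c("r1", "r2"), d)
  expect_true(all(out$p > 0.001, na.rm = TRUE))
  # injected interaction in one cell is detected
  betas2 <- betas
  betas2$r1 <- betas2$r1 + 0.6 * (d$group == "b" & d$sex == "M")
  out2 <- sex_by_group_scan(betas2, c("r1", "r2"), d)
  expect_lt(out2$p_fdr[out2$region == "r1"], 0.05)
  # constant sex column is inestimable
  d3 <- d; d3$sex <- "F"
  out3 <- sex_by_group_scan(betas, "r1", d3)
  expect_match(out3$note, "inestimable")
})
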