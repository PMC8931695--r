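test_that("one-class fit has the closed form", {
  set.seed(1)
  y <- matrix(rbinom(200 * 5, 1, 0.35), 200, 5,
              dimnames = list(NULL, paste0("i", 1:5)))
  f <- fit_lca(y, K = 1)
  expect_equal(drop(f$endorse), colMeans(y), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(f$weights, 1)
  mu <- colMeans(y)
  ll <- sum(y %*% log(mu) + (1 - y) %*% log(1 - mu))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
})

test_that("EM matches a coordinate grid-search oracle on a 3-item toy", {
  # 20 subjects with fixed pattern counts
  pats <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, 0, 1), c(0, 1, 0), c(1, 1, 0))
  counts <- c(8, 6, 3, 2, 1)
  y <- pats[rep(seq_len(nrow(pats)), counts), ]
  colnames(y) <- paste0("i", 1:3)
  f <- fit_lca(y, K = 2, n_starts = 30, seed = 5)
  ll_oracle <- grid_search_lca2(y, n_init = 5, seed = 9)
  expect_lt(abs(f$loglik - ll_oracle), 1e-3)
})

test_that("EM log-likelihood is monotone over iterations", {
  # re-run the E/M recursion by hand from a fixed start and check ascent
  set.seed(4)
  cfg <- phenotype_config()
  s <- simulate_symptoms(800, cfg, seed = 10)
  y <- as.matrix(s[cfg$item_labels])
  pi_k <- rep(0.25, 4)
  rho <- matrix(runif(4 * 22, 0.2, 0.8), 4, 22)
  ll_prev <- -Inf
  for (it in 1:40) {
    lmat <- y %*% t(log(rho)) + (1 - y) %*% t(log(1 - rho))
    lmat <- sweep(lmat, 2, log(pi_k), `+`)
    mx <- apply(lmat, 1, max)
    li <- mx + log(rowSums(exp(lmat - mx)))
    ll <- sum(li)
    expect_gte(ll, ll_prev - 1e-8)
    ll_prev <- ll
    post <- exp(lmat - li)
    pi_k <- colMeans(post)
    rho <- pmin(pmax(t(post) %*% y / colSums(post), 1e-4), 1 - 1e-4)
  }
})

test_that("four-class fit recovers the generating proportions", {
  s <- simulate_symptoms(10000, seed = 11)
  f <- fit_lca(s, K = 4, n_starts = 50, seed = 2)
  al <- align_classes(classify(f), s$.true_class)
  expect_gte(al$agreement, 0.95)
  # permute estimated weights onto the generating labels and compare
  w_aligned <- numeric(4)
  for (k in 1:4) w_aligned[al$perm[k]] <- f$weights[k]
  target <- c(9781, 787, 901, 279) / 11748
  expect_lt(max(abs(w_aligned - target)), 0.005)
})

test_that("information criteria follow their formulas", {
  f <- structure(list(loglik = -100, n_params = 5, n = 100), class = "lca_fit")
  ic <- information_criteria(f)
  expect_equal(ic[["AIC"]], 210)
  expect_equal(ic[["BIC"]], 223.03, tolerance = 1e-4)
  expect_equal(ic[["ABIC"]], 207.23, tolerance = 1e-4)
  f0 <- structure(list(loglik = 0, n_params = 0, n = 50), class = "lca_fit")
  expect_equal(unname(information_criteria(f0)), c(0, 0, 0))
  expect_error(information_criteria(f, n = 0), "positive")
  # AIC < BIC iff n > e^2
  for (n in c(3, 7, 8, 1000)) {
    ic_n <- information_criteria(structure(list(loglik = -50, n_params = 4,
                                                n = n), class = "lca_fit"))
    expect_equal(ic_n[["AIC"]] < ic_n[["BIC"]], n > exp(2))
  }
})

test_that("relative entropy matches hand evaluation and its bounds", {
  mk <- function(post, K) structure(list(posteriors = post, K = K,
                                         n = nrow(post)), class = "lca_fit")
  uniform <- mk(matrix(1 / 3, 9, 3), 3L)
  expect_equal(relative_entropy(uniform), 0)
  hard <- mk(cbind(c(1, 0, 1), c(0, 1, 0)), 2L)
  expect_equal(relative_entropy(hard), 1)
  two <- mk(rbind(c(0.5, 0.5), c(1, 0)), 2L)
  expect_equal(relative_entropy(two), 0.5)
  expect_equal(relative_entropy(mk(matrix(1, 5, 1), 1L)), 1)
})

test_that("modal classification breaks ties toward the lower class", {
  f <- structure(list(posteriors = rbind(c(0.5, 0.5), c(0.2, 0.8))),
                 class = "lca_fit")
  expect_equal(classify(f), c(1L, 2L))
})

test_that("missing items are handled through the observed-data likelihood", {
  s <- simulate_symptoms(2000, seed = 15)
  y <- as.matrix(s[phenotype_config()$item_labels])
  y[sample(length(y), 2000)] <- NA
  f <- fit_lca(y, K = 4, n_starts = 20, seed = 3)
  expect_true(is.finite(f$loglik))
  expect_equal(rowSums(f$posteriors), rep(1, nrow(y)), tolerance = 1e-10)
  al <- align_classes(classify(f), s$.true_class)
  expect_gte(al$agreement, 0.9)
})

test_that("posterior rows sum to one and weights to one", {
  s <- simulate_symptoms(1000, seed = 6)
  f <- fit_lca(s, K = 3, n_starts = 20, seed = 4)
  expect_equal(sum(f$weights), 1, tolerance = 1e-10)
  expect_equal(range(rowSums(f$posteriors)), c(1, 1), tolerance = 1e-10)
  expect_equal(f$n_params, 2 + 3 * 22)
})
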