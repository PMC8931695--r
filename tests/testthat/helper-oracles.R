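# Independent oracles used across the suite. None of these call the
# implementation paths they are meant to check.

# --- two-class Bernoulli-mixture log-likelihood, direct evaluation ---------
mixture_loglik <- function(y, pi1, rho) {
  # rho: 2 x J matrix
  l1 <- exp(y %*% log(rho[1, ]) + (1 - y) %*% log(1 - rho[1, ]))
  l2 <- exp(y %*% log(rho[2, ]) + (1 - y) %*% log(1 - rho[2, ]))
  sum(log(pi1 * l1 + (1 - pi1) * l2))
}

# coordinate-wise grid ascent over (pi1, rho_kj): each parameter is moved to
# the best value on a progressively refined grid until no move helps.
grid_search_lca2 <- function(y, n_init = 5, seed = 1) {
  J <- ncol(y)
  best <- -Inf
  withr::with_seed(seed, {
    for (init in seq_len(n_init)) {
      pi1 <- runif(1, 0.2, 0.8)
      rho <- matrix(runif(2 * J, 0.2, 0.8), 2, J)
      for (step in c(0.1, 0.01, 0.001)) {
        repeat {
          moved <- FALSE
          cand_p <- unique(pmin(pmax(seq(0.01, 0.99, by = step), 0.01), 0.99))
          for (target in seq_len(1 + 2 * J)) {
            cur <- mixture_loglik(y, pi1, rho)
            if (target == 1) {
              vals <- vapply(cand_p, function(v) mixture_loglik(y, v, rho), 0)
              if (max(vals) > cur + 1e-12) { pi1 <- cand_p[which.max(vals)]; moved <- TRUE }
            } else {
              k <- if (target <= 1 + J) 1 else 2
              j <- target - 1 - (k - 1) * J
              cand_r <- pmin(pmax(seq(0.001, 0.999, by = step), 1e-4), 1 - 1e-4)
              vals <- vapply(cand_r, function(v) {
                r2 <- rho; r2[k, j] <- v; mixture_loglik(y, pi1, r2)
              }, 0)
              if (max(vals) > cur + 1e-12) { rho[k, j] <- cand_r[which.max(vals)]; moved <- TRUE }
            }
          }
          if (!moved) break
        }
      }
      # polish the grid point with a derivative-free simplex on the logit
      # scale (coordinate moves alone stall on likelihood ridges)
      par0 <- stats::qlogis(pmin(pmax(c(pi1, as.vector(rho)), 1e-6), 1 - 1e-6))
      nm <- stats::optim(par0, function(p) {
        # same parameter space as the fitted model: rho in [1e-4, 1-1e-4]
        pr <- stats::plogis(p)
        pr[-1] <- 1e-4 + (1 - 2e-4) * pr[-1]
        -mixture_loglik(y, pr[1], matrix(pr[-1], 2, J))
      }, method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-12))
      ll <- -nm$value
      if (ll > best) best <- ll
    }
  })
  best
}

# --- brute-force Benjamini-Hochberg step-up from the definition ------------
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- profiled REML criterion over the site variance ratio ------------------
reml_loglik_profile <- function(y, X, site, phi) {
  Z <- stats::model.matrix(~ 0 + factor(site))
  n <- length(y); p <- ncol(X)
  V <- diag(n) + phi * tcrossprod(Z)
  ch <- chol(V); Vi <- chol2inv(ch)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- drop(y - X %*% beta)
  quad <- drop(t(r) %*% Vi %*% r)
  s2 <- quad / (n - p)
  -0.5 * (2 * sum(log(diag(ch))) + determinant(XtVX)$modulus[1] +
            (n - p) * (log(2 * pi * s2) + 1))
}

# --- closed-form orthant probability of the standard bivariate normal ------
# P(Z1 > 0, Z2 > 0) = 1/4 + asin(rho) / (2*pi)
bvn_orthant <- function(rho) 0.25 + asin(rho) / (2 * pi)

# small helper: simulate a two-group beta table from the default RI network
sim_two_group_ri <- function(n_per_group, seed, shift_region = NULL,
                             shift = 0) {
  cfg <- ri_network(group_latent_means =
                      matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "ri")))
  b1 <- simulate_betas(cfg, rep("g1", n_per_group), seed = seed)
  b2 <- simulate_betas(cfg, rep("g2", n_per_group), seed = seed + 70000L)
  if (!is.null(shift_region)) b2[[shift_region]] <- b2[[shift_region]] + shift
  list(data = rbind(b1, b2),
       group = rep(c("g1", "g2"), each = n_per_group),
       spec = cfa_spec(ri = names(b1)))
}
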