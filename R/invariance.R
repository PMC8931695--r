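#' Measurement-invariance ladder across groups
#'
#' Fits the configural, metric and scalar models bottom-up and applies the
#' conjunctive change-in-fit rule: a step is rejected only when BOTH
#' `ΔCFI > cfi_drop` AND `ΔRMSEA > rmsea_rise` relative to the previous
#' level (`ΔCFI` is the decrease in CFI, `ΔRMSEA` the increase in RMSEA).
#' The default thresholds (0.01 and 0.015) are the conventional large-sample
#' criteria. Testing stops at the first rejected step.
#'
#' @param data Data frame with indicator (and covariate) columns.
#' @param spec A [cfa_spec()].
#' @param group Group label per row.
#' @param cfi_drop,rmsea_rise Rejection thresholds.
#' @param se Compute SEs for the final attained fit.
#' @return An object of class `invariance_ladder`: `steps` tibble (fit
#'   indices and deltas per level with the decision), `attained` (highest
#'   attained level), and the fitted models in `fits`.
#' @export
invariance_ladder <- function(data, spec, group, cfi_drop = 0.01,
                              rmsea_rise = 0.015, se = TRUE) {
  levels_ <- c("configural", "metric", "scalar")
  fits <- list()
  rows <- list()
  prev <- NULL
  attained <- NULL
  for (lv in levels_) {
    f <- fit_cfa(data, spec, group = group, level = lv, se = FALSE)
    if (lv == "configural" && !f$converged) {
      abort("configural model did not converge; ladder aborted")
    }
    fi <- fit_indices(f)
    rejected <- FALSE
    d_cfi <- NA_real_; d_rmsea <- NA_real_
    if (!is.null(prev)) {
      d_cfi <- prev$cfi - fi$cfi
      d_rmsea <- fi$rmsea - prev$rmsea
      rejected <- invariance_step_rejected(d_cfi, d_rmsea,
                                           cfi_drop, rmsea_rise)
    }
    fits[[lv]] <- f
    rows[[lv]] <- tibble(level = lv, chisq = fi$chisq, df = fi$df,
                         cfi = fi$cfi, tli = fi$tli, rmsea = fi$rmsea,
                         srmr = fi$srmr, delta_cfi = d_cfi,
                         delta_rmsea = d_rmsea, rejected = rejected)
    if (rejected) break
    attained <- lv
    prev <- fi
  }
  if (se && !is.null(attained)) {
    fits[[attained]] <- fit_cfa(data, spec, group = group,
                                level = attained, se = TRUE)
  }
  structure(list(steps = bind_rows(rows), attained = attained, fits = fits),
            class = "invariance_ladder")
}

#' Conjunctive change-in-fit rejection rule
#'
#' A constrained invariance step is rejected only when BOTH the CFI drop
#' exceeds `cfi_drop` AND the RMSEA rise exceeds `rmsea_rise`.
#'
#' @param delta_cfi CFI decrease from the previous level.
#' @param delta_rmsea RMSEA increase from the previous level.
#' @param cfi_drop,rmsea_rise Thresholds (defaults 0.01 and 0.015).
#' @return Logical.
#' @export
invariance_step_rejected <- function(delta_cfi, delta_rmsea,
                                     cfi_drop = 0.01, rmsea_rise = 0.015) {
  (delta_cfi > cfi_drop) & (delta_rmsea > rmsea_rise)
}

#' @export
print.invariance_ladder <- function(x, ...) {
  print(x$steps)
  cat("highest attained level:", x$attained %||% "none", "\n")
  invisible(x)
}

#' Pairwise latent-mean contrasts from intercepts
#'
#' Given group latent intercepts (reference fixed at 0) and, optionally,
#' their covariance matrix, computes every pairwise difference
#' `Δ = α_{g2} - α_{g1}` with delta-method SEs, Wald z tests,
#' Benjamini-Hochberg adjusted p-values across the contrast family, and a
#' standardized difference `d = |Δ| / latent_sd`.
#'
#' @param alpha Named numeric vector of latent intercepts (one factor).
#' @param vcov Covariance matrix of `alpha` (0 entries for the fixed
#'   reference); scalar 0 for purely descriptive contrasts.
#' @param latent_sd Pooled latent SD used for the standardized difference
#'   (default 1).
#' @param factor_name Label carried into the output.
#' @return Tibble with one row per ordered pair: `factor`, `group1`,
#'   `group2`, `intercept1`, `intercept2`, `estimate`, `se`, `z`, `p`,
#'   `p_fdr`, `d`.
#' @export
latent_contrasts <- function(alpha, vcov = 0, latent_sd = 1,
                             factor_name = "factor1") {
  g <- names(alpha)
  if (is.null(g)) g <- paste0("g", seq_along(alpha))
  k <- length(alpha)
  if (length(vcov) == 1L) vcov <- matrix(vcov, k, k) * diag(k)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    est <- alpha[[b]] - alpha[[a]]
    v <- vcov[a, a] + vcov[b, b] - 2 * vcov[a, b]
    se <- sqrt(max(v, 0))
    z <- if (se > 0) est / se else NA_real_
    tibble(factor = factor_name, group1 = g[a], group2 = g[b],
           intercept1 = alpha[[a]], intercept2 = alpha[[b]],
           estimate = est, se = se, z = z,
           p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
           d = abs(est) / latent_sd)
  })
  out <- bind_rows(rows)
  out$p_fdr <- fdr_adjust(out$p)
  relocate(out, "p_fdr", .after = "p")
}

#' Latent-mean group contrasts from a scalar-invariance fit
#'
#' Extracts the group latent intercepts (reference group fixed at 0) and
#' their covariance from a scalar multi-group fit and forms all pairwise
#' contrasts per factor via [latent_contrasts()]. FDR adjustment is applied
#' within each factor's contrast family. The standardized difference uses
#' the model-implied pooled latent SD,
#' `sqrt(sum_g n_g psi_g / N)` per factor (a documented definition).
#'
#' @param fit A `cfa_fit` at scalar level with SEs
#'   (or any level if `force = TRUE`, with a warning).
#' @param force Proceed even if the fit is not a scalar-level fit.
#' @return A tibble of contrasts (class `latent_contrast_tbl`).
#' @export
compare_latent_means <- function(fit, force = FALSE) {
  if (fit$level != "scalar") {
    if (!force) abort("latent means require a scalar-invariance fit (or force = TRUE)")
    warn("comparing latent means without scalar invariance")
  }
  if (is.null(fit$vcov)) abort("fit must carry standard errors (se = TRUE)")
  m <- fit$lay$m; G <- fit$G
  out <- list()
  for (f in seq_len(m)) {
    fac <- fit$spec$factors[f]
    alpha <- vapply(fit$mats, function(mm) mm$alpha[f], 0)
    names(alpha) <- fit$groups
    V <- matrix(0, G, G)
    if (fit$lay$alpha_sets > 0L) {
      idx <- fit$lay$offsets[["alpha"]] + (seq_len(G - 1L) - 1L) * m + f
      V[-1L, -1L] <- fit$vcov[idx, idx]
    }
    psi_f <- vapply(fit$mats, function(mm) mm$Psi[f, f], 0)
    pooled_sd <- sqrt(sum(fit$n_g * psi_f) / fit$n)
    out[[f]] <- latent_contrasts(alpha, V, latent_sd = pooled_sd,
                                 factor_name = fac)
  }
  res <- bind_rows(out)
  class(res) <- c("latent_contrast_tbl", class(res))
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1
#' (delegates to [stats::p.adjust()]); `NA`s are passed through.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cluster-robust standard errors for a CFA fit
#'
#' Replaces the observed-information covariance with a cluster sandwich:
#' per-subject score vectors are obtained by central finite differences of
#' the casewise log-likelihood, summed within clusters, and combined as
#' `A^-1 B A^-1` with `A` the observed information and `B` the outer product
#' of cluster score sums. Point estimates are unchanged. Clusters may span
#' groups.
#'
#' @param fit A `cfa_fit` with `se = TRUE`.
#' @param cluster Cluster id per row of the data used in the fit (rows with
#'   missing indicators/covariates were dropped in fitting and must be
#'   dropped here too).
#' @return The fit with `vcov` replaced and `vcov_type = "cluster"`.
#' @export
cluster_robust_se <- function(fit, cluster) {
  if (is.null(fit$vcov)) abort("fit must carry standard errors (se = TRUE)")
  if (length(cluster) != fit$n) {
    abort("cluster must have one id per fitted row")
  }
  S <- casewise_scores(fit)
  cl <- factor(cluster)
  Sc <- rowsum(S, cl)
  B <- crossprod(Sc)
  A_inv <- fit$vcov               # inverse observed information
  fit$vcov <- A_inv %*% B %*% A_inv
  fit$vcov_type <- "cluster"
  fit
}

#' Non-clustered sandwich standard errors for a CFA fit
#'
#' The same estimator as [cluster_robust_se()] with every subject its own
#' cluster.
#'
#' @inheritParams cluster_robust_se
#' @export
sandwich_se <- function(fit) {
  f <- cluster_robust_se(fit, seq_len(fit$n))
  f$vcov_type <- "sandwich"
  f
}

# n x npar matrix of per-subject score vectors by central differences of the
# casewise log-likelihood (one full-data pass per parameter and direction)
casewise_scores <- function(fit, h = 1e-5) {
  par <- fit$par
  npar <- length(par)
  S <- matrix(0, fit$n, npar)
  for (j in seq_len(npar)) {
    hj <- h * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + hj
    pm <- par; pm[j] <- pm[j] - hj
    S[, j] <- (cfa_casewise_ll(pp, fit) - cfa_casewise_ll(pm, fit)) / (2 * hj)
  }
  S
}

# vector of per-subject log-likelihood contributions at par
cfa_casewise_ll <- function(par, fit) {
  mats <- cfa_build(par, fit$spec, fit$lay)
  dat <- fit$dat
  out <- numeric(dat$n)
  for (g in seq_len(dat$G)) {
    mg <- mats[[g]]
    Sigma <- mg$Lambda %*% mg$Psi %*% t(mg$Lambda) + diag(mg$theta, fit$lay$p)
    ch <- chol(Sigma)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    rows <- dat$gidx == g
    base_mu <- mg$nu + as.vector(mg$Lambda %*% mg$alpha)
    R <- sweep(dat$y[rows, , drop = FALSE], 2L, base_mu)
    if (!is.null(dat$x)) {
      B <- mg$Lambda %*% mg$Gamma
      R <- R - dat$x[rows, , drop = FALSE] %*% t(B)
    }
    out[rows] <- -0.5 * (fit$lay$p * LOG2PI + logdet + rowSums(R * (R %*% Sinv)))
  }
  out
}
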