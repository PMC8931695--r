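#' Tetrachoric correlation of two binary items
#'
#' Maximum-likelihood estimate of the latent bivariate-normal correlation
#' underlying a 2x2 table, with thresholds fixed at the normal quantiles of
#' the marginal endorsement rates. Empty cells receive a 0.5 continuity
#' correction (flagged); estimates are capped at +/- 0.999.
#'
#' @param x,y Binary 0/1 vectors (pairwise-complete observations used).
#' @return List with `rho`, `tau_x`, `tau_y`, `smoothed` (continuity
#'   correction applied), `capped`.
#' @export
tetrachoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  smoothed <- any(c(n11, n10, n01, n00) == 0)
  if (smoothed) {
    n11 <- n11 + 0.5; n10 <- n10 + 0.5; n01 <- n01 + 0.5; n00 <- n00 + 0.5
  }
  n <- n11 + n10 + n01 + n00
  px <- (n11 + n10) / n
  py <- (n11 + n01) / n
  tau_x <- qnorm(1 - px)
  tau_y <- qnorm(1 - py)
  negll <- function(rho) {
    p11 <- bvn_upper(tau_x, tau_y, rho)
    p10 <- (1 - pnorm(tau_x)) - p11
    p01 <- (1 - pnorm(tau_y)) - p11
    p00 <- 1 - p11 - p10 - p01
    pr <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(c(n11, n10, n01, n00) * log(pr))
  }
  opt <- optimize(negll, c(-0.999, 0.999))
  rho <- opt$minimum
  capped <- abs(rho) > 0.995
  if (capped) rho <- sign(rho) * 0.999
  list(rho = rho, tau_x = tau_x, tau_y = tau_y,
       smoothed = smoothed, capped = capped)
}

# P(Z1 > h, Z2 > k) under the standard bivariate normal with correlation rho
bvn_upper <- function(h, k, rho) {
  if (abs(rho) >= 0.9999) {
    if (rho > 0) return(min(1 - pnorm(h), 1 - pnorm(k)))
    return(max(0, (1 - pnorm(h)) - pnorm(-k)))
  }
  s <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) * pnorm((rho * z - k) / s),
            lower = h, upper = Inf, rel.tol = 1e-9)$value
}

#' Tetrachoric correlation matrix
#'
#' @param data Data frame/matrix of binary items.
#' @param items Optional item column names.
#' @return List with the correlation matrix `rho`, `thresholds`, and a
#'   tibble `flags` of smoothed/capped pairs.
#' @export
tetrachoric <- function(data, items = NULL) {
  y <- item_matrix(data, items)
  J <- ncol(y)
  R <- diag(1, J)
  dimnames(R) <- list(colnames(y), colnames(y))
  flags <- list()
  for (a in seq_len(J - 1L)) for (b in (a + 1L):J) {
    tp <- tetrachoric_pair(y[, a], y[, b])
    R[a, b] <- R[b, a] <- tp$rho
    if (tp$smoothed || tp$capped) {
      flags[[length(flags) + 1L]] <- tibble(
        item1 = colnames(y)[a], item2 = colnames(y)[b],
        smoothed = tp$smoothed, capped = tp$capped)
    }
  }
  thr <- qnorm(1 - colMeans(y, na.rm = TRUE))
  list(rho = R, thresholds = setNames(thr, colnames(y)),
       flags = if (length(flags)) bind_rows(flags) else tibble())
}

#' Factor analysis of binary items via tetrachoric correlations
#'
#' Two-stage estimator for categorical indicators: (1) the tetrachoric
#' correlation matrix (smoothed to positive definiteness by eigenvalue
#' clipping if needed, flagged); (2) an unweighted-least-squares factor fit
#' minimizing the sum of squared off-diagonal residuals between the
#' tetrachoric matrix and the implied correlation structure
#' `Lambda Phi Lambda'` (unit factor variances, free factor correlations,
#' uniqueness `1 - communality`). Loadings are directly on the standardized
#' (latent response) metric. Fit indices are computed from a heuristic
#' chi-square `(n - 1) * F_ULS` against the zero-correlation baseline and
#' are labelled approximate.
#'
#' @param data Binary item data.
#' @param spec A [cfa_spec()] over the item columns.
#' @return A `binary_cfa_fit`: `loadings` (named, standardized), `phi`,
#'   `thresholds`, `uniquenesses`, `fit` tibble (approximate indices),
#'   `tetrachoric` (the stage-1 output), `smoothed_matrix` flag.
#' @export
fit_cfa_binary <- function(data, spec) {
  y <- item_matrix(data, spec$indicators)
  tc <- tetrachoric(y)
  R <- tc$rho
  sm <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (any(ev$values < 1e-4)) {
    sm <- TRUE
    vals <- pmax(ev$values, 1e-4)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- 1 / sqrt(diag(R))
    R <- diag(d) %*% R %*% diag(d)
    dimnames(R) <- dimnames(tc$rho)
  }
  p <- ncol(R)
  m <- length(spec$blocks)
  blk_idx <- lapply(spec$blocks, match, spec$indicators)
  n_phi <- m * (m - 1L) / 2L
  implied <- function(par) {
    lam <- matrix(0, p, m)
    for (f in seq_len(m)) lam[blk_idx[[f]], f] <- par[seq_along(blk_idx[[f]]) +
                                                        sum(lengths(blk_idx[seq_len(f - 1L)]))]
    Phi <- diag(1, m)
    if (n_phi > 0) {
      Phi[upper.tri(Phi)] <- par[p + seq_len(n_phi)]
      Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    }
    list(S = lam %*% Phi %*% t(lam), lam = lam, Phi = Phi)
  }
  offdiag <- lower.tri(R)
  objective <- function(par) {
    S <- implied(par)$S
    sum((R[offdiag] - S[offdiag])^2)
  }
  start <- c(rep(0.6, p), rep(0.3, n_phi))
  opt <- nlminb(start, objective,
                lower = c(rep(-0.999, p), rep(-0.95, n_phi)),
                upper = c(rep(0.999, p), rep(0.95, n_phi)))
  imp <- implied(opt$par)
  lam_vec <- vapply(seq_len(p), function(j) {
    f <- which(imp$lam[j, ] != 0)[1]
    imp$lam[j, f]
  }, 0)
  names(lam_vec) <- spec$indicators
  n <- nrow(y)
  F_uls <- opt$objective
  F_base <- sum(R[offdiag]^2)
  nfree <- p + n_phi
  df <- p * (p - 1) / 2 - nfree
  df_base <- p * (p - 1) / 2
  chi2 <- (n - 1) * F_uls
  chi2_base <- (n - 1) * F_base
  cfi <- if (max(chi2_base - df_base, chi2 - df, 0) == 0) 1 else
    1 - max(chi2 - df, 0) / max(chi2_base - df_base, chi2 - df, 0)
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * n)) else 0
  srmr <- sqrt(mean((R[offdiag] - imp$S[offdiag])^2))
  structure(
    list(loadings = lam_vec, phi = imp$Phi,
         thresholds = tc$thresholds,
         uniquenesses = 1 - diag(imp$S),
         fit = tibble(chisq_approx = chi2, df = df, cfi_approx = cfi,
                      rmsea_approx = rmsea, srmr = srmr, approximate = TRUE),
         tetrachoric = tc, smoothed_matrix = sm, n = n,
         converged = opt$convergence == 0),
    class = "binary_cfa_fit"
  )
}
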