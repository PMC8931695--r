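#' Fit indices for a confirmatory factor fit
#'
#' Computes the standard descriptive fit battery from the model and baseline
#' (independence) chi-squares:
#' \itemize{
#'   \item `CFI = 1 - max(chisq_M - df_M, 0) / max(chisq_B - df_B, chisq_M - df_M, 0)`
#'   \item `TLI = ((chisq_B/df_B) - (chisq_M/df_M)) / ((chisq_B/df_B) - 1)`,
#'     capped to `[0, 1]` for reporting
#'   \item `RMSEA = sqrt(G * max(chisq_M - df_M, 0) / (df_M * N))` with `G`
#'     groups and total `N`, with a 90% CI obtained by inverting the
#'     noncentral chi-square distribution
#'   \item `SRMR`: root mean square of the standardized residual covariances
#'     (observed minus implied, standardized by the observed SDs), averaged
#'     over groups with weights `n_g / N`. With exogenous covariates the
#'     observed matrix is the residual covariance after the saturated
#'     regression, compared to the model's conditional covariance.
#' }
#' A saturated model (`df = 0`) reports RMSEA 0 and CFI 1 by convention.
#'
#' @param fit A `cfa_fit`.
#' @param ci_level Confidence level for the RMSEA interval.
#' @return Tibble with `chisq`, `df`, `p`, `cfi`, `tli`, `rmsea`,
#'   `rmsea_lo`, `rmsea_hi`, `srmr`.
#' @export
fit_indices <- function(fit, ci_level = 0.90) {
  core <- fit_indices_core(fit$chi2, fit$df, fit$chi2_baseline,
                           fit$df_baseline, fit$n, fit$G, ci_level)
  # SRMR from standardized covariance residuals
  sq <- 0; wt <- 0
  for (g in seq_len(fit$G)) {
    st <- fit$dat$stats[[g]]
    if (fit$lay$q > 0) {
      rows <- fit$dat$gidx == g
      X <- cbind(1, fit$dat$x[rows, , drop = FALSE])
      res <- stats::lm.fit(X, fit$dat$y[rows, , drop = FALSE])$residuals
      S <- crossprod(res) / st$n
    } else S <- st$S
    Sig <- cfa_implied(fit, g)$Sigma
    sds <- sqrt(diag(S))
    Rz <- (S - Sig) / tcrossprod(sds)
    v <- Rz[lower.tri(Rz, diag = TRUE)]
    sq <- sq + st$n * mean(v^2)
    wt <- wt + st$n
  }
  core$srmr <- sqrt(sq / wt)
  core
}

# pure-arithmetic part of the index battery (no data access)
fit_indices_core <- function(chi_m, df_m, chi_b, df_b, N, G = 1,
                             ci_level = 0.90) {
  if (df_m == 0) {
    cfi <- 1; tli <- 1; rmsea <- 0; lo <- 0; hi <- 0
    p <- NA_real_
  } else {
    p <- pchisq(chi_m, df_m, lower.tail = FALSE)
    num <- max(chi_m - df_m, 0)
    den <- max(chi_b - df_b, chi_m - df_m, 0)
    cfi <- if (den == 0) 1 else 1 - num / den
    rb <- chi_b / df_b; rm_ <- chi_m / df_m
    tli <- if (rb <= 1) 1 else (rb - rm_) / (rb - 1)
    tli <- min(max(tli, 0), 1)
    rmsea <- sqrt(G * num / (df_m * N))
    alpha <- 1 - ci_level
    ncp_root <- function(target_p) {
      # largest ncp with P(X <= chi_m) = target_p
      if (pchisq(chi_m, df_m, ncp = 0) < target_p) return(0)
      hi_ncp <- max(chi_m * 2, 10)
      while (pchisq(chi_m, df_m, ncp = hi_ncp) > target_p) hi_ncp <- hi_ncp * 2
      uniroot(function(l) pchisq(chi_m, df_m, ncp = l) - target_p,
              c(0, hi_ncp))$root
    }
    lo <- sqrt(G * ncp_root(1 - alpha / 2) / (df_m * N))
    hi <- sqrt(G * ncp_root(alpha / 2) / (df_m * N))
  }
  tibble(chisq = chi_m, df = df_m, p = p,
         cfi = cfi, tli = tli, rmsea = rmsea,
         rmsea_lo = lo, rmsea_hi = hi, srmr = NA_real_)
}
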