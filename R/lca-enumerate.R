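#' Parametric bootstrap likelihood-ratio test for K vs K-1 classes
#'
#' The observed statistic is `-2 (LL_{K-1} - LL_K)`. `B` datasets are drawn
#' from the fitted `(K-1)`-class model (the null MLE), each refitted at both
#' `K-1` and `K` classes, and the p-value is
#' `(1 + #{boot stat >= observed}) / (B + 1)`. Bootstrap refits yielding a
#' negative statistic (a sign the `K`-class refit found a worse mode) are
#' re-run once with fresh starts; the number of such restarts is reported.
#'
#' @param data Binary item data (as in [fit_lca()]).
#' @param K Alternative class count (>= 2).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param n_starts Random starts for the fits on the observed data.
#' @param boot_starts Random starts inside bootstrap refits.
#' @param fit_null,fit_alt Optional pre-computed `lca_fit`s at `K-1` and `K`.
#' @param items Optional item column names.
#' @param ... Further arguments (e.g. `n_polish`) passed to [fit_lca()] for
#'   both the observed-data and bootstrap fits.
#' @return List with `p_value`, `statistic`, `boot_stats`, `n_restarts`,
#'   and the two observed-data fits.
#' @export
bootstrap_lrt <- function(data, K, B = 50, seed = 1L, n_starts = 20,
                          boot_starts = 20, fit_null = NULL, fit_alt = NULL,
                          items = NULL, ...) {
  if (K < 2) abort("K must be >= 2")
  y <- item_matrix(data, items)
  if (is.null(fit_null)) {
    fit_null <- fit_lca(y, K - 1L, n_starts = n_starts, seed = seed, ...)
  }
  if (is.null(fit_alt)) {
    fit_alt <- fit_lca(y, K, n_starts = n_starts, seed = seed + 1L, ...)
  }
  stat <- -2 * (fit_null$loglik - fit_alt$loglik)
  n <- nrow(y)
  n_restarts <- 0L
  boot_stats <- withr::with_seed(seed + 2L, {
    boot_seeds <- sample.int(2^30, B)
    vapply(seq_len(B), function(b) {
      yb <- withr::with_seed(boot_seeds[b], {
        cls <- sample.int(fit_null$K, n, TRUE, prob = fit_null$weights)
        pr <- fit_null$endorse[cls, , drop = FALSE]
        matrix(rbinom(length(pr), 1L, pr), nrow = n,
               dimnames = list(NULL, colnames(y)))
      })
      one <- function(s) {
        f0 <- fit_lca(yb, K - 1L, n_starts = boot_starts, seed = s, ...)
        f1 <- fit_lca(yb, K, n_starts = boot_starts, seed = s + 1L, ...)
        -2 * (f0$loglik - f1$loglik)
      }
      st <- one(boot_seeds[b] + 11L)
      if (st < 0) {              # alternative stuck in a worse mode: retry
        n_restarts <<- n_restarts + 1L
        st <- max(st, one(boot_seeds[b] + 101L))
      }
      st
    }, 0)
  })
  list(p_value = (1 + sum(boot_stats >= stat)) / (B + 1),
       statistic = stat, boot_stats = boot_stats, n_restarts = n_restarts,
       fit_null = fit_null, fit_alt = fit_alt)
}

#' Lo-Mendell-Rubin likelihood-ratio tests (approximate)
#'
#' Approximate tests of `K` against `K-1` classes from the two fitted
#' log-likelihoods. The unadjusted (Vuong-Lo-Mendell-Rubin-style) p-value
#' refers `2 (LL_K - LL_{K-1})` to a chi-square with degrees of freedom equal
#' to the difference in parameter counts; the adjusted statistic applies the
#' Lo-Mendell-Rubin small-sample correction
#' `LR / (1 + 1 / (d log n))`. Both are labelled approximate: the exact null
#' distribution of a mixture LRT is a data-dependent weighted chi-square, and
#' the parametric bootstrap ([bootstrap_lrt()]) is the reference test.
#'
#' @param fit_alt,fit_null `lca_fit`s at `K` and `K-1` on the same data.
#' @param n Sample size.
#' @return Tibble with `statistic`, `df`, `vlmr_p`, `lmr_statistic`,
#'   `lmr_p`, `approximate = TRUE`.
#' @export
lmr_lrt <- function(fit_alt, fit_null, n = fit_alt$n) {
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  d <- fit_alt$n_params - fit_null$n_params
  vlmr_p <- if (stat <= 0) 1 else pchisq(stat, d, lower.tail = FALSE)
  adj <- stat / (1 + 1 / (d * log(n)))
  lmr_p <- if (adj <= 0) 1 else pchisq(adj, d, lower.tail = FALSE)
  tibble(statistic = stat, df = d, vlmr_p = vlmr_p,
         lmr_statistic = adj, lmr_p = lmr_p, approximate = TRUE)
}

#' Enumerate latent class solutions over a range of K
#'
#' Fits `K = k_min..k_max` class models and assembles, per K, the
#' information criteria (AIC/BIC/ABIC), relative entropy, approximate
#' VLMR/LMR p-values, the parametric-bootstrap LRT p-value, the smallest
#' class proportion, and whether the best log-likelihood was replicated by
#' at least two polished starts.
#'
#' @param data Binary item data.
#' @param k_min,k_max Range of class counts (must start at 1 for the LRT
#'   sequence to be well defined).
#' @param n_starts Random starts per fit.
#' @param B Bootstrap replicates for the PB-LRT (`0` skips it).
#' @param boot_starts Starts inside bootstrap refits.
#' @param seed Integer seed.
#' @param items Optional item column names.
#' @return An object of class `lca_enumeration`: `summary` tibble (one row
#'   per K) and the list of `fits`.
#' @export
enumerate_lca <- function(data, k_min = 1, k_max = 5, n_starts = 50,
                          B = 50, boot_starts = 20, seed = 1L, items = NULL) {
  if (k_min != 1) abort("enumeration must start at K = 1")
  y <- item_matrix(data, items)
  ks <- k_min:k_max
  fits <- lapply(ks, function(k) {
    fit_lca(y, k, n_starts = n_starts, seed = seed + k)
  })
  names(fits) <- paste0("K", ks)
  rows <- lapply(seq_along(ks), function(i) {
    f <- fits[[i]]
    g <- glance(f)
    if (ks[i] == 1L) {
      extra <- tibble(vlmr_p = NA_real_, lmr_p = NA_real_, pb_p = NA_real_,
                      pb_restarts = NA_integer_)
    } else {
      lmr <- lmr_lrt(f, fits[[i - 1L]], n = f$n)
      if (B > 0) {
        pb <- bootstrap_lrt(y, ks[i], B = B, seed = seed + 100L + ks[i],
                            boot_starts = boot_starts,
                            fit_null = fits[[i - 1L]], fit_alt = f)
        extra <- tibble(vlmr_p = lmr$vlmr_p, lmr_p = lmr$lmr_p,
                        pb_p = pb$p_value, pb_restarts = pb$n_restarts)
      } else {
        extra <- tibble(vlmr_p = lmr$vlmr_p, lmr_p = lmr$lmr_p,
                        pb_p = NA_real_, pb_restarts = NA_integer_)
      }
    }
    bind_cols(g, extra)
  })
  structure(list(summary = bind_rows(rows), fits = fits),
            class = "lca_enumeration")
}

#' @export
print.lca_enumeration <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Select the number of classes from an enumeration
#'
#' Applies the selection criteria jointly: (1) each information criterion
#' (AIC, BIC, ABIC) decreases relative to the previous solution; (2) relative
#' entropy exceeds `entropy_min`; (3) all available likelihood-ratio tests
#' (VLMR, LMR, parametric bootstrap) are significant at `alpha`; (4) the
#' smallest class proportion exceeds `min_prop`; (5) the best log-likelihood
#' was replicated. The selected K is the largest K passing all criteria whose
#' successor fails at least one (the top of the range counts as selected if
#' it passes). A per-criterion verdict table is returned alongside.
#'
#' @param enum An `lca_enumeration` (or its `summary` tibble).
#' @param entropy_min Entropy threshold (default 0.90).
#' @param alpha Significance level for the LRTs.
#' @param min_prop Minimum smallest-class proportion (default 0.02).
#' @return List with `selected_k` (`NA` if no K passes), `verdicts` (tibble
#'   of per-criterion logicals by K) and the `summary` tibble.
#' @export
select_model <- function(enum, entropy_min = 0.90, alpha = 0.05,
                         min_prop = 0.02) {
  s <- if (inherits(enum, "lca_enumeration")) enum$summary else as_tibble(enum)
  s <- arrange(s, .data$K)
  ic_drop <- function(v) c(TRUE, diff(v) < 0)   # K=1 has no predecessor
  lrt_ok <- function(p) is.na(p) | p < alpha
  verdicts <- tibble(
    K = s$K,
    ic_decrease = ic_drop(s$AIC) & ic_drop(s$BIC) & ic_drop(s$ABIC),
    entropy_ok = s$entropy > entropy_min | s$K == 1L,
    lrt_significant = lrt_ok(s$vlmr_p) & lrt_ok(s$lmr_p) & lrt_ok(s$pb_p),
    class_size_ok = s$smallest_class > min_prop,
    loglik_replicated = s$loglik_replicated
  )
  pass <- verdicts$ic_decrease & verdicts$entropy_ok &
    verdicts$lrt_significant & verdicts$class_size_ok &
    verdicts$loglik_replicated
  verdicts$passes_all <- pass
  # largest K passing all whose successor fails (top of range counts)
  sel_idx <- which(pass & c(!pass[-1L], TRUE))
  selected <- if (length(sel_idx)) s$K[max(sel_idx)] else NA_integer_
  list(selected_k = selected, verdicts = verdicts, summary = s)
}
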