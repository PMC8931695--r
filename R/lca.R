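#' Fit a latent class model to binary items by EM
#'
#' Maximum-likelihood estimation of a `K`-class mixture of independent
#' Bernoulli items via expectation-maximization with multiple random starts.
#' Missing items are handled by evaluating each subject's likelihood over the
#' observed entries only. Random starts draw item probabilities from
#' Uniform(0.1, 0.9) and class weights from a flat Dirichlet; all starts are
#' run short (capped iterations, loose tolerance) and the best few are
#' polished to full convergence, a standard accelerated multi-start scheme.
#' Estimated item probabilities are clamped to `[1e-4, 1 - 1e-4]` so the
#' log-likelihood stays finite at the boundary.
#'
#' @param data Data frame (or matrix) of 0/1 items; non-item columns
#'   `subject_id` and `.true_class` are ignored.
#' @param K Number of latent classes (>= 1).
#' @param n_starts Number of random starts (K = 1 has a closed form).
#' @param seed Integer seed for the random starts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per (polished) start.
#' @param items Optional character vector naming the item columns.
#' @param n_polish Number of best short-run starts polished to `tol`.
#' @return An object of class `lca_fit`: class weights, the class-by-item
#'   endorsement-probability matrix, posterior class probabilities,
#'   log-likelihood, parameter count `(K-1) + K*J`, and start diagnostics
#'   (`n_starts_run`, `n_starts_at_best` — how many polished starts replicated
#'   the best log-likelihood within 1e-3).
#' @export
fit_lca <- function(data, K, n_starts = 50, seed = 1L, tol = 1e-6,
                    max_iter = 500, items = NULL, n_polish = 10L) {
  y <- item_matrix(data, items)
  n <- nrow(y); J <- ncol(y)
  if (K < 1) abort("K must be >= 1")
  # collapse to unique response patterns: the likelihood only depends on
  # pattern counts, which shrinks the E-step by orders of magnitude
  key <- do.call(paste, c(as.data.frame(y), sep = "\r"))
  first <- !duplicated(key)
  pat_of <- match(key, key[first])
  w <- as.numeric(tabulate(pat_of, sum(first)))
  yp <- y[first, , drop = FALSE]
  y1 <- ifelse(is.na(yp), 0, yp)          # observed-and-endorsed
  y0 <- ifelse(is.na(yp), 0, 1 - yp)      # observed-and-not-endorsed

  if (K == 1L) {
    obs <- colSums((y1 + y0) * w)
    rho <- matrix(pmin(pmax(colSums(y1 * w) / obs, 1e-4), 1 - 1e-4), 1, J,
                  dimnames = list(NULL, colnames(y)))
    ll <- sum(w * (y1 %*% t(log(rho)) + y0 %*% t(log(1 - rho))))
    # closed form: every start would land here, so replication is vacuous
    fit <- list(K = 1L, weights = 1, endorse = rho, loglik = ll,
                n_params = J, posteriors = matrix(1, n, 1), n = n,
                converged = TRUE, n_starts_run = n_starts,
                n_starts_at_best = n_starts, item_labels = colnames(y))
    return(structure(fit, class = "lca_fit"))
  }

  em_run <- function(pi0, rho0, iter_max, tol_run) {
    pi_k <- pi0; rho <- rho0
    ll_old <- -Inf; ll <- -Inf; converged <- FALSE
    for (it in seq_len(iter_max)) {
      lmat <- y1 %*% t(log(rho)) + y0 %*% t(log(1 - rho))
      lmat <- sweep(lmat, 2L, log(pi_k), `+`)
      li <- row_logsumexp(lmat)
      ll <- sum(w * li)
      post <- exp(lmat - li)
      if (is.finite(ll_old) && (ll - ll_old) < tol_run * abs(ll)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      wpost <- post * w
      pi_k <- pmax(colSums(wpost) / n, 1e-12)
      pi_k <- pi_k / sum(pi_k)
      num <- crossprod(wpost, y1)
      den <- crossprod(wpost, y1 + y0)
      rho <- pmin(pmax(num / pmax(den, 1e-12), 1e-4), 1 - 1e-4)
    }
    list(pi = pi_k, rho = rho, loglik = ll, converged = converged, iter = it)
  }

  runs <- withr::with_seed(seed, {
    starts <- replicate(n_starts, {
      w <- stats::rgamma(K, 1)
      list(pi = w / sum(w),
           rho = matrix(runif(K * J, 0.1, 0.9), K, J))
    }, simplify = FALSE)
    short <- lapply(starts, function(s) em_run(s$pi, s$rho, 50L, 1e-4))
    ord <- order(vapply(short, `[[`, 0, "loglik"), decreasing = TRUE)
    polish_idx <- ord[seq_len(min(n_polish, n_starts))]
    lapply(polish_idx, function(i) {
      em_run(short[[i]]$pi, short[[i]]$rho, max_iter, tol)
    })
  })

  lls <- vapply(runs, `[[`, 0, "loglik")
  best <- runs[[which.max(lls)]]
  n_at_best <- sum(abs(lls - max(lls)) < 1e-2)

  # final E-step at the optimum; expand pattern posteriors back to subjects
  lmat <- y1 %*% t(log(best$rho)) + y0 %*% t(log(1 - best$rho))
  lmat <- sweep(lmat, 2L, log(best$pi), `+`)
  post <- exp(lmat - row_logsumexp(lmat))[pat_of, , drop = FALSE]

  # order classes by decreasing weight for stable reporting
  ord <- order(best$pi, decreasing = TRUE)
  rho <- best$rho[ord, , drop = FALSE]
  colnames(rho) <- colnames(y)
  structure(
    list(K = as.integer(K), weights = best$pi[ord], endorse = rho,
         loglik = best$loglik, n_params = (K - 1L) + K * J,
         posteriors = post[, ord, drop = FALSE], n = n,
         converged = best$converged, n_starts_run = n_starts,
         n_starts_at_best = n_at_best, item_labels = colnames(y)),
    class = "lca_fit"
  )
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Latent class fit: K = %d, n = %d, logLik = %.2f (%s)\n",
              x$K, x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat("class weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Information criteria for a latent class fit
#'
#' `AIC = -2LL + 2p`, `BIC = -2LL + p log n`,
#' `ABIC = -2LL + p log((n + 2) / 24)` (the sample-size-adjusted BIC).
#'
#' @param fit An `lca_fit`.
#' @param n Sample size (defaults to the fitted n).
#' @return Named numeric vector `c(AIC, BIC, ABIC)`.
#' @export
information_criteria <- function(fit, n = fit$n) {
  if (n <= 0) abort("n must be positive")
  p <- fit$n_params
  ll <- fit$loglik
  c(AIC = -2 * ll + 2 * p,
    BIC = -2 * ll + p * log(n),
    ABIC = -2 * ll + p * log((n + 2) / 24))
}

#' Relative entropy of a latent class fit
#'
#' Normalized classification certainty,
#' `E = 1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`, in `[0, 1]`;
#' 1 means perfectly separated posteriors. `E = 1` for `K = 1` by convention.
#'
#' @param fit An `lca_fit`.
#' @export
relative_entropy <- function(fit) {
  if (fit$K == 1L) return(1)
  p <- fit$posteriors
  h <- -p * log(p)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (fit$n * log(fit$K))
}

#' Modal class assignment
#'
#' Assigns each subject to the class with the highest posterior probability;
#' ties break toward the lower class index.
#'
#' @param fit An `lca_fit`.
#' @return Integer vector of class indices (classes ordered by decreasing
#'   estimated weight, as in the fit).
#' @export
classify <- function(fit) {
  max.col(fit$posteriors, ties.method = "first")
}

#' Align estimated class labels with reference labels
#'
#' Mixture components are identified only up to permutation. Finds the
#' permutation of estimated labels maximizing agreement with the reference
#' (exhaustive over permutations; K is small) and returns the relabelled
#' estimates plus the agreement rate.
#'
#' @param estimated Integer vector of estimated class indices in `1..K`.
#' @param reference Vector of reference labels (any type, K distinct values;
#'   factor level order defines the index mapping).
#' @return List with `labels` (estimated labels mapped onto the reference
#'   coding), `agreement` (proportion matching), and `perm` (the permutation:
#'   estimated class k corresponds to reference class `perm[k]`).
#' @export
align_classes <- function(estimated, reference) {
  ref <- as.integer(factor(reference))
  K <- max(length(unique(ref)), max(estimated))
  pm <- perms(K)
  agree <- apply(pm, 1L, function(p) mean(p[estimated] == ref))
  best <- pm[which.max(agree), ]
  lv <- levels(factor(reference))
  list(labels = factor(lv[best[estimated]], levels = lv),
       agreement = max(agree), perm = best)
}

#' @export
glance.lca_fit <- function(x, ...) {
  ic <- information_criteria(x)
  tibble(K = x$K, n = x$n, loglik = x$loglik, n_params = x$n_params,
         AIC = ic[["AIC"]], BIC = ic[["BIC"]], ABIC = ic[["ABIC"]],
         entropy = relative_entropy(x),
         smallest_class = min(x$weights),
         converged = x$converged,
         loglik_replicated = x$n_starts_at_best >= 2L)
}

#' @export
tidy.lca_fit <- function(x, ...) {
  tibble(class = rep(seq_len(x$K), each = ncol(x$endorse) + 1L)) |>
    mutate(term = rep(c("weight", colnames(x$endorse)), times = x$K),
           estimate = as.vector(t(cbind(x$weights, x$endorse))))
}

#' @export
augment.lca_fit <- function(x, data = NULL, ...) {
  post <- as_tibble(x$posteriors, .name_repair = ~ paste0(".posterior_", seq_along(.x)))
  out <- bind_cols(post, tibble(.class = classify(x)))
  if (!is.null(data)) out <- bind_cols(as_tibble(data), out)
  out
}
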