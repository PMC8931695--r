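#' Specify a confirmatory factor model
#'
#' Each indicator loads on exactly one factor (no cross-loadings); factors
#' may correlate freely. Covariates, when named, enter as exogenous
#' predictors of every factor (a MIMIC structure), not of the indicators.
#'
#' @param ... Named factor blocks, each a character vector of indicator
#'   (region) column names, e.g. `cfa_spec(ri = c("a", "b", "c"))`.
#' @param covariates Character vector of covariate column names regressed on
#'   the latent factors.
#' @return A `cfa_spec` object.
#' @export
cfa_spec <- function(..., covariates = character()) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1]]) && is.null(names(blocks))) {
    blocks <- blocks[[1]]
  }
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("factor blocks must be named")
  }
  indicators <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(indicators)) abort("an indicator may load on only one factor")
  structure(list(blocks = blocks, indicators = indicators,
                 factors = names(blocks), covariates = covariates),
            class = "cfa_spec")
}

# ---- internal: parameter bookkeeping -------------------------------------

# identification: first indicator per factor has loading fixed to 1,
# factor (co)variances free; single-group latent means fixed at 0.
cfa_layout <- function(spec, G, level, q = length(spec$covariates)) {
  p <- length(spec$indicators)
  m <- length(spec$blocks)
  free_load <- sum(vapply(spec$blocks, length, 0L) - 1L)
  n_psi <- m * (m + 1L) / 2L
  lambda_sets <- if (G > 1L && level == "configural") G else 1L
  nu_sets <- if (G > 1L && level %in% c("configural", "metric")) G else 1L
  alpha_sets <- if (G > 1L && level == "scalar") G - 1L else 0L
  sizes <- c(lambda = lambda_sets * free_load,
             nu = nu_sets * p,
             theta = G * p,
             psi = G * n_psi,
             alpha = alpha_sets * m,
             gamma = if (q > 0) m * q else 0L)
  offsets <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(offsets) <- names(sizes)
  list(p = p, m = m, q = q, G = G, level = level,
       free_load = free_load, n_psi = n_psi,
       lambda_sets = lambda_sets, nu_sets = nu_sets, alpha_sets = alpha_sets,
       sizes = sizes, offsets = offsets, n_free = sum(sizes))
}

# par vector -> list of per-group matrices
cfa_build <- function(par, spec, lay) {
  p <- lay$p; m <- lay$m; q <- lay$q; G <- lay$G
  blk_len <- vapply(spec$blocks, length, 0L)
  blk_start <- cumsum(c(1L, blk_len))[seq_len(m)]
  make_lambda <- function(v) {
    L <- matrix(0, p, m, dimnames = list(spec$indicators, spec$factors))
    k <- 1L
    for (f in seq_len(m)) {
      idx <- blk_start[f]:(blk_start[f] + blk_len[f] - 1L)
      L[idx[1L], f] <- 1
      if (blk_len[f] > 1L) {
        L[idx[-1L], f] <- v[k:(k + blk_len[f] - 2L)]
        k <- k + blk_len[f] - 1L
      }
    }
    L
  }
  make_psi <- function(v) {
    P <- matrix(0, m, m)
    P[upper.tri(P, diag = TRUE)] <- v
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
    P
  }
  take <- function(name, set, size) {
    off <- lay$offsets[[name]] + (set - 1L) * size
    par[(off + 1L):(off + size)]
  }
  out <- vector("list", G)
  for (g in seq_len(G)) {
    lam_set <- if (lay$lambda_sets == G) g else 1L
    nu_set <- if (lay$nu_sets == G) g else 1L
    Lambda <- if (lay$free_load > 0) {
      make_lambda(take("lambda", lam_set, lay$free_load))
    } else make_lambda(numeric(0))
    nu <- take("nu", nu_set, p)
    theta <- take("theta", g, p)
    Psi <- make_psi(take("psi", g, lay$n_psi))
    alpha <- rep(0, m)
    if (lay$alpha_sets > 0L && g > 1L) alpha <- take("alpha", g - 1L, m)
    Gamma <- if (q > 0) matrix(take("gamma", 1L, m * q), m, q) else NULL
    out[[g]] <- list(Lambda = Lambda, nu = nu, theta = theta, Psi = Psi,
                     alpha = alpha, Gamma = Gamma)
  }
  out
}

cfa_par_names <- function(spec, lay, groups,
                          covariate_names = spec$covariates) {
  nm <- character(0)
  lab_load <- unlist(lapply(spec$blocks, function(b) {
    if (length(b) > 1L) b[-1L] else character(0)
  }), use.names = FALSE)
  fac_load <- unlist(lapply(seq_along(spec$blocks), function(f) {
    rep(spec$factors[f], max(0L, length(spec$blocks[[f]]) - 1L))
  }), use.names = FALSE)
  set_tag <- function(sets) if (sets == 1L) "" else paste0("|", groups)
  for (s in seq_len(lay$lambda_sets)) {
    tag <- if (lay$lambda_sets == 1L) "" else paste0("|", groups[s])
    nm <- c(nm, paste0(lab_load, "~", fac_load, tag))
  }
  for (s in seq_len(lay$nu_sets)) {
    tag <- if (lay$nu_sets == 1L) "" else paste0("|", groups[s])
    nm <- c(nm, paste0("nu:", spec$indicators, tag))
  }
  for (g in seq_len(lay$G)) {
    tag <- if (lay$G == 1L) "" else paste0("|", groups[g])
    nm <- c(nm, paste0("theta:", spec$indicators, tag))
  }
  psi_lab <- outer(spec$factors, spec$factors, paste, sep = "~~")
  psi_lab <- psi_lab[upper.tri(psi_lab, diag = TRUE)]
  for (g in seq_len(lay$G)) {
    tag <- if (lay$G == 1L) "" else paste0("|", groups[g])
    nm <- c(nm, paste0("psi:", psi_lab, tag))
  }
  if (lay$alpha_sets > 0L) {
    for (g in 2L:lay$G) {
      nm <- c(nm, paste0("alpha:", spec$factors, "|", groups[g]))
    }
  }
  if (lay$q > 0) {
    nm <- c(nm, paste0("gamma:", rep(spec$factors, lay$q), "~",
                       rep(covariate_names, each = lay$m)))
  }
  nm
}

# ---- internal: likelihood -------------------------------------------------

LOG2PI <- log(2 * pi)

cfa_prepare_data <- function(data, spec, group) {
  df <- as.data.frame(data)
  miss <- setdiff(c(spec$indicators, spec$covariates), names(df))
  if (length(miss)) abort(paste0("columns not found: ", paste(miss, collapse = ", ")))
  y <- as.matrix(df[spec$indicators])
  if (!is.numeric(y)) abort("indicators must be numeric")
  x <- NULL
  if (length(spec$covariates)) {
    xdf <- df[spec$covariates]
    keep_x <- complete.cases(xdf)
  } else keep_x <- TRUE
  if (is.null(group)) {
    gidx <- rep(1L, nrow(y)); groups <- "all"
  } else {
    gf <- factor(group)
    gidx <- as.integer(gf); groups <- levels(gf)
  }
  keep <- complete.cases(y) & keep_x
  y <- y[keep, , drop = FALSE]
  if (length(spec$covariates)) {
    # dummy-code categorical covariates; drop the intercept column
    x <- stats::model.matrix(~ ., data = as.data.frame(xdf)[keep, , drop = FALSE])
    x <- x[, -1, drop = FALSE]
  }
  gidx <- gidx[keep]
  n_g <- tabulate(gidx, length(groups))
  if (any(n_g <= ncol(y))) {
    abort(paste0("group too small for the model: ",
                 paste(groups[n_g <= ncol(y)], collapse = ", ")))
  }
  # sufficient statistics per group (ML covariance, divisor n); with
  # covariates the likelihood depends on the data only through the raw
  # cross-moments of y and w = (1, x), precomputed here
  stats <- lapply(seq_along(groups), function(g) {
    yg <- y[gidx == g, , drop = FALSE]
    xb <- colMeans(yg)
    S <- crossprod(sweep(yg, 2L, xb)) / nrow(yg)
    out <- list(n = nrow(yg), xbar = xb, S = S)
    if (!is.null(x)) {
      wg <- cbind(1, x[gidx == g, , drop = FALSE])
      out$Syy <- crossprod(yg)
      out$SYW <- crossprod(yg, wg)
      out$SWW <- crossprod(wg)
    }
    out
  })
  list(y = y, x = x, gidx = gidx, groups = groups, G = length(groups),
       n = nrow(y), n_g = n_g, stats = stats)
}

cfa_negll <- function(par, spec, lay, dat) {
  mats <- cfa_build(par, spec, lay)
  total <- 0
  for (g in seq_len(dat$G)) {
    mg <- mats[[g]]
    Sigma <- mg$Lambda %*% mg$Psi %*% t(mg$Lambda) + diag(mg$theta, lay$p)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e12)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    st <- dat$stats[[g]]
    base_mu <- mg$nu + as.vector(mg$Lambda %*% mg$alpha)
    if (is.null(dat$x)) {
      d <- st$xbar - base_mu
      ll <- -st$n / 2 * (lay$p * LOG2PI + logdet + sum(Sinv * st$S) +
                           drop(t(d) %*% Sinv %*% d))
    } else {
      # sum_i r_i r_i' expressed through the precomputed cross-moments,
      # with C = [nu + Lambda alpha, Lambda Gamma] and w_i = (1, x_i)
      C <- cbind(base_mu, mg$Lambda %*% mg$Gamma)
      CS <- st$SYW %*% t(C)
      M <- st$Syy - CS - t(CS) + C %*% st$SWW %*% t(C)
      ll <- -st$n / 2 * (lay$p * LOG2PI + logdet) - 0.5 * sum(Sinv * M)
    }
    total <- total + ll
  }
  -total
}

cfa_loglik_saturated <- function(dat, q) {
  ll <- 0
  for (g in seq_len(dat$G)) {
    st <- dat$stats[[g]]
    if (q == 0 || is.null(dat$x)) {
      S <- st$S
    } else {
      rows <- dat$gidx == g
      X <- cbind(1, dat$x[rows, , drop = FALSE])
      res <- stats::lm.fit(X, dat$y[rows, , drop = FALSE])$residuals
      S <- crossprod(res) / st$n
    }
    p <- ncol(S)
    ll <- ll - st$n / 2 * (p * LOG2PI + determinant(S)$modulus[1] + p)
  }
  ll
}

cfa_loglik_baseline <- function(dat) {
  ll <- 0
  for (g in seq_len(dat$G)) {
    st <- dat$stats[[g]]
    ll <- ll - st$n / 2 * sum(LOG2PI + log(diag(st$S)) + 1)
  }
  ll
}

cfa_start <- function(spec, lay, dat) {
  # pooled within-group covariance and per-group means drive the starts
  Sp <- Reduce(`+`, lapply(dat$stats, function(s) s$S * s$n)) / dat$n
  xb <- Reduce(`+`, lapply(dat$stats, function(s) s$xbar * s$n)) / dat$n
  load_start <- numeric(0)
  psi_one <- numeric(0)
  diag_idx <- NULL
  psi_diag <- numeric(lay$m)
  for (f in seq_len(lay$m)) {
    idx <- match(spec$blocks[[f]], spec$indicators)
    j0 <- idx[1L]
    psi_f <- max(0.5 * Sp[j0, j0], 1e-3)
    psi_diag[f] <- psi_f
    if (length(idx) > 1L) {
      lam <- Sp[idx[-1L], j0] / psi_f
      load_start <- c(load_start, pmin(pmax(lam, -3), 3))
    }
  }
  P <- diag(psi_diag, lay$m)
  if (lay$m > 1L) {
    for (a in 1:(lay$m - 1L)) for (b in (a + 1L):lay$m) {
      P[a, b] <- P[b, a] <- 0.3 * sqrt(psi_diag[a] * psi_diag[b])
    }
  }
  psi_one <- P[upper.tri(P, diag = TRUE)]
  theta_one <- pmax(0.5 * diag(Sp), 1e-3)
  par <- c(rep(load_start, lay$lambda_sets),
           rep(xb, lay$nu_sets),
           rep(theta_one, lay$G),
           rep(psi_one, lay$G),
           rep(0, lay$sizes[["alpha"]]),
           rep(0, lay$sizes[["gamma"]]))
  par
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Fits the mean-and-covariance structure implied by a [cfa_spec()] to
#' multivariate data under a normal likelihood, for a single group or for
#' several groups with measurement parameters constrained according to an
#' invariance `level`:
#' \describe{
#'   \item{configural}{same pattern, all measurement parameters group-specific,
#'     latent means fixed at 0 in every group;}
#'   \item{metric}{loadings equated across groups;}
#'   \item{scalar}{loadings and intercepts equated, latent means free except
#'     in the reference (first) group.}
#' }
#' Identification fixes the first loading of each factor to 1 and leaves
#' factor (co)variances free. Covariates named in the model specification
#' enter as exogenous
#' predictors of the factors (MIMIC), with coefficients shared across groups.
#' The model chi-square is the likelihood-ratio statistic against the
#' group-saturated model, `2 (LL_sat - LL_model)`.
#'
#' @param data Data frame containing indicator (and covariate) columns.
#' @param spec A [cfa_spec()].
#' @param group Optional group label per row (factor/character); `NULL` fits
#'   a single group.
#' @param level Invariance level for multi-group fits (ignored when
#'   `group = NULL`).
#' @param se Compute standard errors from the observed information
#'   (numerical Hessian); skip for speed when only the likelihood and fit
#'   indices are needed.
#' @return An object of class `cfa_fit`.
#' @export
fit_cfa <- function(data, spec, group = NULL,
                    level = c("configural", "metric", "scalar"),
                    se = TRUE) {
  level <- match.arg(level)
  dat <- cfa_prepare_data(data, spec, group)
  lay <- cfa_layout(spec, dat$G, level,
                    q = if (is.null(dat$x)) 0L else ncol(dat$x))
  start <- cfa_start(spec, lay, dat)
  negll <- function(par) cfa_negll(par, spec, lay, dat)
  opt <- nlminb(start, negll,
                control = list(iter.max = 1000, eval.max = 4000))
  # one polish pass guards against early flat-region stops
  opt2 <- nlminb(opt$par, negll,
                 control = list(iter.max = 500, eval.max = 2000))
  converged <- opt$convergence == 0 || opt2$convergence == 0
  if (opt2$objective < opt$objective) opt <- opt2
  mats <- cfa_build(opt$par, spec, lay)
  ll <- -opt$objective
  ll_sat <- cfa_loglik_saturated(dat, lay$q)
  ll_base <- cfa_loglik_baseline(dat)
  npar_sat <- dat$G * (lay$p * (1L + lay$q) + lay$p * (lay$p + 1L) / 2L)
  npar_base <- dat$G * 2L * lay$p
  chi2 <- max(0, 2 * (ll_sat - ll))
  df <- npar_sat - lay$n_free
  chi2_base <- max(0, 2 * (ll_sat - ll_base))
  df_base <- npar_sat - npar_base
  heywood <- any(vapply(mats, function(m) any(m$theta < 0), TRUE))
  if (heywood) warn("Heywood case: negative residual variance estimate")
  vc <- NULL
  if (se) {
    H <- optimHess(opt$par, negll)
    vc <- tryCatch(solve(H), error = function(e) {
      ev <- eigen(H, symmetric = TRUE)
      pos <- pmax(ev$values, max(ev$values) * 1e-10)
      ev$vectors %*% diag(1 / pos, length(pos)) %*% t(ev$vectors)
    })
  }
  fit <- structure(
    list(spec = spec, level = if (dat$G > 1L) level else "single",
         groups = dat$groups, G = dat$G, n = dat$n, n_g = dat$n_g,
         par = opt$par,
         par_names = cfa_par_names(spec, lay, dat$groups,
                                   covariate_names = colnames(dat$x)),
         vcov = vc, mats = mats, lay = lay, dat = dat,
         loglik = ll, loglik_saturated = ll_sat, loglik_baseline = ll_base,
         chi2 = chi2, df = df, chi2_baseline = chi2_base, df_baseline = df_base,
         n_free = lay$n_free,
         converged = converged, heywood = heywood),
    class = "cfa_fit"
  )
  fit
}

#' Multi-group confirmatory factor fit
#'
#' Convenience wrapper around [fit_cfa()] requiring a grouping variable.
#'
#' @inheritParams fit_cfa
#' @export
fit_multigroup <- function(data, spec, group,
                           level = c("configural", "metric", "scalar"),
                           se = TRUE) {
  if (is.null(group)) abort("group is required; use fit_cfa() for one group")
  fit_cfa(data, spec, group = group, level = match.arg(level), se = se)
}

# implied covariance / means for group g
cfa_implied <- function(fit, g) {
  m <- fit$mats[[g]]
  Sigma <- m$Lambda %*% m$Psi %*% t(m$Lambda) + diag(m$theta, fit$lay$p)
  mu <- m$nu + as.vector(m$Lambda %*% m$alpha)
  list(Sigma = Sigma, mu = mu)
}

# standardized loadings per group: lambda * sd(factor) / sd(indicator);
# factor variance includes the covariate-explained part when present
cfa_standardized <- function(fit) {
  q <- fit$lay$q
  Sx <- if (q > 0) {
    xc <- sweep(fit$dat$x, 2L, colMeans(fit$dat$x))
    crossprod(xc) / nrow(xc)
  } else NULL
  out <- vector("list", fit$G)
  for (g in seq_len(fit$G)) {
    m <- fit$mats[[g]]
    V_eta <- m$Psi
    if (q > 0) V_eta <- V_eta + m$Gamma %*% Sx %*% t(m$Gamma)
    Sigma <- m$Lambda %*% V_eta %*% t(m$Lambda) + diag(m$theta, fit$lay$p)
    sds <- sqrt(pmax(diag(Sigma), 1e-12))
    fvar <- sqrt(pmax(diag(V_eta), 1e-12))
    std <- sweep(sweep(m$Lambda, 2L, fvar, `*`), 1L, sds, `/`)
    out[[g]] <- std
  }
  names(out) <- fit$groups
  out
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("CFA fit (%s): %d group(s), n = %d, logLik = %.2f\n",
              x$level, x$G, x$n, x$loglik))
  cat(sprintf("chi-square = %.3f on %d df\n", x$chi2, x$df))
  invisible(x)
}

#' @export
tidy.cfa_fit <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else NA_real_
  out <- tibble(term = x$par_names, estimate = x$par, std.error = se)
  std <- cfa_standardized(x)
  # attach standardized loadings as extra rows
  std_rows <- imap(std, function(s, g) {
    lam <- x$mats[[match(g, x$groups)]]$Lambda
    idx <- which(lam != 0, arr.ind = TRUE)
    tibble(term = paste0("std:", rownames(s)[idx[, 1]], "~",
                         colnames(s)[idx[, 2]],
                         if (x$G > 1L) paste0("|", g) else ""),
           estimate = s[idx], std.error = NA_real_)
  }) |> list_rbind()
  bind_rows(out, std_rows)
}

#' Standardized loadings of a CFA fit
#'
#' @param fit A `cfa_fit`.
#' @param group Group name (defaults to the first group).
#' @return Named numeric vector of standardized loadings, one per indicator,
#'   taken from the factor each indicator loads on.
#' @export
standardized_loadings <- function(fit, group = fit$groups[1]) {
  std <- cfa_standardized(fit)[[group]]
  lam <- fit$mats[[match(group, fit$groups)]]$Lambda
  v <- vapply(seq_len(nrow(std)), function(j) std[j, which(lam[j, ] != 0)[1]], 0)
  setNames(v, rownames(std))
}

#' @export
glance.cfa_fit <- function(x, ...) {
  fi <- fit_indices(x)
  tibble(n = x$n, groups = x$G, level = x$level, loglik = x$loglik,
         npar = x$n_free, chisq = x$chi2, df = x$df,
         cfi = fi$cfi, tli = fi$tli, rmsea = fi$rmsea, srmr = fi$srmr,
         converged = x$converged, heywood = x$heywood)
}
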