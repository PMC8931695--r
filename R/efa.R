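#' Exploratory factor analysis with oblique rotation
#'
#' Maximum-likelihood factor extraction (via [stats::factanal()]) on the
#' sample correlation matrix, with an oblique promax rotation applied for
#' two or more factors. The eigenvalues of the sample correlation matrix are
#' reported for the Kaiser retention criterion.
#'
#' @param data Data frame or matrix of numeric indicators.
#' @param n_factors Number of factors to extract.
#' @param rotation `"oblique"` (promax; the default for >= 2 factors) or
#'   `"none"`.
#' @return An `efa_fit`: rotated `loadings` (pattern matrix), factor
#'   correlation matrix `phi`, `uniquenesses`, `eigenvalues`, `n_factors`,
#'   `n`, `converged`.
#' @export
fit_efa <- function(data, n_factors, rotation = c("oblique", "none")) {
  rotation <- match.arg(rotation)
  y <- as.matrix(as.data.frame(data)[vapply(as.data.frame(data), is.numeric,
                                            logical(1))])
  y <- y[complete.cases(y), , drop = FALSE]
  R <- cor(y)
  eig <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  fa <- tryCatch(
    factanal(covmat = R, factors = n_factors, n.obs = nrow(y),
             rotation = "none"),
    error = function(e) abort(paste0("EFA with ", n_factors,
                                     " factor(s) failed: ", conditionMessage(e)))
  )
  L <- unclass(fa$loadings)
  phi <- diag(n_factors)
  if (n_factors >= 2L && rotation == "oblique") {
    pm <- promax(L)
    L <- unclass(pm$loadings)
    Ti <- solve(pm$rotmat)
    phi <- tcrossprod(Ti)
    d <- 1 / sqrt(diag(phi))
    phi <- diag(d, n_factors) %*% phi %*% diag(d, n_factors)
  }
  structure(
    list(loadings = L, phi = phi, uniquenesses = fa$uniquenesses,
         eigenvalues = eig, n_factors = n_factors, n = nrow(y),
         converged = fa$converged %||% TRUE),
    class = "efa_fit"
  )
}

#' @export
print.efa_fit <- function(x, ...) {
  cat(sprintf("EFA: %d factor(s), n = %d\n", x$n_factors, x$n))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Evaluate exploratory structures against the discard criteria
#'
#' Fits EFAs with 1..`max_factors` factors and applies four discard
#' criteria to each candidate structure:
#' \enumerate{
#'   \item a structure extracting more factors than there are eigenvalues
#'     >= 1 in the sample correlation matrix is discarded;
#'   \item a structure containing a cross-loading indicator (absolute
#'     loading above `cross_max` on two or more factors) is discarded;
#'   \item indicators whose largest absolute loading is below `loading_min`
#'     are dropped and the structure re-estimated (repeated until stable);
#'   \item a structure with a factor holding two or fewer indicators
#'     (assigned by largest absolute loading) is discarded.
#' }
#' Among admissible structures the one with the most factors is retained
#' (the most differentiated structure the data support).
#'
#' @param data Numeric indicator data.
#' @param max_factors Largest structure explored.
#' @param loading_min Minimum primary loading (criterion iii).
#' @param cross_max Cross-loading threshold (criterion ii).
#' @return List with `verdicts` (tibble, one row per candidate), `retained`
#'   (a [cfa_spec()] for the surviving structure, or `NULL`),
#'   `retained_factors`, `dropped` (indicators removed under iii), and the
#'   final `efa` fits.
#' @export
efa_discard <- function(data, max_factors = 3, loading_min = 0.30,
                        cross_max = 0.10) {
  df <- as.data.frame(data)
  num <- df[vapply(df, is.numeric, logical(1))]
  verdicts <- list()
  efas <- list()
  specs <- list()
  dropped_all <- list()
  for (m in seq_len(max_factors)) {
    cols <- names(num)
    dropped <- character(0)
    fit <- NULL
    ok_fit <- TRUE
    reason <- NA_character_
    # criterion (iii): drop weak indicators and refit until stable
    repeat {
      if (length(cols) < m + 1L) { ok_fit <- FALSE; reason <- "too few indicators"; break }
      fit <- tryCatch(fit_efa(num[cols], m), error = function(e) e)
      if (inherits(fit, "error")) {
        ok_fit <- FALSE; reason <- conditionMessage(fit); break
      }
      prim <- apply(abs(fit$loadings), 1L, max)
      weak <- rownames(fit$loadings)[prim < loading_min]
      if (!length(weak)) break
      dropped <- c(dropped, weak)
      cols <- setdiff(cols, weak)
    }
    if (!ok_fit) {
      verdicts[[m]] <- tibble(n_factors = m, admissible = FALSE,
                              eigen_ok = NA, no_crossload = NA,
                              loadings_ok = NA, indicators_ok = NA,
                              dropped = length(dropped), note = reason)
      next
    }
    eig_ok <- sum(fit$eigenvalues >= 1) >= m
    cross <- rowSums(abs(fit$loadings) > cross_max) >= 2L
    cross_ok <- !any(cross)
    assign_f <- apply(abs(fit$loadings), 1L, which.max)
    per_factor <- tabulate(assign_f, m)
    ind_ok <- all(per_factor > 2L)
    admissible <- eig_ok && cross_ok && ind_ok
    verdicts[[m]] <- tibble(n_factors = m, admissible = admissible,
                            eigen_ok = eig_ok, no_crossload = cross_ok,
                            loadings_ok = TRUE, indicators_ok = ind_ok,
                            dropped = length(dropped), note = NA_character_)
    efas[[m]] <- fit
    dropped_all[[m]] <- dropped
    if (admissible) {
      blocks <- lapply(seq_len(m), function(f) {
        rownames(fit$loadings)[assign_f == f]
      })
      names(blocks) <- paste0("factor", seq_len(m))
      specs[[m]] <- cfa_spec(blocks)
    }
  }
  v <- bind_rows(verdicts)
  adm <- v$n_factors[v$admissible %in% TRUE]
  retained_m <- if (length(adm)) max(adm) else NA_integer_
  list(
    verdicts = v,
    retained = if (!is.na(retained_m)) specs[[retained_m]] else NULL,
    retained_factors = retained_m,
    dropped = if (!is.na(retained_m)) dropped_all[[retained_m]] else character(0),
    efa = efas
  )
}
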