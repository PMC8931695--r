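#' Linear mixed model for a regional (or behavioural) outcome
#'
#' Fits `outcome ~ group + covariates + (1 | site)` by REML (lme4) and
#' reports the omnibus group test as a type-III Wald F with Satterthwaite
#' denominator degrees of freedom (lmerTest), pairwise group contrasts
#' (emmeans, BH-adjusted), the site and residual variance components, and an
#' effect size `eta2 = SS_group / SS_total` taken from the companion OLS
#' decomposition (type-III group sum of squares over the total sum of
#' squares, with site as a fixed blocking factor). With fewer than two sites
#' the model falls back to OLS with a warning. Categorical covariates are
#' dummy-coded against their modal level.
#'
#' @param data Data frame holding all columns.
#' @param outcome,group,site Column names.
#' @param covariates Character vector of covariate column names.
#' @return An `lmm_result`: `omnibus` tibble (`F`, `df1`, `df2`, `p`,
#'   `eta2`), `pairwise` tibble (estimate, SE, df, p, BH-adjusted p),
#'   `varcomp` (site and residual variances), `model`, `ols_fallback`.
#' @export
fit_lmm <- function(data, outcome, group, covariates = character(),
                    site = "site_id") {
  df <- as.data.frame(data)
  need <- c(outcome, group, covariates, site)
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("columns not found: ", paste(miss, collapse = ", ")))
  df <- df[complete.cases(df[need]), need, drop = FALSE]
  df[[group]] <- droplevels(factor(df[[group]]))
  # dummy-code categorical covariates against the modal level
  for (cv in covariates) {
    if (!is.numeric(df[[cv]])) {
      f <- factor(df[[cv]])
      tab <- sort(table(f), decreasing = TRUE)
      df[[cv]] <- stats::relevel(f, ref = names(tab)[1])
    }
  }
  y <- df[[outcome]]
  if (var(y) == 0) {
    return(structure(list(
      omnibus = tibble(F = 0, df1 = nlevels(df[[group]]) - 1L,
                       df2 = NA_real_, p = 1, eta2 = 0),
      pairwise = tibble(), varcomp = c(site = 0, residual = 0),
      model = NULL, ols_fallback = TRUE), class = "lmm_result"))
  }
  rhs <- paste(c(group, covariates), collapse = " + ")
  n_sites <- length(unique(df[[site]]))
  use_lmm <- n_sites >= 2L
  # companion OLS decomposition for eta-squared (site as fixed blocks)
  ols_rhs <- paste(c(covariates, if (use_lmm) site, group), collapse = " + ")
  ols <- lm(as.formula(paste(outcome, "~", ols_rhs)), data = df)
  if (any(is.na(coef(ols)))) {
    abort(paste0("singular design; aliased columns: ",
                 paste(names(coef(ols))[is.na(coef(ols))], collapse = ", ")))
  }
  a3 <- car::Anova(ols, type = 3)
  ss_group <- a3[group, "Sum Sq"]
  eta2 <- ss_group / sum((y - mean(y))^2)

  if (use_lmm) {
    fml <- as.formula(paste(outcome, "~", rhs, "+ (1 |", site, ")"))
    model <- lmerTest::lmer(fml, data = df, REML = TRUE)
    an <- suppressMessages(stats::anova(model, type = 3))
    row <- an[group, ]
    omnibus <- tibble(F = row[["F value"]], df1 = row[["NumDF"]],
                      df2 = row[["DenDF"]],
                      p = row[["Pr(>F)"]], eta2 = eta2)
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- c(site = vc$vcov[vc$grp == site],
                 residual = vc$vcov[vc$grp == "Residual"])
  } else {
    warn("fewer than 2 sites: falling back to OLS")
    model <- lm(as.formula(paste(outcome, "~", rhs)), data = df)
    a3f <- car::Anova(model, type = 3)
    omnibus <- tibble(F = a3f[group, "F value"], df1 = a3f[group, "Df"],
                      df2 = stats::df.residual(model),
                      p = a3f[group, "Pr(>F)"], eta2 = eta2)
    varcomp <- c(site = 0, residual = summary(model)$sigma^2)
  }
  em <- emmeans::emmeans(model, specs = group)
  pw <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  pairwise <- tibble(contrast = pw$contrast, estimate = pw$estimate,
                     se = pw$SE, df = pw$df, p = pw$p.value,
                     p_fdr = fdr_adjust(pw$p.value))
  structure(list(omnibus = omnibus, pairwise = pairwise, varcomp = varcomp,
                 model = model, ols_fallback = !use_lmm),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  print(x$omnibus)
  invisible(x)
}

#' @export
glance.lmm_result <- function(x, ...) {
  bind_cols(x$omnibus,
            tibble(site_var = x$varcomp[["site"]],
                   residual_var = x$varcomp[["residual"]],
                   ols_fallback = x$ols_fallback))
}

#' @export
tidy.lmm_result <- function(x, ...) x$pairwise

#' Region-by-region group comparison
#'
#' Runs [fit_lmm()] for every region, adjusts the omnibus p-values across
#' regions by Benjamini-Hochberg, and reports BH-adjusted pairwise group
#' contrasts for regions significant after FDR correction.
#'
#' @param betas Data frame of region columns (plus anything else).
#' @param regions Character vector of region column names, or a [cfa_spec()]
#'   whose indicators define the scan set.
#' @param data Data frame with `group`, covariates and `site` columns,
#'   row-aligned with `betas`.
#' @param group,covariates,site Column names in `data`.
#' @param alpha FDR threshold selecting regions for pairwise follow-up.
#' @return List with `regions` (tibble: one row per region with F, dfs, raw
#'   and FDR p, eta2) and `pairwise` (tibble of follow-up contrasts).
#' @export
region_scan <- function(betas, regions, data, group = "group",
                        covariates = character(), site = "site_id",
                        alpha = 0.05) {
  if (inherits(regions, "cfa_spec")) regions <- regions$indicators
  miss <- setdiff(regions, names(betas))
  if (length(miss)) abort(paste0("regions absent from betas: ",
                                 paste(miss, collapse = ", ")))
  fits <- lapply(regions, function(r) {
    d <- as_tibble(data)
    d[[r]] <- betas[[r]]
    fit_lmm(d, outcome = r, group = group, covariates = covariates, site = site)
  })
  names(fits) <- regions
  tab <- purrr::imap(fits, function(f, r) {
    mutate(f$omnibus, region = r, .before = 1L)
  }) |> list_rbind()
  tab$p_fdr <- fdr_adjust(tab$p)
  sig <- tab$region[!is.na(tab$p_fdr) & tab$p_fdr < alpha]
  pairwise <- purrr::map(sig, function(r) {
    mutate(fits[[r]]$pairwise, region = r, .before = 1L)
  }) |> list_rbind()
  list(regions = tab, pairwise = pairwise)
}

#' Sex-by-group interaction scan across regions
#'
#' Adds sex, and sex-by-group interaction terms, to the regional model and
#' reports the omnibus interaction F per region with BH adjustment across
#' regions. Regions with an empty sex-by-group cell are skipped with a
#' warning; a constant sex column makes the interaction inestimable and is
#' flagged for all regions.
#'
#' @inheritParams region_scan
#' @param sex Column name of the (two-level) sex variable in `data`.
#' @return Tibble: one row per region with the interaction `F`, dfs, raw and
#'   FDR-adjusted p, and a `note` for skipped regions.
#' @export
sex_by_group_scan <- function(betas, regions, data, group = "group",
                              sex = "sex", covariates = character(),
                              site = "site_id") {
  if (inherits(regions, "cfa_spec")) regions <- regions$indicators
  dd <- as_tibble(data)
  dd[[group]] <- factor(dd[[group]])
  dd[[sex]] <- factor(dd[[sex]])
  rows <- lapply(regions, function(r) {
    if (nlevels(droplevels(dd[[sex]])) < 2L) {
      return(tibble(region = r, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_, note = "sex constant: interaction inestimable"))
    }
    cells <- table(dd[[group]], dd[[sex]])
    if (any(cells == 0)) {
      warn(paste0("empty sex-by-group cell: region ", r, " skipped"))
      return(tibble(region = r, F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    p = NA_real_, note = "empty cell: skipped"))
    }
    d <- dd
    d[[r]] <- betas[[r]]
    rhs <- paste(c(covariates, paste0(group, " * ", sex)), collapse = " + ")
    fml <- as.formula(paste(r, "~", rhs, "+ (1 |", site, ")"))
    m <- lmerTest::lmer(fml, data = d, REML = TRUE)
    an <- suppressMessages(stats::anova(m, type = 3))
    term <- paste0(group, ":", sex)
    tibble(region = r, F = an[term, "F value"], df1 = an[term, "NumDF"],
           df2 = an[term, "DenDF"], p = an[term, "Pr(>F)"],
           note = NA_character_)
  })
  out <- bind_rows(rows)
  out$p_fdr <- fdr_adjust(out$p)
  relocate(out, "p_fdr", .after = "p")
}
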