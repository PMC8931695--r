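#' Configuration for the symptom-item mixture generator
#'
#' Describes a finite mixture of independent Bernoulli items: `n_classes`
#' latent classes with mixing proportions `class_proportions` and a
#' class-by-item matrix of endorsement probabilities. The default emulates a
#' four-class phenotype structure over 22 binary symptom items (4 irritability
#' and 18 ADHD items): a large typically-developing class (83.3%), a high-ADHD
#' class with co-occurring irritability (6.7%), a moderate-ADHD class (7.7%),
#' and a small high-irritability class (2.4%); the default proportions are
#' exact class counts (9781, 787, 901, 279 of 11748) so they sum to one. The default endorsement
#' profiles are a synthetic calibration (high ~0.9, moderate ~0.5, low ~0.02)
#' chosen to give well-separated classes; they are not estimates from any
#' dataset.
#'
#' @param n_classes Number of latent classes.
#' @param class_proportions Mixing proportions, summing to 1.
#' @param endorse_probs `n_classes` x `n_items` matrix of endorsement
#'   probabilities, all strictly inside (0, 1) (or exactly 0/1 for degenerate
#'   test cases).
#' @param item_labels Item identifiers; the default is `irr_1..irr_4`,
#'   `adhd_1..adhd_18`.
#' @param class_labels Names for the classes.
#' @return A `phenotype_config` list.
#' @export
phenotype_config <- function(n_classes = 4,
                             class_proportions = c(9781, 787, 901, 279) / 11748,
                             endorse_probs = NULL,
                             item_labels = c(paste0("irr_", 1:4),
                                             paste0("adhd_", 1:18)),
                             class_labels = c("TD", "ADHD_IRR", "ADHD", "IRR")) {
  if (length(class_proportions) != n_classes) {
    abort("class_proportions must have length n_classes")
  }
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    abort("class_proportions must sum to 1 (tolerance 1e-12)")
  }
  if (any(class_proportions < 0)) abort("class_proportions must be non-negative")
  n_items <- length(item_labels)
  if (is.null(endorse_probs)) {
    if (n_classes != 4 || n_items != 22) {
      abort("default endorse_probs only defined for the 4-class / 22-item config")
    }
    irr <- c(TD = 0.02, ADHD_IRR = 0.50, ADHD = 0.06, IRR = 0.90)
    adhd <- c(TD = 0.02, ADHD_IRR = 0.90, ADHD = 0.50, IRR = 0.05)
    endorse_probs <- cbind(
      matrix(rep(irr, 4), 4, 4, dimnames = list(class_labels, item_labels[1:4])),
      matrix(rep(adhd, 18), 4, 18, dimnames = list(class_labels, item_labels[5:22]))
    )
  }
  endorse_probs <- as.matrix(endorse_probs)
  if (!all(dim(endorse_probs) == c(n_classes, n_items))) {
    abort("endorse_probs must be n_classes x n_items")
  }
  if (any(endorse_probs < 0 | endorse_probs > 1)) {
    abort("endorse_probs must lie in [0, 1]")
  }
  dimnames(endorse_probs) <- list(class_labels, item_labels)
  structure(
    list(n_classes = n_classes,
         class_proportions = setNames(class_proportions, class_labels),
         endorse_probs = endorse_probs,
         item_labels = item_labels,
         class_labels = class_labels),
    class = "phenotype_config"
  )
}

#' Simulate binary symptom items from a latent class mixture
#'
#' Draws a latent class for each subject from the configured mixing
#' proportions, then draws each item independently Bernoulli given the class.
#'
#' @param n Number of subjects.
#' @param config A [phenotype_config()].
#' @param seed Integer seed; the draw is bit-reproducible given the seed.
#' @return A tibble with `subject_id`, `.true_class` (the generating class,
#'   a factor) and one 0/1 column per item.
#' @export
simulate_symptoms <- function(n, config = phenotype_config(), seed = 1L) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    cls <- sample.int(config$n_classes, n, replace = TRUE,
                      prob = config$class_proportions)
    pr <- config$endorse_probs[cls, , drop = FALSE]
    y <- matrix(rbinom(length(pr), 1L, pr), nrow = n,
                dimnames = list(NULL, config$item_labels))
    tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      .true_class = factor(config$class_labels[cls], levels = config$class_labels)
    ) |>
      bind_cols(as_tibble(y))
  })
}

#' Configuration for a synthetic neural coactivation network
#'
#' Describes the measurement model used to generate region-level beta
#' weights: each region loads on exactly one latent factor with a
#' standardized loading; subjects' factor scores are shifted by their group's
#' latent mean and (optionally) by covariate effects; scan-site random
#' intercepts and region-specific residual noise are added on top. Under the
#' standardized defaults (unit factor variance, residual variance
#' `1 - loading^2`, no site/covariate effects) every indicator has unit
#' variance and the implied correlation of two same-factor indicators is the
#' product of their loadings.
#'
#' @param factor_blocks Named list, one element per factor, each a named
#'   numeric vector of standardized loadings with region names.
#' @param group_latent_means Matrix (group x factor) of latent means; the
#'   reference group row is 0.
#' @param factor_correlations Factor correlation matrix (identity default).
#' @param residual_variances Named per-region residual variances; default
#'   `1 - loading^2`.
#' @param covariate_effects Named numeric vector of linear effects of
#'   (standardized) covariates on every factor, or `NULL` for none.
#' @param site_sd SD of site random intercepts (per site and region).
#' @param n_sites Number of scan sites used when site ids are generated.
#' @return A `network_config` list.
#' @export
network_config <- function(factor_blocks,
                           group_latent_means = NULL,
                           factor_correlations = NULL,
                           residual_variances = NULL,
                           covariate_effects = NULL,
                           site_sd = 0,
                           n_sites = 21) {
  loadings <- unlist(factor_blocks)
  if (any(abs(loadings) >= 1)) abort("standardized loadings must lie in (-1, 1)")
  regions <- unlist(lapply(factor_blocks, names), use.names = FALSE)
  if (anyDuplicated(regions)) abort("region names must be unique")
  m <- length(factor_blocks)
  if (is.null(factor_correlations)) factor_correlations <- diag(m)
  factor_correlations <- as.matrix(factor_correlations)
  if (is.null(group_latent_means)) {
    group_latent_means <- matrix(0, 1, m, dimnames = list("all", names(factor_blocks)))
  }
  group_latent_means <- as.matrix(group_latent_means)
  if (ncol(group_latent_means) != m) {
    abort("group_latent_means must have one column per factor")
  }
  if (is.null(residual_variances)) {
    residual_variances <- setNames(1 - unlist(lapply(factor_blocks, function(b) b^2),
                                              use.names = FALSE), regions)
  }
  structure(
    list(factor_blocks = factor_blocks,
         regions = regions,
         group_latent_means = group_latent_means,
         factor_correlations = factor_correlations,
         residual_variances = residual_variances,
         covariate_effects = covariate_effects,
         site_sd = site_sd,
         n_sites = n_sites),
    class = "network_config"
  )
}

#' Default response-inhibition network configuration
#'
#' Single latent factor over four left-hemisphere regions with standardized
#' loadings 0.91 (inferior parietal), 0.86 (supramarginal), 0.68 (lateral
#' occipital) and 0.51 (pars orbitalis); group latent means
#' (TD, ADHD_IRR, ADHD, IRR) = (0, 0.17, -0.17, -0.56).
#'
#' @param ... Overrides passed to [network_config()].
#' @export
ri_network <- function(...) {
  blocks <- list(ri = c(L_inferior_parietal = 0.91,
                        L_supramarginal = 0.86,
                        L_lateral_occipital = 0.68,
                        L_pars_orbitalis = 0.51))
  gm <- matrix(c(0, 0.17, -0.17, -0.56), 4, 1,
               dimnames = list(c("TD", "ADHD_IRR", "ADHD", "IRR"), "ri"))
  args <- modifyList(list(factor_blocks = blocks, group_latent_means = gm),
                     list(...))
  do.call(network_config, args)
}

#' Default error-processing network configuration
#'
#' Two correlated latent factors: factor `ep1` over the bilateral lateral
#' orbitofrontal cortices and pars orbitalis (loadings 0.84, 0.93, 0.79) and
#' factor `ep2` over the bilateral superior parietal cortices and lateral
#' occipital cortex (0.93, 0.98, 0.68); inter-factor correlation 0.4; group
#' latent means (TD, ADHD_IRR, ADHD, IRR) of (0, -0.13, 0.06, 0.20) for `ep1`
#' and (0, -0.06, -0.21, -0.11) for `ep2`.
#'
#' @param ... Overrides passed to [network_config()].
#' @export
ep_network <- function(...) {
  blocks <- list(
    ep1 = c(R_lateral_orbitofrontal = 0.84,
            L_lateral_orbitofrontal = 0.93,
            L_pars_orbitalis = 0.79),
    ep2 = c(R_superior_parietal = 0.93,
            L_superior_parietal = 0.98,
            L_lateral_occipital = 0.68)
  )
  gm <- matrix(c(0, -0.13, 0.06, 0.20,
                 0, -0.06, -0.21, -0.11), 4, 2,
               dimnames = list(c("TD", "ADHD_IRR", "ADHD", "IRR"),
                               c("ep1", "ep2")))
  phi <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  args <- modifyList(list(factor_blocks = blocks, group_latent_means = gm,
                          factor_correlations = phi),
                     list(...))
  do.call(network_config, args)
}

#' Simulate region-level task-contrast beta weights
#'
#' Generates indicators from the measurement model
#' `y_ij = lambda_j * (alpha_g + gamma' x_i + zeta_i) + u_site,j + e_ij`,
#' with `zeta ~ MVN(0, Phi)` (factor correlations), site intercepts drawn per
#' site and region with SD `site_sd`, and residuals with the configured
#' per-region variances.
#'
#' @param config A [network_config()].
#' @param class_labels Character/factor vector of group labels, one per
#'   subject; every label must be a row of `config$group_latent_means`.
#' @param covariates Optional data frame holding the columns named in
#'   `config$covariate_effects`.
#' @param site_ids Optional site identifier per subject; generated uniformly
#'   over `config$n_sites` sites when `NULL` and `site_sd > 0`.
#' @param seed Integer seed.
#' @return Tibble of beta weights, one column per region.
#' @export
simulate_betas <- function(config, class_labels, covariates = NULL,
                           site_ids = NULL, seed = 1L) {
  class_labels <- as.character(class_labels)
  n <- length(class_labels)
  gm <- config$group_latent_means
  if (!all(class_labels %in% rownames(gm))) {
    abort("every class label must match a row of group_latent_means")
  }
  m <- length(config$factor_blocks)
  withr::with_seed(seed, {
    # factor scores: group shift + covariate effect + correlated noise
    z <- matrix(rnorm(n * m), n, m) %*% chol(config$factor_correlations)
    eta <- gm[class_labels, , drop = FALSE] + z
    if (!is.null(config$covariate_effects)) {
      if (is.null(covariates)) abort("covariates required by covariate_effects")
      xnames <- names(config$covariate_effects)
      if (!all(xnames %in% names(covariates))) {
        abort("covariates missing columns named in covariate_effects")
      }
      shift <- as.matrix(covariates[xnames]) %*% config$covariate_effects
      eta <- eta + matrix(shift, n, m)
    }
    if (config$site_sd > 0) {
      if (is.null(site_ids)) {
        site_ids <- sprintf("site%02d", sample.int(config$n_sites, n, TRUE))
      }
      sites <- unique(site_ids)
    }
    out <- matrix(NA_real_, n, length(config$regions),
                  dimnames = list(NULL, config$regions))
    col <- 1L
    for (f in seq_len(m)) {
      block <- config$factor_blocks[[f]]
      for (j in seq_along(block)) {
        region <- names(block)[j]
        e <- rnorm(n, 0, sqrt(config$residual_variances[[region]]))
        y <- block[[j]] * eta[, f] + e
        if (config$site_sd > 0) {
          u <- setNames(rnorm(length(sites), 0, config$site_sd), sites)
          y <- y + u[site_ids]
        }
        out[, col] <- y
        col <- col + 1L
      }
    }
    as_tibble(out)
  })
}

#' Configuration for a synthetic stop-signal session
#'
#' Defaults mirror the task design emulated throughout the package: two runs
#' of 180 trials, 30 stop trials per run (so 300 go and 60 stop trials per
#' session), a one-up/one-down stop-signal-delay staircase with 50 ms steps
#' floored at 0 ms, lognormal go reaction times and an independent-race
#' responder with a fixed true SSRT.
#'
#' @param n_runs,trials_per_run,stop_per_run Task layout.
#' @param ssd_start,ssd_step,ssd_min Staircase parameters in ms.
#' @param go_rt_meanlog,go_rt_sdlog Lognormal go-RT parameters (ms scale).
#' @param ssrt_true True stop-signal reaction time in ms.
#' @param omission_prob Probability a go trial receives no response.
#' @export
sst_config <- function(n_runs = 2, trials_per_run = 180, stop_per_run = 30,
                       ssd_start = 50, ssd_step = 50, ssd_min = 0,
                       go_rt_meanlog = log(480), go_rt_sdlog = 0.28,
                       ssrt_true = 280, omission_prob = 0.02) {
  if (stop_per_run > trials_per_run) abort("stop_per_run must be <= trials_per_run")
  if (any(c(ssd_start, ssd_step, ssrt_true) < 0) || ssd_min < 0) {
    abort("durations must be non-negative")
  }
  if (omission_prob < 0 || omission_prob > 1) abort("omission_prob must be in [0,1]")
  structure(
    list(n_runs = n_runs, trials_per_run = trials_per_run,
         stop_per_run = stop_per_run, ssd_start = ssd_start,
         ssd_step = ssd_step, ssd_min = ssd_min,
         go_rt_meanlog = go_rt_meanlog, go_rt_sdlog = go_rt_sdlog,
         ssrt_true = ssrt_true, omission_prob = omission_prob),
    class = "sst_config"
  )
}

#' Simulate one stop-signal session
#'
#' Stop trials follow a one-up/one-down staircase: the stop-signal delay
#' (SSD) increases by one step after a successful stop and decreases by one
#' step after a failed stop, floored at `ssd_min`; the staircase carries over
#' across runs. Stop-trial outcomes follow an independent horse race: the
#' subject responds iff the (latent) go RT is below `SSD + ssrt_true`.
#' Go trials are omitted (no response) with probability `omission_prob`.
#'
#' @param config An [sst_config()].
#' @param seed Integer seed (e.g. a per-subject seed).
#' @param ssrt_true Optional override of the subject's true SSRT in ms.
#' @return Tibble with columns `run`, `trial_index`, `trial_type`, `ssd_ms`,
#'   `responded`, `rt_ms`, `correct`.
#' @export
simulate_sst_session <- function(config = sst_config(), seed = 1L,
                                 ssrt_true = NULL) {
  ssrt <- ssrt_true %||% config$ssrt_true
  withr::with_seed(seed, {
    rows <- vector("list", config$n_runs)
    ssd <- config$ssd_start
    for (r in seq_len(config$n_runs)) {
      nt <- config$trials_per_run
      stop_pos <- sort(sample.int(nt, config$stop_per_run))
      type <- rep("go", nt)
      type[stop_pos] <- "stop"
      ssd_ms <- rep(NA_real_, nt)
      responded <- integer(nt)
      rt <- rep(NA_real_, nt)
      correct <- integer(nt)
      for (t in seq_len(nt)) {
        if (type[t] == "go") {
          if (runif(1) < config$omission_prob) {
            responded[t] <- 0L; correct[t] <- 0L
          } else {
            responded[t] <- 1L
            rt[t] <- rlnorm(1, config$go_rt_meanlog, config$go_rt_sdlog)
            correct[t] <- 1L
          }
        } else {
          ssd_ms[t] <- ssd
          race_rt <- rlnorm(1, config$go_rt_meanlog, config$go_rt_sdlog)
          if (race_rt < ssd + ssrt) {      # race lost: response escapes
            responded[t] <- 1L
            rt[t] <- race_rt
            correct[t] <- 0L
            ssd <- max(config$ssd_min, ssd - config$ssd_step)
          } else {                          # successful inhibition
            responded[t] <- 0L
            correct[t] <- 1L
            ssd <- ssd + config$ssd_step
          }
        }
      }
      rows[[r]] <- tibble(run = r, trial_index = seq_len(nt),
                          trial_type = type, ssd_ms = ssd_ms,
                          responded = responded, rt_ms = rt, correct = correct)
    }
    bind_rows(rows)
  })
}

#' Simulate socio-demographic covariates, sites and families
#'
#' Continuous covariates are independent standardized draws; categorical
#' covariates are drawn with fixed marginal probabilities; site ids are
#' uniform over `n_sites`; a fraction of subjects share a family id with one
#' sibling (for cluster-robust analyses).
#'
#' @param n Number of subjects.
#' @param n_sites Number of scan sites.
#' @param sibling_rate Fraction of subjects in two-member families.
#' @param seed Integer seed.
#' @export
simulate_covariates <- function(n, n_sites = 21, sibling_rate = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    fam <- seq_len(n)
    n_pairs <- floor(n * sibling_rate / 2)
    if (n_pairs > 0) {
      idx <- sample.int(n, 2 * n_pairs)
      fam[idx[seq_len(n_pairs) * 2]] <- fam[idx[seq_len(n_pairs) * 2 - 1]]
    }
    tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = rnorm(n),
      sex = sample(c("F", "M"), n, TRUE),
      race = sample(c("white", "black", "other"), n, TRUE, prob = c(.6, .2, .2)),
      ethnicity = sample(c("hisp", "nonhisp"), n, TRUE, prob = c(.2, .8)),
      caregiver_education = rnorm(n),
      caregiver_married = rbinom(n, 1L, 0.7),
      family_income = rnorm(n),
      site_id = sprintf("site%02d", sample.int(n_sites, n, TRUE)),
      family_id = sprintf("F%05d", fam)
    )
  })
}

#' Simulate a full synthetic study bundle
#'
#' Generates, for `n` subjects, the complete set of tables the analysis
#' pipeline consumes: binary symptom items from the default four-class
#' mixture, response-inhibition and error-processing beta weights generated
#' at the default network configurations from the subjects' true classes,
#' socio-demographic covariates with site and family structure, trial-level
#' stop-signal sessions, and scan-QC fields (with a small fraction of
#' subjects violating each exclusion rule).
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param site_sd SD of site intercepts added to the beta weights.
#' @param covariate_effects Optional named vector of covariate effects on the
#'   latent factors (applied to both networks).
#' @return A named list of tibbles: `symptoms`, `betas`, `covariates`,
#'   `sst_trials`, `qc`.
#' @export
simulate_study <- function(n, seed = 1L, site_sd = 0.1,
                           covariate_effects = c(age = 0.1)) {
  symptoms <- simulate_symptoms(n, seed = seed)
  covars <- simulate_covariates(n, seed = seed + 1L)
  ri_cfg <- ri_network(site_sd = site_sd, covariate_effects = covariate_effects)
  ep_cfg <- ep_network(site_sd = site_sd, covariate_effects = covariate_effects)
  cls <- as.character(symptoms$.true_class)
  ri <- simulate_betas(ri_cfg, cls, covariates = covars,
                       site_ids = covars$site_id, seed = seed + 2L)
  ep <- simulate_betas(ep_cfg, cls, covariates = covars,
                       site_ids = covars$site_id, seed = seed + 3L)
  names(ri) <- paste0("ri_", names(ri))
  names(ep) <- paste0("ep_", names(ep))
  betas <- bind_cols(tibble(subject_id = symptoms$subject_id), ri, ep)

  cfg <- sst_config()
  withr::with_seed(seed + 4L, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    ssrt_i <- pmax(120, rnorm(n, cfg$ssrt_true, 25))
    mean_fd <- abs(rnorm(n, 0.22, 0.18))
    dof <- round(rnorm(n, 700, 120))
    fs_qc <- rbinom(n, 1L, 0.98)
    perf_flag <- rbinom(n, 1L, 0.97)
  })
  trials <- purrr::map2(sub_seeds, seq_len(n), function(s, i) {
    simulate_sst_session(cfg, seed = s, ssrt_true = ssrt_i[i]) |>
      mutate(subject_id = symptoms$subject_id[i], .before = 1L)
  }) |> bind_rows()

  qc <- trials |>
    filter(.data$trial_type == "stop") |>
    group_by(.data$subject_id) |>
    summarise(
      speedy_ssd50_n = sum(.data$ssd_ms == 50 & .data$responded == 1L &
                             !is.na(.data$rt_ms) & .data$rt_ms < 50),
      prop_ssd0 = mean(.data$ssd_ms == 0),
      .groups = "drop"
    )
  qc <- tibble(subject_id = symptoms$subject_id,
               mean_fd_mm = mean_fd, dof = dof,
               fs_qc = fs_qc, perf_flag = perf_flag) |>
    left_join(qc, by = "subject_id")

  list(symptoms = symptoms, betas = betas, covariates = covars,
       sst_trials = trials, qc = qc)
}

#' Write a synthetic study bundle to CSV files
#'
#' @param bundle Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_study_csv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(symptoms = "symptoms.csv", betas = "betas.csv",
             covariates = "covariates.csv", sst_trials = "sst_trials.csv",
             qc = "qc.csv")
  out <- character(0)
  for (nm in names(paths)) {
    p <- file.path(dir, paths[[nm]])
    df <- bundle[[nm]]
    if (nm == "symptoms") df <- df[setdiff(names(df), ".true_class")]
    utils::write.csv(df, p, row.names = FALSE)
    out <- c(out, p)
  }
  invisible(out)
}
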