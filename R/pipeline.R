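#' Pipeline configuration
#'
#' Bundles the tunable choices of the end-to-end analysis. Defaults mirror
#' the package's standard workflow: enumerate 1-5 latent classes with 50
#' random starts and a 50-replicate parametric bootstrap, 5% FDR, the
#' largest class as reference, and covariate adjustment of the latent
#' factors.
#'
#' @param k_min,k_max Latent-class enumeration range (must start at 1).
#' @param lca_starts Random starts per LCA fit.
#' @param boot_B Parametric-bootstrap replicates (0 disables the PB-LRT).
#' @param boot_starts Starts inside bootstrap refits.
#' @param fdr_alpha FDR significance level.
#' @param covariates Covariate columns used in the latent and regional
#'   models.
#' @param seed Integer seed, recorded in every output.
#' @param covariate_free Also re-run the latent contrasts without
#'   covariates.
#' @param sex_interaction Run the regional sex-by-group interaction scan.
#' @param family_clustering Recompute latent-contrast SEs with
#'   family-cluster-robust covariance.
#' @export
pipeline_config <- function(k_min = 1, k_max = 5, lca_starts = 50,
                            boot_B = 50, boot_starts = 20, fdr_alpha = 0.05,
                            covariates = c("age", "sex",
                                           "caregiver_education",
                                           "family_income"),
                            seed = 1L, covariate_free = FALSE,
                            sex_interaction = FALSE,
                            family_clustering = FALSE) {
  if (fdr_alpha <= 0 || fdr_alpha >= 1) abort("fdr_alpha must be in (0, 1)")
  if (k_min != 1) abort("enumeration must start at K = 1")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate an input bundle against the expected schemas
#'
#' Checks presence, types and coding of every table the pipeline consumes:
#' symptom items must be 0/1/missing, beta weights numeric, covariate / QC /
#' trial tables must carry their required columns.
#'
#' @param bundle Named list of tibbles (`symptoms`, `betas`, `covariates`,
#'   `sst_trials`, `qc`) or a directory containing the corresponding CSVs.
#' @return Tibble of violations (`table`, `column`, `problem`); zero rows
#'   means the bundle is valid.
#' @export
validate_inputs <- function(bundle) {
  if (is.character(bundle)) bundle <- read_study_csv(bundle)
  v <- list()
  note <- function(tab, col, problem) {
    v[[length(v) + 1L]] <<- tibble(table = tab, column = col, problem = problem)
  }
  need <- list(
    symptoms = "subject_id",
    betas = "subject_id",
    covariates = c("subject_id", "site_id"),
    sst_trials = c("subject_id", "run", "trial_index", "trial_type",
                   "ssd_ms", "responded", "rt_ms"),
    qc = c("subject_id", "mean_fd_mm", "dof", "fs_qc", "perf_flag")
  )
  for (tab in names(need)) {
    if (is.null(bundle[[tab]])) { note(tab, NA, "table missing"); next }
    for (cl in need[[tab]]) {
      if (!cl %in% names(bundle[[tab]])) note(tab, cl, "column missing")
    }
  }
  if (!is.null(bundle$symptoms)) {
    items <- setdiff(names(bundle$symptoms), c("subject_id", ".true_class"))
    for (cl in items) {
      x <- bundle$symptoms[[cl]]
      bad <- which(!(x %in% c(0, 1) | is.na(x)))
      if (length(bad)) {
        note("symptoms", cl, paste0("non-binary value at row(s) ",
                                    paste(head(bad, 5), collapse = ",")))
      }
    }
  }
  if (!is.null(bundle$betas)) {
    for (cl in setdiff(names(bundle$betas), "subject_id")) {
      if (!is.numeric(bundle$betas[[cl]])) note("betas", cl, "non-numeric column")
    }
  }
  if (length(v)) bind_rows(v) else
    tibble(table = character(), column = character(), problem = character())
}

#' Read a study bundle from a directory of CSVs
#'
#' @param dir Directory holding `symptoms.csv`, `betas.csv`,
#'   `covariates.csv`, `sst_trials.csv`, `qc.csv`.
#' @export
read_study_csv <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  }
  list(symptoms = rd("symptoms.csv"), betas = rd("betas.csv"),
       covariates = rd("covariates.csv"), sst_trials = rd("sst_trials.csv"),
       qc = rd("qc.csv"))
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on an input bundle: input validation,
#' scan/behaviour QC exclusion, winsorization of beta weights, latent-class
#' enumeration and selection on the symptom items, modal classification,
#' exploratory-then-confirmatory derivation of each coactivation network,
#' the measurement-invariance ladder across classes, latent-mean contrasts,
#' region-level mixed models, and the SSRT group comparison. Any stage
#' failure aborts with the stage name and cause; stages already written to
#' `out_dir` are retained.
#'
#' @param bundle Named list of input tibbles (see [validate_inputs()]) or a
#'   directory of CSVs.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; each stage's tables are written (CSV /
#'   JSON) as they complete.
#' @param contrasts Named list mapping a contrast label to the prefix of its
#'   beta columns (default response inhibition `ri_`, error processing
#'   `ep_`).
#' @return A report list with every stage's output, the config, its hash,
#'   and the package version.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), out_dir = NULL,
                         contrasts = list(ri = "ri_", ep = "ep_")) {
  if (is.character(bundle)) bundle <- read_study_csv(bundle)
  report <- list(config = unclass(config),
                 config_hash = rlang::hash(unclass(config)),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("phenoact")))
  emit <- function(name, obj) {
    report[[name]] <<- obj
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      if (is.data.frame(obj)) {
        utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                         row.names = FALSE)
      } else {
        jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                             auto_unbox = TRUE, digits = NA, force = TRUE,
                             pretty = TRUE)
      }
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  stage("validate", {
    viol <- validate_inputs(bundle)
    if (nrow(viol)) {
      abort(paste0("schema violations:\n",
                   paste(viol$table, viol$column, viol$problem,
                         sep = ": ", collapse = "\n")))
    }
    emit("validation", tibble(status = "ok"))
  })

  qcres <- stage("qc", {
    out <- qc_filter(bundle$qc, trials = bundle$sst_trials)
    emit("qc_exclusions", out$exclusions)
    out
  })

  wins <- stage("winsorize", {
    out <- winsorize_betas(bundle$betas)
    emit("winsorization_report", out$region_report)
    out
  })

  enum <- stage("lca_enumeration", {
    e <- enumerate_lca(bundle$symptoms, k_min = config$k_min,
                       k_max = config$k_max, n_starts = config$lca_starts,
                       B = config$boot_B, boot_starts = config$boot_starts,
                       seed = config$seed)
    emit("lca_summary", e$summary)
    e
  })

  sel <- stage("lca_selection", {
    s <- select_model(enum, alpha = config$fdr_alpha)
    if (is.na(s$selected_k)) abort("no class solution passes the criteria")
    emit("lca_verdicts", s$verdicts)
    s
  })

  labels <- stage("classify", {
    fit <- enum$fits[[paste0("K", sel$selected_k)]]
    lab <- paste0("class", classify(fit))  # classes ordered by size
    emit("class_labels", tibble(subject_id = bundle$symptoms$subject_id,
                                class = lab))
    lab
  })
  report$selected_k <- sel$selected_k

  # analysis sample: QC-included subjects with betas and covariates
  keep <- bundle$betas$subject_id %in% qcres$included
  adat <- bind_cols(
    wins$data[keep, , drop = FALSE],
    bundle$covariates[match(bundle$betas$subject_id[keep],
                            bundle$covariates$subject_id),
                      setdiff(names(bundle$covariates), "subject_id")]
  )
  adat$class <- labels[match(adat$subject_id, bundle$symptoms$subject_id)]

  for (cn in names(contrasts)) {
    prefix <- contrasts[[cn]]
    regions <- grep(paste0("^", prefix), names(wins$data), value = TRUE)
    net <- stage(paste0("network_", cn), {
      ed <- efa_discard(adat[regions])
      if (is.null(ed$retained)) abort("no admissible factor structure")
      emit(paste0("efa_verdicts_", cn), ed$verdicts)
      ed
    })
    spec <- cfa_spec(net$retained$blocks, covariates = config$covariates)
    lad <- stage(paste0("invariance_", cn), {
      l <- invariance_ladder(adat, spec, group = adat$class)
      emit(paste0("ladder_", cn), l$steps)
      l
    })
    stage(paste0("contrasts_", cn), {
      if (!identical(lad$attained, "scalar")) {
        emit(paste0("contrasts_", cn),
             tibble(note = "scalar invariance not attained"))
      } else {
        fit <- lad$fits$scalar
        if (isTRUE(config$family_clustering)) {
          fam <- adat$family_id
          fit <- cluster_robust_se(fit, fam[complete.cases(
            adat[c(spec$indicators, spec$covariates)])])
        }
        emit(paste0("contrasts_", cn), compare_latent_means(fit))
        if (isTRUE(config$covariate_free)) {
          spec0 <- cfa_spec(net$retained$blocks)
          l0 <- invariance_ladder(adat, spec0, group = adat$class)
          if (identical(l0$attained, "scalar")) {
            emit(paste0("contrasts_", cn, "_covariate_free"),
                 compare_latent_means(l0$fits$scalar))
          }
        }
      }
    })
    stage(paste0("regions_", cn), {
      rs <- region_scan(adat, spec$indicators, adat, group = "class",
                        covariates = config$covariates,
                        alpha = config$fdr_alpha)
      emit(paste0("regions_", cn), rs$regions)
      if (nrow(rs$pairwise)) emit(paste0("regions_", cn, "_pairwise"),
                                  rs$pairwise)
      if (isTRUE(config$sex_interaction)) {
        emit(paste0("sex_interaction_", cn),
             sex_by_group_scan(adat, spec$indicators, adat, group = "class",
                               covariates = setdiff(config$covariates, "sex")))
      }
    })
  }

  stage("ssrt", {
    keep_tr <- bundle$sst_trials$subject_id %in% qcres$included
    ssrt <- compute_ssrt_all(bundle$sst_trials[keep_tr, , drop = FALSE])
    emit("ssrt", ssrt)
    sd2 <- left_join(ssrt, adat[c("subject_id", "class", "site_id",
                                  config$covariates)], by = "subject_id")
    sd2 <- sd2[complete.cases(sd2[c("ssrt_ms", "class")]), , drop = FALSE]
    res <- compare_ssrt_groups(sd2, outcome = "ssrt_ms", group = "class",
                               covariates = config$covariates)
    emit("ssrt_comparison", glance(res))
    emit("ssrt_pairwise", res$pairwise)
  })

  invisible(report)
}
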