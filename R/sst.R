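#' Integration-method stop-signal reaction time
#'
#' Implements the integration (nth-RT) estimator with the standard
#' behavioural adjustments: go omissions are assigned the maximum observed
#' go RT; the probability of responding given a stop signal counts premature
#' responses as failed stops; the index into the ascending adjusted go-RT
#' distribution is `n = ceiling(p_respond * N_go)`; and
#' `SSRT = nth go RT - mean SSD` (mean over all stop trials).
#'
#' @param trials Tibble of one session's trials with columns `trial_type`
#'   (`"go"`/`"stop"`), `ssd_ms`, `responded` (0/1), `rt_ms`.
#' @return Tibble (one row): `ssrt_ms`, `p_respond_signal`, `nth_go_rt`,
#'   `mean_ssd_ms`, `n_go`, `n_stop`, `n_omissions_replaced`,
#'   `n_stop_responses`, `flag` (`NA` result flagged when `p_respond = 0`).
#' @export
compute_ssrt <- function(trials) {
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  st <- trials[trials$trial_type == "stop", , drop = FALSE]
  if (nrow(go) < 1L || nrow(st) < 1L) abort("need at least one go and one stop trial")
  go_rt <- go$rt_ms
  omitted <- go$responded == 0L | is.na(go_rt)
  n_om <- sum(omitted)
  if (all(omitted)) abort("no observed go reaction times")
  max_rt <- max(go_rt[!omitted])
  go_rt[omitted] <- max_rt
  p_resp <- mean(st$responded == 1L)
  mean_ssd <- mean(st$ssd_ms)
  if (p_resp == 0) {
    return(tibble(ssrt_ms = NA_real_, p_respond_signal = 0,
                  nth_go_rt = NA_real_, mean_ssd_ms = mean_ssd,
                  n_go = nrow(go), n_stop = nrow(st),
                  n_omissions_replaced = n_om,
                  n_stop_responses = 0L, flag = "p_respond_zero"))
  }
  srt <- sort(go_rt)
  idx <- min(length(srt), ceiling(p_resp * length(srt)))
  nth <- srt[idx]
  tibble(ssrt_ms = nth - mean_ssd, p_respond_signal = p_resp,
         nth_go_rt = nth, mean_ssd_ms = mean_ssd,
         n_go = nrow(go), n_stop = nrow(st),
         n_omissions_replaced = n_om,
         n_stop_responses = sum(st$responded == 1L), flag = NA_character_)
}

#' SSRT for every subject in a trial table
#'
#' @param trials Trial table with a `subject_id` column plus the columns of
#'   [compute_ssrt()].
#' @return Tibble, one row per subject.
#' @export
compute_ssrt_all <- function(trials) {
  trials |>
    group_by(.data$subject_id) |>
    group_modify(~ compute_ssrt(.x)) |>
    ungroup()
}

#' Scan- and behaviour-based exclusion filter
#'
#' Excludes a subject when ANY of the following holds: mean framewise
#' displacement >= 0.9 mm; total degrees of freedom across runs <= 200;
#' FreeSurfer QC fail; task performance flag fail; any speedy (< 50 ms)
#' response on a stop trial with SSD = 50 ms; proportion of stop trials with
#' SSD = 0 ms >= 10%; or a missing QC field. Every exclusion lists all
#' triggering rules.
#'
#' @param qc Tibble with columns `subject_id`, `mean_fd_mm`, `dof`, `fs_qc`
#'   (1 = pass), `perf_flag` (1 = pass), `speedy_ssd50_n`, `prop_ssd0`. The
#'   last two can be derived from `trials` when supplied.
#' @param trials Optional trial table used to (re)compute the two
#'   trial-derived fields.
#' @return List with `included` (subject ids) and `exclusions` (tibble of
#'   `subject_id`, `reasons`).
#' @export
qc_filter <- function(qc, trials = NULL) {
  qc <- as_tibble(qc)
  if (!is.null(trials)) {
    derived <- trials |>
      filter(.data$trial_type == "stop") |>
      group_by(.data$subject_id) |>
      summarise(
        speedy_ssd50_n = sum(.data$ssd_ms == 50 & .data$responded == 1L &
                               !is.na(.data$rt_ms) & .data$rt_ms < 50),
        prop_ssd0 = mean(.data$ssd_ms == 0),
        .groups = "drop")
    qc <- qc |>
      select(-any_of(c("speedy_ssd50_n", "prop_ssd0"))) |>
      left_join(derived, by = "subject_id")
  }
  needed <- c("mean_fd_mm", "dof", "fs_qc", "perf_flag",
              "speedy_ssd50_n", "prop_ssd0")
  miss_cols <- setdiff(needed, names(qc))
  if (length(miss_cols)) {
    abort(paste0("qc table missing columns: ", paste(miss_cols, collapse = ", ")))
  }
  reasons <- purrr::pmap(qc[c("subject_id", needed)], function(subject_id,
      mean_fd_mm, dof, fs_qc, perf_flag, speedy_ssd50_n, prop_ssd0) {
    r <- character(0)
    vals <- c(mean_fd_mm, dof, fs_qc, perf_flag, speedy_ssd50_n, prop_ssd0)
    if (anyNA(vals)) r <- c(r, "missing")
    if (isTRUE(mean_fd_mm >= 0.9)) r <- c(r, "fd_ge_0.9mm")
    if (isTRUE(dof <= 200)) r <- c(r, "dof_le_200")
    if (isTRUE(fs_qc == 0)) r <- c(r, "freesurfer_qc_fail")
    if (isTRUE(perf_flag == 0)) r <- c(r, "performance_flag_fail")
    if (isTRUE(speedy_ssd50_n > 0)) r <- c(r, "speedy_response_at_ssd50")
    if (isTRUE(prop_ssd0 >= 0.10)) r <- c(r, "ssd0_ge_10pct")
    r
  })
  excluded <- lengths(reasons) > 0
  list(
    included = qc$subject_id[!excluded],
    exclusions = tibble(subject_id = qc$subject_id[excluded],
                        reasons = vapply(reasons[excluded],
                                         paste, "", collapse = ";"))
  )
}

#' Winsorize extreme-outlier regions
#'
#' A region (column) is flagged an extreme-outlier region when at least one
#' value lies outside mean +/- 3 SD AND the absolute adjusted Fisher-Pearson
#' moment skewness exceeds 2 — the conjunction is required. In flagged
#' columns, out-of-bound values are clipped to the mean +/- 3 SD boundary
#' computed from the ORIGINAL column (single pass, no recomputation).
#' Zero-variance columns are skipped and noted.
#'
#' @param betas Data frame; non-numeric columns (e.g. `subject_id`) pass
#'   through untouched.
#' @param sd_mult Boundary multiple of the SD (default 3).
#' @param skew_min Skewness threshold (default 2).
#' @return List with `data` (winsorized tibble), `region_report` (per
#'   region: flagged, n/percent altered, bounds), `subject_report` (percent
#'   of a subject's regional values altered).
#' @export
winsorize_betas <- function(betas, sd_mult = 3, skew_min = 2) {
  df <- as_tibble(betas)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  altered <- matrix(FALSE, nrow(df), length(num_cols),
                    dimnames = list(NULL, num_cols))
  rows <- list()
  for (cl in num_cols) {
    x <- df[[cl]]
    m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      rows[[cl]] <- tibble(region = cl, flagged = FALSE, skewness = NA_real_,
                           n_outside = 0L, n_altered = 0L, pct_altered = 0,
                           lower = NA_real_, upper = NA_real_,
                           note = "zero variance, skipped")
      next
    }
    if (sum(!is.na(x)) < 3L) abort("winsorization needs at least 3 subjects per region")
    lo <- m - sd_mult * s; hi <- m + sd_mult * s
    out <- !is.na(x) & (x < lo | x > hi)
    sk <- skewness_g1(x)
    flag <- any(out) && abs(sk) > skew_min
    n_alt <- 0L
    if (flag) {
      df[[cl]] <- pmin(pmax(x, lo), hi)
      altered[, cl] <- out
      n_alt <- sum(out)
    }
    rows[[cl]] <- tibble(region = cl, flagged = flag, skewness = sk,
                         n_outside = sum(out), n_altered = n_alt,
                         pct_altered = 100 * n_alt / sum(!is.na(x)),
                         lower = lo, upper = hi, note = NA_character_)
  }
  subj <- tibble(row = seq_len(nrow(df)),
                 pct_altered = 100 * rowMeans(altered))
  if ("subject_id" %in% names(df)) subj <- mutate(subj, subject_id = df$subject_id,
                                                 .before = 1L)
  list(data = df, region_report = bind_rows(rows), subject_report = subj)
}

#' Group comparison of SSRT with site random intercepts
#'
#' Delegates to [fit_lmm()]: a linear mixed model of SSRT on group and
#' covariates with a scan-site random intercept, with the omnibus group test
#' and pairwise contrasts.
#'
#' @param data Tibble with the SSRT outcome, group labels, covariates, site.
#' @param outcome,group,site Column names.
#' @param covariates Covariate column names.
#' @return An `lmm_result` (see [fit_lmm()]).
#' @export
compare_ssrt_groups <- function(data, outcome = "ssrt_ms", group = "group",
                                covariates = character(), site = "site_id") {
  fit_lmm(data, outcome = outcome, group = group,
          covariates = covariates, site = site)
}
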