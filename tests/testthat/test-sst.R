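mk_trials <- function(go_rt, responded_go = NULL, stop_ssd, stop_resp) {
  if (is.null(responded_go)) responded_go <- as.integer(!is.na(go_rt))
  dplyr::bind_rows(
    tibble::tibble(trial_type = "go", ssd_ms = NA_real_,
                   responded = responded_go, rt_ms = go_rt),
    tibble::tibble(trial_type = "stop", ssd_ms = stop_ssd,
                   responded = stop_resp, rt_ms = NA_real_)
  )
}

test_that("integration SSRT matches the hand-worked examples", {
  # p(respond|signal) = 0.4, mean SSD = 100 -> n = 2, nth RT = 350
  tr <- mk_trials(go_rt = c(300, 350, 400, 450, 500),
                  stop_ssd = rep(100, 5), stop_resp = c(1, 1, 0, 0, 0))
  r <- compute_ssrt(tr)
  expect_equal(r$nth_go_rt, 350)
  expect_equal(r$ssrt_ms, 250)
  expect_equal(r$p_respond_signal, 0.4)

  # every stop fails, SSD 0 -> SSRT equals the maximum go RT
  tr2 <- mk_trials(go_rt = c(320, 280, 410), stop_ssd = c(0, 0),
                   stop_resp = c(1, 1))
  r2 <- compute_ssrt(tr2)
  expect_equal(r2$ssrt_ms, 410)

  # omission replaced by the max observed go RT before indexing
  tr3 <- mk_trials(go_rt = c(300, NA, 400), responded_go = c(1, 0, 1),
                   stop_ssd = c(150, 150, 150), stop_resp = c(1, 1, 0))
  r3 <- compute_ssrt(tr3)
  expect_equal(r3$n_omissions_replaced, 1L)
  expect_equal(r3$nth_go_rt, 400)   # sorted (300, 400, 400), n = ceil(2/3*3) = 2
  expect_equal(r3$ssrt_ms, 250)
})

test_that("SSRT is invariant to trial ordering and flags p_respond = 0", {
  tr <- mk_trials(go_rt = c(300, 350, 400, 450, 500),
                  stop_ssd = c(50, 100, 150, 100, 100),
                  stop_resp = c(1, 0, 1, 0, 0))
  shuffled <- tr[withr::with_seed(1, sample(nrow(tr))), ]
  expect_equal(compute_ssrt(tr)$ssrt_ms, compute_ssrt(shuffled)$ssrt_ms)

  none <- mk_trials(go_rt = c(300, 400), stop_ssd = c(100, 100),
                    stop_resp = c(0, 0))
  r <- compute_ssrt(none)
  expect_true(is.na(r$ssrt_ms))
  expect_equal(r$flag, "p_respond_zero")
})

test_that("SSRT near the generating value on simulated sessions", {
  res <- dplyr::bind_rows(lapply(1:40, function(i) {
    compute_ssrt(simulate_sst_session(seed = 900 + i))
  }))
  expect_lt(abs(mean(res$ssrt_ms) - 280), 15)
})

test_that("QC filter applies every exclusion rule inclusively", {
  qc <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10),
    mean_fd_mm = c(0.2, 0.9, rep(0.2, 8)),        # S02: FD boundary
    dof        = c(700, 700, 200, rep(700, 7)),   # S03: dof boundary
    fs_qc      = c(1, 1, 1, 0, rep(1, 6)),        # S04: FreeSurfer fail
    perf_flag  = c(1, 1, 1, 1, 0, rep(1, 5)),     # S05: performance fail
    speedy_ssd50_n = c(0, 0, 0, 0, 0, 2, rep(0, 4)),  # S06: speedy response
    prop_ssd0  = c(rep(0, 6), 0.10, rep(0, 3))    # S07: 10% boundary
  )
  qc$dof[8] <- NA                                  # S08: missing field
  out <- qc_filter(qc)
  expect_setequal(out$included, c("S01", "S09", "S10"))
  reason_of <- function(id) out$exclusions$reasons[out$exclusions$subject_id == id]
  expect_equal(reason_of("S02"), "fd_ge_0.9mm")
  expect_equal(reason_of("S03"), "dof_le_200")
  expect_equal(reason_of("S04"), "freesurfer_qc_fail")
  expect_equal(reason_of("S05"), "performance_flag_fail")
  expect_equal(reason_of("S06"), "speedy_response_at_ssd50")
  expect_equal(reason_of("S07"), "ssd0_ge_10pct")
  expect_match(reason_of("S08"), "missing")
  # rerunning yields an identical partition
  expect_identical(out, qc_filter(qc))
})

test_that("winsorization clips only under the outlier-and-skew conjunction", {
  # hand case: 20 zeros and one 50 -> mean 50/21, clear outlier, skew >> 2
  x <- c(rep(0, 20), 50)
  m <- mean(x); s <- sd(x)
  g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
  skew <- g1 * sqrt(21 * 20) / 19
  expect_gt(skew, 2)
  expect_gt(50, m + 3 * s)
  w <- winsorize_betas(tibble::tibble(r = x))
  expect_true(w$region_report$flagged)
  expect_equal(max(w$data$r), m + 3 * s)          # clipped to original bounds
  expect_equal(w$data$r[1:20], rep(0, 20))
  expect_equal(w$region_report$n_altered, 1L)

  # symmetric outliers: skewness ~ 0, conjunction fails, untouched
  y <- c(rep(0, 20), -50, 50)
  w2 <- winsorize_betas(tibble::tibble(r = y))
  expect_false(w2$region_report$flagged)
  expect_equal(w2$data$r, y)

  # nothing outside the bounds: identity
  z <- rnorm(100)
  w3 <- winsorize_betas(tibble::tibble(r = z))
  expect_equal(w3$data$r, z)

  # zero-variance column skipped with a note
  w4 <- winsorize_betas(tibble::tibble(r = rep(1, 10)))
  expect_match(w4$region_report$note, "zero variance")
})

test_that("winsorized values stay in the original envelope with ranks kept", {
  set.seed(8)
  x <- c(rnorm(200), rexp(20, 1 / 8))   # right-skewed with outliers
  w <- winsorize_betas(tibble::tibble(r = x))
  if (w$region_report$flagged) {
    expect_true(all(w$data$r <= w$region_report$upper + 1e-12))
    expect_true(all(w$data$r >= w$region_report$lower - 1e-12))
    inside <- x > w$region_report$lower & x < w$region_report$upper
    expect_equal(rank(w$data$r[inside]), rank(x[inside]))
  }
})
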