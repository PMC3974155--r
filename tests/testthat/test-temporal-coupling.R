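# Events with 1 hit oddball (last) and 2 standards; amplitudes set by test
three_trial_events <- function() {
  trial_events(1:3, c(4, 6, 8), c("standard", "standard", "oddball"),
               c("none", "none", "hit"))
}

test_that("trial selection thresholds on the hit-trial mean", {
  ev <- three_trial_events()
  sel <- select_trials(c(10, 50, 100), ev, threshold_frac = 0.30)
  expect_identical(sel, c(FALSE, TRUE, TRUE))       # 30% of 100 = 30
  expect_identical(select_trials(c(10, 50, 100), ev, 0), rep(TRUE, 3))
  expect_identical(select_trials(c(0, 0, 0), ev), rep(FALSE, 3))
  ev_nohit <- trial_events(1:2, c(4, 6), rep("standard", 2), rep("none", 2))
  expect_error(select_trials(c(1, 2), ev_nohit), "no hit")
})

test_that("concatenated pair has shared-flank layout and flank values", {
  ev <- three_trial_events()
  end <- attr(ev, "session_end_s")
  sp <- spike_train("u", c(4.01, 4.1603, 8.05), c(0, end))
  rec <- const_recording(c(0, 0, 0), n = end * 1000)
  rec$samples[1, ] <- rnorm(ncol(rec$samples))
  pair <- build_concatenated_pair(sp, rec, ev, c(TRUE, FALSE, TRUE),
                                  rectify = FALSE)
  expect_equal(length(pair$spike_seq), 2 * 270 + 100)   # 640 for 2 trials
  expect_equal(length(pair$eeg_seq), length(pair$spike_seq))
  flank_idx <- c(1:100, 271:370, 541:640)
  expect_equal(unique(pair$spike_seq[flank_idx]), 3 / end / 1000)
  expect_equal(unique(pair$eeg_seq[flank_idx]), mean(rec$samples[1, ]))
  # spike bins: trial 1 contains spikes at +10 and +160.3 ms
  t1 <- pair$spike_seq[101:270]
  expect_equal(sum(t1), 2 + 0)  # third spike belongs to trial 3
  expect_equal(which(t1 == 1), c(11, 161))
  expect_error(build_concatenated_pair(sp, rec, ev, rep(FALSE, 3)), "empty")
})

test_that("a copied, shifted EEG yields its construction lag at r ~ 1", {
  set.seed(13)
  ev <- tiny_events(8)
  end <- attr(ev, "session_end_s")
  n <- end * 1000
  sp_t <- sort(c(runif(300, 0, end),
                 as.vector(outer(ev$onset_s, runif(8, 0.02, 0.16), `+`))))
  sp <- spike_train("u", sp_t, c(0, end))
  counts <- tabulate(floor(sp_t * 1000) + 1, nbins = n)
  x <- c(rep(0, 10), counts[1:(n - 10)])       # EEG = spikes shifted +10 ms
  rec <- const_recording(c(0, 0, 0), n = n)
  rec$samples[1, ] <- x
  pair <- build_concatenated_pair(sp, rec, ev, rectify = FALSE)
  xc <- concatenated_xcorr(pair)
  expect_equal(xc$best_lag_ms, 10)
  expect_gt(xc$max_r, 0.9)
})

test_that("correlation function equals a brute-force Pearson oracle", {
  set.seed(14)
  for (i in 1:5) {
    len <- sample(2000:8000, 1)
    pair <- structure(list(spike_seq = rpois(len, 2),
                           eeg_seq = rnorm(len),
                           trial_starts = 1, trial_len = 10, n_trials = 1),
                      class = "concat_pair")
    xc <- concatenated_xcorr(pair, lags_ms = -20:20)
    oracle <- vapply(-20:20, function(l) {
      if (l >= 0) {a <- pair$spike_seq[1:(len - l)]; b <- pair$eeg_seq[(1 + l):len]}
      else {a <- pair$spike_seq[(1 - l):len]; b <- pair$eeg_seq[1:(len + l)]}
      pearson_bruteforce(a, b)
    }, numeric(1))
    expect_equal(xc$r, oracle, tolerance = 1e-12)
  }
})

test_that("coefficient is affine-invariant and flanks carry no covariance", {
  ev <- three_trial_events()
  end <- attr(ev, "session_end_s")
  set.seed(15)
  sp <- spike_train("u", sort(runif(60, 0, end)), c(0, end))
  rec <- const_recording(c(0, 0, 0), n = end * 1000)
  rec$samples[1, ] <- rnorm(ncol(rec$samples))
  pair <- build_concatenated_pair(sp, rec, ev, rectify = FALSE)
  xc <- concatenated_xcorr(pair, -10:10)
  pair2 <- pair
  pair2$eeg_seq <- 3.7 * pair$eeg_seq - 12
  expect_equal(concatenated_xcorr(pair2, -10:10)$r, xc$r, tolerance = 1e-12)
  # constant flank segments have zero covariance with anything
  flank <- 1:100
  s <- pair$spike_seq[flank]
  expect_equal(sum((s - mean(s)) * pair$eeg_seq[flank]), 0, tolerance = 1e-12)
})

test_that("trial-order permutation null is seeded and calibrated", {
  set.seed(16)
  ev <- tiny_events(2)   # 9 trials
  end <- attr(ev, "session_end_s")
  sp <- spike_train("u", sort(runif(150, 0, end)), c(0, end))
  rec <- const_recording(c(0, 0, 0), n = end * 1000)
  rec$samples[1, ] <- rnorm(ncol(rec$samples))
  pair <- build_concatenated_pair(sp, rec, ev, rectify = FALSE)
  e1 <- xcorr_permutation(pair, -20:20, n_perm = 100, seed = 5)
  e2 <- xcorr_permutation(pair, -20:20, n_perm = 100, seed = 5)
  expect_identical(e1$hi, e2$hi)
  # max-stat variant gives a symmetric global band
  em <- xcorr_permutation(pair, -20:20, n_perm = 100, seed = 5,
                          method = "max_stat")
  expect_equal(em$lo, -em$hi)
  expect_equal(length(unique(em$hi)), 1)

  # null data: per-lag false positives near the nominal 1%
  fp <- 0; total <- 0
  for (k in 1:8) {
    rec$samples[1, ] <- rnorm(ncol(rec$samples))
    pr <- build_concatenated_pair(sp, rec, ev, rectify = FALSE)
    env <- xcorr_permutation(pr, -20:20, n_perm = 400, alpha = 0.01,
                             seed = 100 + k)
    fp <- fp + sum(env$significant); total <- total + 41
  }
  expect_lt(fp / total, 0.06)
})

test_that("perfect-copy pairs are significant near the best lag", {
  set.seed(17)
  ev <- tiny_events(6)
  end <- attr(ev, "session_end_s")
  sp_t <- sort(c(runif(250, 0, end),
                 as.vector(outer(ev$onset_s, runif(10, 0.02, 0.16), `+`))))
  sp <- spike_train("u", sp_t, c(0, end))
  n <- end * 1000
  counts <- tabulate(floor(sp_t * 1000) + 1, nbins = n)
  rec <- const_recording(c(0, 0, 0), n = n)
  rec$samples[1, ] <- c(rep(0, 5), counts[1:(n - 5)])
  pair <- build_concatenated_pair(sp, rec, ev, rectify = FALSE)
  env <- xcorr_permutation(pair, -20:20, n_perm = 200, seed = 3)
  xc <- concatenated_xcorr(pair, -20:20)
  expect_true(env$significant[which(xc$lags_ms == xc$best_lag_ms)])
  expect_true(env$significant_anywhere)
})

test_that("population summaries: averaging, delay correlations, session norm", {
  mk <- function(id, r, sig) {
    structure(list(unit_id = id, lags_ms = -2:2, r = r,
                   best_lag_ms = (-2:2)[which.max(r)], max_r = max(r),
                   significant_anywhere = sig), class = "xcorr_result")
  }
  r1 <- c(0.1, 0.2, 0.5, 0.2, 0.1)
  avg1 <- average_significant_xcorr(list(mk("a", r1, TRUE)))
  expect_equal(avg1$mean_r, r1)                       # single unit: identity
  avg2 <- average_significant_xcorr(list(mk("a", r1, TRUE),
                                         mk("b", -r1, TRUE)))
  expect_equal(avg2$mean_r, rep(0, 5))                # mirrored: zero
  expect_error(average_significant_xcorr(list(mk("a", r1, FALSE))), "no signif")

  # graded association: collinear (lag, max_r) and (lag, index) pairs
  res <- list(mk("a", c(0.90, 0.5, 0.2, 0.1, 0.0), TRUE),   # lag -2, r .90
              mk("b", c(0.10, 0.55, 0.3, 0.1, 0.0), TRUE),  # lag -1, r .55
              mk("c", c(0.00, 0.1, 0.2, 0.1, 0.0), TRUE))   # lag  0, r .20
  met <- data.frame(unit_id = c("a", "b", "c"),
                    bursting_index = c(8, 5.5, 3),
                    session_mean_hz = c(4, 4.1, 3.9))
  dc <- delay_metric_correlations(res, met)
  expect_equal(dc$r[dc$pairing == "best_lag_vs_max_r"], -1, tolerance = 1e-9)
  expect_equal(dc$r[dc$pairing == "best_lag_vs_bursting_index"], -1,
               tolerance = 1e-9)
  same <- list(mk("a", r1, TRUE), mk("b", r1, TRUE))
  expect_error(delay_metric_correlations(same, met[1:2, ]), "constant")

  expect_equal(normalize_by_session_min(0.3), 1)
  expect_equal(normalize_by_session_min(c(0.2, 0.4)), c(1, 2))
  expect_equal(normalize_by_session_min(c(0.2, 0.4, -0.1, 0.3),
                                        c(1, 1, 2, 2)),
               c(1, 2, 1, 3))
  expect_error(normalize_by_session_min(c(0, 0.4)), "zero minimum")
})

test_that("stronger-bursting units lead and couple more strongly", {
  # graded ensemble, spike-driven ERP: neuron 1 (100 Hz) earlier best lag
  # and larger max_r than neuron 10 (20 Hz)
  p <- forward_model_params(noise_sd_uv = 0)
  ev <- generate_trial_sequence(60, seed = 21)
  sp <- simulate_bf_ensemble(p, ev, seed = 22)
  rec <- render_erp(p, ev, mode = "spike_driven", spikes = sp)
  pa <- population_bursting_amplitude(sp, ev)
  sel <- select_trials(pa, ev)
  x1 <- concatenated_xcorr(build_concatenated_pair(sp[[1]], rec, ev, sel))
  x10 <- concatenated_xcorr(build_concatenated_pair(sp[[10]], rec, ev, sel))
  expect_gt(x1$max_r, x10$max_r)
  # positive lag = unit leads the EEG: the early strong burster leads, the
  # late weak one trails the population-driven ERP
  expect_gt(x1$best_lag_ms, x10$best_lag_ms)
})
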