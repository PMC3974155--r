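make_psth <- function(rate, bin_ms = 10, start = -5) {
  structure(list(bin_edges_ms = seq(start, start + bin_ms * length(rate),
                                    by = bin_ms),
                 rate_hz = rate, n_trials = 10, smoothing_sigma_ms = NULL),
            class = "psth")
}

test_that("burst peak time is the argmax with earliest tie-break", {
  rate <- rep(1, 31); rate[11] <- 9          # centers 0,10,...,300; peak 100
  expect_equal(burst_peak_time(make_psth(rate)), 100)
  rate2 <- rep(1, 31); rate2[c(11, 15)] <- 9
  expect_equal(burst_peak_time(make_psth(rate2)), 100)   # earliest of ties
  expect_error(burst_peak_time(make_psth(rep(2, 31))), "flat")
  expect_error(burst_peak_time(make_psth(rate), search_ms = c(400, 500)),
               "empty")
})

test_that("layer profile extraction averages the 60-ms window per channel", {
  ev <- tiny_events(1)
  p <- forward_model_params()
  # constant-channel recording: profile entry equals the constant
  ch <- data.frame(label = sprintf("l%02d", 1:32), role = "laminar_lfp",
                   depth_rank = 1:32)
  const <- continuous_recording(outer(1:32, rep(0.5, 30000)), 1000, ch)
  prof <- extract_layer_profile(const, ev, center_ms = 100)
  expect_equal(prof$values, (1:32) * 0.5)
  expect_equal(prof$window_ms, c(70, 130))
  expect_error(extract_layer_profile(const, ev[0, ], 100), "no trials")

  # noise-free simulated session: profile proportional to the true profile
  lfp <- render_laminar_lfp(p, ev, mode = "noise_free_intensity")
  prof2 <- extract_layer_profile(lfp, ev[ev$tone == "oddball", ],
                                 center_ms = 55)
  expect_equal(cosine_similarity(prof2$values, p$layer_profile_true), 1,
               tolerance = 1e-9)
})

test_that("cosine similarity is bounded, symmetric and scale-invariant", {
  set.seed(41)
  a <- rnorm(32)
  expect_equal(cosine_similarity(a, 3 * a), 1, tolerance = 1e-12)
  expect_equal(cosine_similarity(a, -a), -1, tolerance = 1e-12)
  b <- c(1, rep(0, 31)); d <- c(0, 1, rep(0, 30))
  expect_equal(cosine_similarity(b, d), 0)
  for (i in 1:20) {
    x <- rnorm(32); y <- rnorm(32)
    s <- cosine_similarity(x, y)
    expect_lte(abs(s), 1 + 1e-12)
    expect_equal(cosine_similarity(y, x), s, tolerance = 1e-12)
    al <- runif(1, 0.1, 10); be <- runif(1, 0.1, 10)
    expect_equal(cosine_similarity(al * x, be * y), s, tolerance = 1e-12)
  }
  expect_error(cosine_similarity(rep(0, 32), a), "zero vector")
})

test_that("dimension-permutation null flags structured similarity only", {
  set.seed(42)
  a <- default_layer_profile()
  pp <- profile_permutation_p(a, 2 * a, n_perm = 1000, seed = 9)
  expect_equal(pp$p_two_sided, 1 / 1001)
  expect_identical(pp$p_two_sided,
                   profile_permutation_p(a, 2 * a, n_perm = 1000,
                                         seed = 9)$p_two_sided)
  # independent profiles: p roughly uniform (independent data/perm seeds)
  pv <- vapply(1:150, function(i) {
    set.seed(2000 + i)
    profile_permutation_p(rnorm(32), rnorm(32), n_perm = 99,
                          seed = 700000 + i)$p_two_sided
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 1e-3)
})

test_that("peak-positive normalization", {
  v <- c(-2, 1, 4, rep(0, 29))
  nv <- normalize_profile(v)
  expect_equal(nv$values[1:3], c(-0.5, 0.25, 1))
  expect_true(nv$normalized)
  expect_equal(normalize_profile(nv)$values, nv$values)   # idempotent
  expect_error(normalize_profile(-(1:32)), "no positive")
})

test_that("oddball and standard profiles agree within one session", {
  # noise-free: similarity exactly 1; with noise: significant vs the null
  p <- forward_model_params()
  ev <- tiny_events(4)
  lfp <- render_laminar_lfp(p, ev, mode = "noise_free_intensity")
  odd <- ev[ev$tone == "oddball", ]; std <- ev[ev$tone == "standard", ]
  p_odd <- extract_layer_profile(lfp, odd, 55)
  p_std <- extract_layer_profile(lfp, std, 55)
  expect_equal(cosine_similarity(p_odd, p_std), 1, tolerance = 1e-9)

  ses <- small_session()
  ev2 <- ses$events
  pp <- profile_permutation_p(
    extract_layer_profile(ses$recording, ev2[ev2$tone == "oddball", ], 80),
    extract_layer_profile(ses$recording, ev2[ev2$tone == "standard", ], 80),
    n_perm = 500, seed = 3)
  expect_lt(pp$p_two_sided, 0.05)
})

test_that("stim similarity series normalizes, detects onset, rejects nulls", {
  p <- forward_model_params(noise_sd_uv = 0)
  ss <- simulate_stim_session(p, n_pulses = 8, latency_ms = 8,
                              early_transient_uv = 20, artifact_uv = 300)
  ref <- structure(list(values = p$layer_profile_true, window_ms = c(70, 130),
                        n_trials = 10, normalized = FALSE),
                   class = "layer_profile")
  ser <- stim_similarity_series(ss$recording, ss$stim, ref, n_perm = 400,
                                seed = 4)
  expect_equal(max(abs(ser$s_norm[abs(ser$t_ms) > 5])), 1)   # peak-normalized
  expect_equal(ser$onset_ms, 8)                              # configured latency
  # scalar projection of the reference onto itself equals its norm:
  # at the evoked peak the 32-channel vector is evoked_gain * profile/max,
  # so s = gain * ||profile|| / max(profile) before normalization
  expect_equal(ser$peak_abs,
               150 * sqrt(sum(p$layer_profile_true^2)) /
                 max(p$layer_profile_true), tolerance = 0.05)

  # orthogonal reference: never significant, no onset
  v <- numeric(32); v[1:16] <- p$layer_profile_true[17:32]
  v <- v - p$layer_profile_true * sum(v * p$layer_profile_true)
  ser0 <- stim_similarity_series(ss$recording, ss$stim, v, n_perm = 400,
                                 seed = 5)
  expect_true(is.na(ser0$onset_ms))

  # zero evoked amplitude: flat series error or never significant
  ss0 <- simulate_stim_session(p, n_pulses = 4, evoked_gain_uv = 0,
                               early_transient_uv = 0, artifact_uv = 100,
                               noise_sd_uv = 1)
  ser00 <- stim_similarity_series(ss0$recording, ss0$stim, ref, n_perm = 200,
                                  seed = 6)
  expect_true(is.na(ser00$onset_ms))
})

test_that("similarity onset requires a sustained run outside the artifact", {
  mk <- function(s, hi, t = -20:80) {
    structure(list(t_ms = t, s_norm = s, lo = -hi, hi = hi, peak_abs = 1,
                   artifact_exclusion_ms = 5, onset_ms = NA),
              class = "similarity_series")
  }
  t <- -20:80
  hi <- rep(0.2, length(t))
  s <- ifelse(t >= 8, 0.5, 0)
  expect_equal(similarity_onset(mk(s, hi)), 8)
  expect_true(is.na(similarity_onset(mk(rep(0, length(t)), hi))))
  s_art <- ifelse(t >= -2 & t <= 4, 0.9, 0)      # only inside artifact window
  expect_true(is.na(similarity_onset(mk(s_art, hi))))
  s_blip <- ifelse(t >= 10 & t < 13, 0.5, 0)     # 3 ms run < 5 ms requirement
  expect_true(is.na(similarity_onset(mk(s_blip, hi))))
})
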