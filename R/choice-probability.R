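# Windowed ROC "choice probability": non-parametric discrimination of two
# trial groups (hit vs miss, oddball vs standard) from per-trial EEG/LFP
# amplitude, with a trial-label permutation null.

#' Per-trial windowed signal amplitude
#'
#' Mean of the channel's samples in `[onset + lag, onset + lag + window)` for
#' each event.  Events whose window falls (partly) outside the recorded span
#' are excluded with a warning.
#'
#' @param rec a [continuous_recording()].
#' @param events a [trial_events()] table (or subset).
#' @param lag_s window start relative to tone onset, seconds.
#' @param window_ms window length, ms.
#' @param role,label channel selector (see [channel_samples()]).
#' @return Numeric vector of per-trial mean amplitudes (uV); names are trial
#'   ids.
#' @export
windowed_amplitude <- function(rec, events, lag_s = 0.05, window_ms = 100,
                               role = "frontal_eeg", label = NULL) {
  if (nrow(events) == 0) stop_bfc("windowed_amplitude: no events")
  x <- channel_samples(rec, role = role, label = label)
  n <- length(x)
  a <- events$onset_s + lag_s
  b <- a + ms_to_s(window_ms)
  span_hi <- rec$t0_s + n / rec$fs_hz
  ok <- a >= rec$t0_s & b <= span_hi
  if (any(!ok))
    warning(sprintf("%d trial(s) outside recorded span excluded", sum(!ok)))
  if (!any(ok)) stop_bfc("windowed_amplitude: no trial window inside span")
  out <- vapply(which(ok), function(k) {
    idx <- sample_index_range(a[k], b[k], rec$t0_s, rec$fs_hz, n)
    mean(x[idx])
  }, numeric(1))
  names(out) <- events$trial_id[ok]
  out
}

#' ROC choice probability (area under the ROC curve)
#'
#' `auc = (#{a > b} + 0.5 #{a = b}) / (|A| |B|)` over all cross pairs, with
#' midrank tie handling (Mann-Whitney equivalence).  0.5 means the two
#' distributions fully overlap; 1 (or 0) means complete non-overlap with
#' group A larger (or smaller).
#'
#' @param values_a,values_b per-trial amplitudes of the two groups; by
#'   convention A is the hit (or oddball) group, so auc > 0.5 means A more
#'   positive.
#' @return The AUC in `[0, 1]`.
#' @export
choice_probability <- function(values_a, values_b) {
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a == 0 || n_b == 0) stop_bfc("choice_probability: empty group")
  r <- rank(c(values_a, values_b))            # midranks
  (sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2) / (n_a * n_b)
}

#' Permutation significance of a choice probability
#'
#' Two-sided p-value against the null built by permuting the group labels
#' `n_perm` times: `p = (1 + #{ |null - 0.5| >= |obs - 0.5| }) / (n_perm + 1)`
#' (add-one finite-sample correction).
#'
#' @inheritParams choice_probability
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return List: `auc`, `p_two_sided`, `n_perm`.
#' @export
permutation_significance <- function(values_a, values_b, n_perm = 1000,
                                     seed = 1) {
  obs <- choice_probability(values_a, values_b)
  n_a <- length(values_a)
  pool <- c(values_a, values_b)
  set.seed(seed)
  null_dev <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), n_a)
    abs(choice_probability(pool[idx], pool[-idx]) - 0.5)
  }, numeric(1))
  p <- (1 + sum(null_dev >= abs(obs - 0.5) - 1e-12)) / (n_perm + 1)
  list(auc = obs, p_two_sided = p, n_perm = n_perm)
}

#' Choice-probability series over peri-stimulus lags
#'
#' Applies [choice_probability()] + [permutation_significance()] to the
#' window-averaged signal at each lag of a grid (default `[-0.2, 0.4]` s in
#' 10 ms steps, 100 ms windows, left-aligned on the lag).
#'
#' @inheritParams windowed_amplitude
#' @param events_a,events_b the two trial groups (e.g. hits and misses).
#' @param lags_s lag grid, seconds.
#' @param n_perm,alpha,seed permutation-null settings; `n_perm = 0` skips
#'   significance (p and significant are `NA`).
#' @return `data.frame`: `lag_s`, `auc`, `p_two_sided`, `significant`.
#' @export
choice_probability_series <- function(rec, events_a, events_b,
                                      lags_s = seq(-0.2, 0.4, by = 0.01),
                                      window_ms = 100, n_perm = 1000,
                                      alpha = 0.01, seed = 1,
                                      role = "frontal_eeg", label = NULL) {
  rows <- lapply(seq_along(lags_s), function(k) {
    lag <- lags_s[k]
    va <- windowed_amplitude(rec, events_a, lag, window_ms, role, label)
    vb <- windowed_amplitude(rec, events_b, lag, window_ms, role, label)
    if (n_perm > 0) {
      ps <- permutation_significance(va, vb, n_perm,
                                     seed = derive_seed(seed, paste0("cp", k)))
      data.frame(lag_s = lag, auc = ps$auc, p_two_sided = ps$p_two_sided,
                 significant = ps$p_two_sided < alpha)
    } else {
      data.frame(lag_s = lag, auc = choice_probability(va, vb),
                 p_two_sided = NA_real_, significant = NA)
    }
  })
  do.call(rbind, rows)
}
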