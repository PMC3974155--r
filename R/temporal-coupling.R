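# Millisecond-scale spike-EEG cross-correlation on concatenated, flanked
# per-trial windows, with a trial-order permutation null, and the population
# lead/lag summaries.

#' Select high-bursting trials
#'
#' Keeps trials (oddball and standard) whose population bursting amplitude
#' exceeds `threshold_frac` of the average hit-trial amplitude.
#'
#' @param pop_amplitude per-trial population bursting amplitude, in trial
#'   order of `events`.
#' @param events [trial_events()] table.
#' @param threshold_frac fraction of the hit-trial mean (default 0.30).
#' @return Logical vector over trials.
#' @export
select_trials <- function(pop_amplitude, events, threshold_frac = 0.30) {
  hit <- events$tone == "oddball" & events$outcome == "hit"
  if (!any(hit)) stop_bfc("select_trials: no hit trials")
  pop_amplitude > threshold_frac * mean(pop_amplitude[hit])
}

# 2 kHz -> 1 kHz: mean of each consecutive sample pair, then decimate.
downsample_to_1khz <- function(x, fs) {
  if (fs == 1000) return(x)
  if (fs != 2000) stop_bfc("unsupported sampling rate %g", fs)
  n2 <- floor(length(x) / 2) * 2
  colMeans(matrix(x[seq_len(n2)], nrow = 2))
}

#' Build the concatenated spike/EEG sequence pair
#'
#' For each selected trial, the unit's spike counts in 1-ms bins and the
#' 1-kHz EEG samples over the `[0, 170)` ms post-onset window are cut out;
#' trials are concatenated with a shared 100-ms constant flank between (and
#' around) them — the spike flank is the unit's whole-session mean rate in
#' counts per 1-ms bin, the EEG flank the channel mean — giving two aligned
#' sequences of length `n_trials * 270 + 100`.  By default the EEG is first
#' polarity-rectified (multiplied by the sign of its session-average evoked
#' deflection) so the coupling peak is a positive correlation.
#'
#' @param spikes a [spike_train()].
#' @param rec a [continuous_recording()]; 2 kHz signals are downsampled to
#'   1 kHz first.
#' @param events [trial_events()] table.
#' @param selected logical trial selection from [select_trials()] (default:
#'   all trials).
#' @param window_ms per-trial analysis window, ms after onset.
#' @param flank_ms flank segment length, ms.
#' @param rectify polarity-rectify the EEG (see [trial_pairs()]).
#' @param role,label channel selector.
#' @return List of class `"concat_pair"`: `spike_seq`, `eeg_seq`,
#'   `trial_starts` (start index of each trial block), `trial_len`,
#'   `n_trials`.
#' @export
build_concatenated_pair <- function(spikes, rec, events, selected = NULL,
                                    window_ms = c(0, 170), flank_ms = 100,
                                    rectify = TRUE, role = "frontal_eeg",
                                    label = NULL) {
  selected <- selected %||% rep(TRUE, nrow(events))
  ev <- events[selected, , drop = FALSE]
  if (nrow(ev) == 0) stop_bfc("build_concatenated_pair: empty trial selection")
  x <- downsample_to_1khz(channel_samples(rec, role = role, label = label),
                          rec$fs_hz)
  if (rectify) {
    pol <- evoked_polarity(rec, events, role = role, label = label)
    x <- pol * x
  }
  trial_len <- diff(window_ms)
  spike_flank <- length(spikes$spikes_s) / diff(spikes$span_s) / 1000
  eeg_flank <- mean(x)
  n_tr <- nrow(ev)
  total <- n_tr * (trial_len + flank_ms) + flank_ms
  spike_seq <- rep(spike_flank, total)
  eeg_seq <- rep(eeg_flank, total)
  starts <- flank_ms + (seq_len(n_tr) - 1) * (trial_len + flank_ms) + 1
  for (k in seq_len(n_tr)) {
    on <- ev$onset_s[k]
    # 1-ms spike bins over [onset + w0, onset + w1); the 1e-6 ms guard keeps
    # spikes lying exactly on a bin edge in their half-open bin despite
    # floating-point subtraction noise
    rel <- floor((spikes$spikes_s - on) * 1000 + 1e-6)
    rel <- rel[rel >= window_ms[1] & rel < window_ms[2]]
    cnt <- tabulate(rel - window_ms[1] + 1L, nbins = trial_len)
    i0 <- round((on - rec$t0_s) * 1000) + window_ms[1] + 1
    seg <- x[i0:(i0 + trial_len - 1)]
    idx <- starts[k]:(starts[k] + trial_len - 1)
    spike_seq[idx] <- cnt
    eeg_seq[idx] <- seg
  }
  structure(list(spike_seq = spike_seq, eeg_seq = eeg_seq,
                 trial_starts = starts, trial_len = trial_len,
                 n_trials = n_tr),
            class = "concat_pair")
}

# Pearson r of x against y shifted by `lag` samples, over the overlap.
# lag > 0 compares x[t] with y[t + lag]: a positive best lag means the spike
# sequence leads the EEG.
shifted_cor <- function(x, y, lag) {
  n <- length(x)
  if (lag >= 0) stats::cor(x[seq_len(n - lag)], y[seq_len(n - lag) + lag])
  else stats::cor(x[seq_len(n + lag) - lag], y[seq_len(n + lag)])
}

# Pearson r at every lag from precomputed sliding dot products, using prefix
# sums for the per-overlap means and variances.  `dots[k]` must equal
# sum_i x[i] * y[i + lags[k]] over the overlap.
r_from_dots <- function(dots, x, y, lags) {
  n <- length(x)
  cx <- cumsum(x); cxx <- cumsum(x * x)
  cy <- cumsum(y); cyy <- cumsum(y * y)
  r <- numeric(length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]; m <- n - abs(l)
    if (l >= 0) {
      sx <- cx[m]; sxx <- cxx[m]
      sy <- cy[n] - if (l) cy[l] else 0
      syy <- cyy[n] - if (l) cyy[l] else 0
    } else {
      sx <- cx[n] - cx[-l]; sxx <- cxx[n] - cxx[-l]
      sy <- cy[m]; syy <- cyy[m]
    }
    r[k] <- (dots[k] - sx * sy / m) /
      sqrt((sxx - sx^2 / m) * (syy - sy^2 / m))
  }
  r
}

# Exact sliding dots (one vectorized product per lag).
lag_dots_exact <- function(x, y, lags) {
  n <- length(x)
  vapply(lags, function(l) {
    if (l >= 0) sum(x[seq_len(n - l)] * y[seq_len(n - l) + l])
    else sum(x[seq_len(n + l) - l] * y[seq_len(n + l)])
  }, numeric(1))
}

# All sliding dots at once via padded FFT (used inside the permutation loop,
# where ~1e-10 accuracy is irrelevant).  Zero padding to a 2-3-5-smooth
# length beyond n + max|lag| makes the circular correlation equal the linear
# one at the requested lags: s[k] = sum_i x[i] y[i + k].
lag_dots_fft <- function(x, y, lags) {
  n <- length(x)
  pad <- stats::nextn(n + max(abs(lags)) + 1, c(2, 3, 5))
  xp <- c(x, numeric(pad - n)); yp <- c(y, numeric(pad - n))
  s <- Re(stats::fft(Conj(stats::fft(xp)) * stats::fft(yp),
                     inverse = TRUE)) / pad
  s[ifelse(lags >= 0, lags + 1, pad + lags + 1)]
}

#' Cross-correlation of a concatenated pair over millisecond lags
#'
#' Pearson correlation between the spike and EEG sequences at each integer
#' lag in `[-50, 50]` ms.  Positive `best_lag_ms` means the unit's spiking
#' leads the (rectified) EEG by that many milliseconds.
#'
#' @param pair a [build_concatenated_pair()] result.
#' @param lags_ms integer lag grid.
#' @return List of class `"xcorr_result"`: `lags_ms`, `r`, `best_lag_ms`,
#'   `max_r`.
#' @export
concatenated_xcorr <- function(pair, lags_ms = -50:50) {
  if (stats::sd(pair$spike_seq) == 0 || stats::sd(pair$eeg_seq) == 0)
    stop_bfc("concatenated_xcorr: constant sequence")
  r <- r_from_dots(lag_dots_exact(pair$spike_seq, pair$eeg_seq, lags_ms),
                   pair$spike_seq, pair$eeg_seq, lags_ms)
  best <- which.max(r)
  structure(list(lags_ms = lags_ms, r = r, best_lag_ms = lags_ms[best],
                 max_r = r[best]),
            class = "xcorr_result")
}

# Reassemble the EEG sequence with its per-trial blocks in permuted order.
permute_eeg_trials <- function(pair, perm) {
  out <- pair$eeg_seq
  for (k in seq_along(perm)) {
    src <- pair$trial_starts[perm[k]]:(pair$trial_starts[perm[k]] + pair$trial_len - 1)
    dst <- pair$trial_starts[k]:(pair$trial_starts[k] + pair$trial_len - 1)
    out[dst] <- pair$eeg_seq[src]
  }
  out
}

#' Trial-order permutation null for the concatenated cross-correlation
#'
#' The null is built by permuting the order of the EEG trial blocks (flanks
#' fixed) `n_perm` times and recomputing the correlation function.  The
#' significance envelope is, per lag, the two-sided `alpha` quantile band of
#' the null correlations (`method = "per_lag"`), or a global band from the
#' null distribution of the maximum |r| across lags (`method = "max_stat"`).
#'
#' @inheritParams concatenated_xcorr
#' @param n_perm number of trial-order permutations.
#' @param alpha two-sided significance level.
#' @param seed RNG seed.
#' @param method `"per_lag"` (default) or `"max_stat"`.
#' @return List: `lo`, `hi` (per-lag envelope), `significant` (per lag),
#'   `significant_anywhere`, `method`, `n_perm`.
#' @export
xcorr_permutation <- function(pair, lags_ms = -50:50, n_perm = 1000,
                              alpha = 0.01, seed = 1, method = "per_lag") {
  obs <- concatenated_xcorr(pair, lags_ms)
  set.seed(seed)
  null_r <- matrix(NA_real_, nrow = n_perm, ncol = length(lags_ms))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(pair$n_trials)
    eeg_p <- permute_eeg_trials(pair, perm)
    null_r[b, ] <- r_from_dots(lag_dots_fft(pair$spike_seq, eeg_p, lags_ms),
                               pair$spike_seq, eeg_p, lags_ms)
  }
  if (method == "per_lag") {
    lo <- apply(null_r, 2, stats::quantile, probs = alpha / 2)
    hi <- apply(null_r, 2, stats::quantile, probs = 1 - alpha / 2)
  } else if (method == "max_stat") {
    m <- apply(abs(null_r), 1, max)
    thr <- stats::quantile(m, 1 - alpha)
    lo <- rep(-thr, length(lags_ms)); hi <- rep(thr, length(lags_ms))
  } else stop_bfc("unknown envelope method '%s'", method)
  sig <- obs$r < lo | obs$r > hi
  list(lo = unname(lo), hi = unname(hi), significant = sig,
       significant_anywhere = any(sig), method = method, n_perm = n_perm)
}

#' Unit-level cross-correlation analysis
#'
#' Convenience wrapper: trial selection, pair construction, correlation
#' function and permutation envelope for one unit.
#'
#' @inheritParams build_concatenated_pair
#' @param pop_amplitude per-trial population bursting amplitude.
#' @param threshold_frac trial-selection threshold (see [select_trials()]).
#' @param n_perm,alpha,seed,method see [xcorr_permutation()]; `n_perm = 0`
#'   skips the envelope.
#' @return `xcorr_result` with envelope fields merged in when computed.
#' @export
unit_xcorr <- function(spikes, rec, events, pop_amplitude,
                       threshold_frac = 0.30, lags_ms = -50:50,
                       n_perm = 1000, alpha = 0.01, seed = 1,
                       method = "per_lag", role = "frontal_eeg",
                       label = NULL) {
  sel <- select_trials(pop_amplitude, events, threshold_frac)
  pair <- build_concatenated_pair(spikes, rec, events, sel,
                                  role = role, label = label)
  res <- concatenated_xcorr(pair, lags_ms)
  res$unit_id <- spikes$unit_id
  res$n_trials <- pair$n_trials
  if (n_perm > 0) {
    env <- xcorr_permutation(pair, lags_ms, n_perm, alpha, seed, method)
    res[names(env)] <- env
  }
  res
}

#' Average correlation function over significant units
#'
#' @param results list of `xcorr_result` with `significant_anywhere` set.
#' @return List: `lags_ms`, `mean_r`, `n_units` (significant units only).
#' @export
average_significant_xcorr <- function(results) {
  sig <- Filter(function(r) isTRUE(r$significant_anywhere), results)
  if (!length(sig)) stop_bfc("no significant correlation functions to average")
  list(lags_ms = sig[[1]]$lags_ms,
       mean_r = rowMeans(vapply(sig, `[[`, numeric(length(sig[[1]]$r)), "r")),
       n_units = length(sig))
}

#' Across-unit correlations of the best lag with coupling and bursting
#'
#' Pearson correlations, across units, of the best (lead) lag against the
#' maximum correlation coefficient, the bursting index, and the
#' session-mean (baseline) firing rate.
#'
#' @param results list of `xcorr_result`.
#' @param metrics [burst_metrics()] table for the same units.
#' @return `data.frame`: `pairing`, `r`, `p`, `n`.
#' @export
delay_metric_correlations <- function(results, metrics) {
  tab <- data.frame(
    unit_id = vapply(results, `[[`, character(1), "unit_id"),
    best_lag_ms = vapply(results, `[[`, numeric(1), "best_lag_ms"),
    max_r = vapply(results, `[[`, numeric(1), "max_r"))
  tab <- merge(tab, metrics, by = "unit_id")
  one <- function(nm, y) {
    if (stats::var(tab$best_lag_ms) == 0 || stats::var(y) == 0)
      stop_bfc("delay correlation undefined: constant values (%s)", nm)
    ct <- stats::cor.test(tab$best_lag_ms, y)
    data.frame(pairing = nm, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(tab))
  }
  rbind(one("best_lag_vs_max_r", tab$max_r),
        one("best_lag_vs_bursting_index", tab$bursting_index),
        one("best_lag_vs_baseline_rate", tab$session_mean_hz))
}

#' Normalize coupling magnitudes by the session minimum
#'
#' `|max_r|` of each unit divided by the smallest `|max_r|` among that
#' session's units, so the least-correlated unit maps to 1.
#'
#' @param max_r per-unit maximum correlation coefficients.
#' @param session session id per unit (single session if omitted).
#' @return Numeric vector of normalized magnitudes.
#' @export
normalize_by_session_min <- function(max_r, session = rep(1L, length(max_r))) {
  out <- numeric(length(max_r))
  for (s in unique(session)) {
    i <- session == s
    m <- min(abs(max_r[i]))
    if (m == 0) stop_bfc("session %s: zero minimum |max_r|", s)
    out[i] <- abs(max_r[i]) / m
  }
  out
}
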