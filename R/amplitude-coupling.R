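# Single-trial amplitude coupling between per-unit spike counts and EEG/LFP
# amplitude, plus the quintile linear-scaling summary.

# Sign of the session-average evoked deflection of a channel in the burst
# window: used to rectify signal polarity so that "stronger bursting <->
# stronger (deeper) evoked response" is a positive relationship even for the
# negative-going frontal ERP.
evoked_polarity <- function(rec, events, window_ms = c(50, 200),
                            role = "frontal_eeg", label = NULL) {
  amps <- windowed_amplitude(rec, events, ms_to_s(window_ms[1]),
                             diff(window_ms), role, label)
  s <- sign(mean(amps))
  if (s == 0) 1 else s
}

#' Per-trial (spike count, signal amplitude) pairs
#'
#' For every oddball and standard tone: the unit's spike count in the
#' `[50, 200)` ms window and the polarity-rectified window-mean signal
#' amplitude (window mean times the sign of the session-average evoked
#' deflection, so a deeper negative ERP counts as a larger amplitude).
#'
#' @param spikes a [spike_train()].
#' @param rec a [continuous_recording()].
#' @param events full [trial_events()] table; all oddball + standard tones
#'   are used (>= 3 required).
#' @param window_ms counting/averaging window, ms after onset, half-open.
#' @param rectify multiply the signal by its evoked-deflection sign
#'   (default); `FALSE` keeps the raw signed mean.
#' @param role,label channel selector.
#' @return `data.frame`: `trial_id`, `spike_count`, `amplitude_uv`.
#' @export
trial_pairs <- function(spikes, rec, events, window_ms = c(50, 200),
                        rectify = TRUE, role = "frontal_eeg", label = NULL) {
  if (nrow(events) < 3) stop_bfc("trial_pairs needs >= 3 trials")
  w <- ms_to_s(window_ms)
  counts <- vapply(events$onset_s, function(on)
    count_in_window(spikes$spikes_s, on + w[1], on + w[2]), numeric(1))
  amps <- windowed_amplitude(rec, events, w[1], diff(window_ms), role, label)
  pol <- if (rectify) evoked_polarity(rec, events, window_ms, role, label) else 1
  data.frame(trial_id = events$trial_id, spike_count = counts,
             amplitude_uv = pol * as.numeric(amps))
}

#' Pearson amplitude correlation for one unit
#'
#' @param pairs output of [trial_pairs()].
#' @param sig_level significance threshold on the two-sided p-value.
#' @return List: `r`, `p`, `significant`, `n_trials`.
#' @export
amplitude_correlation <- function(pairs, sig_level = 0.001) {
  if (stats::var(pairs$spike_count) == 0 || stats::var(pairs$amplitude_uv) == 0)
    stop_bfc("amplitude_correlation undefined: zero variance")
  ct <- stats::cor.test(pairs$spike_count, pairs$amplitude_uv,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value < sig_level, n_trials = nrow(pairs))
}

# Quintile labels 1..5 by ascending x, stable in input order, bin sizes
# differing by at most one (larger bins first).
quintile_bins <- function(x, k = 5) {
  n <- length(x)
  ord <- order(x)                      # stable: ties keep input order
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  lab <- integer(n)
  lab[ord] <- rep(seq_len(k), sizes)
  lab
}

#' Quintile linear-scaling curve
#'
#' Trials are binned into five quintiles of the per-trial population bursting
#' amplitude; per quintile, the mean unit measure and mean signal measure are
#' each expressed as a percentage of their hit-trial averages (hit average =
#' 100%).
#'
#' @param pop_amplitude per-trial population bursting amplitude (Hz), in
#'   trial order of `events`.
#' @param pairs per-unit [trial_pairs()] for the same trials.
#' @param events [trial_events()] table (identifies the hit trials).
#' @return `data.frame`: `quintile`, `n_trials`, `bf_pct`, `signal_pct`.
#' @export
quintile_scaling <- function(pop_amplitude, pairs, events) {
  n <- nrow(events)
  if (n < 5) stop_bfc("quintile_scaling needs >= 5 trials")
  stopifnot(length(pop_amplitude) == n, nrow(pairs) == n)
  hit <- events$tone == "oddball" & events$outcome == "hit"
  hit_bf <- mean(pairs$spike_count[hit])
  hit_sig <- mean(pairs$amplitude_uv[hit])
  if (!any(hit) || hit_bf == 0 || hit_sig == 0)
    stop_bfc("quintile_scaling: zero hit-trial average")
  q <- quintile_bins(pop_amplitude)
  do.call(rbind, lapply(1:5, function(k) {
    sel <- q == k
    data.frame(quintile = k, n_trials = sum(sel),
               bf_pct = 100 * mean(pairs$spike_count[sel]) / hit_bf,
               signal_pct = 100 * mean(pairs$amplitude_uv[sel]) / hit_sig)
  }))
}
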