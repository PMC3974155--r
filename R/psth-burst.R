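# Peri-stimulus rate estimation, bursting-index classification and the
# per-trial population bursting amplitude.

#' Peri-stimulus time histogram
#'
#' Spike counts around each event onset, converted to rate:
#' `count / (n_trials * bin width)`, with optional Gaussian smoothing
#' (normalized kernel; area preserved on interior bins).
#'
#' @param spikes a [spike_train()].
#' @param events a [trial_events()] table (or subset) to align on.
#' @param window_ms length-2 peri-stimulus window in ms, half-open.
#' @param bin_ms bin width in ms.
#' @param smoothing_sigma_ms optional Gaussian smoothing sigma in ms.
#' @return List of class `"psth"`: `bin_edges_ms`, `rate_hz`, `n_trials`,
#'   `smoothing_sigma_ms`.
#' @export
compute_psth <- function(spikes, events, window_ms = c(-200, 400),
                         bin_ms = 10, smoothing_sigma_ms = NULL) {
  if (bin_ms <= 0) stop_bfc("bin_ms must be positive")
  if (nrow(events) == 0) stop_bfc("compute_psth: no events")
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  counts <- numeric(length(edges) - 1)
  sp <- spikes$spikes_s
  for (on in events$onset_s) {
    lo <- findInterval(on + ms_to_s(window_ms[1]), sp, left.open = TRUE) + 1
    hi <- findInterval(on + ms_to_s(window_ms[2]), sp, left.open = TRUE)
    if (hi < lo) next
    rel_ms <- (sp[lo:hi] - on) * 1000
    rel_ms <- rel_ms[rel_ms >= window_ms[1] & rel_ms < window_ms[2]]
    if (length(rel_ms))
      counts <- counts + tabulate(findInterval(rel_ms, edges),
                                  nbins = length(counts))
  }
  rate <- counts / (nrow(events) * ms_to_s(bin_ms))
  if (!is.null(smoothing_sigma_ms) && smoothing_sigma_ms > 0)
    rate <- smooth_same(rate, gaussian_kernel(smoothing_sigma_ms / bin_ms))
  structure(list(bin_edges_ms = edges, rate_hz = rate,
                 n_trials = nrow(events),
                 smoothing_sigma_ms = smoothing_sigma_ms),
            class = "psth")
}

#' Bursting index of one unit
#'
#' Ratio of the unit's mean firing rate in the `[50, 200)` ms window after
#' hit-trial tone onsets to its mean rate over the entire session.  Units
#' with index at or above the cutoff (default 2.5) are classified as
#' bursting neurons.
#'
#' @param spikes a [spike_train()].
#' @param events full [trial_events()] table (hit trials are selected here).
#' @param window_ms burst window, ms after tone onset, half-open.
#' @param cutoff classification cutoff on the index.
#' @return One-row `data.frame`: `unit_id`, `window_rate_hz`,
#'   `session_mean_hz`, `bursting_index`, `is_bursting`.
#' @export
bursting_index <- function(spikes, events, window_ms = c(50, 200),
                           cutoff = 2.5) {
  hits <- events[events$tone == "oddball" & events$outcome == "hit", ]
  if (nrow(hits) == 0) stop_bfc("bursting_index: no hit trials")
  w <- ms_to_s(window_ms)
  counts <- vapply(hits$onset_s, function(on)
    count_in_window(spikes$spikes_s, on + w[1], on + w[2]), numeric(1))
  window_rate <- mean(counts) / diff(w)
  session_mean <- length(spikes$spikes_s) / diff(spikes$span_s)
  if (session_mean == 0)
    stop_bfc("bursting_index undefined for silent unit %s", spikes$unit_id)
  idx <- window_rate / session_mean
  data.frame(unit_id = spikes$unit_id, window_rate_hz = window_rate,
             session_mean_hz = session_mean, bursting_index = idx,
             is_bursting = idx >= cutoff, stringsAsFactors = FALSE)
}

#' @rdname bursting_index
#' @param units list of [spike_train()].
#' @return `burst_metrics()`: one row per unit.
#' @export
burst_metrics <- function(units, events, window_ms = c(50, 200),
                          cutoff = 2.5) {
  do.call(rbind, lapply(units, bursting_index, events = events,
                        window_ms = window_ms, cutoff = cutoff))
}

#' Per-trial population bursting amplitude
#'
#' For every trial (oddball and standard), the mean across the supplied
#' bursting units of that unit's firing rate in the `[50, 200)` ms window
#' after tone onset.
#'
#' @param units list of [spike_train()] classified as bursting.
#' @param events [trial_events()] table.
#' @param window_ms burst window in ms, half-open.
#' @return Numeric vector, one amplitude (Hz) per trial, in trial order.
#' @export
population_bursting_amplitude <- function(units, events,
                                          window_ms = c(50, 200)) {
  if (!length(units)) stop_bfc("population amplitude needs >= 1 unit")
  w <- ms_to_s(window_ms)
  rates <- vapply(units, function(st)
    vapply(events$onset_s, function(on)
      count_in_window(st$spikes_s, on + w[1], on + w[2]), numeric(1)) / diff(w),
    numeric(nrow(events)))
  rowMeans(matrix(rates, nrow = nrow(events)))
}
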