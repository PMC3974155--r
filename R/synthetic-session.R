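# Generative forward model for synthetic sessions.
#
# An ensemble of graded BF bursting neurons fires as an inhomogeneous Poisson
# process: neuron i adds, on each tone, a Gaussian rate bump whose peak
# amplitude decreases linearly across the ensemble while its onset latency
# increases (strong bursters fire first).  Every neuron's (smoothed) drive,
# delayed by a fixed spike-to-ERP interval, sums linearly into the frontal
# EEG; the same summed drive, weighted by a fixed depth profile positive in
# deep layers, generates the 32-channel laminar LFP.  Per-trial amplitude is
# a single multiplicative scale (1.0 on hits, lower on miss/standard), which
# makes both renderers exactly linear in the bursting amplitude.

#' Forward-model parameters
#'
#' @param n_neurons ensemble size.
#' @param peak_rates_hz per-neuron peak burst rates (Hz), descending;
#'   default linear from 100 down to 20.
#' @param onset_stagger_ms onset latency increment per neuron (ms): neuron i
#'   peaks at `burst_peak_ms + (i-1) * onset_stagger_ms`.
#' @param burst_peak_ms burst-peak latency of the first (strongest) neuron,
#'   ms after tone onset.
#' @param kernel_sigma_ms width (Gaussian sigma, ms) of the burst rate bump;
#'   also the smoothing kernel used by the spike-driven ERP renderer.
#' @param baseline_rate_hz tonic rate added to every neuron's intensity.
#' @param erp_delay_ms fixed spike-to-ERP delay (ms).
#' @param erp_polarity -1 for the negative-going frontal ERP.
#' @param erp_gain_uv_per_hz microvolts of signal per Hz of summed drive.
#' @param trial_scale_hit,trial_scale_other multiplicative burst amplitude on
#'   hit trials and on miss/standard trials.
#' @param noise_sd_uv additive Gaussian noise SD on rendered signals (uV).
#' @param layer_profile_true unit-norm 32-vector (superficial to deep)
#'   weighting the laminar LFP; default has a positive deep-layer lobe and a
#'   weaker negative superficial lobe.
#' @param hit_rate,fa_rate probability an oddball is a hit / a standard is a
#'   false alarm, used by the trial-sequence generator.
#' @return A list of class `"forward_model_params"`.
#' @export
forward_model_params <- function(n_neurons = 10,
                                 peak_rates_hz = seq(100, 20, length.out = n_neurons),
                                 onset_stagger_ms = 5,
                                 burst_peak_ms = 50,
                                 kernel_sigma_ms = 25,
                                 baseline_rate_hz = 4,
                                 erp_delay_ms = 5,
                                 erp_polarity = -1,
                                 erp_gain_uv_per_hz = 0.2,
                                 trial_scale_hit = 1.0,
                                 trial_scale_other = 0.5,
                                 noise_sd_uv = 15,
                                 layer_profile_true = default_layer_profile(),
                                 hit_rate = 0.85,
                                 fa_rate = 0.05) {
  stopifnot(length(peak_rates_hz) == n_neurons)
  if (any(peak_rates_hz <= 0)) stop_bfc("peak rates must be positive")
  if (length(layer_profile_true) != 32)
    stop_bfc("layer_profile_true must have 32 entries")
  if (!any(layer_profile_true > 0))
    stop_bfc("layer_profile_true needs at least one positive entry")
  structure(list(
    n_neurons = n_neurons, peak_rates_hz = peak_rates_hz,
    onset_stagger_ms = onset_stagger_ms, burst_peak_ms = burst_peak_ms,
    kernel_sigma_ms = kernel_sigma_ms, baseline_rate_hz = baseline_rate_hz,
    erp_delay_ms = erp_delay_ms, erp_polarity = erp_polarity,
    erp_gain_uv_per_hz = erp_gain_uv_per_hz,
    trial_scale_hit = trial_scale_hit, trial_scale_other = trial_scale_other,
    noise_sd_uv = noise_sd_uv, layer_profile_true = layer_profile_true,
    hit_rate = hit_rate, fa_rate = fa_rate
  ), class = "forward_model_params")
}

#' @rdname forward_model_params
#' @export
default_layer_profile <- function() {
  rank <- 1:32
  p <- exp(-(rank - 26)^2 / (2 * 3^2)) - 0.35 * exp(-(rank - 10)^2 / (2 * 4^2))
  p / sqrt(sum(p^2))
}

# Per-neuron burst-peak latency, ms after tone onset.
neuron_peak_ms <- function(params, i) {
  params$burst_peak_ms + (i - 1) * params$onset_stagger_ms
}

# Per-trial amplitude scale: 1.0 (hit) or trial_scale_other (miss/standard).
trial_scales <- function(params, events) {
  ifelse(events$tone == "oddball" & events$outcome == "hit",
         params$trial_scale_hit, params$trial_scale_other)
}

#' Peri-stimulus firing intensity of one model neuron
#'
#' Returns the rate function (Hz) of neuron `neuron_index` for a trial with
#' amplitude scale `trial_scale`:
#' `baseline + trial_scale * peak_rate[i] * exp(-(t - peak_i)^2 / 2 sigma^2)`.
#'
#' @param params [forward_model_params()].
#' @param neuron_index 1-based neuron index.
#' @param trial_scale nonnegative amplitude multiplier.
#' @return A function mapping peri-stimulus time in ms to rate in Hz.
#' @export
neuron_intensity <- function(params, neuron_index, trial_scale = 1) {
  if (neuron_index < 1 || neuron_index > params$n_neurons)
    stop_bfc("neuron_index out of range")
  if (trial_scale < 0) stop_bfc("trial_scale must be nonnegative")
  peak_t <- neuron_peak_ms(params, neuron_index)
  amp <- params$peak_rates_hz[neuron_index]
  sig <- params$kernel_sigma_ms
  base <- params$baseline_rate_hz
  function(t_ms) base + trial_scale * amp * exp(-(t_ms - peak_t)^2 / (2 * sig^2))
}

#' Generate an oddball-task trial sequence
#'
#' Tones are presented every 2 s; the number of standards between consecutive
#' oddballs (and before the first / after the last) is drawn uniformly from
#' {2,3,4,5,6}, so oddball-to-oddball gaps are 6-14 s.  Each oddball is a hit
#' with probability `hit_rate` (response time drawn in (0.3, 1.5) s) else a
#' miss; each standard is marked a false alarm with probability `fa_rate`.
#'
#' @param n_oddballs number of oddball tones (>= 0).
#' @param hit_rate probability of a hit on each oddball.
#' @param seed RNG seed.
#' @param fa_rate false-alarm probability per standard.
#' @param start_s onset of the first tone.
#' @return A [trial_events()] table.
#' @export
generate_trial_sequence <- function(n_oddballs, hit_rate = 0.85, seed = 1,
                                    fa_rate = 0.05, start_s = 4) {
  stopifnot(n_oddballs >= 0, hit_rate >= 0, hit_rate <= 1)
  set.seed(seed)
  gaps <- sample(2:6, n_oddballs + 1, replace = TRUE)
  tone <- character(0)
  for (g in seq_len(n_oddballs + 1)) {
    tone <- c(tone, rep("standard", gaps[g]))
    if (g <= n_oddballs) tone <- c(tone, "oddball")
  }
  n <- length(tone)
  onset <- start_s + 2 * (seq_len(n) - 1)
  outcome <- rep("none", n)
  rt <- rep(NA_real_, n)
  odd <- tone == "oddball"
  hit <- odd & stats::runif(n) < hit_rate
  outcome[odd] <- ifelse(hit[odd], "hit", "miss")
  rt[hit] <- stats::runif(sum(hit), 0.3, 1.5)
  fa <- !odd & stats::runif(n) < fa_rate
  rt[fa] <- stats::runif(sum(fa), 0.3, 1.9)
  trial_events(seq_len(n), onset, tone, outcome, rt)
}

#' Simulate the BF bursting ensemble as inhomogeneous Poisson spike trains
#'
#' Each neuron's spikes are the union of a homogeneous baseline process over
#' the whole session and, per trial, a Poisson number of burst spikes (mean =
#' `trial_scale * peak_rate_i * sigma * sqrt(2*pi)`) with times drawn from
#' the Gaussian burst kernel around that neuron's peak latency.
#'
#' @inheritParams neuron_intensity
#' @param events trial table; the per-trial scale is 1.0 on hits and
#'   `trial_scale_other` on miss/standard trials.
#' @param seed RNG seed (reproducible: same seed, identical trains).
#' @return List of [spike_train()], one per neuron.
#' @export
simulate_bf_ensemble <- function(params, events, seed = 1) {
  set.seed(seed)
  span <- c(0, attr(events, "session_end_s"))
  dur <- diff(span)
  scales <- trial_scales(params, events)
  sig_s <- ms_to_s(params$kernel_sigma_ms)
  burst_mass <- sig_s * sqrt(2 * pi)    # integral of the unit-peak kernel, s
  lapply(seq_len(params$n_neurons), function(i) {
    n_base <- stats::rpois(1, params$baseline_rate_hz * dur)
    sp <- stats::runif(n_base, span[1], span[2])
    if (nrow(events)) {
      peak_t <- events$onset_s + ms_to_s(neuron_peak_ms(params, i))
      n_burst <- stats::rpois(nrow(events),
                              scales * params$peak_rates_hz[i] * burst_mass)
      bs <- stats::rnorm(sum(n_burst), rep(peak_t, n_burst), sig_s)
      sp <- c(sp, bs[bs >= span[1] & bs < span[2]])
    }
    spike_train(sprintf("unit%02d", i), sort(sp), span)
  })
}

# Summed (over neurons and trials) evoked drive on the sample grid, Hz,
# *before* the spike-to-ERP delay is applied.  Baseline is excluded in
# noise_free_intensity mode so a zero-amplitude trial contributes nothing.
evoked_drive <- function(params, events, mode, spikes = NULL, fs = 1000,
                         duration_s = NULL) {
  dur <- duration_s %||% attr(events, "session_end_s")
  n <- round(dur * fs)
  drive <- numeric(n)
  if (mode == "noise_free_intensity") {
    sig <- ms_to_s(params$kernel_sigma_ms)
    half <- ceiling(4 * sig * fs)
    off <- seq(-half, half)
    # evaluate at bin centers (off + 0.5 samples): sample i then represents
    # the [t_i, t_i + 1/fs) bin, consistent with how spikes are binned, so
    # millisecond-scale lags are comparable between the two
    bump <- exp(-((off + 0.5) / fs)^2 / (2 * sig^2))
    scales <- trial_scales(params, events)
    for (i in seq_len(params$n_neurons)) {
      peak_idx <- round((events$onset_s + ms_to_s(neuron_peak_ms(params, i))) * fs) + 1
      amp <- params$peak_rates_hz[i] * scales
      for (k in seq_len(nrow(events))) {
        idx <- peak_idx[k] + off
        ok <- idx >= 1 & idx <= n
        drive[idx[ok]] <- drive[idx[ok]] + amp[k] * bump[ok]
      }
    }
  } else if (mode == "spike_driven") {
    if (is.null(spikes)) stop_bfc("spike_driven mode needs spike trains")
    kern <- gaussian_kernel(params$kernel_sigma_ms * fs / 1000)
    counts <- numeric(n)
    for (st in spikes) {
      idx <- floor(st$spikes_s * fs) + 1
      idx <- idx[idx >= 1 & idx <= n]
      counts <- counts + tabulate(idx, nbins = n)
    }
    drive <- smooth_same(counts * fs, kern)   # summed smoothed rate, Hz
  } else stop_bfc("unknown render mode '%s'", mode)
  drive
}

shift_right <- function(x, k) {
  if (k == 0) return(x)
  c(numeric(k), x[seq_len(length(x) - k)])
}

#' Render the frontal EEG from the forward model
#'
#' `frontal = erp_polarity * erp_gain * sum_i drive_i(t - erp_delay) + noise`.
#' In `noise_free_intensity` mode the drive is each neuron's exact evoked
#' intensity (no Poisson sampling, no noise), making the output exactly
#' linear in the per-trial amplitude scale; in `spike_driven` mode it is the
#' Gaussian-smoothed spike rate of the supplied trains.
#'
#' @inheritParams simulate_bf_ensemble
#' @param mode `"noise_free_intensity"` or `"spike_driven"`.
#' @param spikes list of [spike_train()] (required in spike_driven mode).
#' @param fs sampling rate, Hz.
#' @param include_control also emit a task-unlocked control EEG channel
#'   (noise only).
#' @return A [continuous_recording()] with a `frontal_eeg` channel.
#' @export
render_erp <- function(params, events, mode = "noise_free_intensity",
                       spikes = NULL, seed = 1, fs = 1000,
                       include_control = FALSE) {
  drive <- evoked_drive(params, events, mode, spikes, fs)
  d <- round(ms_to_s(params$erp_delay_ms) * fs)
  eeg <- params$erp_polarity * params$erp_gain_uv_per_hz * shift_right(drive, d)
  noisy <- mode != "noise_free_intensity" && params$noise_sd_uv > 0
  set.seed(derive_seed(seed, "erp_noise"))
  if (noisy) eeg <- eeg + stats::rnorm(length(eeg), 0, params$noise_sd_uv)
  samples <- matrix(eeg, nrow = 1)
  ch <- data.frame(label = "FrA", role = "frontal_eeg", depth_rank = NA_integer_)
  if (include_control) {
    ctrl <- if (noisy) stats::rnorm(length(eeg), 0, params$noise_sd_uv)
            else numeric(length(eeg))
    samples <- rbind(samples, ctrl)
    ch <- rbind(ch, data.frame(label = "V1", role = "control_eeg",
                               depth_rank = NA_integer_))
  }
  continuous_recording(samples, fs, ch, t0_s = 0)
}

#' Render the 32-channel laminar LFP from the forward model
#'
#' Channel `c` (ordered superficial to deep) is
#' `layer_profile_true[c] * erp_gain * summed delayed drive + noise`; the
#' default profile makes deep channels positive-going.
#'
#' @inheritParams render_erp
#' @return A [continuous_recording()] with 32 `laminar_lfp` channels.
#' @export
render_laminar_lfp <- function(params, events, mode = "noise_free_intensity",
                               spikes = NULL, seed = 1, fs = 1000) {
  drive <- evoked_drive(params, events, mode, spikes, fs)
  d <- round(ms_to_s(params$erp_delay_ms) * fs)
  base <- params$erp_gain_uv_per_hz * shift_right(drive, d)
  noisy <- mode != "noise_free_intensity" && params$noise_sd_uv > 0
  set.seed(derive_seed(seed, "lfp_noise"))
  samples <- matrix(0, nrow = 32, ncol = length(base))
  for (c0 in 1:32) {
    x <- params$layer_profile_true[c0] * base
    if (noisy) x <- x + stats::rnorm(length(base), 0, params$noise_sd_uv)
    samples[c0, ] <- x
  }
  ch <- data.frame(label = sprintf("lam%02d", 1:32), role = "laminar_lfp",
                   depth_rank = 1:32)
  continuous_recording(samples, fs, ch, t0_s = 0)
}

# Stimulation-evoked temporal kernel: zero before onset, then a truncated
# Gaussian rising to its peak `rise_ms` after onset.  The jump at onset makes
# the configured latency exactly recoverable on noise-free data.
stim_kernel <- function(u_ms, rise_ms = 10, width_ms = 5) {
  ifelse(u_ms >= 0, exp(-(u_ms - rise_ms)^2 / (2 * width_ms^2)), 0)
}

#' Simulate a BF electrical-stimulation session
#'
#' Pulses every 2 s (no tones); each pulse evokes
#' `layer_profile_true x stim kernel` starting `latency_ms` after the pulse,
#' plus an optional early channel-uniform transient and a +/-2 ms artifact
#' deflection on all channels, plus noise.
#'
#' @inheritParams render_erp
#' @param n_pulses number of stimulation pulses (>= 1).
#' @param latency_ms onset of the profile-shaped evoked response after each
#'   pulse (ms).
#' @param evoked_gain_uv peak amplitude (uV) of the evoked component on the
#'   profile's largest channel.
#' @param early_transient_uv amplitude of the channel-uniform early transient
#'   at ~3 ms (0 disables).
#' @param artifact_uv amplitude of the stimulation artifact within +/-2 ms of
#'   each pulse.
#' @param noise_sd_uv overrides `params$noise_sd_uv` when not `NULL`.
#' @return list with `stim` ([stim_events()]) and `recording` (32 laminar
#'   channels).
#' @export
simulate_stim_session <- function(params, n_pulses, seed = 1, fs = 1000,
                                  latency_ms = 8, evoked_gain_uv = 150,
                                  early_transient_uv = 30, artifact_uv = 400,
                                  noise_sd_uv = NULL) {
  stopifnot(n_pulses >= 1)
  nsd <- noise_sd_uv %||% params$noise_sd_uv
  pulses <- 5 + 2 * (seq_len(n_pulses) - 1)
  dur <- max(pulses) + 2
  n <- round(dur * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  prof <- params$layer_profile_true / max(params$layer_profile_true)
  evoked <- numeric(n); transient <- numeric(n); artifact <- numeric(n)
  for (p in pulses) {
    u <- t_ms - p * 1000
    win <- u >= -3 & u < 60
    evoked[win] <- evoked[win] + stim_kernel(u[win] - latency_ms)
    transient[win] <- transient[win] +
      ifelse(u[win] >= 0, exp(-(u[win] - 3)^2 / (2 * 1^2)), 0)
    artifact[abs(u) <= 2] <- artifact_uv
  }
  set.seed(derive_seed(seed, "stim_noise"))
  samples <- matrix(0, nrow = 32, ncol = n)
  for (c0 in 1:32) {
    x <- prof[c0] * evoked_gain_uv * evoked +
      early_transient_uv * transient + artifact
    if (nsd > 0) x <- x + stats::rnorm(n, 0, nsd)
    samples[c0, ] <- x
  }
  ch <- data.frame(label = sprintf("lam%02d", 1:32), role = "laminar_lfp",
                   depth_rank = 1:32)
  list(stim = stim_events(pulses),
       recording = continuous_recording(samples, fs, ch, t0_s = 0))
}

#' Simulate a complete session bundle
#'
#' Trial sequence, BF ensemble spike trains, and a combined recording with
#' frontal EEG, control EEG and 32 laminar LFP channels; optionally a
#' stimulation block.
#'
#' @inheritParams render_erp
#' @param n_oddballs number of oddball trials.
#' @param with_stim also simulate a stimulation session (returned in `stim`
#'   and `stim_recording`).
#' @param n_pulses pulses in the stimulation block.
#' @return list with `events`, `spikes`, `recording`, and optionally `stim`,
#'   `stim_recording`; suitable for [write_session()] (the stim recording is
#'   a separate bundle).
#' @export
simulate_session <- function(params = forward_model_params(), n_oddballs = 20,
                             seed = 1, mode = "spike_driven", fs = 1000,
                             with_stim = FALSE, n_pulses = 50) {
  events <- generate_trial_sequence(n_oddballs, params$hit_rate,
                                    seed = derive_seed(seed, "trials"),
                                    fa_rate = params$fa_rate)
  spikes <- simulate_bf_ensemble(params, events,
                                 seed = derive_seed(seed, "spikes"))
  eeg <- render_erp(params, events, mode, spikes,
                    seed = derive_seed(seed, "eeg"), fs = fs,
                    include_control = TRUE)
  lfp <- render_laminar_lfp(params, events, mode, spikes,
                            seed = derive_seed(seed, "lfp"), fs = fs)
  recording <- continuous_recording(rbind(eeg$samples, lfp$samples), fs,
                                    rbind(eeg$channels, lfp$channels), 0)
  out <- list(events = events, spikes = spikes, recording = recording,
              stim = NULL)
  if (with_stim) {
    ss <- simulate_stim_session(params, n_pulses,
                                seed = derive_seed(seed, "stim"), fs = fs)
    out$stim <- ss$stim
    out$stim_recording <- ss$recording
  }
  out
}
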