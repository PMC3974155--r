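# Laminar LFP layer profiles: 60-ms window extraction around the population
# burst peak, cosine similarity with a dimension-permutation null,
# peak-positive normalization, and the stimulation-evoked scalar-projection
# similarity series with onset latency detection.

#' Peak time of the population bursting response
#'
#' Argmax of a (smoothed) population PSTH within a post-onset search window;
#' the earliest bin is returned on ties.
#'
#' @param psth a [compute_psth()] result (population PSTH of bursting units).
#' @param search_ms search window, ms after tone onset.
#' @return Peak time in ms (bin center).
#' @export
burst_peak_time <- function(psth, search_ms = c(0, 300)) {
  centers <- psth$bin_edges_ms[-length(psth$bin_edges_ms)] +
    diff(psth$bin_edges_ms) / 2
  sel <- centers >= search_ms[1] & centers < search_ms[2]
  if (!any(sel)) stop_bfc("burst_peak_time: empty search window")
  r <- psth$rate_hz[sel]
  if (max(r) == min(r)) stop_bfc("burst_peak_time: flat PSTH")
  centers[sel][which.max(r)]
}

#' Extract the 32-channel LFP layer profile
#'
#' Per laminar channel (ordered superficial to deep), the trial-averaged mean
#' LFP in the 60-ms window centered on `center_ms`
#' (`[center - 30, center + 30)` ms after tone onset).
#'
#' @param rec a [continuous_recording()] with 32 laminar channels.
#' @param events trial group to average over.
#' @param center_ms window center, ms after tone onset (typically
#'   [burst_peak_time()]).
#' @param width_ms window length, ms.
#' @return List of class `"layer_profile"`: `values` (32, by depth rank),
#'   `window_ms`, `n_trials`, `normalized`.
#' @export
extract_layer_profile <- function(rec, events, center_ms, width_ms = 60) {
  if (nrow(events) == 0) stop_bfc("extract_layer_profile: no trials")
  lam <- laminar_index(rec)
  if (length(lam) != 32) stop_bfc("recording has no 32-channel laminar array")
  win <- c(center_ms - width_ms / 2, center_ms + width_ms / 2)
  n <- ncol(rec$samples)
  vals <- vapply(lam, function(ci) {
    per_trial <- vapply(events$onset_s, function(on) {
      idx <- sample_index_range(on + ms_to_s(win[1]), on + ms_to_s(win[2]),
                                rec$t0_s, rec$fs_hz, n)
      if (!length(idx)) stop_bfc("layer-profile window outside recorded span")
      mean(rec$samples[ci, idx])
    }, numeric(1))
    mean(per_trial)
  }, numeric(1))
  structure(list(values = vals, window_ms = win, n_trials = nrow(events),
                 normalized = FALSE),
            class = "layer_profile")
}

profile_values <- function(x) if (inherits(x, "layer_profile")) x$values else x

#' Cosine similarity between two layer profiles
#'
#' `dot(a, b) / (||a|| ||b||)`: 1 when aligned, -1 when opposite, 0 when
#' orthogonal; invariant to positive rescaling of either profile.
#'
#' @param a,b `layer_profile` objects or plain numeric vectors.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  va <- profile_values(a); vb <- profile_values(b)
  stopifnot(length(va) == length(vb))
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop_bfc("cosine similarity undefined for zero vector")
  sum(va * vb) / (na * nb)
}

#' Dimension-permutation significance of a profile similarity
#'
#' Null distribution built by permuting the 32 entries of one profile
#' `n_perm` times; two-sided add-one p-value on |similarity|.
#'
#' @inheritParams cosine_similarity
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List: `similarity`, `p_two_sided`, `n_perm`.
#' @export
profile_permutation_p <- function(a, b, n_perm = 1000, seed = 1) {
  obs <- cosine_similarity(a, b)
  vb <- profile_values(b)
  set.seed(seed)
  null_s <- vapply(seq_len(n_perm), function(i)
    cosine_similarity(a, vb[sample.int(length(vb))]), numeric(1))
  p <- (1 + sum(abs(null_s) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(similarity = obs, p_two_sided = p, n_perm = n_perm)
}

#' Normalize a layer profile to its peak positive value
#'
#' @param a a `layer_profile` (or numeric vector) with at least one positive
#'   entry.
#' @return A normalized `layer_profile` (max positive value = 1).
#' @export
normalize_profile <- function(a) {
  v <- profile_values(a)
  mx <- max(v)
  if (mx <= 0) stop_bfc("normalize_profile: no positive entry")
  out <- if (inherits(a, "layer_profile")) a
         else structure(list(values = v, window_ms = NULL, n_trials = NA,
                             normalized = FALSE), class = "layer_profile")
  out$values <- v / mx
  out$normalized <- TRUE
  out
}

#' Stimulation-evoked scalar-projection similarity series
#'
#' At each 1-ms peri-pulse time point, the pulse-averaged 32-channel LFP
#' vector is projected onto the reference layer profile (scalar projection,
#' `dot(v, ref) / ||ref||`); the series is normalized by its peak |value|
#' outside the `+/- artifact_exclusion_ms` stimulation-artifact window.  The
#' per-time-point permutation band comes from permuting the reference's 32
#' dimensions.
#'
#' @param rec stimulation-session recording (32 laminar channels).
#' @param stim a [stim_events()] table.
#' @param reference oddball-task `layer_profile` to project onto.
#' @param window_ms peri-pulse time grid, ms.
#' @param artifact_exclusion_ms half-width of the artifact window around the
#'   pulse excluded from peak normalization and onset detection.
#' @param n_perm,alpha,seed permutation-band settings (`alpha = 0.05`: 95%
#'   band).
#' @param min_run_ms sustained-run requirement for [similarity_onset()].
#' @return List of class `"similarity_series"`: `t_ms`, `s_norm`, `lo`, `hi`,
#'   `onset_ms`, `peak_abs` (the pre-normalization peak scalar projection).
#' @export
stim_similarity_series <- function(rec, stim, reference,
                                   window_ms = c(-50, 200),
                                   artifact_exclusion_ms = 5, n_perm = 1000,
                                   alpha = 0.05, seed = 1, min_run_ms = 5) {
  ref <- profile_values(reference)
  nref <- sqrt(sum(ref^2))
  if (nref == 0) stop_bfc("stim_similarity_series: zero reference")
  lam <- laminar_index(rec)
  if (length(lam) != 32) stop_bfc("recording has no 32-channel laminar array")
  t_ms <- seq(window_ms[1], window_ms[2] - 1)
  n <- ncol(rec$samples)
  # pulse-averaged 32 x T matrix: mean over pulses of the samples in each
  # 1-ms bin [t, t+1) relative to the pulse
  v <- matrix(0, nrow = 32, ncol = length(t_ms))
  for (p in stim$pulse_times_s) {
    idx0 <- vapply(t_ms, function(tm)
      sample_index_range(p + ms_to_s(tm), p + ms_to_s(tm + 1),
                         rec$t0_s, rec$fs_hz, n)[1], numeric(1))
    width <- round(rec$fs_hz / 1000)
    for (j in seq_along(t_ms)) {
      cols <- idx0[j] + seq_len(width) - 1
      v[, j] <- v[, j] + rowMeans(rec$samples[lam, cols, drop = FALSE])
    }
  }
  v <- v / length(stim$pulse_times_s)
  s <- as.numeric(crossprod(v, ref)) / nref
  outside <- abs(t_ms) > artifact_exclusion_ms
  peak <- max(abs(s[outside]))
  if (peak == 0) stop_bfc("stim_similarity_series: flat series")
  s_norm <- s / peak
  lo <- hi <- rep(NA_real_, length(t_ms))
  if (n_perm > 0) {
    set.seed(seed)
    null_s <- matrix(NA_real_, nrow = n_perm, ncol = length(t_ms))
    for (b in seq_len(n_perm)) {
      pr <- ref[sample.int(32)]
      null_s[b, ] <- as.numeric(crossprod(v, pr)) / nref / peak
    }
    lo <- apply(null_s, 2, stats::quantile, probs = alpha / 2)
    hi <- apply(null_s, 2, stats::quantile, probs = 1 - alpha / 2)
  }
  out <- structure(list(t_ms = t_ms, s_norm = s_norm, lo = unname(lo),
                        hi = unname(hi), peak_abs = peak,
                        artifact_exclusion_ms = artifact_exclusion_ms,
                        onset_ms = NA_real_),
                   class = "similarity_series")
  if (n_perm > 0)
    out$onset_ms <- similarity_onset(out, min_run_ms, artifact_exclusion_ms)
  out
}

#' Onset latency of sustained profile similarity
#'
#' First post-pulse time at which the normalized similarity exceeds the upper
#' permutation band for at least `min_run_ms` consecutive milliseconds,
#' excluding the artifact window; `NA` when never sustained.
#'
#' @param series a `similarity_series`.
#' @param min_run_ms required consecutive run, ms.
#' @param artifact_exclusion_ms artifact half-width, ms (defaults to the
#'   series' own setting).
#' @return Onset in ms, or `NA`.
#' @export
similarity_onset <- function(series, min_run_ms = 5,
                             artifact_exclusion_ms = NULL) {
  art <- artifact_exclusion_ms %||% series$artifact_exclusion_ms
  ok <- series$t_ms > art & !is.na(series$hi) &
    series$s_norm > series$hi
  cand <- which(series$t_ms > art)
  for (i in cand) {
    run <- i + seq_len(min_run_ms) - 1
    if (max(run) > length(ok)) break
    if (all(ok[run])) return(series$t_ms[i])
  }
  NA_real_
}
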