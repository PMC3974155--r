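# Session data model and bundle I/O.
#
# A session bundle is a directory of plain-text/raw files:
#   events.tsv       trial_id, onset_s, tone, outcome, response_time_s
#   spikes.tsv       unit_id, spike_s (long format) + span in spikes.json
#   continuous.bin   little-endian float32, channel-major
#   continuous.json  sidecar: fs_hz, t0_s, n_samples, units, channels[]
#   stim.tsv         pulse_s, current_uA (optional)
# Timestamps are written as decimal text with microsecond precision.

#' Trial event table
#'
#' Constructs and validates the table of tone events that forms the temporal
#' backbone of a session.  Onsets are seconds from session start; `tone` is
#' `"oddball"` or `"standard"`; `outcome` is `"hit"`/`"miss"` for oddballs
#' and `"none"` for standards (a standard with a non-missing
#' `response_time_s` is a false alarm).
#'
#' Invariants checked: onsets strictly ascending and at least 2 s apart;
#' between consecutive oddballs the number of standards is in 2..6;
#' `outcome == "none"` exactly for standard tones.
#'
#' @param trial_id integer trial identifiers.
#' @param onset_s tone onset times, seconds from session start.
#' @param tone character, `"oddball"` or `"standard"`.
#' @param outcome character, `"hit"`, `"miss"` or `"none"`.
#' @param response_time_s optional response latency in seconds (`NA` if no
#'   response); on a standard tone marks a false alarm.
#' @param session_end_s end of the recorded session, seconds; defaults to
#'   2 s after the last onset.
#' @return A `data.frame` of class `"trial_events"` with one row per tone.
#' @export
trial_events <- function(trial_id, onset_s, tone, outcome,
                         response_time_s = rep(NA_real_, length(onset_s)),
                         session_end_s = NULL) {
  ev <- data.frame(
    trial_id = as.integer(trial_id),
    onset_s = as.numeric(onset_s),
    tone = as.character(tone),
    outcome = as.character(outcome),
    response_time_s = as.numeric(response_time_s),
    stringsAsFactors = FALSE
  )
  attr(ev, "session_end_s") <- session_end_s %||%
    (if (nrow(ev)) max(ev$onset_s) + 2 else 0)
  class(ev) <- c("trial_events", "data.frame")
  validate_trial_events(ev)
  ev
}

#' @rdname trial_events
#' @param ev a `trial_events` object.
#' @export
validate_trial_events <- function(ev) {
  if (!all(ev$tone %in% c("oddball", "standard")))
    stop_bfc("trial_events: tone must be 'oddball' or 'standard'")
  if (!all(ev$outcome %in% c("hit", "miss", "none")))
    stop_bfc("trial_events: outcome must be 'hit', 'miss' or 'none'")
  if (nrow(ev) > 1) {
    d <- diff(ev$onset_s)
    if (any(d <= 0)) stop_bfc("trial_events: onsets not ascending")
    if (any(d < 2 - 1e-9))
      stop_bfc("trial_events: consecutive onsets closer than 2 s")
  }
  odd <- which(ev$tone == "oddball")
  if (length(odd) > 1) {
    n_std <- diff(odd) - 1L
    if (!all(n_std %in% 2:6))
      stop_bfc("trial_events: standards between consecutive oddballs must be 2..6 (got %s)",
               paste(unique(n_std[!n_std %in% 2:6]), collapse = ", "))
  }
  if (any(ev$outcome == "none" & ev$tone == "oddball"))
    stop_bfc("trial_events: oddball tones must have outcome hit or miss")
  if (any(ev$outcome != "none" & ev$tone == "standard"))
    stop_bfc("trial_events: outcome must be 'none' for standard tones")
  invisible(ev)
}

#' Single-unit spike train
#'
#' @param unit_id unit label.
#' @param spikes_s ascending spike times, seconds from session start.
#' @param span_s numeric length-2 `(start, end)` of the session span the unit
#'   was recorded over; the whole-session mean rate denominator.
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(unit_id, spikes_s, span_s) {
  spikes_s <- as.numeric(spikes_s)
  st <- structure(
    list(unit_id = as.character(unit_id), spikes_s = spikes_s,
         span_s = as.numeric(span_s)),
    class = "spike_train"
  )
  validate_spike_train(st)
  st
}

#' @rdname spike_train
#' @param st a `spike_train` object.
#' @export
validate_spike_train <- function(st) {
  if (length(st$span_s) != 2 || diff(st$span_s) <= 0)
    stop_bfc("spike_train %s: span length must be > 0", st$unit_id)
  if (is.unsorted(st$spikes_s))
    stop_bfc("spike_train %s: spikes not sorted", st$unit_id)
  if (length(st$spikes_s) &&
      (min(st$spikes_s) < st$span_s[1] || max(st$spikes_s) > st$span_s[2]))
    stop_bfc("spike_train %s: spikes outside session span", st$unit_id)
  invisible(st)
}

#' Uniformly sampled multichannel recording
#'
#' Continuous EEG/LFP signal in microvolts.  Channel roles are
#' `"frontal_eeg"`, `"control_eeg"` or `"laminar_lfp"`; laminar channels
#' carry a `depth_rank` (1 = most superficial, 32 = deepest) and, when
#' present, must number exactly 32 with ranks forming a permutation of 1..32.
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param fs_hz sampling rate, 1000 or 2000 Hz.
#' @param channels data.frame with columns `label`, `role`, `depth_rank`
#'   (`NA` for non-laminar channels).
#' @param t0_s time of the first sample, seconds.
#' @return An object of class `"continuous_recording"`.
#' @export
continuous_recording <- function(samples, fs_hz, channels, t0_s = 0) {
  rec <- structure(
    list(samples = as.matrix(samples), fs_hz = as.numeric(fs_hz),
         channels = as.data.frame(channels), t0_s = as.numeric(t0_s)),
    class = "continuous_recording"
  )
  validate_continuous_recording(rec)
  rec
}

#' @rdname continuous_recording
#' @param rec a `continuous_recording` object.
#' @export
validate_continuous_recording <- function(rec) {
  if (!rec$fs_hz %in% c(1000, 2000))
    stop_bfc("continuous_recording: fs_hz must be 1000 or 2000")
  ch <- rec$channels
  if (!all(c("label", "role", "depth_rank") %in% names(ch)))
    stop_bfc("continuous_recording: channels need label, role, depth_rank")
  if (!all(ch$role %in% c("frontal_eeg", "control_eeg", "laminar_lfp")))
    stop_bfc("continuous_recording: unknown channel role")
  if (nrow(ch) != nrow(rec$samples))
    stop_bfc("continuous_recording: channel table does not match sample rows")
  lam <- ch$role == "laminar_lfp"
  if (any(lam)) {
    if (sum(lam) != 32)
      stop_bfc("continuous_recording: laminar channels must number exactly 32")
    if (!setequal(ch$depth_rank[lam], 1:32))
      stop_bfc("continuous_recording: depth_rank must be a permutation of 1..32")
  }
  invisible(rec)
}

#' @rdname continuous_recording
#' @param role,label select one channel by role (first match) or exact label.
#' @return `channel_samples()`: the selected channel's samples as a vector.
#' @export
channel_samples <- function(rec, role = NULL, label = NULL) {
  if (!is.null(label)) {
    i <- match(label, rec$channels$label)
    if (is.na(i)) stop_bfc("no channel labelled '%s'", label)
  } else {
    i <- which(rec$channels$role == role)[1]
    if (is.na(i)) stop_bfc("no channel with role '%s'", role)
  }
  rec$samples[i, ]
}

# Laminar channel rows ordered superficial -> deep.
laminar_index <- function(rec) {
  lam <- which(rec$channels$role == "laminar_lfp")
  lam[order(rec$channels$depth_rank[lam])]
}

#' Electrical stimulation pulse table
#'
#' @param pulse_times_s ascending pulse times, seconds.
#' @param current_per_electrode_uA current per electrode, microamperes.
#' @param ipi_tol_s tolerated deviation of inter-pulse intervals from 2 s.
#' @return An object of class `"stim_events"`.
#' @export
stim_events <- function(pulse_times_s, current_per_electrode_uA = 70,
                        ipi_tol_s = 0.25) {
  se <- structure(
    list(pulse_times_s = as.numeric(pulse_times_s),
         current_per_electrode_uA = as.numeric(current_per_electrode_uA)),
    class = "stim_events"
  )
  if (is.unsorted(se$pulse_times_s, strictly = TRUE))
    stop_bfc("stim_events: pulse times not strictly ascending")
  if (length(se$pulse_times_s) > 1) {
    ipi <- diff(se$pulse_times_s)
    if (any(abs(ipi - 2) > ipi_tol_s))
      stop_bfc("stim_events: inter-pulse intervals must be ~2 s")
  }
  se
}

fmt_s <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Write a session bundle
#'
#' Serializes a session to a directory: TSV tables for events, spikes and
#' stimulation pulses, and raw little-endian float32 (channel-major) plus a
#' JSON sidecar for the continuous signal.  Timestamps are written with
#' microsecond precision and round-trip bit-exactly at that precision;
#' samples round-trip within float32.
#'
#' @param session list with elements `events`, `spikes` (list of
#'   [spike_train()]), `recording`, and optionally `stim`.
#' @param bundle_path directory to create/fill.
#' @export
write_session <- function(session, bundle_path) {
  dir.create(bundle_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(bundle_path)) stop_bfc("cannot create '%s'", bundle_path)
  ev <- session$events
  ev_out <- data.frame(trial_id = ev$trial_id, onset_s = fmt_s(ev$onset_s),
                       tone = ev$tone, outcome = ev$outcome,
                       response_time_s = fmt_s(ev$response_time_s))
  utils::write.table(ev_out, file.path(bundle_path, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- do.call(rbind, lapply(session$spikes, function(st) {
    if (!length(st$spikes_s)) return(NULL)
    data.frame(unit_id = st$unit_id, spike_s = fmt_s(st$spikes_s))
  }))
  if (is.null(sp)) sp <- data.frame(unit_id = character(0), spike_s = character(0))
  utils::write.table(sp, file.path(bundle_path, "spikes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spans <- lapply(session$spikes, function(st)
    list(unit_id = st$unit_id, span_s = st$span_s))
  jsonlite::write_json(
    list(session_end_s = attr(ev, "session_end_s"), units = spans),
    file.path(bundle_path, "spikes.json"), auto_unbox = TRUE, digits = NA)

  rec <- session$recording
  con <- file(file.path(bundle_path, "continuous.bin"), "wb")
  on.exit(close(con), add = TRUE)
  # channel-major: each channel's full time series in turn
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(fs_hz = rec$fs_hz, t0_s = rec$t0_s, n_samples = ncol(rec$samples),
         units = "uV",
         channels = lapply(seq_len(nrow(rec$channels)), function(i)
           list(label = rec$channels$label[i], role = rec$channels$role[i],
                depth_rank = rec$channels$depth_rank[i]))),
    file.path(bundle_path, "continuous.json"), auto_unbox = TRUE,
    digits = NA, null = "null", na = "null")
  if (!is.null(session$stim)) {
    st <- session$stim
    utils::write.table(
      data.frame(pulse_s = fmt_s(st$pulse_times_s),
                 current_uA = st$current_per_electrode_uA),
      file.path(bundle_path, "stim.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bundle_path)
}

#' Read a session bundle
#'
#' Inverse of [write_session()].  All type invariants are re-validated on
#' load; a violation raises an error naming the invariant and the file.
#'
#' @param bundle_path bundle directory.
#' @return list with `events`, `spikes`, `recording`, `stim` (`NULL` when
#'   absent).
#' @export
read_session <- function(bundle_path) {
  need <- c("events.tsv", "spikes.tsv", "spikes.json",
            "continuous.bin", "continuous.json")
  missing <- need[!file.exists(file.path(bundle_path, need))]
  if (length(missing))
    stop_bfc("bundle '%s' is missing: %s", bundle_path,
             paste(missing, collapse = ", "))
  ev_raw <- utils::read.delim(file.path(bundle_path, "events.tsv"),
                              colClasses = "character")
  meta_sp <- jsonlite::read_json(file.path(bundle_path, "spikes.json"))
  events <- tryCatch(
    trial_events(as.integer(ev_raw$trial_id), as.numeric(ev_raw$onset_s),
                 ev_raw$tone, ev_raw$outcome,
                 suppressWarnings(as.numeric(ev_raw$response_time_s)),
                 session_end_s = meta_sp$session_end_s),
    error = function(e) stop_bfc("events.tsv: %s", conditionMessage(e)))

  sp_raw <- utils::read.delim(file.path(bundle_path, "spikes.tsv"),
                              colClasses = "character")
  spikes <- lapply(meta_sp$units, function(u) {
    s <- as.numeric(sp_raw$spike_s[sp_raw$unit_id == u$unit_id])
    spike_train(u$unit_id, s, unlist(u$span_s))
  })

  meta <- jsonlite::read_json(file.path(bundle_path, "continuous.json"))
  ch <- do.call(rbind, lapply(meta$channels, function(c0)
    data.frame(label = c0$label, role = c0$role,
               depth_rank = if (is.null(c0$depth_rank)) NA_integer_
                            else as.integer(c0$depth_rank))))
  n_ch <- nrow(ch); n_t <- meta$n_samples
  con <- file(file.path(bundle_path, "continuous.bin"), "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "numeric", n = n_ch * n_t, size = 4, endian = "little")
  if (length(x) != n_ch * n_t)
    stop_bfc("continuous.bin: expected %d samples, read %d", n_ch * n_t, length(x))
  recording <- continuous_recording(
    matrix(x, nrow = n_ch, byrow = TRUE), meta$fs_hz, ch, meta$t0_s)

  stim <- NULL
  if (file.exists(file.path(bundle_path, "stim.tsv"))) {
    st_raw <- utils::read.delim(file.path(bundle_path, "stim.tsv"),
                                colClasses = "character")
    stim <- stim_events(as.numeric(st_raw$pulse_s),
                        as.numeric(st_raw$current_uA[1]))
  }
  list(events = events, spikes = spikes, recording = recording, stim = stim)
}
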