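# Fixtures built in code; no data files.

# Minimal valid trial table: s s O s s O s ... (2 standards between oddballs)
tiny_events <- function(n_oddballs = 2, outcome = "hit", start_s = 4) {
  tone <- c("standard", "standard")
  for (k in seq_len(n_oddballs))
    tone <- c(tone, "oddball", "standard", "standard")
  tone <- c(tone, "standard")
  onset <- start_s + 2 * (seq_along(tone) - 1)
  out <- ifelse(tone == "oddball", outcome, "none")
  trial_events(seq_along(tone), onset, tone, out)
}

# A deterministic spike train: regular `rate` Hz over (0, dur)
regular_train <- function(rate = 10, dur = 100, unit_id = "reg") {
  spike_train(unit_id, seq(1 / (2 * rate), dur - 1e-9, by = 1 / rate),
              c(0, dur))
}

# A small 3-channel recording with prescribed per-channel values
const_recording <- function(values = c(1, 2, 3), n = 2000, fs = 1000) {
  ch <- data.frame(label = c("FrA", "V1", "x1"),
                   role = c("frontal_eeg", "control_eeg", "frontal_eeg"),
                   depth_rank = NA_integer_)
  continuous_recording(outer(values, rep(1, n)), fs, ch, t0_s = 0)
}

# Small simulated session shared by several tests (cached per test run)
.session_cache <- new.env(parent = emptyenv())
small_session <- function(seed = 7, n_oddballs = 12, mode = "spike_driven",
                          hit_rate = 0.7) {
  key <- paste(seed, n_oddballs, mode, hit_rate, sep = "_")
  if (is.null(.session_cache[[key]])) {
    p <- forward_model_params(hit_rate = hit_rate)
    .session_cache[[key]] <- simulate_session(p, n_oddballs, seed = seed,
                                              mode = mode)
  }
  .session_cache[[key]]
}

# Independent brute-force AUC: explicit pair enumeration with midrank ties
auc_bruteforce <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(a) * length(b))
}

# Independent Pearson r from raw sum formulas (no stats::cor)
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}
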