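#!/usr/bin/env Rscript
# Simulate one complete oddball session (plus a BF-stimulation block) from
# the generative forward model and write it as a session bundle.
#
# Output: results/session_bundle/ (events, spikes, continuous signals),
#         results/behavior.json

suppressMessages(library(bfcoupling))

seed <- 20260928L
params <- forward_model_params()
dir.create("results", showWarnings = FALSE)

message("simulating: 40 oddball trials, 10 BF neurons, 34-channel recording")
session <- simulate_session(params, n_oddballs = 40, seed = seed,
                            with_stim = TRUE, n_pulses = 60)
write_session(session, "results/session_bundle")
# the stimulation block is its own mini-bundle (no tones, same probe)
write_session(list(events = trial_events(integer(0), numeric(0),
                                         character(0), character(0),
                                         session_end_s = 130),
                   spikes = list(), recording = session$stim_recording,
                   stim = session$stim),
              "results/stim_bundle")

bs <- behavioral_summary(session$events)
jsonlite::write_json(c(bs, list(seed = seed)), "results/behavior.json",
                     auto_unbox = TRUE, digits = NA)
message(sprintf("behavior: hit rate %.2f over %d oddballs, false alarms %.3f",
                bs$hit_rate, bs$n_oddballs, bs$fa_rate))
message("bundle written to results/session_bundle")
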