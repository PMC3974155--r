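# End-to-end orchestration: simulate (or load) a session, run every analysis
# stage in dependency order, and assemble a machine-readable session report.

#' Behavioral summary of a session
#'
#' @param events a [trial_events()] table.
#' @return List: `hit_rate` (hits / oddballs), `fa_rate` (standards with a
#'   response / standards), `n_oddballs`, `n_standards`.
#' @export
behavioral_summary <- function(events) {
  odd <- events$tone == "oddball"
  if (!any(odd)) stop_bfc("behavioral_summary: no oddball trials")
  std <- !odd
  list(hit_rate = mean(events$outcome[odd] == "hit"),
       fa_rate = if (any(std)) mean(!is.na(events$response_time_s[std])) else NA_real_,
       n_oddballs = sum(odd), n_standards = sum(std))
}

#' Default pipeline configuration
#'
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @param n_oddballs simulated oddball count.
#' @param n_perm permutations for every null (0 disables significance).
#' @param with_stim include the stimulation block and its analyses.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(seed = 1, n_oddballs = 20, n_perm = 200,
                            with_stim = TRUE) {
  list(seed = seed, n_oddballs = n_oddballs, n_perm = n_perm,
       with_stim = with_stim, mode = "spike_driven",
       burst_cutoff = 2.5, cp_alpha = 0.01, coupling_alpha = 0.001,
       xcorr_alpha = 0.01, stim_alpha = 0.05, threshold_frac = 0.30,
       schema_version = "1")
}

#' Run the full analysis pipeline on a simulated session
#'
#' Simulates a session from the forward model, then runs: behavioral summary,
#' bursting classification, hit-vs-miss choice probability on the frontal and
#' control EEG, per-unit amplitude coupling with the quintile scaling curve,
#' concatenated cross-correlation with lead/lag summaries, oddball/standard
#' layer-profile similarity, and (optionally) the stimulation-evoked
#' similarity series with onset latency.  Deterministic under `config$seed`.
#'
#' @param config list from [pipeline_config()] (or a path to a JSON file of
#'   overrides).
#' @param params [forward_model_params()].
#' @param session optional pre-built session (as from [simulate_session()] or
#'   [read_session()]); when supplied the simulate stage is skipped.
#' @param out_json optional path; the report is written there as JSON.
#' @return The session report (nested list), invisibly also written to
#'   `out_json` when given.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         params = forward_model_params(),
                         session = NULL, out_json = NULL) {
  if (is.character(config)) {
    over <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- utils::modifyList(pipeline_config(), over)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop_bfc("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }
  np <- config$n_perm

  session <- session %||% stage("simulate",
    simulate_session(params, config$n_oddballs, seed = config$seed,
                     mode = config$mode, with_stim = config$with_stim))
  events <- session$events
  rec <- session$recording

  behavioral <- stage("behavior", behavioral_summary(events))

  metrics <- stage("burst",
    burst_metrics(session$spikes, events, cutoff = config$burst_cutoff))
  bursting_units <- session$spikes[metrics$is_bursting]
  pop_amp <- population_bursting_amplitude(bursting_units, events)

  hits <- events[events$tone == "oddball" & events$outcome == "hit", ]
  miss <- events[events$tone == "oddball" & events$outcome == "miss", ]
  cp <- stage("cp", {
    per_channel <- function(role) {
      ser <- choice_probability_series(
        rec, hits, miss, n_perm = np, alpha = config$cp_alpha,
        seed = derive_seed(config$seed, paste0("cp_", role)), role = role)
      burst_lags <- ser$lag_s >= 0.05 & ser$lag_s < 0.2
      list(series = ser,
           n_significant = if (np > 0) sum(ser$significant) else NULL,
           min_auc_burst_window = min(ser$auc[burst_lags]))
    }
    if (nrow(miss) >= 2) list(frontal_eeg = per_channel("frontal_eeg"),
                              control_eeg = per_channel("control_eeg"))
    else NULL
  })

  coupling <- stage("coupling", {
    rows <- lapply(seq_along(session$spikes), function(i) {
      pr <- trial_pairs(session$spikes[[i]], rec, events)
      ac <- amplitude_correlation(pr, sig_level = config$coupling_alpha)
      data.frame(unit_id = session$spikes[[i]]$unit_id, r = ac$r, p = ac$p,
                 significant = ac$significant)
    })
    tab <- do.call(rbind, rows)
    example_unit <- bursting_units[[1]]
    quint <- quintile_scaling(
      pop_amp, trial_pairs(example_unit, rec, events), events)
    list(table = tab,
         frac_bursting_significant =
           mean(tab$significant[metrics$is_bursting]),
         quintile_example = quint)
  })

  xcorr <- stage("xcorr", {
    res <- lapply(bursting_units, function(st)
      unit_xcorr(st, rec, events, pop_amp, config$threshold_frac,
                 n_perm = np, alpha = config$xcorr_alpha,
                 seed = derive_seed(config$seed, paste0("xc_", st$unit_id))))
    tab <- data.frame(
      unit_id = vapply(res, `[[`, character(1), "unit_id"),
      best_lag_ms = vapply(res, `[[`, numeric(1), "best_lag_ms"),
      max_r = vapply(res, `[[`, numeric(1), "max_r"),
      significant = if (np > 0)
        vapply(res, `[[`, logical(1), "significant_anywhere") else NA)
    out <- list(table = tab)
    if (np > 0 && sum(tab$significant) > 0)
      out$mean_significant_r <- average_significant_xcorr(res)
    if (stats::var(tab$best_lag_ms) > 0)
      out$delay_correlations <-
        delay_metric_correlations(res, metrics[metrics$is_bursting, ])
    out$normalized_max_r <- normalize_by_session_min(tab$max_r)
    out
  })

  layers <- stage("layers", {
    pop_psth <- compute_psth(
      spike_train("population",
                  sort(unlist(lapply(bursting_units, `[[`, "spikes_s"))),
                  bursting_units[[1]]$span_s),
      hits, window_ms = c(-200, 400), bin_ms = 5, smoothing_sigma_ms = 10)
    peak <- burst_peak_time(pop_psth)
    odd_ev <- events[events$tone == "oddball", ]
    std_ev <- events[events$tone == "standard", ]
    p_odd <- extract_layer_profile(rec, odd_ev, peak)
    p_std <- extract_layer_profile(rec, std_ev, peak)
    sim <- if (np > 0)
      profile_permutation_p(p_odd, p_std, n_perm = np,
                            seed = derive_seed(config$seed, "layers"))
    else list(similarity = cosine_similarity(p_odd, p_std),
              p_two_sided = NULL)
    overall <- extract_layer_profile(rec, events, peak)
    list(burst_peak_ms = peak, oddball_profile = p_odd$values,
         standard_profile = p_std$values,
         similarity = sim$similarity, p = sim$p_two_sided,
         overall_profile_normalized = normalize_profile(overall)$values)
  })

  stim <- if (config$with_stim && !is.null(session$stim_recording))
    stage("stim", {
      overall <- extract_layer_profile(rec, events, layers$burst_peak_ms)
      ser <- stim_similarity_series(
        session$stim_recording, session$stim, overall, n_perm = np,
        alpha = config$stim_alpha, seed = derive_seed(config$seed, "stim"))
      list(onset_ms = ser$onset_ms, peak_scalar_projection = ser$peak_abs,
           series = list(t_ms = ser$t_ms, s_norm = ser$s_norm,
                         lo = ser$lo, hi = ser$hi))
    })
  else NULL

  report <- list(schema_version = config$schema_version, seed = config$seed,
                 config = config, behavioral = behavioral,
                 burst = metrics, n_units = length(session$spikes),
                 n_bursting = sum(metrics$is_bursting),
                 choice_probability = cp, coupling = coupling,
                 xcorr = xcorr, layers = layers, stim = stim)
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  report
}
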