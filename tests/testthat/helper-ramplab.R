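# Shared fixture builders. Everything is generated in code; no stored data.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A minimal hand-written trial table (cue-relative press times).
toy_trials <- function(press_lists, interval_type = "FI12", iti = 8,
                       cue_gap = NULL) {
  n <- length(press_lists)
  dur <- if (interval_type == "FI3") 3 else 12
  rewards <- vapply(press_lists, function(p) {
    r <- p[p > dur][1]
    if (is.na(r)) dur + 1 else r
  }, numeric(1))
  gap <- cue_gap %||% (dur + 10)
  tibble::tibble(
    trial_id = seq_len(n),
    interval_type = interval_type,
    cue_onset = iti + (seq_len(n) - 1) * gap,
    interval_duration = dur,
    press_times = press_lists,
    reward_time = rewards,
    iti_before = iti
  )
}

# Deterministic regular trial grid for spike-based tests (no behavior).
regular_trials <- function(n_trials, interval_type = "FI12", gap_extra = 10) {
  dur <- if (interval_type == "FI3") 3 else 12
  toy_trials(replicate(n_trials, numeric(0), simplify = FALSE),
             interval_type = interval_type, cue_gap = dur + gap_extra)
}

# Homogeneous-Poisson spike train over the whole session span.
poisson_spikes <- function(rate, span) {
  sort(runif(rpois(1, rate * span), 0, span))
}

# Units tibble wrapper for hand-built spike trains.
toy_units <- function(spike_list, area = "MFC") {
  n <- length(spike_list)
  wf <- simulate_waveform("putative_MSN", noise_sd = 0, seed = 1)
  tibble::tibble(
    unit_id = sprintf("u%02d", seq_len(n)),
    area = rep_len(area, n),
    spike_times = spike_list,
    wf_samples = replicate(n, wf$samples, simplify = FALSE),
    wf_dt_ms = wf$dt_ms,
    unit_class = NA_character_
  )
}

# A small, fast generator configuration for integration-style tests.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_animals = 1, n_units_per_area = 4, days = 0:1,
         n_trials_per_interval = 10, seed = 99L),
    list(...)
  )
  do.call(generator_config, args)
}

# Noiseless "perfectly informative" ensemble: each unit's rate profile is a
# deterministic injective function of time, identical on every trial. Built
# directly as a feature array for decoder limit tests.
injective_feature_array <- function(n_units, n_trials, T = 12,
                                    config = decoder_config()) {
  centers <- seq(-config$pad + config$bin / 2, T + config$pad - config$bin / 2,
                 by = config$bin)
  nb <- length(centers)
  arr <- array(0, dim = c(n_units, nb, n_trials))
  for (u in seq_len(n_units)) {
    # distinct monotone profiles; jointly injective over bins
    prof <- 5 + u * (seq_len(nb) / nb) * 3
    for (j in seq_len(n_trials)) arr[u, , j] <- prof
  }
  list(features = arr, bin_centers = centers)
}
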