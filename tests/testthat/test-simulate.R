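test_that("day-0 sessions contain only FI12 trials, in the configured number", {
  cfg <- generator_config(n_trials_per_interval = 50, seed = 3L)
  tr <- simulate_trials(cfg, 0, seed = 5L)
  expect_identical(nrow(tr$trials), 50L)
  expect_true(all(tr$trials$interval_type == "FI12"))
  expect_true(all(tr$trials$iti_before %in% c(6, 8, 10, 12)))
  # two-interval days interleave both types
  tr1 <- simulate_trials(cfg, 1, seed = 5L)
  expect_identical(unname(table(tr1$trials$interval_type)["FI3"]), 50L)
  expect_identical(unname(table(tr1$trials$interval_type)["FI12"]), 50L)
  expect_error(simulate_trials(cfg, 7))
})

test_that("trial generation is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 9L)
  a <- simulate_trials(cfg, 1, seed = 123L)
  b <- simulate_trials(cfg, 1, seed = 123L)
  expect_identical(a, b)
})

test_that("identical config and seed give byte-identical serialized sessions", {
  cfg <- quick_config()
  s1 <- simulate_session(cfg, "A1", 1)
  s2 <- simulate_session(cfg, "A1", 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_session(s1$session, d1)
  write_session(s2$session, d2)
  for (f in c("trials.csv", "units.csv", "spikes.csv", "session.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("start-time variability is scalar: equal CVs across interval types", {
  cfg <- generator_config(n_trials_per_interval = 500, response_cv = 0.15,
                          seed = 21L)
  tr <- simulate_trials(cfg, 1, seed = 77L)
  cvs <- vapply(split(tr$truth$start_time, tr$truth$interval_type),
                function(s) sd(s) / mean(s), numeric(1))
  expect_lt(abs(cvs[["FI3"]] - cvs[["FI12"]]), 0.05)
})

test_that("untuned units fire at the configured baseline rate", {
  cfg <- generator_config(n_trials_per_interval = 100, baseline_rate = 5,
                          seed = 2L)
  tr <- simulate_trials(cfg, 0, seed = 31L)
  res <- simulate_unit(cfg, "untuned", "MFC", tr$trials, seed = 32L)
  counts <- vapply(seq_len(nrow(tr$trials)), function(i) {
    length(trial_relative_spikes(res$unit$spike_times[[1]],
                                 tr$trials$cue_onset[i], c(0, 12)))
  }, numeric(1))
  expect_lt(abs(mean(counts) / 12 - 5), 0.5)
})

test_that("every unit's empirical rate sits within its Poisson interval", {
  cfg <- quick_config(n_trials_per_interval = 20)
  res <- simulate_session(cfg, "A1", 1)
  span <- session_span(res$session)
  for (i in seq_len(nrow(res$session$units))) {
    n <- length(res$session$units$spike_times[[i]])
    tc <- res$truth$units[i, ]
    # generous bound: baseline everywhere; modulation adds at most the
    # in-interval means computed in the ground truth
    lo <- cfg$baseline_rate * span * 0.5
    hi <- (max(tc$mean_rate_fi3, tc$mean_rate_fi12) +
             cfg$response_bump_amp) * span
    expect_gt(n, lo - 3 * sqrt(hi))
    expect_lt(n, hi + 3 * sqrt(hi))
  }
})

test_that("planted slope ratio between intervals is exact by construction", {
  cfg <- generator_config(slope_scale_fi3 = 4, seed = 5L)
  tr <- simulate_trials(cfg, 1, seed = 6L)
  res <- simulate_unit(cfg, "ramp_up", "MFC", tr$trials, seed = 7L)
  expect_identical(res$truth$slope_fi3 / res$truth$slope_fi12, 4)
  res_dn <- simulate_unit(cfg, "ramp_down", "DMS", tr$trials, seed = 8L)
  expect_identical(abs(res_dn$truth$slope_fi3) / abs(res_dn$truth$slope_fi12), 4)
})

test_that("fitted slope recovers the planted ramp at 200 trials", {
  cfg <- generator_config(n_trials_per_interval = 200, baseline_rate = 2,
                          ramp_slope_fi12 = 1, seed = 13L)
  tr <- simulate_trials(cfg, 0, seed = 14L)
  res <- simulate_unit(cfg, "ramp_up", "MFC", tr$trials, seed = 15L)
  fit <- fit_ramp_slope(res$unit$spike_times[[1]], tr$trials)
  expect_lt(abs(fit$slope - 1), 0.1)
})

test_that("a unit with zero intensity everywhere is rejected", {
  cfg <- generator_config(baseline_rate = 0, seed = 1L)
  tr <- simulate_trials(cfg, 0, seed = 2L)
  expect_error(simulate_unit(cfg, "untuned", "MFC", tr$trials, seed = 3L),
               class = "ramplab_degenerate_unit")
  expect_error(simulate_unit(cfg, "ramp_down", "MFC", tr$trials, seed = 3L),
               class = "ramplab_degenerate_unit")
})

test_that("noiseless templates have their analytic half-peak width", {
  for (cls in c("putative_MSN", "putative_interneuron")) {
    wf <- simulate_waveform(cls, noise_sd = 0, seed = 1L)
    m <- waveform_metrics(wf$samples, wf$dt_ms)
    expect_lt(abs(m$half_peak_width_ms - wf$fwhm_ms), wf$dt_ms)
  }
})

test_that("waveform generation is reproducible under a fixed seed", {
  a <- simulate_waveform("putative_MSN", seed = 42L)
  b <- simulate_waveform("putative_MSN", seed = 42L)
  expect_identical(a, b)
})

test_that("tuning classes are allocated deterministically by fraction", {
  cfg <- generator_config(n_units_per_area = 20, ramping_fraction = 0.5,
                          interval_mod_fraction = 0.2,
                          response_locked_fraction = 0.1,
                          n_trials_per_interval = 4, days = 0:1, seed = 4L)
  res <- simulate_session(cfg, "A1", 1)
  tu <- res$truth$units
  counts <- table(tu$area, tu$tuning_class %in% c("ramp_up", "ramp_down"))
  expect_identical(unname(counts["MFC", "TRUE"]), 10L)
  expect_identical(unname(counts["DMS", "TRUE"]), 10L)
  expect_identical(nrow(res$session$units), 40L)
  # every generated unit has exactly one primary tuning class
  expect_true(all(tu$tuning_class %in% c("ramp_up", "ramp_down",
                                         "interval_modulated",
                                         "response_locked", "untuned")))
})

test_that("a generated session passes the full invariant suite and I/O", {
  cfg <- quick_config()
  res <- simulate_session(cfg, "A2", 1)
  expect_silent(validate_session(res$session))
  dir <- withr::local_tempdir()
  write_session(res$session, dir)
  back <- read_session(dir)
  expect_identical(back$units$spike_times, res$session$units$spike_times)
})
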