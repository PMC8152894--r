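#' Configuration for the synthetic session generator
#'
#' The generator emulates the structure of a two-interval fixed-interval
#' experiment: 7 animals, one FI12-only session (day 0) followed by three
#' sessions with randomly intermixed FI12 and FI3 trials (days 1--3),
#' intertrial intervals drawn from 6/8/10/12 s, approximately scalar response
#' variability (one `response_cv` for both intervals), and ensembles
#' containing ramping, interval-modulated, response-locked and untuned units
#' with medium-spiny-neuron-like or interneuron-like waveforms.
#'
#' @param n_animals Number of animals (default 7).
#' @param n_units_per_area Units recorded per area per session (default 8,
#'   in the range of typical per-animal yields).
#' @param days Subset of 0:3.
#' @param n_trials_per_interval Trials per interval type per session.
#' @param ramping_fraction,interval_mod_fraction,response_locked_fraction
#'   Fractions of units per area assigned to each tuning class (remainder
#'   untuned). `interval_mod_fraction` may be a named vector
#'   `c(MFC = ..., DMS = ...)` to make interval modulation area-dependent.
#' @param baseline_rate Baseline firing rate, Hz.
#' @param ramp_slope_fi12 Ramp slope magnitude on FI12 trials, Hz/s.
#' @param slope_scale_fi3 Multiplier (> 1) applied to the FI12 slope on FI3
#'   trials, so ramps are steeper on the short interval; the default 4 is the
#'   12 s / 3 s interval ratio, the scaling a drift-diffusion account of
#'   interval timing predicts.
#' @param response_cv Coefficient of variation of the behavioral start time
#'   (identical for both intervals: the scalar property).
#' @param mean_response_fraction Fraction of the interval at which responding
#'   starts on average (default 0.8, so mean FI12 start is 9.6 s).
#' @param press_rate_low,press_rate_high Lever-press rates (Hz) before and
#'   after the behavioral start time.
#' @param interval_mod_offset Rate offset (Hz) added on one interval type for
#'   interval-modulated units; default equals `baseline_rate`.
#' @param response_bump_amp Peak rate increase (Hz) around each press for
#'   response-locked units; default equals `baseline_rate`.
#' @param response_bump_sd SD of the press-locked Gaussian rate bump, s.
#' @param msn_fraction Fraction of DMS units given a broad MSN-like waveform
#'   (the rest are interneuron-like); MFC units are all pyramidal-like.
#' @param refractory_ms Absolute dead time imposed on generated spike trains.
#' @param seed Master seed; fixed seed implies fully reproducible output.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_animals = 7,
                             n_units_per_area = 8,
                             days = 0:3,
                             n_trials_per_interval = 40,
                             ramping_fraction = 0.4,
                             interval_mod_fraction = 0.25,
                             response_locked_fraction = 0.1,
                             baseline_rate = 5,
                             ramp_slope_fi12 = 0.5,
                             slope_scale_fi3 = 4,
                             response_cv = 0.15,
                             mean_response_fraction = 0.8,
                             press_rate_low = 0.05,
                             press_rate_high = 1.0,
                             interval_mod_offset = NULL,
                             response_bump_amp = NULL,
                             response_bump_sd = 0.3,
                             msn_fraction = 0.8,
                             refractory_ms = 2,
                             seed = 42L) {
  cfg <- list(
    n_animals = as.integer(n_animals),
    n_units_per_area = as.integer(n_units_per_area),
    days = as.integer(days),
    n_trials_per_interval = as.integer(n_trials_per_interval),
    ramping_fraction = ramping_fraction,
    interval_mod_fraction = interval_mod_fraction,
    response_locked_fraction = response_locked_fraction,
    baseline_rate = baseline_rate,
    ramp_slope_fi12 = ramp_slope_fi12,
    slope_scale_fi3 = slope_scale_fi3,
    response_cv = response_cv,
    mean_response_fraction = mean_response_fraction,
    press_rate_low = press_rate_low,
    press_rate_high = press_rate_high,
    interval_mod_offset = interval_mod_offset %||% baseline_rate,
    response_bump_amp = response_bump_amp %||% baseline_rate,
    response_bump_sd = response_bump_sd,
    msn_fraction = msn_fraction,
    refractory_ms = refractory_ms,
    seed = as.integer(seed)
  )
  fracs <- c(cfg$ramping_fraction, cfg$interval_mod_fraction,
             cfg$response_locked_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    abort("Tuning-class fractions must lie in [0, 1].")
  }
  if (!all(cfg$days %in% 0:3)) {
    abort("`days` must be a subset of 0:3.")
  }
  assert_scalar_number(cfg$baseline_rate, "baseline_rate")
  if (cfg$baseline_rate < 0) abort("`baseline_rate` must be >= 0.")
  assert_scalar_number(cfg$slope_scale_fi3, "slope_scale_fi3", positive = TRUE)
  structure(cfg, class = c("generator_config", "list"))
}

slope_for_interval <- function(config, interval_type) {
  if (interval_type == "FI3") {
    config$ramp_slope_fi12 * config$slope_scale_fi3
  } else {
    config$ramp_slope_fi12
  }
}

area_mod_fraction <- function(config, area) {
  f <- config$interval_mod_fraction
  if (!is.null(names(f)) && area %in% names(f)) unname(f[[area]]) else unname(f[[1]])
}

# Truncated-normal behavioral start time on (0, T), scalar by construction:
# both mean and SD are proportional to T.
draw_start_time <- function(T, config) {
  mu <- config$mean_response_fraction * T
  sdv <- config$response_cv * mu
  repeat {
    s <- rnorm(1, mu, sdv)
    if (s > 0 && s < T) {
      return(s)
    }
  }
}

# Two-state press process: low-rate Poisson before the start time, high-rate
# after, continuing until the first press after interval end (the rewarded
# press). Times are relative to cue onset.
draw_press_times <- function(start_time, T, config) {
  pre <- numeric(0)
  t <- 0
  repeat {
    t <- t + rexp(1, config$press_rate_low)
    if (t >= start_time) break
    pre <- c(pre, t)
  }
  post <- numeric(0)
  t <- start_time
  repeat {
    t <- t + rexp(1, config$press_rate_high)
    post <- c(post, t)
    if (t > T) break
  }
  list(press_times = c(pre, post), reward_time = post[length(post)])
}

#' Generate the trial table for one synthetic session
#'
#' Day 0 yields FI12 trials only; days 1--3 yield `n_trials_per_interval`
#' trials of each type, randomly interleaved. Each trial gets a behavioral
#' start time drawn from a truncated normal with mean
#' `mean_response_fraction * T` and SD `response_cv` times that mean, then
#' lever presses from a low/high-rate two-state Poisson process; the first
#' press after interval end is the rewarded press and ends the trial.
#'
#' @param config A [generator_config()].
#' @param day Integer in `config$days`.
#' @param seed Optional seed for this call (otherwise the current RNG stream
#'   is used).
#' @return List with `trials` (tibble as in [fi_session()]) and `truth`
#'   (tibble `trial_id`, `start_time` with the planted start times).
#' @export
simulate_trials <- function(config, day, seed = NULL) {
  if (!day %in% config$days) {
    abort(sprintf("Day %s is not in config$days.", day))
  }
  with_seed(seed, {
    types <- if (day == 0L) {
      rep("FI12", config$n_trials_per_interval)
    } else {
      sample(rep(c("FI3", "FI12"), each = config$n_trials_per_interval))
    }
    n <- length(types)
    durations <- ifelse(types == "FI3", 3, 12)
    itis <- sample(c(6, 8, 10, 12), n, replace = TRUE)
    starts <- vapply(durations, draw_start_time, numeric(1), config = config)
    presses <- vector("list", n)
    rewards <- numeric(n)
    cues <- numeric(n)
    clock <- 0
    for (i in seq_len(n)) {
      pr <- draw_press_times(starts[i], durations[i], config)
      presses[[i]] <- pr$press_times
      rewards[i] <- pr$reward_time
      cues[i] <- clock + itis[i]
      clock <- cues[i] + pr$reward_time
    }
    trials <- tibble::tibble(
      trial_id = seq_len(n),
      interval_type = types,
      cue_onset = cues,
      interval_duration = durations,
      press_times = presses,
      reward_time = rewards,
      iti_before = itis
    )
    list(trials = trials, truth = tibble::tibble(trial_id = seq_len(n),
                                                 interval_type = types,
                                                 start_time = starts))
  })
}

# Build the session-clock intensity function for one unit. Returns the
# vectorized rate function and a sharp upper bound for thinning.
make_intensity <- function(tuning_class, modulated_interval, trials, config) {
  base <- config$baseline_rate
  cues <- trials$cue_onset
  durs <- trials$interval_duration
  types <- trials$interval_type
  press_abs <- unlist(purrr::map2(trials$press_times, cues, `+`))
  bump_sd <- config$response_bump_sd
  fn <- function(t) {
    lam <- rep(base, length(t))
    j <- findInterval(t, cues)
    in_int <- j >= 1 & (t - cues[pmax(j, 1)]) <= durs[pmax(j, 1)]
    if (tuning_class %in% c("ramp_up", "ramp_down")) {
      sgn <- if (tuning_class == "ramp_up") 1 else -1
      idx <- which(in_int)
      if (length(idx)) {
        sl <- vapply(types[j[idx]], slope_for_interval, numeric(1), config = config)
        lam[idx] <- lam[idx] + sgn * sl * (t[idx] - cues[j[idx]])
      }
    } else if (tuning_class == "interval_modulated") {
      idx <- which(in_int & types[pmax(j, 1)] == modulated_interval)
      lam[idx] <- lam[idx] + config$interval_mod_offset
    } else if (tuning_class == "response_locked" && length(press_abs)) {
      for (p in press_abs) {
        k <- which(abs(t - p) < 4 * bump_sd)
        if (length(k)) {
          lam[k] <- lam[k] + config$response_bump_amp *
            exp(-(t[k] - p)^2 / (2 * bump_sd^2))
        }
      }
    }
    pmax(lam, 0)
  }
  max_slope_term <- if (tuning_class == "ramp_up") {
    max(vapply(unique(types), function(ty) {
      slope_for_interval(config, ty) * (if (ty == "FI3") 3 else 12)
    }, numeric(1)))
  } else {
    0
  }
  extra <- switch(tuning_class,
    interval_modulated = config$interval_mod_offset,
    response_locked = 2 * config$response_bump_amp,
    0
  )
  list(fn = fn, lambda_max = base + max_slope_term + extra)
}

# Exact inhomogeneous-Poisson sampling by thinning, followed by an absolute
# dead time (refractory period) as expected of a sorted single unit.
sample_inhom_poisson <- function(rate_fn, lambda_max, t_end, refractory_ms) {
  if (lambda_max <= 0) {
    abort("Unit intensity is everywhere zero.", class = "ramplab_degenerate_unit")
  }
  n_cand <- rpois(1, lambda_max * t_end)
  if (n_cand == 0) {
    return(numeric(0))
  }
  cand <- sort(runif(n_cand, 0, t_end))
  keep <- runif(n_cand) < rate_fn(cand) / lambda_max
  st <- cand[keep]
  if (!length(st)) {
    return(st)
  }
  dead <- refractory_ms / 1000
  out <- st[1]
  for (s in st[-1]) {
    if (s - out[length(out)] >= dead) {
      out <- c(out, s)
    }
  }
  out
}

#' Generate one synthetic unit
#'
#' Spikes are drawn from an inhomogeneous Poisson process by thinning (exact,
#' no bin-size artifacts) with intensity `max(0, baseline + class term)`:
#' ramping units add `+/- slope * t` within the interval (FI3 slope =
#' `slope_scale_fi3` times the FI12 slope), interval-modulated units add a
#' rate offset on one interval type only, response-locked units add a
#' Gaussian bump (`response_bump_sd` s) around each press, untuned units are
#' homogeneous. A 2 ms dead time is imposed, as expected of a well-sorted
#' single unit.
#'
#' @param config A [generator_config()].
#' @param tuning_class One of `"ramp_up"`, `"ramp_down"`,
#'   `"interval_modulated"`, `"response_locked"`, `"untuned"`.
#' @param area `"MFC"` or `"DMS"`.
#' @param trials Trial tibble from [simulate_trials()].
#' @param wf_class Waveform class passed to [simulate_waveform()]; default
#'   MSN-like for DMS and pyramidal-like for MFC.
#' @param unit_id Identifier for the unit.
#' @param modulated_interval For interval-modulated units, which interval
#'   carries the offset (default drawn at random).
#' @param seed Optional seed.
#' @return List with `unit` (one-row tibble in [fi_session()] unit format)
#'   and `truth` (one-row tibble of ground-truth tuning parameters).
#' @export
simulate_unit <- function(config, tuning_class, area, trials,
                          wf_class = NULL, unit_id = "u1",
                          modulated_interval = NULL, seed = NULL) {
  classes <- c("ramp_up", "ramp_down", "interval_modulated",
               "response_locked", "untuned")
  if (!tuning_class %in% classes) {
    abort(sprintf("Unknown tuning class '%s'.", tuning_class))
  }
  wf_class <- wf_class %||% if (area == "DMS") "putative_MSN" else "putative_pyramidal"
  with_seed(seed, {
    if (is.null(modulated_interval)) {
      modulated_interval <- sample(c("FI3", "FI12"), 1)
    }
    t_end <- max(trials$cue_onset +
                   pmax(trials$reward_time, trials$interval_duration, na.rm = TRUE)) + 12
    intensity <- make_intensity(tuning_class, modulated_interval, trials, config)
    spikes <- sample_inhom_poisson(intensity$fn, intensity$lambda_max, t_end,
                                   config$refractory_ms)
    wf <- simulate_waveform(wf_class)
    slope_sign <- switch(tuning_class, ramp_up = 1, ramp_down = -1, 0)
    mean_rate_for <- function(ty) {
      T <- if (ty == "FI3") 3 else 12
      r <- config$baseline_rate +
        slope_sign * slope_for_interval(config, ty) * T / 2
      if (tuning_class == "interval_modulated" && ty == modulated_interval) {
        r <- r + config$interval_mod_offset
      }
      max(r, 0)
    }
    unit <- tibble::tibble(
      unit_id = unit_id, area = area, spike_times = list(spikes),
      wf_samples = list(wf$samples), wf_dt_ms = wf$dt_ms,
      unit_class = NA_character_
    )
    truth <- tibble::tibble(
      unit_id = unit_id, area = area, tuning_class = tuning_class,
      wf_class = wf_class,
      modulated_interval = if (tuning_class == "interval_modulated") {
        modulated_interval
      } else {
        NA_character_
      },
      slope_fi12 = slope_sign * slope_for_interval(config, "FI12"),
      slope_fi3 = slope_sign * slope_for_interval(config, "FI3"),
      mean_rate_fi12 = mean_rate_for("FI12"),
      mean_rate_fi3 = mean_rate_for("FI3"),
      wf_fwhm_ms = wf$fwhm_ms, wf_ratio = wf$ratio
    )
    list(unit = unit, truth = truth)
  })
}

#' Generate a synthetic extracellular waveform
#'
#' Biphasic template built as the difference of two Gaussians: a positive
#' peak followed by a slower trough. MSN-like (and pyramidal-like) templates
#' are broad with a high peak-to-trough ratio; interneuron-like templates are
#' narrow with a low ratio. Additive Gaussian noise with SD 2% of the peak.
#'
#' @param wf_class `"putative_MSN"`, `"putative_pyramidal"`, or
#'   `"putative_interneuron"`.
#' @param fwhm_ms Full width at half maximum of the positive peak; default
#'   drawn from the class distribution (MSN/pyramidal mean 0.30 ms,
#'   interneuron mean 0.12 ms).
#' @param ratio Peak-to-trough amplitude ratio; default drawn from the class
#'   distribution (MSN/pyramidal mean 1.6, interneuron mean 0.85).
#' @param noise_sd Noise SD as a fraction of peak amplitude (default 0.02;
#'   set 0 for the noiseless template).
#' @param dt_ms Sampling interval, ms (default 0.025, i.e. 40 kHz).
#' @param seed Optional seed.
#' @return List with `samples`, `dt_ms`, and the true `fwhm_ms` and `ratio`.
#' @export
simulate_waveform <- function(wf_class, fwhm_ms = NULL, ratio = NULL,
                              noise_sd = 0.02, dt_ms = 0.025, seed = NULL) {
  if (!wf_class %in% c("putative_MSN", "putative_pyramidal", "putative_interneuron")) {
    abort(sprintf("Unknown waveform class '%s'.", wf_class))
  }
  broad <- wf_class != "putative_interneuron"
  with_seed(seed, {
    fwhm_ms <- fwhm_ms %||% if (broad) rnorm(1, 0.30, 0.02) else rnorm(1, 0.12, 0.012)
    ratio <- ratio %||% if (broad) rnorm(1, 1.6, 0.08) else rnorm(1, 0.85, 0.07)
    fwhm_ms <- max(fwhm_ms, 4 * dt_ms)
    ratio <- max(ratio, 0.2)
    sig_p <- fwhm_ms / (2 * sqrt(2 * log(2)))
    trough_lag <- if (broad) 0.55 else 0.25
    sig_t <- if (broad) 0.18 else 0.08
    amp <- 100
    t <- seq(0, 1.5, by = dt_ms)
    peak_at <- 0.5
    w <- amp * exp(-(t - peak_at)^2 / (2 * sig_p^2)) -
      (amp / ratio) * exp(-(t - peak_at - trough_lag)^2 / (2 * sig_t^2))
    if (noise_sd > 0) {
      w <- w + rnorm(length(w), 0, noise_sd * amp)
    }
    list(samples = w, dt_ms = dt_ms, fwhm_ms = fwhm_ms, ratio = ratio)
  })
}

# Deterministic allocation of tuning classes to n units.
allocate_classes <- function(n, f_ramp, f_mod, f_resp) {
  n_ramp <- round(f_ramp * n)
  n_mod <- round(f_mod * n)
  n_resp <- round(f_resp * n)
  if (n_ramp + n_mod + n_resp > n) {
    abort("Tuning-class fractions allocate more units than available.")
  }
  c(rep("ramp_up", ceiling(n_ramp / 2)), rep("ramp_down", floor(n_ramp / 2)),
    rep("interval_modulated", n_mod), rep("response_locked", n_resp),
    rep("untuned", n - n_ramp - n_mod - n_resp))
}

#' Generate one full synthetic session with ground truth
#'
#' Composes [simulate_trials()], [simulate_unit()] and [simulate_waveform()]:
#' `n_units_per_area` units per area with tuning classes assigned
#' deterministically by the configured fractions (remainder untuned), DMS
#' waveforms split MSN-like vs interneuron-like by `msn_fraction`.
#'
#' @param config A [generator_config()].
#' @param animal_id Animal label.
#' @param day Day 0--3.
#' @param seed Seed for the session; default derived from `config$seed`,
#'   the animal id and the day, so sessions are independent substreams.
#' @return List with `session` (an [fi_session()]) and `truth` (list of
#'   tibbles `units` and `trials`).
#' @export
simulate_session <- function(config, animal_id = "A1", day = 0L, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, animal_id, day)
  with_seed(seed, {
    tr <- simulate_trials(config, day)
    n <- config$n_units_per_area
    units <- list()
    truths <- list()
    for (area in c("MFC", "DMS")) {
      classes <- allocate_classes(n, config$ramping_fraction,
                                  area_mod_fraction(config, area),
                                  config$response_locked_fraction)
      n_msn <- round(config$msn_fraction * n)
      wf_classes <- if (area == "DMS") {
        c(rep("putative_MSN", n_msn), rep("putative_interneuron", n - n_msn))
      } else {
        rep("putative_pyramidal", n)
      }
      for (i in seq_len(n)) {
        uid <- sprintf("%s_d%d_%s_%02d", animal_id, day, area, i)
        res <- simulate_unit(config, classes[i], area, tr$trials,
                             wf_class = wf_classes[i], unit_id = uid)
        units[[uid]] <- res$unit
        truths[[uid]] <- res$truth
      }
    }
    session <- fi_session(tr$trials, dplyr::bind_rows(units), animal_id, day)
    list(session = session,
         truth = list(units = dplyr::bind_rows(truths), trials = tr$truth))
  })
}

#' Generate a full synthetic experiment (all animals and days)
#'
#' @param config A [generator_config()].
#' @return List of elements named `<animal>_d<day>`, each as returned by
#'   [simulate_session()].
#' @export
simulate_experiment <- function(config) {
  out <- list()
  for (a in seq_len(config$n_animals)) {
    animal_id <- sprintf("A%d", a)
    for (day in config$days) {
      out[[sprintf("%s_d%d", animal_id, day)]] <-
        simulate_session(config, animal_id, day)
    }
  }
  out
}
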