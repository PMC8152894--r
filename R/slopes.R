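#' Firing-rate slope over the interval for one unit
#'
#' Spike counts in 0.1 s bins are averaged across trials of one interval type
#' and converted to rates; the slope of rate versus time (Hz/s) comes from an
#' identity-link least-squares fit, with the p-value from the regression
#' t-test of slope = 0. Slope magnitude (`abs_slope`) is the quantity
#' compared across intervals, since units ramp up or down interchangeably.
#' A Poisson count-GLM alternative (identity link on summed counts with a
#' log-exposure offset) is available via `method = "poisson"`.
#'
#' @param spike_times Spike times on the session clock, s.
#' @param trials Trial tibble, all of one interval type (at least 2 trials;
#'   10+ recommended for a stable p-value).
#' @param bin Bin width, s (default 0.1).
#' @param method `"lm"` (default) or `"poisson"`.
#' @return Tibble with `slope`, `intercept`, `p_value`, `abs_slope`,
#'   `n_trials`.
#' @export
fit_ramp_slope <- function(spike_times, trials, bin = 0.1,
                           method = c("lm", "poisson")) {
  method <- match.arg(method)
  ty <- unique(trials$interval_type)
  if (length(ty) != 1L) {
    abort("All trials must share one interval type.")
  }
  if (nrow(trials) < 2L) {
    abort("Need at least 2 trials to fit a slope.")
  }
  T <- trials$interval_duration[1]
  edges <- seq(0, T, by = bin)
  centers <- edges[-1] - bin / 2
  counts <- matrix(0, nrow(trials), length(centers))
  for (i in seq_len(nrow(trials))) {
    rel <- trial_relative_spikes(spike_times, trials$cue_onset[i], c(0, T))
    if (length(rel)) {
      counts[i, ] <- tabulate(pmin(floor(rel / bin) + 1L, length(centers)),
                              nbins = length(centers))
    }
  }
  if (all(counts == 0)) {
    abort("Unit fired no spikes in the interval; slope undefined.",
          class = "ramplab_degenerate_fit")
  }
  if (method == "lm") {
    y <- colMeans(counts) / bin
    fit <- lm(y ~ centers)
    sm <- summary(fit)$coefficients
    slope <- sm["centers", "Estimate"]
    p <- sm["centers", "Pr(>|t|)"]
    intercept <- sm["(Intercept)", "Estimate"]
  } else {
    tot <- colSums(counts)
    expo <- nrow(trials) * bin
    fit <- glm(tot ~ centers, family = poisson(link = "log"))
    sm <- summary(fit)$coefficients
    # transform log-link slope to Hz/s at the mean rate for interpretability
    mean_rate <- mean(tot) / expo
    slope <- sm["centers", "Estimate"] * mean_rate
    p <- sm["centers", "Pr(>|z|)"]
    intercept <- exp(sm["(Intercept)", "Estimate"]) / expo
  }
  tibble::tibble(slope = slope, intercept = intercept, p_value = p,
                 abs_slope = abs(slope), n_trials = nrow(trials))
}

#' Ramping flag from a slope fit
#'
#' A unit is called ramping when its slope differs from zero at level
#' `alpha` (default 0.05, the same criterion used for interval modulation).
#'
#' @param slope_fit Tibble from [fit_ramp_slope()] (vectorized over rows).
#' @param alpha Significance level.
#' @return Logical vector.
#' @export
classify_ramping <- function(slope_fit, alpha = 0.05) {
  slope_fit$p_value < alpha
}

#' Slopes and ramping flags for every unit in a session
#'
#' @param session An [fi_session()].
#' @param interval_type `"FI3"` or `"FI12"`.
#' @param bin Bin width, s.
#' @param alpha Ramping significance level.
#' @return Tibble with one row per unit: `unit_id`, `area`, `interval_type`,
#'   slope fit columns, and `ramping`.
#' @export
session_ramp_slopes <- function(session, interval_type, bin = 0.1, alpha = 0.05) {
  trials <- dplyr::filter(session$trials, .data$interval_type == !!interval_type)
  un <- session$units
  rows <- purrr::map(seq_len(nrow(un)), function(i) {
    fit <- tryCatch(
      fit_ramp_slope(un$spike_times[[i]], trials, bin),
      ramplab_degenerate_fit = function(e) {
        tibble::tibble(slope = NA_real_, intercept = NA_real_,
                       p_value = NA_real_, abs_slope = NA_real_,
                       n_trials = nrow(trials))
      }
    )
    dplyr::bind_cols(
      tibble::tibble(unit_id = un$unit_id[i], area = un$area[i],
                     interval_type = interval_type), fit
    )
  })
  out <- dplyr::bind_rows(rows)
  out$ramping <- !is.na(out$p_value) & classify_ramping(out, alpha)
  out
}

#' Screen one unit for interval-dependent firing
#'
#' The per-trial in-interval spike count is modeled as a Poisson outcome with
#' the interval type as predictor and the log interval duration as exposure
#' offset, so the tested effect is a rate difference between FI3 and FI12
#' trials. A unit is interval-modulated when the interval effect has
#' `p < alpha`.
#'
#' @param spike_times Spike times on the session clock, s.
#' @param trials Trial tibble containing both interval types.
#' @param alpha Significance level (default 0.05).
#' @param min_trials Minimum trials per interval type (default 10); fewer
#'   yields an `NA` result.
#' @return Tibble with `interval_effect_p`, `modulated`, `rate_fi3`,
#'   `rate_fi12`.
#' @export
screen_interval_modulation <- function(spike_times, trials, alpha = 0.05,
                                       min_trials = 10) {
  n3 <- sum(trials$interval_type == "FI3")
  n12 <- sum(trials$interval_type == "FI12")
  if (n3 < min_trials || n12 < min_trials) {
    return(tibble::tibble(interval_effect_p = NA_real_, modulated = NA,
                          rate_fi3 = NA_real_, rate_fi12 = NA_real_))
  }
  counts <- vapply(seq_len(nrow(trials)), function(i) {
    length(trial_relative_spikes(spike_times, trials$cue_onset[i],
                                 c(0, trials$interval_duration[i])))
  }, numeric(1))
  df <- tibble::tibble(count = counts,
                       interval = factor(trials$interval_type,
                                         levels = c("FI12", "FI3")),
                       dur = trials$interval_duration)
  fit <- glm(count ~ interval + offset(log(dur)), family = poisson(), data = df)
  p <- summary(fit)$coefficients["intervalFI3", "Pr(>|z|)"]
  tibble::tibble(
    interval_effect_p = p,
    modulated = p < alpha,
    rate_fi3 = sum(counts[df$interval == "FI3"]) / (3 * n3),
    rate_fi12 = sum(counts[df$interval == "FI12"]) / (12 * n12)
  )
}

#' Interval-modulation screen for every unit in a session
#'
#' @param session An [fi_session()] with both interval types.
#' @param alpha Significance level.
#' @param min_trials Minimum trials per interval type.
#' @param slopes Optional result of [session_ramp_slopes()] (either interval)
#'   used to fill the `also_ramping` flag; when `NULL`, slopes are computed
#'   on both intervals and a unit is `also_ramping` when either is ramping.
#' @return Tibble with one row per unit: screen columns plus `also_ramping`.
#' @export
session_interval_modulation <- function(session, alpha = 0.05, min_trials = 10,
                                        slopes = NULL) {
  un <- session$units
  rows <- purrr::map(seq_len(nrow(un)), function(i) {
    dplyr::bind_cols(
      tibble::tibble(unit_id = un$unit_id[i], area = un$area[i]),
      screen_interval_modulation(un$spike_times[[i]], session$trials,
                                 alpha, min_trials)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(slopes)) {
    slopes <- dplyr::bind_rows(
      session_ramp_slopes(session, "FI3", alpha = alpha),
      session_ramp_slopes(session, "FI12", alpha = alpha)
    )
  }
  ramp_any <- dplyr::summarise(dplyr::group_by(slopes, .data$unit_id),
                               also_ramping = any(.data$ramping), .groups = "drop")
  dplyr::left_join(out, ramp_any, by = "unit_id")
}
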