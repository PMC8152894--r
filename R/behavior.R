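#' Response-time table for a set of trials
#'
#' @param trials Trial tibble (see [fi_session()]).
#' @param scope `"all_presses"` (default; one row per in-interval press, the
#'   convention used for response-time models and plots) or `"first_press"`
#'   (one row per trial with at least one in-interval press).
#' @return Tibble with `trial_id`, `interval_type`, `response_time` (s from
#'   cue onset).
#' @export
response_times <- function(trials, scope = c("all_presses", "first_press")) {
  scope <- match.arg(scope)
  if (!nrow(trials)) {
    abort("`trials` must be non-empty.")
  }
  rows <- purrr::map(seq_len(nrow(trials)), function(i) {
    p <- trials$press_times[[i]]
    p <- p[p <= trials$interval_duration[i]]
    if (!length(p)) {
      return(NULL)
    }
    if (scope == "first_press") {
      p <- p[1]
    }
    tibble::tibble(trial_id = trials$trial_id[i],
                   interval_type = trials$interval_type[i],
                   response_time = p)
  })
  dplyr::bind_rows(rows)
}

#' Single-trial start time from the low/high press-rate change point
#'
#' Adapts the classic single-trial analysis of timed responding to
#' fixed-interval trials, where only the start transition exists (the trial
#' ends at reward). Candidate change points are the press times `s`; the
#' estimator maximizes
#' `index(s) = s * (r_overall - r_pre(s)) + (T - s) * (r_post(s) - r_overall)`
#' where `r_pre`/`r_post` are the press rates before/after `s` (the press at
#' `s` counts as post) and `r_overall` the whole-trial press rate over
#' `[0, T]`. Ties break toward the earliest candidate. Note the estimate is a
#' press time: it sits at or after the first press of the high-rate state, so
#' it carries a one-sided delay of order one high-rate inter-press interval
#' relative to the latent transition.
#'
#' @param press_times Press times within the trial, s from cue onset; presses
#'   after `T` (e.g. the rewarded press) are allowed and contribute as
#'   context but are not candidates.
#' @param T Interval duration, s.
#' @param min_presses Minimum number of presses for a defined estimate
#'   (default 2); below this the result is `NA`.
#' @return Tibble with `start_time`, `index_value`, `n_presses`.
#' @export
start_time_single_trial <- function(press_times, T, min_presses = 2) {
  assert_scalar_number(T, "T", positive = TRUE)
  p_all <- sort(press_times)
  if (length(p_all) < min_presses) {
    return(tibble::tibble(start_time = NA_real_, index_value = NA_real_,
                          n_presses = length(p_all)))
  }
  p <- p_all[p_all <= T]
  if (!length(p)) {
    return(tibble::tibble(start_time = NA_real_, index_value = NA_real_,
                          n_presses = length(p_all)))
  }
  r_overall <- length(p) / T
  idx <- vapply(p, function(s) {
    r_pre <- sum(p < s) / s
    r_post <- if (s < T) sum(p >= s) / (T - s) else Inf
    s * (r_overall - r_pre) + (T - s) * (r_post - r_overall)
  }, numeric(1))
  best <- which.max(idx) # ties: which.max returns the earliest
  tibble::tibble(start_time = p[best], index_value = idx[best],
                 n_presses = length(p_all))
}

#' Start times for every trial in a table
#'
#' @param trials Trial tibble.
#' @param min_presses Passed to [start_time_single_trial()].
#' @return Tibble with `trial_id`, `interval_type`, `start_time`,
#'   `index_value`, `n_presses`; trials with too few presses carry `NA`.
#' @export
start_times <- function(trials, min_presses = 2) {
  rows <- purrr::map(seq_len(nrow(trials)), function(i) {
    res <- start_time_single_trial(trials$press_times[[i]],
                                   trials$interval_duration[i], min_presses)
    dplyr::bind_cols(tibble::tibble(trial_id = trials$trial_id[i],
                                    interval_type = trials$interval_type[i]), res)
  })
  dplyr::bind_rows(rows)
}

#' Coefficient of variation of start times
#'
#' The scalar property of interval timing predicts a constant CV (sample SD
#' over mean, n-1 denominator) across interval durations.
#'
#' @param x Numeric vector of start times (NAs dropped), or a tibble from
#'   [start_times()] — then one row per `interval_type` is returned.
#' @return Tibble with `n`, `mean`, `sd`, `cv` (and `interval_type` when the
#'   input is a start-time table).
#' @export
cv_start_times <- function(x) {
  if (is.data.frame(x)) {
    return(dplyr::bind_rows(lapply(split(x, x$interval_type), function(d) {
      dplyr::bind_cols(tibble::tibble(interval_type = d$interval_type[1]),
                       cv_start_times(d$start_time))
    })))
  }
  v <- x[!is.na(x)]
  if (length(v) < 2) {
    abort("Need at least 2 defined start times for a CV.")
  }
  m <- mean(v)
  if (m == 0) {
    abort("Mean start time is zero; CV undefined.")
  }
  s <- sd(v)
  tibble::tibble(n = length(v), mean = m, sd = s, cv = s / m)
}
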