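#' Waveform shape metrics
#'
#' Computes the two features used to separate striatal medium spiny neurons
#' from interneurons: the peak-to-trough amplitude ratio
#' (`|max| / |min|`) and the half-peak width — the time between the two
#' crossings of half the peak amplitude around the peak, with linear
#' interpolation between samples.
#'
#' @param samples Numeric vector of waveform amplitudes (at least 8 samples).
#' @param dt_ms Sampling interval in milliseconds.
#' @return Tibble with `peak_trough_ratio` and `half_peak_width_ms`.
#' @export
waveform_metrics <- function(samples, dt_ms) {
  if (length(samples) < 8L) {
    abort("Waveform must have at least 8 samples.", class = "ramplab_metric_error")
  }
  assert_scalar_number(dt_ms, "dt_ms", positive = TRUE)
  pk <- max(samples)
  tr <- min(samples)
  if (!(pk > 0 && tr < 0)) {
    abort("Waveform is not biphasic (needs a positive peak and a negative trough).",
          class = "ramplab_metric_error")
  }
  ratio <- abs(pk) / abs(tr)
  ip <- which.max(samples)
  half <- pk / 2
  # left crossing
  left <- NA_real_
  for (i in seq(ip, 2L)) {
    if (samples[i - 1] <= half && samples[i] > half) {
      frac <- (half - samples[i - 1]) / (samples[i] - samples[i - 1])
      left <- (i - 1) + frac
      break
    }
  }
  right <- NA_real_
  for (i in seq(ip, length(samples) - 1L)) {
    if (samples[i] > half && samples[i + 1] <= half) {
      frac <- (samples[i] - half) / (samples[i] - samples[i + 1])
      right <- i + frac
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    abort("Peak does not fall to half amplitude on both sides within the window.",
          class = "ramplab_metric_error")
  }
  tibble::tibble(
    peak_trough_ratio = ratio,
    half_peak_width_ms = (right - left) * dt_ms
  )
}

#' Thresholds for unit screening and waveform classification
#'
#' @param min_rate Minimum mean firing rate for inclusion, Hz (default 0.1:
#'   units at or below this rate are excluded).
#' @param min_refractory_ms Minimum interspike interval expected of a single
#'   unit, ms (default 2).
#' @param max_violation_fraction Tolerated fraction of interspike intervals
#'   below `min_refractory_ms` (default 0.01; a consistent refractory period
#'   tolerates rare violations).
#' @param width_boundary_ms Half-peak-width boundary between interneuron-like
#'   (narrow) and MSN-like (broad) waveforms, ms.
#' @param ratio_boundary Peak-to-trough-ratio boundary.
#' @return List of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(min_rate = 0.1, min_refractory_ms = 2,
                                  max_violation_fraction = 0.01,
                                  width_boundary_ms = 0.20, ratio_boundary = 1.2) {
  for (nm in c("min_rate", "min_refractory_ms", "width_boundary_ms", "ratio_boundary")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  structure(list(min_rate = min_rate, min_refractory_ms = min_refractory_ms,
                 max_violation_fraction = max_violation_fraction,
                 width_boundary_ms = width_boundary_ms,
                 ratio_boundary = ratio_boundary),
            class = c("classifier_thresholds", "list"))
}

#' Screen a unit for inclusion
#'
#' Excludes units whose mean rate over the session is at or below
#' `min_rate` (0.1 Hz by default) or whose interspike-interval histogram
#' violates the refractory criterion (more than `max_violation_fraction` of
#' ISIs shorter than `min_refractory_ms`).
#'
#' @param spike_times Ascending spike times, s.
#' @param span Recording span, s (see [session_span()]).
#' @param thresholds A [classifier_thresholds()].
#' @return Tibble with `included` (logical), `reason` (`NA`, `"rate"` or
#'   `"refractory"`), `mean_rate_hz`, `isi_violation_fraction`.
#' @export
screen_unit <- function(spike_times, span, thresholds = classifier_thresholds()) {
  assert_scalar_number(span, "span", positive = TRUE)
  rate <- length(spike_times) / span
  isi <- diff(spike_times)
  viol <- if (length(isi)) mean(isi < thresholds$min_refractory_ms / 1000) else 0
  if (rate <= thresholds$min_rate) {
    res <- list(FALSE, "rate")
  } else if (viol > thresholds$max_violation_fraction) {
    res <- list(FALSE, "refractory")
  } else {
    res <- list(TRUE, NA_character_)
  }
  tibble::tibble(included = res[[1]], reason = res[[2]],
                 mean_rate_hz = rate, isi_violation_fraction = viol)
}

#' Classify a unit from its waveform metrics
#'
#' DMS units with broad, high-ratio waveforms (half-peak width and
#' peak-to-trough ratio both at or above their boundaries) are putative
#' medium spiny neurons; other DMS units are putative interneurons. MFC
#' units are labelled putative pyramidal neurons (cortical interneurons are
#' assumed removed at spike sorting).
#'
#' @param metrics One-row data frame from [waveform_metrics()].
#' @param area `"MFC"` or `"DMS"`.
#' @param thresholds A [classifier_thresholds()].
#' @return Character scalar: `"putative_MSN"`, `"putative_interneuron"`, or
#'   `"putative_pyramidal"`.
#' @export
classify_unit <- function(metrics, area, thresholds = classifier_thresholds()) {
  if (area == "MFC") {
    return("putative_pyramidal")
  }
  if (metrics$half_peak_width_ms >= thresholds$width_boundary_ms &&
      metrics$peak_trough_ratio >= thresholds$ratio_boundary) {
    "putative_MSN"
  } else {
    "putative_interneuron"
  }
}

#' Screen and classify every unit in a session
#'
#' Applies [waveform_metrics()], [screen_unit()] and [classify_unit()] to
#' each unit and returns the unit table with `included`, `reason`,
#' `unit_class` and metric columns filled in.
#'
#' @param session An [fi_session()].
#' @param thresholds A [classifier_thresholds()].
#' @return Tibble: the session's unit table plus screening/classification
#'   columns.
#' @export
classify_session_units <- function(session, thresholds = classifier_thresholds()) {
  un <- session$units
  span <- session_span(session)
  out <- purrr::map(seq_len(nrow(un)), function(i) {
    m <- waveform_metrics(un$wf_samples[[i]], un$wf_dt_ms[i])
    scr <- screen_unit(un$spike_times[[i]], span, thresholds)
    cls <- if (scr$included) classify_unit(m, un$area[i], thresholds) else "excluded"
    dplyr::bind_cols(
      tibble::tibble(unit_id = un$unit_id[i], area = un$area[i]),
      m, scr, tibble::tibble(unit_class = cls)
    )
  })
  dplyr::bind_rows(out)
}
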