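#' Construct a recording-session object
#'
#' A session bundles one animal-day of a fixed-interval timing experiment:
#' a trial table, a unit table, and per-unit spike trains. All analysis
#' functions in the package consume these objects (or the tibbles inside
#' them). Times inside the trial table (`press_times`, `reward_time`) are
#' seconds relative to cue onset; `cue_onset` and `spike_times` are on the
#' session clock.
#'
#' @param trials Tibble with columns `trial_id` (integer), `interval_type`
#'   (`"FI3"` or `"FI12"`), `cue_onset` (s, session clock), `interval_duration`
#'   (3 or 12 s), `press_times` (list column of ascending press times, s
#'   relative to cue), `reward_time` (s relative to cue, `NA` if unrewarded),
#'   and `iti_before` (s, one of 6/8/10/12).
#' @param units Tibble with columns `unit_id`, `area` (`"MFC"` or `"DMS"`),
#'   `spike_times` (list column, ascending, session clock), `wf_samples`
#'   (list column of waveform amplitudes), `wf_dt_ms` (sampling interval, ms),
#'   and optionally `peak_trough_ratio`, `half_peak_width_ms`, `unit_class`.
#' @param animal_id Character scalar.
#' @param day Integer 0--3; day 0 is the single-interval (FI12-only) session.
#' @param validate Run [validate_session()]? Default `TRUE`.
#'
#' @return An object of class `fi_session`.
#' @export
fi_session <- function(trials, units, animal_id, day, validate = TRUE) {
  trials <- tibble::as_tibble(trials)
  units <- tibble::as_tibble(units)
  if (!"unit_class" %in% names(units)) {
    units$unit_class <- NA_character_
  }
  x <- structure(
    list(
      trials = trials,
      units = units,
      animal_id = as.character(animal_id),
      day = as.integer(day)
    ),
    class = "fi_session"
  )
  if (validate) validate_session(x)
  x
}

#' @exportS3Method base::print
print.fi_session <- function(x, ...) {
  cat(sprintf(
    "<fi_session> animal %s, day %d: %d trials (%s), %d units (%s)\n",
    x$animal_id, x$day, nrow(x$trials),
    paste(sprintf("%s: %d", names(table(x$trials$interval_type)),
                  as.integer(table(x$trials$interval_type))), collapse = ", "),
    nrow(x$units),
    paste(sprintf("%s: %d", names(table(x$units$area)),
                  as.integer(table(x$units$area))), collapse = ", ")
  ))
  invisible(x)
}

#' Validate a session against the domain invariants
#'
#' Checks the structural invariants assumed by every downstream analysis:
#' ascending press and spike times, legal interval durations (3 or 12 s),
#' rewards at or after interval end, intertrial intervals drawn from
#' 6/8/10/12 s, FI12-only trials on day 0, and non-overlapping trials.
#'
#' @param session An `fi_session`.
#' @return `session`, invisibly; aborts with an informative error otherwise.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  un <- session$units
  need_tr <- c("trial_id", "interval_type", "cue_onset", "interval_duration",
               "press_times", "reward_time", "iti_before")
  missing_tr <- setdiff(need_tr, names(tr))
  if (length(missing_tr)) {
    abort(paste0("Trial table is missing columns: ", paste(missing_tr, collapse = ", ")),
          class = "ramplab_schema_error")
  }
  need_un <- c("unit_id", "area", "spike_times", "wf_samples", "wf_dt_ms")
  missing_un <- setdiff(need_un, names(un))
  if (length(missing_un)) {
    abort(paste0("Unit table is missing columns: ", paste(missing_un, collapse = ", ")),
          class = "ramplab_schema_error")
  }
  if (!all(tr$interval_type %in% c("FI3", "FI12"))) {
    abort("interval_type must be 'FI3' or 'FI12'.", class = "ramplab_validation_error")
  }
  if (!all(tr$interval_duration %in% c(3, 12))) {
    abort("interval_duration must be 3 or 12 s.", class = "ramplab_validation_error")
  }
  bad_type <- tr$interval_duration != ifelse(tr$interval_type == "FI3", 3, 12)
  if (any(bad_type)) {
    abort("interval_duration inconsistent with interval_type.",
          class = "ramplab_validation_error")
  }
  if (!all(tr$iti_before %in% c(6, 8, 10, 12))) {
    abort("iti_before must be one of 6, 8, 10, 12 s.", class = "ramplab_validation_error")
  }
  if (session$day == 0L && any(tr$interval_type != "FI12")) {
    abort("Day 0 sessions contain FI12 trials only.", class = "ramplab_validation_error")
  }
  for (i in seq_len(nrow(tr))) {
    p <- tr$press_times[[i]]
    if (!is_ascending(p)) {
      abort(sprintf("press_times not strictly ascending in trial %s.", tr$trial_id[i]),
            class = "ramplab_validation_error")
    }
    rw <- tr$reward_time[i]
    if (!is.na(rw) && rw < tr$interval_duration[i]) {
      abort(sprintf("reward_time before interval end in trial %s.", tr$trial_id[i]),
            class = "ramplab_validation_error")
    }
  }
  if (nrow(tr) > 1L) {
    o <- order(tr$cue_onset)
    span <- pmax(tr$reward_time, tr$interval_duration, na.rm = TRUE)
    gap_ok <- diff(tr$cue_onset[o]) >= span[o][-nrow(tr)] - 1e-9
    if (!all(gap_ok)) {
      abort("Trials overlap: cue onsets closer than the preceding trial span.",
            class = "ramplab_validation_error")
    }
  }
  for (i in seq_len(nrow(un))) {
    s <- un$spike_times[[i]]
    if (!is_ascending(s, strict = FALSE) || is.unsorted(s)) {
      abort(sprintf("spike_times not ascending for unit %s.", un$unit_id[i]),
            class = "ramplab_validation_error")
    }
  }
  invisible(session)
}

#' Session duration in seconds
#'
#' End of the last trial (reward press or interval end) plus a 12 s tail,
#' used as the recording span for rate screening.
#'
#' @param session An `fi_session`.
#' @return Scalar seconds.
#' @export
session_span <- function(session) {
  tr <- session$trials
  if (!nrow(tr)) {
    return(0)
  }
  max(tr$cue_onset + pmax(tr$reward_time, tr$interval_duration, na.rm = TRUE)) + 12
}

#' Shift spike times into cue-relative coordinates for one trial
#'
#' @param spike_times Ascending spike times on the session clock (s).
#' @param cue_onset Cue onset of the trial (s, session clock).
#' @param window Length-2 numeric, window relative to cue onset (s); spikes
#'   outside it are dropped. Use negative start (e.g. `c(-6, 18)`) to include
#'   pre-cue padding.
#' @return Ascending numeric vector of cue-relative spike times.
#' @export
trial_relative_spikes <- function(spike_times, cue_onset, window) {
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be c(start, end) with start < end.")
  }
  rel <- spike_times - cue_onset
  rel[rel >= window[1] & rel <= window[2]]
}

#' Long table of cue-relative spikes for every unit x trial pair
#'
#' @param session An `fi_session`.
#' @param window Window relative to cue onset, default `c(0, interval_duration)`
#'   per trial when `NULL`.
#' @return Tibble with columns `unit_id`, `area`, `trial_id`, `interval_type`,
#'   `time` (s relative to cue).
#' @export
session_spike_table <- function(session, window = NULL) {
  tr <- session$trials
  un <- session$units
  rows <- purrr::map(seq_len(nrow(un)), function(i) {
    purrr::map(seq_len(nrow(tr)), function(j) {
      w <- window %||% c(0, tr$interval_duration[j])
      t_rel <- trial_relative_spikes(un$spike_times[[i]], tr$cue_onset[j], w)
      if (!length(t_rel)) {
        return(NULL)
      }
      tibble::tibble(
        unit_id = un$unit_id[i], area = un$area[i],
        trial_id = tr$trial_id[j], interval_type = tr$interval_type[j],
        time = t_rel
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Write a session to a directory of plain-text tables
#'
#' One CSV per entity (`trials.csv`, `units.csv`, `spikes.csv`) plus a JSON
#' manifest (`session.json`). Lists (press times, waveform samples) are
#' serialized as semicolon-joined floats at 17 significant digits so that
#' [read_session()] inverts exactly.
#'
#' @param session An `fi_session`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort(sprintf("Cannot create directory '%s'.", path), class = "ramplab_io_error")
  }
  tr <- session$trials
  trials_out <- tibble::tibble(
    trial_id = tr$trial_id,
    interval_type = tr$interval_type,
    cue_onset = fmt_num(tr$cue_onset),
    interval_duration = fmt_num(tr$interval_duration),
    press_times = join_list_num(tr$press_times),
    reward_time = fmt_num(tr$reward_time),
    iti_before = fmt_num(tr$iti_before)
  )
  readr::write_csv(trials_out, file.path(path, "trials.csv"), progress = FALSE)

  un <- session$units
  units_out <- tibble::tibble(
    unit_id = un$unit_id,
    area = un$area,
    wf_dt_ms = fmt_num(un$wf_dt_ms),
    wf_samples = join_list_num(un$wf_samples),
    unit_class = ifelse(is.na(un$unit_class), "", un$unit_class)
  )
  readr::write_csv(units_out, file.path(path, "units.csv"), progress = FALSE)

  spikes_out <- dplyr::bind_rows(purrr::map(seq_len(nrow(un)), function(i) {
    st <- un$spike_times[[i]]
    if (!length(st)) {
      return(NULL)
    }
    tibble::tibble(unit_id = un$unit_id[i], spike_time = fmt_num(st))
  }))
  if (is.null(spikes_out) || !nrow(spikes_out)) {
    spikes_out <- tibble::tibble(unit_id = character(0), spike_time = character(0))
  }
  readr::write_csv(spikes_out, file.path(path, "spikes.csv"), progress = FALSE)

  manifest <- list(
    animal_id = session$animal_id,
    day = session$day,
    files = list(trials = "trials.csv", units = "units.csv", spikes = "spikes.csv")
  )
  jsonlite::write_json(manifest, file.path(path, "session.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path Directory containing `session.json` and the three CSV tables.
#' @return A validated `fi_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "session.json")
  if (!file.exists(mf)) {
    abort(sprintf("No session manifest at '%s'.", mf), class = "ramplab_io_error")
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  trials_raw <- readr::read_csv(
    file.path(path, manifest$files$trials), progress = FALSE,
    col_types = readr::cols(.default = readr::col_character(),
                            trial_id = readr::col_integer())
  )
  need <- c("trial_id", "interval_type", "cue_onset", "interval_duration",
            "press_times", "reward_time", "iti_before")
  if (length(setdiff(need, names(trials_raw)))) {
    abort("trials.csv is missing required columns.", class = "ramplab_schema_error")
  }
  trials <- trials_raw
  # parse via strtod (as.numeric) so that 17-digit output round-trips exactly
  for (col in c("cue_onset", "interval_duration", "reward_time", "iti_before")) {
    trials[[col]] <- as.numeric(trials_raw[[col]])
  }
  trials$press_times <- split_list_num(trials_raw$press_times)

  units_raw <- readr::read_csv(
    file.path(path, manifest$files$units), progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (length(setdiff(c("unit_id", "area", "wf_dt_ms", "wf_samples"), names(units_raw)))) {
    abort("units.csv is missing required columns.", class = "ramplab_schema_error")
  }
  spikes <- readr::read_csv(
    file.path(path, manifest$files$spikes), progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  spikes$spike_time <- as.numeric(spikes$spike_time)
  spike_lists <- lapply(units_raw$unit_id, function(id) {
    spikes$spike_time[spikes$unit_id == id]
  })
  units <- tibble::tibble(
    unit_id = units_raw$unit_id,
    area = units_raw$area,
    spike_times = spike_lists,
    wf_samples = split_list_num(units_raw$wf_samples),
    wf_dt_ms = as.numeric(units_raw$wf_dt_ms),
    unit_class = if ("unit_class" %in% names(units_raw)) {
      ifelse(is.na(units_raw$unit_class) | units_raw$unit_class == "",
             NA_character_, units_raw$unit_class)
    } else {
      NA_character_
    }
  )
  fi_session(trials, units, manifest$animal_id, manifest$day)
}
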