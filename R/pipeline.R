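#' Configuration for the end-to-end pipeline
#'
#' @param generator A [generator_config()] describing the synthetic
#'   experiment (or the experiment to emulate when loading real sessions).
#' @param thresholds A [classifier_thresholds()].
#' @param decoder A [decoder_config()].
#' @param alpha Significance level for ramping and interval-modulation calls.
#' @param stages Stages to run after simulation, in dependency order; any of
#'   `"classify"`, `"behavior"`, `"ramping"`, `"decode"`, `"stats"`.
#' @param decode_interval Interval type decoded by the decode stage.
#' @param seed Master seed; each stage, animal and day draws from a derived
#'   substream so that toggling one stage leaves the others unchanged.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            thresholds = classifier_thresholds(),
                            decoder = decoder_config(),
                            alpha = 0.05,
                            stages = c("classify", "behavior", "ramping",
                                       "decode", "stats"),
                            decode_interval = "FI12",
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(generator = generator, thresholds = thresholds,
                 decoder = decoder, alpha = alpha, stages = stages,
                 decode_interval = decode_interval, seed = as.integer(seed)),
            class = c("pipeline_config", "list"))
}

log_line <- function(log, stage, message, ...) {
  entry <- c(list(stage = stage, message = message), list(...))
  c(log, list(entry))
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Simulates the configured experiment, then runs the enabled stages in
#' dependency order: unit screening/classification, behavioral start-time
#' and CV analysis, PETH/PCA ramping quantification with slope fits and
#' interval-modulation screening, leave-one-out Bayesian time decoding with
#' a time-shuffled control, and the summary statistics (mixed models,
#' contingency test, shuffle comparison). Identical config and seed give an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV, the summary as JSON, and the log as JSON lines.
#' @return List with one element per stage (tibbles), plus `summary` (list)
#'   and `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  gen <- config$generator
  gen$seed <- derive_seed(config$seed, "simulate")
  log <- list()
  log <- log_line(log, "simulate", "generating experiment",
                  seed = gen$seed, n_animals = gen$n_animals)
  experiment <- simulate_experiment(gen)
  sessions <- lapply(experiment, `[[`, "session")
  truths <- lapply(experiment, `[[`, "truth")
  report <- list(config = config, log = NULL)
  meta <- dplyr::bind_rows(lapply(sessions, function(s) {
    tibble::tibble(animal_id = s$animal_id, day = s$day,
                   n_trials = nrow(s$trials), n_units = nrow(s$units))
  }))
  report$sessions <- meta

  if ("classify" %in% config$stages) {
    report$units <- dplyr::bind_rows(lapply(sessions, function(s) {
      dplyr::mutate(classify_session_units(s, config$thresholds),
                    animal_id = s$animal_id, day = s$day)
    }))
    log <- log_line(log, "classify", "units screened and classified",
                    n_units = nrow(report$units),
                    n_excluded = sum(!report$units$included))
  }

  if ("behavior" %in% config$stages) {
    rt <- dplyr::bind_rows(lapply(sessions, function(s) {
      dplyr::mutate(response_times(s$trials, "all_presses"),
                    animal_id = s$animal_id, day = s$day)
    }))
    st <- dplyr::bind_rows(lapply(sessions, function(s) {
      dplyr::mutate(start_times(s$trials), animal_id = s$animal_id, day = s$day)
    }))
    st_ok <- st[!is.na(st$start_time), ]
    cv <- dplyr::bind_rows(lapply(
      split(st_ok, paste(st_ok$animal_id, st_ok$day, st_ok$interval_type)),
      function(d) {
        if (nrow(d) < 2) {
          return(NULL)
        }
        dplyr::bind_cols(
          tibble::tibble(animal_id = d$animal_id[1], day = d$day[1],
                         interval_type = d$interval_type[1]),
          cv_start_times(d$start_time)
        )
      }))
    report$response_times <- rt
    report$start_times <- st
    report$start_time_cv <- cv
    log <- log_line(log, "behavior", "response and start times computed",
                    n_responses = nrow(rt))
  }

  if ("ramping" %in% config$stages) {
    peths <- lapply(sessions, function(s) {
      zscore_peth(session_peths(s, "FI12"))
    })
    pooled <- bind_peths(peths)
    pca <- ensemble_pca(pooled)
    scores <- ramp_strength(pca)
    unit_meta <- dplyr::bind_rows(lapply(sessions, function(s) {
      tibble::tibble(unit_id = s$units$unit_id, area = s$units$area,
                     animal_id = s$animal_id, day = s$day)
    }))
    report$pca <- pca
    report$ramp_scores <- dplyr::left_join(scores, unit_meta, by = "unit_id")
    slopes <- dplyr::bind_rows(lapply(sessions, function(s) {
      types <- intersect(c("FI3", "FI12"), unique(s$trials$interval_type))
      dplyr::bind_rows(lapply(types, function(ty) {
        dplyr::mutate(session_ramp_slopes(s, ty, alpha = config$alpha),
                      animal_id = s$animal_id, day = s$day)
      }))
    }))
    report$slopes <- slopes
    two_int <- sessions[vapply(sessions, function(s) s$day >= 1, logical(1))]
    report$interval_modulation <- dplyr::bind_rows(lapply(two_int, function(s) {
      dplyr::mutate(
        session_interval_modulation(
          s, alpha = config$alpha,
          slopes = dplyr::filter(slopes, .data$animal_id == s$animal_id,
                                 .data$day == s$day)),
        animal_id = s$animal_id, day = s$day)
    }))
    log <- log_line(log, "ramping", "PCA, slopes and interval screen done",
                    pc1_var = pca$explained[1])
  }

  if ("decode" %in% config$stages) {
    rows <- list()
    for (key in names(sessions)) {
      s <- sessions[[key]]
      if (!config$decode_interval %in% s$trials$interval_type) next
      sd_seed <- derive_seed(config$seed, "decode", s$animal_id, s$day)
      real <- decode_ensemble(s, config$decode_interval, config$decoder)
      shuf <- decode_ensemble(s, config$decode_interval, config$decoder,
                              shuffle = TRUE, seed = sd_seed)
      rows[[key]] <- tibble::tibble(
        animal_id = s$animal_id, day = s$day,
        interval_type = config$decode_interval,
        r2_real = real$r_squared, r2_shuffled = shuf$r_squared
      )
    }
    report$decoding <- dplyr::bind_rows(rows)
    log <- log_line(log, "decode", "ensemble decoding complete",
                    n_ensembles = nrow(report$decoding))
  }

  if ("stats" %in% config$stages) {
    summary <- list()
    if (!is.null(report$ramp_scores)) {
      df <- dplyr::mutate(report$ramp_scores,
                          context = ifelse(.data$day == 0, "one_interval",
                                           "two_interval"))
      if (length(unique(df$context)) > 1 && length(unique(df$animal_id)) > 1) {
        fit <- fit_model(model_spec("pc1_score_abs", c("context", "area"),
                                    "(1|animal_id)", "gaussian"), df)
        summary$pc1_context <- tidy.glmm_fit(fit)
      }
    }
    if (!is.null(report$interval_modulation)) {
      d1 <- dplyr::filter(report$interval_modulation, .data$day == 1,
                          !is.na(.data$modulated))
      if (nrow(d1) && length(unique(d1$area)) == 2) {
        tab <- with(d1, table(factor(area, c("MFC", "DMS")),
                              factor(modulated, c(TRUE, FALSE))))
        summary$interval_mod_chisq <- chi_square_2x2(as.matrix(tab))
        summary$interval_mod_counts <- dplyr::count(d1, .data$area,
                                                    .data$modulated)
      }
    }
    if (!is.null(report$decoding) && nrow(report$decoding) >= 5) {
      summary$decode_shuffle_test <- signed_rank_d(report$decoding$r2_real,
                                                   report$decoding$r2_shuffled)
    }
    report$summary <- summary
    log <- log_line(log, "stats", "summary statistics computed")
  }

  report$log <- log
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tbls <- c("sessions", "units", "response_times", "start_times",
            "start_time_cv", "ramp_scores", "slopes", "interval_modulation",
            "decoding")
  for (nm in intersect(tbls, names(report))) {
    df <- report[[nm]]
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    readr::write_csv(df, file.path(out_dir, paste0(nm, ".csv")), progress = FALSE)
  }
  if (!is.null(report$summary)) {
    jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_file <- file.path(out_dir, "pipeline_log.jsonl")
  writeLines(vapply(report$log, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE)
  }, character(1)), log_file)
  invisible(out_dir)
}

#' Write a miniature committed-size fixture dataset
#'
#' Two animals, days 0 and 1, 8 units per area, 30 trials per interval:
#' small enough to version, while exercising every trial and unit class.
#' Sessions are written with [write_session()]; ground truth goes to
#' `truth_units.csv` and `truth_trials.csv` per session directory.
#'
#' @param path Output directory.
#' @param seed Seed.
#' @return Tibble of session directories and their animal/day, invisibly.
#' @export
make_fixtures <- function(path, seed = 1L) {
  cfg <- generator_config(n_animals = 2, n_units_per_area = 8, days = 0:1,
                          n_trials_per_interval = 30, seed = as.integer(seed))
  rows <- list()
  for (a in 1:2) {
    for (day in 0:1) {
      res <- simulate_session(cfg, sprintf("A%d", a), day)
      dir <- file.path(path, sprintf("A%d_d%d", a, day))
      write_session(res$session, dir)
      tu <- res$truth$units
      readr::write_csv(tu, file.path(dir, "truth_units.csv"), progress = FALSE)
      readr::write_csv(res$truth$trials, file.path(dir, "truth_trials.csv"),
                       progress = FALSE)
      rows[[dir]] <- tibble::tibble(dir = dir, animal_id = sprintf("A%d", a),
                                    day = day)
    }
  }
  invisible(dplyr::bind_rows(rows))
}
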