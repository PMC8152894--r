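#' Configuration for the naive Bayes temporal decoder
#'
#' @param bin Time bin, s (default 0.1).
#' @param kde_bandwidth Temporal smoothing SD for trial-by-trial firing-rate
#'   estimates, s (default 1.2).
#' @param pad Padding added before the cue and after interval end, s (default
#'   6). Padded bins participate in training and as prediction candidates —
#'   preventing edge effects from biasing performance — but are excluded from
#'   the R-squared, which is computed over in-interval bins only.
#' @param likelihood `"poisson"` (default; per unit and bin, a Poisson
#'   likelihood with mean = training-mean rate times bin width, matching the
#'   Poisson family used for all firing-rate models) or `"gaussian_kde"`
#'   (kernel density over training rates).
#' @param r2_method `"pearson"` (default; squared Pearson correlation of
#'   observed and predicted time) or `"ss"` (1 - SS_res/SS_tot).
#' @param rate_floor Lower bound on training-mean rates, Hz, keeping the
#'   Poisson log-likelihood finite for silent bins.
#' @param kde_rate_bandwidth Rate-space kernel SD for the `"gaussian_kde"`
#'   likelihood, Hz.
#' @return List of class `decoder_config`.
#' @export
decoder_config <- function(bin = 0.1, kde_bandwidth = 1.2, pad = 6,
                           likelihood = c("poisson", "gaussian_kde"),
                           r2_method = c("pearson", "ss"),
                           rate_floor = 1e-3, kde_rate_bandwidth = 1) {
  likelihood <- match.arg(likelihood)
  r2_method <- match.arg(r2_method)
  assert_scalar_number(bin, "bin", positive = TRUE)
  assert_scalar_number(kde_bandwidth, "kde_bandwidth", positive = TRUE)
  if (pad < 0) {
    abort("`pad` must be >= 0.")
  }
  structure(list(bin = bin, kde_bandwidth = kde_bandwidth, pad = pad,
                 likelihood = likelihood, r2_method = r2_method,
                 rate_floor = rate_floor,
                 kde_rate_bandwidth = kde_rate_bandwidth),
            class = c("decoder_config", "list"))
}

decoder_bin_centers <- function(T, config) {
  seq(-config$pad + config$bin / 2, T + config$pad - config$bin / 2,
      by = config$bin)
}

#' Smoothed single-trial firing-rate features
#'
#' Gaussian kernel-density rate estimate (Hz) for one unit on one trial,
#' evaluated at every bin center of the padded window `[-pad, T + pad]`.
#'
#' @param spike_times Spike times, session clock, s.
#' @param cue_onset Trial cue onset, session clock, s.
#' @param T Interval duration, s.
#' @param config A [decoder_config()].
#' @return Numeric vector of rates, one per padded-window bin.
#' @export
rate_features <- function(spike_times, cue_onset, T, config = decoder_config()) {
  centers <- decoder_bin_centers(T, config)
  bw <- config$kde_bandwidth
  rel <- trial_relative_spikes(spike_times, cue_onset,
                               c(-config$pad - 4 * bw, T + config$pad + 4 * bw))
  if (!length(rel)) {
    return(numeric(length(centers)))
  }
  d <- outer(centers, rel, "-")
  k <- dnorm(d, sd = bw)
  k[abs(d) > 4 * bw] <- 0
  rowSums(k)
}

# units x bins x trials feature array for one interval type
feature_array <- function(units, trials, config) {
  T <- trials$interval_duration[1]
  centers <- decoder_bin_centers(T, config)
  arr <- array(0, dim = c(nrow(units), length(centers), nrow(trials)),
               dimnames = list(units$unit_id, NULL, NULL))
  for (i in seq_len(nrow(units))) {
    for (j in seq_len(nrow(trials))) {
      arr[i, , j] <- rate_features(units$spike_times[[i]], trials$cue_onset[j],
                                   T, config)
    }
  }
  arr
}

# circular shift of each unit's rate vector on each trial by an independent
# uniform offset: preserves each unit's rate marginal, destroys time locking
shuffle_features <- function(arr) {
  nb <- dim(arr)[2]
  for (i in seq_len(dim(arr)[1])) {
    for (j in seq_len(dim(arr)[3])) {
      off <- sample.int(nb, 1) - 1L
      if (off > 0L) {
        arr[i, , j] <- arr[i, c((nb - off + 1):nb, 1:(nb - off)), j]
      }
    }
  }
  arr
}

#' Train the naive Bayes decoder
#'
#' For each unit and time bin, fits the likelihood of the observed rate given
#' the bin: in `"poisson"` mode the training-trial mean rate; in
#' `"gaussian_kde"` mode a Gaussian kernel density over the training rates.
#' The classifier factorizes across units (the naive assumption).
#'
#' @param features Units x bins x trials array of training features (from
#'   [rate_features()]), or a list of unit x bin matrices (one per trial).
#' @param bin_centers Bin centers matching the feature columns, s.
#' @param config A [decoder_config()].
#' @return A `bayes_decoder` model object.
#' @export
train_decoder <- function(features, bin_centers, config = decoder_config()) {
  if (is.list(features)) {
    features <- simplify2array(features)
  }
  if (length(dim(features)) != 3L) {
    abort("`features` must be a units x bins x trials array.")
  }
  if (dim(features)[3] < 2L) {
    abort("Need at least 2 training trials.", class = "ramplab_insufficient_data")
  }
  structure(
    list(mean_rates = apply(features, c(1, 2), mean),
         train_rates = if (config$likelihood == "gaussian_kde") features else NULL,
         bin_centers = bin_centers, config = config),
    class = "bayes_decoder"
  )
}

# log-likelihood matrix: rows = observed bins, cols = candidate bins
decoder_loglik <- function(model, feat) {
  cfg <- model$config
  bin <- cfg$bin
  if (cfg$likelihood == "poisson") {
    lam <- pmax(model$mean_rates, cfg$rate_floor) * bin # units x cand
    x <- feat * bin                                     # units x obs
    crossprod(x, log(lam)) - matrix(colSums(lam), ncol(x), ncol(lam),
                                    byrow = TRUE)
  } else {
    tr <- model$train_rates
    h <- cfg$kde_rate_bandwidth
    n_obs <- ncol(feat)
    n_cand <- ncol(model$mean_rates)
    ll <- matrix(0, n_obs, n_cand)
    for (u in seq_len(nrow(feat))) {
      dens <- vapply(seq_len(n_cand), function(cb) {
        r <- tr[u, cb, ]
        vapply(feat[u, ], function(x) mean(dnorm(x - r, sd = h)), numeric(1))
      }, numeric(n_obs))
      ll <- ll + log(pmax(dens, 1e-300))
    }
    ll
  }
}

#' Decode one held-out trial
#'
#' For every observed bin, the maximum a posteriori candidate bin under a
#' uniform prior over candidates; ties break toward the earliest bin.
#'
#' @param model A [train_decoder()] model.
#' @param feat Units x bins feature matrix for the held-out trial.
#' @param return_posterior Also return the normalized posterior matrix
#'   (observed bins x candidate bins)?
#' @return Tibble with `observed` and `predicted` bin centers (s); with
#'   `return_posterior = TRUE`, a list with `predictions` and `posterior`.
#' @export
decode_trial <- function(model, feat, return_posterior = FALSE) {
  ll <- decoder_loglik(model, feat)
  pred_idx <- max.col(ll, ties.method = "first")
  preds <- tibble::tibble(observed = model$bin_centers,
                          predicted = model$bin_centers[pred_idx])
  if (!return_posterior) {
    return(preds)
  }
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  list(predictions = preds, posterior = post)
}

#' Leave-one-out ensemble decoding of time within the interval
#'
#' For each trial, the decoder is trained on all other trials and predicts
#' time for every observed bin of the held-out trial. Performance is the
#' squared Pearson correlation of observed and predicted time pooled over
#' in-interval bins only (padded bins train the model and serve as
#' candidates but are not scored). With `shuffle = TRUE`, each unit's rate
#' vector on each trial is circularly shifted by an independent uniform
#' offset before training and testing, destroying time locking while
#' preserving rate marginals — the decoder's null.
#'
#' @param session An [fi_session()], or a unit tibble.
#' @param interval_type `"FI3"` or `"FI12"`.
#' @param config A [decoder_config()].
#' @param shuffle Run the time-shuffled control?
#' @param seed Seed for the shuffle offsets.
#' @param trials Trial tibble when `session` is a unit tibble.
#' @return A `decode_result`: `predictions` tibble (trial, observed,
#'   predicted, in_interval), `r_squared`, `shuffled` flag and metadata.
#' @export
decode_ensemble <- function(session, interval_type, config = decoder_config(),
                            shuffle = FALSE, seed = NULL, trials = NULL) {
  if (inherits(session, "fi_session")) {
    units <- session$units
    trials <- dplyr::filter(session$trials, .data$interval_type == !!interval_type)
  } else {
    units <- session
    trials <- dplyr::filter(trials, .data$interval_type == !!interval_type)
  }
  n <- nrow(trials)
  if (n < 3L) {
    abort("Leave-one-out decoding needs at least 3 trials.",
          class = "ramplab_insufficient_data")
  }
  T <- trials$interval_duration[1]
  centers <- decoder_bin_centers(T, config)
  arr <- feature_array(units, trials, config)
  if (shuffle) {
    arr <- with_seed(seed, shuffle_features(arr))
  }
  sums <- apply(arr, c(1, 2), sum)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    held <- matrix(arr[, , i], nrow = dim(arr)[1])
    model <- structure(
      list(mean_rates = (sums - held) / (n - 1),
           train_rates = if (config$likelihood == "gaussian_kde") {
             arr[, , -i, drop = FALSE]
           } else {
             NULL
           },
           bin_centers = centers, config = config),
      class = "bayes_decoder"
    )
    p <- decode_trial(model, held)
    p$trial_id <- trials$trial_id[i]
    preds[[i]] <- p
  }
  predictions <- dplyr::bind_rows(preds)
  predictions$in_interval <- predictions$observed > 0 & predictions$observed < T
  r2 <- decode_r2(predictions$observed[predictions$in_interval],
                  predictions$predicted[predictions$in_interval],
                  config$r2_method)
  structure(
    list(predictions = predictions[, c("trial_id", "observed", "predicted",
                                       "in_interval")],
         r_squared = r2, shuffled = shuffle, interval_type = interval_type,
         n_trials = n, n_units = nrow(units), config = config, seed = seed),
    class = "decode_result"
  )
}

decode_r2 <- function(observed, predicted, method = "pearson") {
  if (sd(predicted) == 0 || sd(observed) == 0) {
    return(0)
  }
  if (method == "pearson") {
    cor(observed, predicted)^2
  } else {
    max(0, 1 - sum((observed - predicted)^2) /
          sum((observed - mean(observed))^2))
  }
}

#' @exportS3Method base::print
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s, %d units, %d trials%s: R^2 = %.3f\n",
              x$interval_type, x$n_units, x$n_trials,
              if (x$shuffled) " (time-shuffled)" else "", x$r_squared))
  invisible(x)
}

#' @rdname tidy_ramplab
#' @export
tidy.decode_result <- function(x, ...) {
  x$predictions
}

#' @rdname glance_ramplab
#' @export
glance.decode_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, shuffled = x$shuffled,
                 interval_type = x$interval_type, n_units = x$n_units,
                 n_trials = x$n_trials)
}

#' Predicted-versus-observed time heat map
#'
#' @param object A `decode_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decode_result <- function(object, ...) {
  df <- dplyr::count(object$predictions, .data$observed, .data$predicted)
  df <- dplyr::mutate(dplyr::group_by(df, .data$observed),
                      prob = .data$n / sum(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                   fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Relative\nprobability") +
    ggplot2::labs(x = "Observed time (s)", y = "Predicted time (s)",
                  subtitle = sprintf("R² = %.2f%s", object$r_squared,
                                     if (object$shuffled) " (shuffled)" else "")) +
    ggplot2::theme_minimal()
}
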