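default_bandwidth <- function(interval_type) {
  if (interval_type == "FI3") 0.2 else 0.5
}

#' Kernel-density peri-event time histogram for one unit
#'
#' Per trial, the instantaneous rate is a Gaussian kernel-density estimate,
#' `rate(t) = sum over spikes of K_bw(t - t_spike)` with each kernel
#' integrating to 1 (so the estimate is in Hz), evaluated exactly at the
#' 0.1 s bin centers 0.05, 0.15, ... over `[0, T]` and averaged across
#' trials. No edge correction is applied: mass falling outside the interval
#' is simply not counted (unnormalized-tail convention).
#'
#' @param spike_times Ascending spike times on the session clock, s.
#' @param trials Trial tibble, all of one interval type.
#' @param bandwidth Kernel SD, s; defaults to 0.2 for FI3 and 0.5 for FI12.
#' @param bin Bin width, s (default 0.1).
#' @return Tibble with `bin_center` and `rate_hz`.
#' @export
compute_peth <- function(spike_times, trials, bandwidth = NULL, bin = 0.1) {
  if (!nrow(trials)) {
    abort("Need at least one trial for a PETH.")
  }
  ty <- unique(trials$interval_type)
  if (length(ty) != 1L) {
    abort("All trials passed to compute_peth() must share one interval type.")
  }
  T <- trials$interval_duration[1]
  bandwidth <- bandwidth %||% default_bandwidth(ty)
  assert_scalar_number(bandwidth, "bandwidth", positive = TRUE)
  centers <- seq(bin / 2, T - bin / 2, by = bin)
  acc <- numeric(length(centers))
  for (i in seq_len(nrow(trials))) {
    rel <- trial_relative_spikes(spike_times, trials$cue_onset[i],
                                 c(-4 * bandwidth, T + 4 * bandwidth))
    if (length(rel)) {
      # truncate each kernel at +/- 4 bandwidths
      d <- outer(centers, rel, "-")
      k <- dnorm(d, sd = bandwidth)
      k[abs(d) > 4 * bandwidth] <- 0
      acc <- acc + rowSums(k)
    }
  }
  tibble::tibble(bin_center = centers, rate_hz = acc / nrow(trials))
}

#' PETH matrix for every unit in a session
#'
#' @param session An [fi_session()].
#' @param interval_type `"FI3"` or `"FI12"`.
#' @param bandwidth Kernel SD, s; default 0.2 (FI3) / 0.5 (FI12).
#' @param bin Bin width, s.
#' @param unit_ids Optional subset of units.
#' @return A `peth_matrix`: units x bins rate matrix with bin metadata.
#' @export
session_peths <- function(session, interval_type, bandwidth = NULL, bin = 0.1,
                          unit_ids = NULL) {
  trials <- dplyr::filter(session$trials, .data$interval_type == !!interval_type)
  if (!nrow(trials)) {
    abort(sprintf("Session has no %s trials.", interval_type))
  }
  un <- session$units
  if (!is.null(unit_ids)) {
    un <- un[un$unit_id %in% unit_ids, ]
  }
  bandwidth <- bandwidth %||% default_bandwidth(interval_type)
  rows <- purrr::map(seq_len(nrow(un)), function(i) {
    compute_peth(un$spike_times[[i]], trials, bandwidth, bin)$rate_hz
  })
  peth_matrix(do.call(rbind, rows), un$unit_id,
              seq(bin / 2, trials$interval_duration[1] - bin / 2, by = bin),
              normalization = "rate_hz", bandwidth = bandwidth,
              interval_type = interval_type)
}

#' Construct a PETH matrix object
#'
#' @param values Units x bins numeric matrix.
#' @param unit_ids Character vector, one per row.
#' @param bin_centers Numeric vector, one per column (s from cue onset).
#' @param normalization `"rate_hz"` or `"zscore"`.
#' @param bandwidth Kernel SD used, s.
#' @param interval_type `"FI3"` or `"FI12"` (optional metadata).
#' @return A `peth_matrix`.
#' @export
peth_matrix <- function(values, unit_ids, bin_centers,
                        normalization = c("rate_hz", "zscore"),
                        bandwidth = NA_real_, interval_type = NA_character_) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (nrow(values) != length(unit_ids) || ncol(values) != length(bin_centers)) {
    abort("PETH matrix dimensions do not match unit_ids / bin_centers.")
  }
  rownames(values) <- unit_ids
  structure(
    list(values = values, unit_ids = as.character(unit_ids),
         bin_centers = bin_centers, normalization = normalization,
         bandwidth = bandwidth, interval_type = interval_type),
    class = "peth_matrix"
  )
}

#' @exportS3Method base::print
print.peth_matrix <- function(x, ...) {
  cat(sprintf("<peth_matrix> %d units x %d bins (%s, bandwidth %.2g s%s)\n",
              nrow(x$values), ncol(x$values), x$normalization, x$bandwidth,
              if (is.na(x$interval_type)) "" else paste0(", ", x$interval_type)))
  invisible(x)
}

#' Combine PETH matrices (e.g. across sessions) by stacking units
#'
#' @param ... `peth_matrix` objects sharing bin centers and normalization.
#' @return A `peth_matrix`.
#' @export
bind_peths <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "peth_matrix")) {
    xs <- xs[[1]]
  }
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!isTRUE(all.equal(x$bin_centers, ref$bin_centers)) ||
        x$normalization != ref$normalization) {
      abort("PETH matrices must share bin centers and normalization.")
    }
  }
  peth_matrix(do.call(rbind, lapply(xs, `[[`, "values")),
              unlist(lapply(xs, `[[`, "unit_ids")),
              ref$bin_centers, ref$normalization, ref$bandwidth,
              ref$interval_type)
}

#' Z-score each unit's PETH
#'
#' Rows are centered and scaled to unit standard deviation. Rows with zero
#' variance (silent or constant units) cannot be z-scored; they are dropped
#' with a warning.
#'
#' @param peth A `peth_matrix` with `normalization = "rate_hz"`.
#' @return A `peth_matrix` with `normalization = "zscore"`.
#' @export
zscore_peth <- function(peth) {
  v <- peth$values
  sds <- apply(v, 1, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warn(sprintf("Dropping %d zero-variance unit(s) before z-scoring: %s",
                 sum(drop), paste(peth$unit_ids[drop], collapse = ", ")))
    v <- v[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  if (!nrow(v)) {
    abort("No units left after dropping zero-variance rows.")
  }
  z <- (v - rowMeans(v)) / sds
  peth_matrix(z, rownames(v), peth$bin_centers, "zscore",
              peth$bandwidth, peth$interval_type)
}

#' @rdname tidy_ramplab
#' @export
tidy.peth_matrix <- function(x, ...) {
  tibble::as_tibble(
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(x$values, .name_repair = ~ fmt_num(x$bin_centers)),
                    unit_id = x$unit_ids),
      -dplyr::all_of("unit_id"),
      names_to = "bin_center", values_to = "value",
      names_transform = list(bin_center = as.numeric)
    )
  )
}

#' Heatmap of a PETH matrix
#'
#' @param object A `peth_matrix`.
#' @param order_by Optional numeric vector (one per unit) used to order rows,
#'   e.g. PC1 scores.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peth_matrix <- function(object, order_by = NULL, ...) {
  df <- tidy.peth_matrix(object)
  lev <- if (is.null(order_by)) {
    object$unit_ids
  } else {
    object$unit_ids[order(order_by)]
  }
  df$unit_id <- factor(df$unit_id, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_center, .data$unit_id,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$normalization) +
    ggplot2::labs(x = "Time from cue (s)", y = "Unit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
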