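#' Ensemble PCA of z-scored PETHs
#'
#' Principal component analysis of the units x bins matrix with units as
#' observations and time bins as variables (columns mean-centered, covariance
#' PCA — with z-scored rows, covariance and correlation are nearly
#' equivalent). The leading component typically captures time-related
#' ramping; a unit's projection onto it, in absolute value, is the package's
#' ramping-strength measure (see [ramp_strength()]).
#'
#' @param peth A `peth_matrix`, normally z-scored ([zscore_peth()]); pooling
#'   across areas/days is done by stacking units ([bind_peths()]) before the
#'   call.
#' @return An `ensemble_pca` object: `components` (bins x k matrix of
#'   orthonormal time courses), `explained` (variance fractions,
#'   non-increasing), `scores` (units x k), `bin_centers`, `unit_ids`.
#' @export
ensemble_pca <- function(peth) {
  v <- peth$values
  if (nrow(v) < 2L || ncol(v) < 2L) {
    abort("Ensemble PCA needs at least 2 units and 2 bins.")
  }
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(components = pc$rotation, explained = expl, scores = pc$x,
         center = pc$center, bin_centers = peth$bin_centers,
         unit_ids = peth$unit_ids, interval_type = peth$interval_type),
    class = "ensemble_pca"
  )
}

#' @exportS3Method base::print
print.ensemble_pca <- function(x, ...) {
  cat(sprintf("<ensemble_pca> %d units x %d bins; PC1-3 variance: %s\n",
              nrow(x$scores), length(x$bin_centers),
              paste(sprintf("%.1f%%", 100 * head(x$explained, 3)), collapse = ", ")))
  invisible(x)
}

#' Ramping strength as the absolute PC1 score
#'
#' Units can ramp up or down; the magnitude of the projection onto the first
#' principal component measures ramping strength irrespective of sign (and is
#' invariant to the arbitrary sign convention of PC1).
#'
#' @param pca An [ensemble_pca()] result.
#' @return Tibble with `unit_id`, `pc1_score`, `pc1_score_abs`.
#' @export
ramp_strength <- function(pca) {
  tibble::tibble(unit_id = pca$unit_ids,
                 pc1_score = pca$scores[, 1],
                 pc1_score_abs = abs(pca$scores[, 1]))
}

#' @rdname tidy_ramplab
#' @export
tidy.ensemble_pca <- function(x, matrix = c("scores", "components"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    df <- tibble::as_tibble(x$scores, .name_repair = "minimal")
    names(df) <- paste0("PC", seq_len(ncol(df)))
    dplyr::bind_cols(tibble::tibble(unit_id = x$unit_ids), df)
  } else {
    df <- tibble::as_tibble(x$components, .name_repair = "minimal")
    names(df) <- paste0("PC", seq_len(ncol(df)))
    dplyr::bind_cols(tibble::tibble(bin_center = x$bin_centers), df)
  }
}

#' @rdname glance_ramplab
#' @export
glance.ensemble_pca <- function(x, ...) {
  tibble::tibble(n_units = nrow(x$scores), n_bins = length(x$bin_centers),
                 pc1_var = x$explained[1], pc2_var = x$explained[2],
                 pc3_var = x$explained[3])
}

#' Time courses of the leading principal components
#'
#' @param object An `ensemble_pca`.
#' @param n_components How many components to draw (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_pca <- function(object, n_components = 3, ...) {
  k <- min(n_components, ncol(object$components))
  df <- tidy.ensemble_pca(object, matrix = "components")[, c("bin_center",
                                                             paste0("PC", seq_len(k)))]
  long <- tidyr::pivot_longer(df, -dplyr::all_of("bin_center"),
                              names_to = "component", values_to = "loading")
  lab <- setNames(sprintf("%s (%.0f%%)", paste0("PC", seq_len(k)),
                          100 * object$explained[seq_len(k)]),
                  paste0("PC", seq_len(k)))
  long$component <- factor(long$component, levels = names(lab), labels = lab)
  ggplot2::ggplot(long, ggplot2::aes(.data$bin_center, .data$loading,
                                     colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time from cue (s)", y = "Component loading",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
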