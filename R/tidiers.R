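#' Tidy ramplab result objects
#'
#' Broom-style `tidy()` methods returning one tibble row per elementary
#' result: PETH bins (`peth_matrix`), unit scores or component loadings
#' (`ensemble_pca`), per-bin predictions (`decode_result`), or per-term
#' ANOVA rows (`glmm_fit`).
#'
#' @param x The object to tidy.
#' @param matrix For `ensemble_pca`: `"scores"` (default) or `"components"`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_ramplab
NULL

#' One-row summaries of ramplab result objects
#'
#' Broom-style `glance()` methods: ensemble size and leading variance
#' fractions (`ensemble_pca`), decoding performance (`decode_result`), or
#' fit metadata (`glmm_fit`).
#'
#' @param x The object to summarize.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance_ramplab
NULL
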