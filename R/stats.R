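#' Pearson chi-square test on a 2x2 contingency table
#'
#' Without continuity correction: `sum((O - E)^2 / E)` with expected counts
#' from the row/column margins — the convention for comparing counts of
#' modulated neurons between areas.
#'
#' @param counts 2x2 matrix of nonnegative integers (rows: groups, columns:
#'   outcome yes/no), or a data frame coercible to one.
#' @return Tibble with `statistic`, `df` (= 1), `p_value`.
#' @export
chi_square_2x2 <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2L, 2L))) {
    abort("`counts` must be a 2x2 table.")
  }
  if (any(m < 0) || sum(m) == 0) {
    abort("Counts must be nonnegative with a positive total.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Chi-square undefined: a margin is zero.")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = 1L,
                 p_value = unname(ct$p.value))
}

#' Wilcoxon signed-rank test with Cohen's d for paired samples
#'
#' Zero differences are dropped, ties get mid-ranks, and the normal
#' approximation is used above n = 25 pairs (exact below). Cohen's d is
#' `mean(x - y) / sd(x - y)`; when the differences have zero variance but a
#' nonzero mean, d is reported capped at `d_cap` with `d_capped = TRUE`.
#'
#' @param x,y Paired numeric vectors of equal length (>= 5).
#' @param d_cap Reported magnitude for zero-variance differences.
#' @return Tibble with `statistic` (W), `p_value`, `cohens_d`, `d_capped`,
#'   `n`.
#' @export
signed_rank_d <- function(x, y, d_cap = 1e6) {
  if (length(x) != length(y) || length(x) < 5L) {
    abort("`x` and `y` must be paired vectors of equal length >= 5.")
  }
  d <- x - y
  if (all(d == 0)) {
    abort("All paired differences are zero; test degenerate.",
          class = "ramplab_degenerate_test")
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
  sdd <- sd(d)
  if (sdd == 0) {
    cd <- sign(mean(d)) * d_cap
    capped <- TRUE
  } else {
    cd <- mean(d) / sdd
    capped <- FALSE
  }
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 cohens_d = cd, d_capped = capped, n = length(x))
}

#' Specify a (generalized) linear mixed-effects model
#'
#' Encodes the model families used throughout the pipeline: gaussian models
#' for response times, start times, CVs, PC1 |scores| and slope magnitudes;
#' Poisson models for binned firing rates. Random effects are written in
#' `lme4` syntax (e.g. `"(1|animal_id)"`).
#'
#' @param outcome Outcome variable name.
#' @param predictors Character vector of fixed-effect terms (interactions
#'   allowed, e.g. `"context*area"`).
#' @param random_effects Character vector of random-effect terms; may be
#'   empty.
#' @param family `"gaussian"` or `"poisson"`.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(outcome, predictors, random_effects = character(0),
                       family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  if (outcome %in% predictors) {
    abort("The outcome cannot also be a predictor.")
  }
  structure(list(outcome = outcome, predictors = predictors,
                 random_effects = random_effects, family = family),
            class = c("model_spec", "list"))
}

spec_formula <- function(spec) {
  rhs <- paste(c(spec$predictors, spec$random_effects), collapse = " + ")
  as.formula(paste(spec$outcome, "~", rhs))
}

#' Fit a model specification
#'
#' Gaussian models with random effects go through [lmerTest::lmer()]
#' (Satterthwaite F tests per predictor); Poisson models with random effects
#' through [lme4::glmer()] (Wald chi-square per predictor); models without
#' random effects fall back to `lm()` / `glm()`. A singular random-effects
#' fit is flagged and refit with fixed effects only, with a warning.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with all model variables.
#' @return A `glmm_fit`: the fitted object plus a per-term ANOVA tibble
#'   (`term`, `statistic`, `p_value`) and a `singular` flag. Deterministic
#'   given the data (fixed optimizer settings).
#' @export
fit_model <- function(spec, data) {
  miss <- setdiff(c(all.vars(as.formula(paste(
    "~", paste(spec$predictors, collapse = "+")))), spec$outcome), names(data))
  if (length(miss)) {
    abort(paste0("Data is missing model variables: ", paste(miss, collapse = ", ")))
  }
  mixed <- length(spec$random_effects) > 0
  singular <- FALSE
  if (mixed) {
    fml <- spec_formula(spec)
    fit <- if (spec$family == "gaussian") {
      lmerTest::lmer(fml, data = data, REML = TRUE)
    } else {
      lme4::glmer(fml, data = data, family = poisson(),
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    }
    if (lme4::isSingular(fit, tol = 1e-5)) {
      singular <- TRUE
      warn("Random-effects fit is singular; refitting with fixed effects only.")
      mixed <- FALSE
    }
  }
  if (!mixed) {
    fml <- as.formula(paste(spec$outcome, "~",
                            paste(spec$predictors, collapse = " + ")))
    fit <- if (spec$family == "gaussian") {
      lm(fml, data = data)
    } else {
      glm(fml, data = data, family = poisson())
    }
  }
  aov_tbl <- model_anova(fit)
  structure(list(fit = fit, anova = aov_tbl, spec = spec, singular = singular),
            class = "glmm_fit")
}

model_anova <- function(fit) {
  if (inherits(fit, "lmerModLmerTest")) {
    a <- anova(fit, type = 3)
    tibble::tibble(term = rownames(a), statistic = a[["F value"]],
                   df = a[["NumDF"]], p_value = a[["Pr(>F)"]])
  } else if (inherits(fit, "glmerMod")) {
    a <- car_anova_chisq(fit)
    a
  } else if (inherits(fit, "glm")) {
    a <- anova(fit, test = "LRT")
    a <- a[-1, , drop = FALSE]
    tibble::tibble(term = rownames(a), statistic = a[["Deviance"]],
                   df = a[["Df"]], p_value = a[["Pr(>Chi)"]])
  } else {
    a <- anova(fit)
    keep <- rownames(a) != "Residuals"
    tibble::tibble(term = rownames(a)[keep], statistic = a[["F value"]][keep],
                   df = a[["Df"]][keep], p_value = a[["Pr(>F)"]][keep])
  }
}

# Type-II Wald chi-square per fixed-effect term for glmer fits, computed from
# the coefficient covariance (avoids a hard dependency on car for mixed fits).
car_anova_chisq <- function(fit) {
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  asg <- attr(stats::model.matrix(fit), "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  rows <- lapply(seq_along(labs), function(k) {
    idx <- which(asg == k)
    chi <- as.numeric(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx])
    tibble::tibble(term = labs[k], statistic = chi, df = length(idx),
                   p_value = pchisq(chi, length(idx), lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' @exportS3Method base::print
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s ~ %s%s (%s%s)\n", x$spec$outcome,
              paste(x$spec$predictors, collapse = " + "),
              if (length(x$spec$random_effects)) {
                paste0(" + ", paste(x$spec$random_effects, collapse = " + "))
              } else {
                ""
              },
              x$spec$family,
              if (x$singular) ", singular -> fixed effects only" else ""))
  print(x$anova)
  invisible(x)
}

#' @rdname tidy_ramplab
#' @export
tidy.glmm_fit <- function(x, ...) {
  x$anova
}

#' @rdname glance_ramplab
#' @export
glance.glmm_fit <- function(x, ...) {
  fe <- if (inherits(x$fit, "merMod")) lme4::fixef(x$fit) else coef(x$fit)
  tibble::tibble(n_obs = stats::nobs(x$fit), n_terms = length(fe),
                 singular = x$singular,
                 family = x$spec$family)
}

#' Fixed-effect coefficients of a fitted model
#'
#' @param x A `glmm_fit`.
#' @return Named numeric vector.
#' @export
fixed_effects <- function(x) {
  if (inherits(x$fit, "merMod")) lme4::fixef(x$fit) else coef(x$fit)
}

#' Post hoc pairwise contrasts via estimated marginal means
#'
#' All pairwise contrasts between the levels of `factor`, with Tukey
#' adjustment for the comparison family. For a two-level factor the Tukey
#' adjustment leaves the p-value unchanged.
#'
#' @param model A `glmm_fit` (or any model `emmeans` accepts).
#' @param factor Factor name, optionally conditioned as in emmeans specs
#'   (e.g. `"context | area"`).
#' @return Tibble of contrasts with `estimate`, `p_value` and friends.
#' @export
posthoc_marginal_means <- function(model, factor) {
  fit <- if (inherits(model, "glmm_fit")) model$fit else model
  vars <- all.vars(as.formula(paste("~", factor)))
  mf <- stats::model.frame(fit)
  for (v in vars) {
    if (!v %in% names(mf)) {
      abort(sprintf("Factor '%s' is not in the model.", v))
    }
    if (length(unique(mf[[v]])) < 2L) {
      abort(sprintf("Factor '%s' has a single level.", v))
    }
  }
  em <- emmeans::emmeans(fit, specs = as.formula(paste("~", factor)))
  ct <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  out <- tibble::as_tibble(ct)
  names(out)[names(out) == "p.value"] <- "p_value"
  out
}

#' Recorded-unit census of the two-area fixed-interval learning experiment
#'
#' Counts of simultaneously recorded MFC and striatal (DMS) units per animal
#' (7 animals) and day (day 0 = single-interval session; days 1--3 =
#' two-interval sessions), as printed in the source experiment's recording
#' census. Used to recompute session totals and the day-1 denominators of
#' the interval-modulation contingency table.
#'
#' @return Tibble with `day`, `animal`, `mfc`, `str`.
#' @export
unit_count_table <- function() {
  path <- system.file("extdata", "unit_counts.csv", package = "ramplab")
  readr::read_csv(path, col_types = readr::cols(
    day = readr::col_integer(), animal = readr::col_integer(),
    mfc = readr::col_integer(), str = readr::col_integer()
  ))
}

#' Totals of a unit census
#'
#' @param counts Tibble as from [unit_count_table()].
#' @return Tibble with per-area and overall totals for the single-interval
#'   day, the two-interval days, and all sessions.
#' @export
unit_count_totals <- function(counts = unit_count_table()) {
  two <- dplyr::filter(counts, .data$day >= 1)
  tibble::tibble(
    period = c("day0", "two_interval", "all_sessions"),
    mfc = c(sum(counts$mfc[counts$day == 0]), sum(two$mfc), sum(counts$mfc)),
    str = c(sum(counts$str[counts$day == 0]), sum(two$str), sum(counts$str)),
    total = mfc + str
  )
}
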