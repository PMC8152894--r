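test_that("the 2x2 chi-square follows its closed form on random tables", {
  withr::local_seed(1)
  for (i in 1:50) {
    m <- matrix(rpois(4, 20) + 1, 2, 2)
    res <- chi_square_2x2(m)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    closed <- (a * d - b * c)^2 * sum(m) /
      (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
    expect_equal(res$statistic, closed, tolerance = 1e-12)
    # invariance under row and column permutation
    expect_equal(chi_square_2x2(m[2:1, ])$statistic, res$statistic)
    expect_equal(chi_square_2x2(m[, 2:1])$statistic, res$statistic)
  }
})

test_that("chi-square handles the canonical examples and degenerate margins", {
  expect_equal(chi_square_2x2(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(1, 9, 9, 1), 2))$statistic, 12.8,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)))
  expect_error(chi_square_2x2(matrix(1:6, 2)))
})

test_that("signed-rank test and Cohen's d behave on paired samples", {
  expect_error(signed_rank_d(rep(1, 10), rep(1, 10)),
               class = "ramplab_degenerate_test")
  # constant positive difference: zero variance guard caps d
  res <- signed_rank_d(2:11, 1:10)
  expect_true(res$d_capped)
  expect_gt(res$cohens_d, 0)
  expect_lt(res$p_value, 0.01)
  expect_error(signed_rank_d(1:3, 2:4))
})

test_that("signed-rank power and d match a Normal(1,1) difference", {
  withr::local_seed(2)
  rej <- 0; ds <- c()
  for (i in 1:300) {
    y <- rnorm(30)
    x <- y + rnorm(30, 1, 1)
    res <- signed_rank_d(x, y)
    rej <- rej + (res$p_value < 0.05)
    ds <- c(ds, res$cohens_d)
  }
  expect_gt(rej / 300, 0.99)
  expect_lt(abs(mean(ds) - 1), 0.15)
})

test_that("gaussian fit without random effects reproduces OLS", {
  withr::local_seed(3)
  df <- tibble::tibble(x = rnorm(50), g = rep(c("a", "b"), 25))
  df$y <- 1 + 2 * df$x + (df$g == "b") * 0.5 + rnorm(50, 0, 0.3)
  fit <- fit_model(model_spec("y", c("x", "g")), df)
  ols <- lm(y ~ x + g, df)
  expect_equal(unname(fixed_effects(fit)), unname(coef(ols)), tolerance = 1e-8)
  td <- tidy(fit)
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  expect_true(all(td$statistic >= 0))
})

test_that("a mixed model recovers a planted context shift", {
  withr::local_seed(4)
  n_animals <- 7; n_trials <- 200
  df <- tidyr::expand_grid(animal_id = sprintf("A%d", 1:n_animals),
                           context = c("one", "two"),
                           trial = 1:n_trials)
  animal_fx <- setNames(rnorm(n_animals, 0, 0.3), sprintf("A%d", 1:n_animals))
  df$y <- 9.6 + ifelse(df$context == "two", -0.5, 0) +
    animal_fx[df$animal_id] + rnorm(nrow(df), 0, 1.4)
  fit <- fit_model(model_spec("y", "context", "(1|animal_id)"), df)
  eff <- fixed_effects(fit)[["contexttwo"]]
  expect_lt(abs(eff - (-0.5)), 0.15)
  expect_lt(tidy(fit)$p_value[1], 0.001)
})

test_that("fixed-effect tests are calibrated under the null", {
  withr::local_seed(5)
  pvals <- replicate(300, {
    df <- tibble::tibble(g = rep(c("a", "b"), each = 25), y = rnorm(50))
    tidy(fit_model(model_spec("y", "g"), df))$p_value[1]
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})

test_that("poisson firing-rate models recover the ramp direction", {
  withr::local_seed(6)
  cfg <- generator_config(n_trials_per_interval = 60, baseline_rate = 3,
                          ramp_slope_fi12 = 0.5, seed = 7L)
  tr <- simulate_trials(cfg, 0)
  hit <- 0
  for (k in 1:10) {
    cls <- if (k %% 2 == 0) "ramp_up" else "ramp_down"
    res <- simulate_unit(cfg, cls, "MFC", tr$trials)
    counts <- unlist(lapply(seq_len(nrow(tr$trials)), function(i) {
      rel <- trial_relative_spikes(res$unit$spike_times[[1]],
                                   tr$trials$cue_onset[i], c(0, 12))
      tabulate(pmin(floor(rel / 2) + 1, 6), nbins = 6)
    }))
    df <- tibble::tibble(count = counts,
                         time = rep(seq(1, 11, by = 2), nrow(tr$trials)))
    fit <- fit_model(model_spec("count", "time", family = "poisson"), df)
    sign_ok <- sign(fixed_effects(fit)[["time"]]) ==
      sign(res$truth$slope_fi12)
    hit <- hit + sign_ok
  }
  expect_identical(hit, 10)
})

test_that("Tukey post hoc on a two-level factor equals the unadjusted contrast", {
  withr::local_seed(8)
  df <- tibble::tibble(g = rep(c("a", "b"), each = 20),
                       y = rnorm(40) + rep(c(0, 0.8), each = 20))
  fit <- fit_model(model_spec("y", "g"), df)
  ph <- posthoc_marginal_means(fit, "g")
  tt <- summary(lm(y ~ g, df))$coefficients["gb", "Pr(>|t|)"]
  expect_equal(ph$p_value, tt, tolerance = 1e-8)
  expect_error(posthoc_marginal_means(fit, "missing_factor"))
})

test_that("Tukey-adjusted p-values are near 1 for equal groups", {
  withr::local_seed(9)
  med <- median(unlist(replicate(150, {
    df <- tibble::tibble(g = rep(c("a", "b", "c"), each = 15), y = rnorm(45))
    posthoc_marginal_means(fit_model(model_spec("y", "g"), df), "g")$p_value
  }, simplify = FALSE)))
  expect_gt(med, 0.5)
})

test_that("an area-specific context drop is found only where planted", {
  withr::local_seed(10)
  hits_mfc <- 0; hits_dms <- 0; n_sim <- 40
  for (i in 1:n_sim) {
    df <- tidyr::expand_grid(animal_id = sprintf("A%d", 1:7),
                             area = c("MFC", "DMS"),
                             context = c("one", "two"), unit = 1:8)
    fx <- setNames(rnorm(7, 0, 0.3), sprintf("A%d", 1:7))
    # |PC1| drops by 1 in the two-interval context in MFC only
    df$score <- 3 + fx[df$animal_id] +
      ifelse(df$area == "MFC" & df$context == "two", -1, 0) +
      rnorm(nrow(df), 0, 0.8)
    fit <- suppressWarnings(
      fit_model(model_spec("score", "context * area", "(1|animal_id)"), df))
    ph <- posthoc_marginal_means(fit, "context | area")
    p_mfc <- ph$p_value[ph$area == "MFC"]
    p_dms <- ph$p_value[ph$area == "DMS"]
    hits_mfc <- hits_mfc + (p_mfc < 0.05)
    hits_dms <- hits_dms + (p_dms < 0.05)
  }
  expect_gt(hits_mfc / n_sim, 0.9)
  expect_lt(hits_dms / n_sim, 0.3)
})

test_that("the unit census reproduces its printed totals", {
  counts <- unit_count_table()
  expect_identical(nrow(counts), 28L)
  totals <- unit_count_totals(counts)
  expect_identical(totals$mfc[totals$period == "two_interval"], 158L)
  expect_identical(totals$total[totals$period == "all_sessions"], 476L)
  # day-1 denominators of the interval-modulation table
  d1 <- dplyr::filter(counts, day == 1)
  expect_identical(sum(d1$mfc), 47L)
  expect_identical(sum(d1$str), 58L)
})
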