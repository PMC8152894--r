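test_that("rate features span the padded window and normalize", {
  cfg <- decoder_config()
  f <- rate_features(numeric(0), 100, 12, cfg)
  expect_identical(length(f), 240L) # (12 + 2*6) / 0.1
  expect_true(all(f == 0))
  # one spike mid-window: the rate integrates to ~1 spike
  f1 <- rate_features(106, 100, 12, cfg)
  expect_equal(sum(f1) * cfg$bin, 1, tolerance = 1e-3)
  expect_lt(abs(which.max(f1) - 120.5), 1.5)
})

test_that("poisson training means equal the training-trial mean rates", {
  withr::local_seed(3)
  arr <- array(rexp(2 * 5 * 4), dim = c(2, 5, 4))
  centers <- seq(0.05, by = 0.1, length.out = 5)
  model <- train_decoder(arr, centers, decoder_config(pad = 0))
  expect_equal(model$mean_rates, apply(arr, c(1, 2), mean))
  expect_error(train_decoder(arr[, , 1, drop = FALSE], centers),
               class = "ramplab_insufficient_data")
})

test_that("the decoder posterior matches a hand-computed Bayes rule", {
  # two units, two bins, three training trials with hand-set rates
  cfg <- decoder_config(pad = 0)
  train <- array(0, dim = c(2, 2, 3))
  train[1, , 1] <- c(2, 8); train[2, , 1] <- c(6, 1)
  train[1, , 2] <- c(3, 9); train[2, , 2] <- c(5, 2)
  train[1, , 3] <- c(4, 10); train[2, , 3] <- c(7, 3)
  centers <- c(0.05, 0.15)
  model <- train_decoder(train, centers, cfg)
  x <- matrix(c(3, 6, 9, 2), 2, 2) # observed rates: bin1 = (3,6), bin2 = (9,2)
  out <- decode_trial(model, x, return_posterior = TRUE)
  # hand computation: lambda = mean training rate * bin; x_count = rate * bin;
  # continuous-Poisson likelihood per unit, naive product across units,
  # uniform prior, normalized over the two candidate bins
  lam <- apply(train, c(1, 2), mean) * cfg$bin
  loglik <- function(xc, l) xc * log(l) - l - lgamma(xc + 1)
  for (obs in 1:2) {
    logp <- vapply(1:2, function(cand) {
      sum(vapply(1:2, function(u) loglik(x[u, obs] * cfg$bin, lam[u, cand]),
                 numeric(1)))
    }, numeric(1))
    post <- exp(logp - max(logp)); post <- post / sum(post)
    expect_equal(out$posterior[obs, ], post, tolerance = 1e-12)
  }
  # posterior rows sum to one
  expect_equal(rowSums(out$posterior), c(1, 1), tolerance = 1e-9)
})

test_that("a noiseless injective ensemble decodes perfectly (R^2 -> 1)", {
  inj <- injective_feature_array(n_units = 3, n_trials = 4)
  model <- train_decoder(inj$features[, , -1], inj$bin_centers)
  pred <- decode_trial(model, inj$features[, , 1])
  expect_identical(pred$predicted, pred$observed)
})

test_that("a constant-rate ensemble ties to the earliest bin and scores 0", {
  cfg <- decoder_config()
  arr <- array(5, dim = c(2, 240, 4))
  centers <- seq(-5.95, 17.95, by = 0.1)
  model <- train_decoder(arr, centers, cfg)
  pred <- decode_trial(model, arr[, , 1])
  expect_true(all(pred$predicted == centers[1]))
  expect_equal(ramplab:::decode_r2(pred$observed, pred$predicted), 0)
})

test_that("LOOCV decoding of ramping ensembles beats its shuffled null", {
  cfg <- quick_config(n_units_per_area = 6, n_trials_per_interval = 12,
                      ramping_fraction = 0.7, interval_mod_fraction = 0.15,
                      response_locked_fraction = 0)
  res <- simulate_session(cfg, "A1", 0)
  real <- decode_ensemble(res$session, "FI12")
  shuf <- decode_ensemble(res$session, "FI12", shuffle = TRUE, seed = 5L)
  expect_gt(real$r_squared, shuf$r_squared)
  expect_gte(real$r_squared, 0)
  expect_lte(real$r_squared, 1)
  # median in-interval error is small for an informative ensemble
  p <- real$predictions[real$predictions$in_interval, ]
  expect_lt(median(abs(p$predicted - p$observed)), 2)
  # R^2 is invariant to unit ordering
  sess2 <- res$session
  perm <- rev(seq_len(nrow(sess2$units)))
  sess2$units <- sess2$units[perm, ]
  expect_equal(decode_ensemble(sess2, "FI12")$r_squared, real$r_squared,
               tolerance = 1e-12)
  expect_error(decode_ensemble(res$session$units, "FI12",
                               trials = res$session$trials[1:2, ]),
               class = "ramplab_insufficient_data")
})

test_that("decoding is reproducible and the shuffle respects its seed", {
  cfg <- quick_config(n_units_per_area = 3, n_trials_per_interval = 8)
  res <- simulate_session(cfg, "A1", 0)
  a <- decode_ensemble(res$session, "FI12", shuffle = TRUE, seed = 11L)
  b <- decode_ensemble(res$session, "FI12", shuffle = TRUE, seed = 11L)
  c <- decode_ensemble(res$session, "FI12", shuffle = TRUE, seed = 12L)
  expect_identical(a$predictions, b$predictions)
  expect_false(identical(a$predictions, c$predictions))
})

test_that("shuffling is calibrated: untuned ensembles show no real advantage", {
  withr::local_seed(13)
  cfg <- generator_config(n_units_per_area = 4, ramping_fraction = 0,
                          interval_mod_fraction = 0,
                          response_locked_fraction = 0,
                          n_trials_per_interval = 10, days = 0:1, seed = 14L)
  diffs <- replicate(12, {
    seed <- sample.int(1e6, 1)
    res <- simulate_session(cfg, "A1", 1, seed = seed)
    r <- decode_ensemble(res$session, "FI3")$r_squared
    s <- decode_ensemble(res$session, "FI3", shuffle = TRUE,
                         seed = seed + 1L)$r_squared
    r - s
  })
  wt <- suppressWarnings(wilcox.test(diffs))
  expect_gt(wt$p.value, 0.05)
})

test_that("adding an informative unit does not hurt decoding", {
  withr::local_seed(15)
  cfg <- generator_config(n_trials_per_interval = 12, days = 0L, seed = 16L)
  r2_small <- c(); r2_big <- c()
  for (k in 1:8) {
    tr <- simulate_trials(cfg, 0)
    units <- dplyr::bind_rows(
      simulate_unit(cfg, "ramp_up", "MFC", tr$trials, unit_id = "u1")$unit,
      simulate_unit(cfg, "ramp_down", "MFC", tr$trials, unit_id = "u2")$unit,
      simulate_unit(cfg, "untuned", "MFC", tr$trials, unit_id = "u3")$unit
    )
    extra <- simulate_unit(cfg, "ramp_up", "MFC", tr$trials, unit_id = "u4")$unit
    s_small <- fi_session(tr$trials, units, "A1", 0)
    s_big <- fi_session(tr$trials, dplyr::bind_rows(units, extra), "A1", 0)
    r2_small <- c(r2_small, decode_ensemble(s_small, "FI12")$r_squared)
    r2_big <- c(r2_big, decode_ensemble(s_big, "FI12")$r_squared)
  }
  # one-sided: the larger ensemble is at least as good up to simulation noise
  expect_gt(median(r2_big) - median(r2_small), -0.1)
})

test_that("the gaussian-kde likelihood decodes a clean toy ensemble", {
  cfg <- decoder_config(pad = 0, likelihood = "gaussian_kde",
                        kde_rate_bandwidth = 0.5)
  centers <- seq(0.05, by = 0.1, length.out = 6)
  prof <- rbind(seq(2, 12, by = 2), seq(12, 2, by = -2))
  arr <- array(0, dim = c(2, 6, 5))
  withr::local_seed(17)
  for (j in 1:5) arr[, , j] <- prof + rnorm(12, 0, 0.05)
  model <- train_decoder(arr[, , -1], centers, cfg)
  pred <- decode_trial(model, arr[, , 1])
  expect_identical(pred$predicted, pred$observed)
})
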