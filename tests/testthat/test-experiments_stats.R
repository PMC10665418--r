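# Experiment harness and statistical analyses.

test_that("logarithmic regression reproduces known fits", {
  # perfect fit: y = 2 - ln(x)
  x <- c(1, exp(1), exp(2))
  f <- suppressWarnings(fit_log_regression(x, 2 - log(x)))
  expect_equal(f$intercept_a, 2, tolerance = 1e-10)
  expect_equal(f$slope_b, -1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # random points against a closed-form normal-equations solve
  withr::with_seed(23, {
    for (rep in 1:5) {
      xs <- runif(6, 10, 3000)
      ys <- runif(6, 0.5, 8)
      f <- fit_log_regression(xs, ys)
      z <- log(xs)
      bb <- sum((z - mean(z)) * (ys - mean(ys))) / sum((z - mean(z))^2)
      aa <- mean(ys) - bb * mean(z)
      expect_equal(f$slope_b, bb, tolerance = 1e-9)
      expect_equal(f$intercept_a, aa, tolerance = 1e-9)
      pred <- aa + bb * z
      r2 <- 1 - sum((ys - pred)^2) / sum((ys - mean(ys))^2)
      expect_equal(f$r_squared, r2, tolerance = 1e-9)
    }
  })
  expect_error(fit_log_regression(c(5, 5, 5), c(1, 2, 3)), "singular")
  expect_error(fit_log_regression(c(-1, 2), c(1, 2)))
})

test_that("group comparison reproduces the hand-computed unpaired t", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742, tolerance = 1e-3)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)
  expect_true(r$significant)
  expect_true(is.finite(r$normality$W_a))
  same <- c(2.5, 3.5, 4.5)
  r2 <- compare_groups(same, same)
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  # constant groups with equal means: defined limit
  r3 <- compare_groups(rep(2, 4), rep(2, 5))
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)))
})

test_that("EER-WRR correlation has its exact limits and guards", {
  res <- list(eers = c(1, 2, 3, 4), wrrs = 2 * c(1, 2, 3, 4) + 1)
  expect_equal(correlate_eer_wrr(res), 1)
  res$wrrs <- -res$eers
  expect_equal(correlate_eer_wrr(res), -1)
  res$wrrs <- rep(5, 4)
  expect_error(correlate_eer_wrr(res), "zero variance")
})

test_that("experiment runs are reproducible and structured per spec", {
  g <- default_group_table(c(0, 0, 0, 0, 0, 4, 4))
  cfg <- synth_config(groups = g, utterances_per_speaker = 8,
                      master_seed = 66)
  d <- withr::local_tempdir()
  man <- synth_corpus(cfg, d)
  feats <- prepare_features(man, d)
  spec <- experiment_spec("ctrl-desk-8", n_speakers = 8, repetitions = 2,
                          seed = 17)
  ec <- encoder_config(1, 16, 8)
  tc <- train_config(learning_rate = 2e-3, steps = 10, N = 4, M = 3,
                     crop_frames = c(40L, 60L))
  r1 <- run_experiment(man, spec, features = feats, encoder_cfg = ec,
                       train_cfg = tc)
  expect_length(r1$eers, 2)
  expect_length(r1$wrrs, 2)
  expect_true(all(r1$eers >= 0 & r1$eers <= 100))
  expect_equal(r1$mean_eer, mean(r1$eers))
  r2 <- run_experiment(man, spec, features = feats, encoder_cfg = ec,
                       train_cfg = tc)
  expect_identical(r1$eers, r2$eers)
  expect_identical(r1$wrrs, r2$wrrs)
  # insufficient speakers fail loudly with the shortfall named
  big <- experiment_spec("too-big", n_speakers = 50, repetitions = 1)
  expect_error(run_experiment(man, big, features = feats), "only 8")
  # empty sweep: empty result list
  expect_length(training_size_sweep(man, integer(0), features = feats), 0)
})

test_that("age-matched sampling steers cohort ages toward the target", {
  g <- default_group_table(c(0, 0, 0, 30, 30, 0, 0))
  pr <- make_profiles(synth_config(groups = g, master_seed = 88))
  sp <- data.frame(speaker_id = vapply(pr, `[[`, character(1), "speaker_id"),
                   age = vapply(pr, `[[`, numeric(1), "age"))
  withr::with_seed(29, {
    picks <- replicate(40, {
      ids <- pathasv:::sample_speakers(sp, 20,
                                       list(mean = 9.30, sd = 2.60))
      mean(sp$age[match(ids, sp$speaker_id)])
    })
  })
  pool_gap <- abs(mean(sp$age) - 9.30)
  expect_lt(abs(mean(picks) - 9.30), pool_gap + 0.5)
})
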