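# Synthetic corpus generator: profile sampling, waveform properties,
# corpus-level determinism and speaker separability.

test_that("profile counts, ranges and determinism follow the config", {
  g <- default_group_table(c(5, 0, 0, 3, 2, 0, 4))
  cfg <- synth_config(groups = g, master_seed = 21)
  pr <- make_profiles(cfg)
  expect_length(pr, 14)
  groups <- vapply(pr, `[[`, character(1), "group")
  expect_equal(sum(groups == "dysglossia"), 5)
  expect_equal(sum(groups == "CLP"), 5)
  expect_equal(sum(groups == "control"), 4)
  for (p in pr) {
    expect_gt(p$f0_base, 0)
    expect_true(all(diff(p$formant_freqs) > 0))
    expect_true(p$wrr >= 0 && p$wrr <= 100)
    expect_true(p$age >= 2 && p$age <= 94)
  }
  pr2 <- make_profiles(synth_config(groups = g, master_seed = 21))
  expect_identical(pr, pr2)
  expect_false(identical(
    pr, make_profiles(synth_config(groups = g, master_seed = 22))))
  # zero speakers: explicit empty result
  expect_length(make_profiles(synth_config(
    groups = default_group_table(0))), 0)
})

test_that("sampled ages track the configured distribution", {
  g <- default_group_table(0)
  g$n[g$group == "CLP"] <- c(300, 300) # children, target mean 9.58 +/- 3.71
  pr <- make_profiles(synth_config(groups = g, master_seed = 33))
  ages <- vapply(pr, `[[`, numeric(1), "age")
  target_mean <- mean(c(9.69, 9.27))
  se <- mean(c(3.98, 2.58)) / sqrt(600)
  # clipping to [2, 20] shifts the mean slightly; 3 SE plus that bias margin
  expect_lt(abs(mean(ages) - target_mean), 3 * se + 0.15)
  expect_true(all(ages >= 2 & ages <= 20))
})

test_that("a jitter-free voice is periodic at its fundamental", {
  pr <- test_profile(f0 = 120)
  x <- synth_utterance(pr, 2.0, utt_seed = 5, silence_n = c(0L, 0L))
  expect_length(x, 32000)
  expect_lte(max(abs(x)), 1)
  mid <- x[8000:24000]
  ac <- stats::acf(mid, lag.max = 200, plot = FALSE)$acf[-1]
  period <- 16000 / 120
  peak_lag <- which.max(ac[80:200]) + 79 # search away from lag-0 shoulder
  expect_lte(abs(peak_lag - period), 1)
})

test_that("exact duration and distinct spectra across speakers", {
  pr <- test_profile()
  expect_length(synth_utterance(pr, 3.0, 9), 48000)
  pr2 <- test_profile(f0 = 210)
  pr2$formant_freqs <- c(650, 1200, 2800, 3600)
  a <- synth_utterance(pr, 2.0, utt_seed = 7, silence_n = c(0L, 0L))
  b <- synth_utterance(pr2, 2.0, utt_seed = 7, silence_n = c(0L, 0L))
  fa <- colMeans(log_mel(a))
  fb <- colMeans(log_mel(b))
  expect_gt(sqrt(sum((fa - fb)^2)), 0)
})

test_that("corpus generation writes a reproducible, filter-clean manifest", {
  g <- default_group_table(c(0, 0, 0, 0, 0, 2, 2))
  cfg <- synth_config(groups = g, utterances_per_speaker = 10,
                      master_seed = 44)
  d1 <- withr::local_tempdir()
  man <- synth_corpus(cfg, d1)
  expect_equal(nrow(man), 40)
  expect_identical(as.data.frame(apply_exclusion_filters(man)),
                   as.data.frame(man))
  # byte-identical regeneration from the same master seed
  d2 <- withr::local_tempdir()
  synth_corpus(cfg, d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  wavs <- man$wav_path[c(1, 20)]
  for (w in wavs)
    expect_identical(readBin(file.path(d1, w), "raw", 2e6),
                     readBin(file.path(d2, w), "raw", 2e6))
  # audio is valid 16 kHz PCM in [-1, 1]
  got <- read_wav(file.path(d1, man$wav_path[1]))
  expect_equal(got$sample_rate, 16000L)
  expect_lte(max(abs(got$samples)), 1)
})

test_that("a speaker left with fewer than 8 utterances is filtered out", {
  g <- default_group_table(c(0, 0, 0, 0, 0, 3, 0))
  cfg <- synth_config(groups = g, utterances_per_speaker = c(7L, 10L, 10L),
                      master_seed = 45)
  d <- withr::local_tempdir()
  man <- synth_corpus(cfg, d)
  f <- apply_exclusion_filters(man)
  expect_equal(length(unique(man$speaker_id)), 3)
  expect_equal(length(unique(f$speaker_id)), 2)
  expect_false(man$speaker_id[1] %in% f$speaker_id)
})

test_that("speakers are separable in mean log-mel space", {
  g <- default_group_table(c(2, 1, 1, 2, 1, 2, 1))
  cfg <- synth_config(groups = g, utterances_per_speaker = 4,
                      master_seed = 55)
  d <- withr::local_tempdir()
  man <- synth_corpus(cfg, d)
  per_utt <- lapply(seq_len(nrow(man)), function(r) {
    x <- read_wav(file.path(d, man$wav_path[r]))$samples
    colMeans(log_mel(x))
  })
  M <- do.call(rbind, per_utt)
  D <- as.matrix(dist(M))
  same <- outer(man$speaker_id, man$speaker_id, "==") & upper.tri(D)
  diff_spk <- outer(man$speaker_id, man$speaker_id, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff_spk]))
})

test_that("synth config serializes to JSON and back", {
  cfg <- synth_config(groups = default_group_table(c(1, 2, 3, 4, 5, 6, 7)),
                      utterances_per_speaker = 9, master_seed = 77)
  p <- withr::local_tempfile(fileext = ".json")
  write_synth_config(cfg, p)
  got <- read_synth_config(p)
  expect_equal(got$groups$n, cfg$groups$n)
  expect_equal(got$master_seed, cfg$master_seed)
  expect_equal(got$duration_range, cfg$duration_range)
})
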