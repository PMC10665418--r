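# Manifest data model, exclusion filters, age split and file round-trips.

test_that("exclusion filters keep complete speakers and drop deficient ones", {
  m <- make_test_manifest(list(
    list(id = "keep", n_utt = 9),
    list(id = "noisy7", n_utt = 10, flags = rep("noisy", 3)),
    list(id = "nowrr", n_utt = 20, wrr = NA),
    list(id = "noage", n_utt = 12, age = NA),
    list(id = "nodiag", n_utt = 12, diag = FALSE),
    list(id = "noenv", n_utt = 12, env = FALSE)
  ))
  f <- apply_exclusion_filters(m)
  expect_setequal(unique(f$speaker_id), "keep")
  expect_equal(nrow(f), 9)
  expect_true(all(f$quality_flag == "ok"))
})

test_that("utterance-level flags are dropped before the 8-utterance count", {
  # 11 utterances, 3 unusable (noisy / test / multi_speaker) -> 8 remain
  m <- make_test_manifest(list(
    list(id = "a", n_utt = 11, flags = c("noisy", "test", "multi_speaker"))))
  f <- apply_exclusion_filters(m)
  expect_equal(nrow(f), 8)
  # one more bad utterance -> 7 remain -> speaker excluded
  m2 <- make_test_manifest(list(
    list(id = "a", n_utt = 11, flags = rep("noisy", 4))))
  expect_equal(nrow(apply_exclusion_filters(m2)), 0)
})

test_that("filtering is idempotent, monotone, and safe on empty input", {
  m <- make_test_manifest(list(
    list(id = "a", n_utt = 9, flags = "noisy"),
    list(id = "b", n_utt = 8),
    list(id = "c", n_utt = 8, wrr = NA)))
  f1 <- apply_exclusion_filters(m)
  f2 <- apply_exclusion_filters(f1)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_lte(nrow(f1), nrow(m))
  for (s in unique(f1$speaker_id))
    expect_lte(sum(f1$speaker_id == s), sum(m$speaker_id == s))
  empty <- f1[f1$speaker_id == "nope", ]
  expect_equal(nrow(apply_exclusion_filters(empty)), 0)
})

test_that("age split assigns 20-year-olds to children and partitions", {
  m <- make_test_manifest(list(
    list(id = "a21", n_utt = 8, age = 21),
    list(id = "a62", n_utt = 8, age = 62.5),
    list(id = "c20", n_utt = 8, age = 20),
    list(id = "c9", n_utt = 8, age = 9.1),
    list(id = "baby", n_utt = 8, age = 1)))
  s <- split_by_age(m)
  expect_setequal(unique(s$adults$speaker_id), c("a21", "a62"))
  expect_setequal(unique(s$children$speaker_id), c("c20", "c9"))
  expect_length(intersect(s$adults$speaker_id, s$children$speaker_id), 0)
  # union is the input minus the under-2 speaker
  expect_setequal(c(unique(s$adults$speaker_id), unique(s$children$speaker_id)),
                  setdiff(unique(m$speaker_id), "baby"))
  m$age[1] <- -3
  expect_error(split_by_age(m), "negative")
  m$age[1] <- NA
  expect_error(split_by_age(m), "age")
})

test_that("WAV files round-trip within 16-bit quantization", {
  withr::with_seed(1, x <- runif(16000, -0.8, 0.8))
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, p)
  got <- read_wav(p)
  expect_equal(got$sample_rate, 16000L)
  expect_equal(length(got$samples), 16000L)
  expect_lt(max(abs(got$samples - x)), 1.5 / 32768)
  # 1 s of silence: all-zero samples
  write_wav(numeric(16000), p)
  expect_true(all(read_wav(p)$samples == 0))
})

test_that("sample-rate policy rejects or resamples non-16 kHz input", {
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(sin(2 * pi * 440 * (0:7999) / 8000) * 0.5, p, sample_rate = 8000L)
  expect_error(read_wav(p), "sample rate")
  got <- read_wav(p, rate_policy = "resample")
  expect_equal(got$sample_rate, 16000L)
  expect_equal(length(got$samples), 16000L)
})

test_that("manifest CSV round-trips losslessly", {
  m <- make_test_manifest(list(
    list(id = "s1", n_utt = 8, age = 34.5, wrr = 61.25),
    list(id = "s2", n_utt = 9, group = "CLP", mic = "dnt", age = 9),
    list(id = "s3", n_utt = 8, group = "dysphonia", mic = "logi")))
  p <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, p)
  got <- read_manifest(p)
  expect_equal(as.data.frame(got), as.data.frame(m))
})

test_that("manifest validation catches malformed input", {
  df <- as.data.frame(make_test_manifest(list(list(id = "a", n_utt = 8))))
  expect_s3_class(corpus_manifest(df), "corpus_manifest")
  expect_error(corpus_manifest(df[, -3]), "missing columns")
  bad <- df; bad$group[1] <- "aphasia"
  expect_error(corpus_manifest(bad), "unknown pathology group")
  bad <- df; bad$wrr[1] <- 130
  expect_error(corpus_manifest(bad), "WRR")
  bad <- df; bad$duration_s[2] <- 0
  expect_error(corpus_manifest(bad), "duration")
})
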