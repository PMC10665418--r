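# Synthetic pathological-speech corpus generator.
#
# Classic source-filter synthesis: a glottal pulse train (with cycle-to-cycle
# jitter and shimmer) is shaped by a spectral-tilt filter, mixed with
# aspiration noise, and passed through a cascade of second-order formant
# resonators whose targets move from syllable to syllable. Group-specific
# perturbations operationalize the clinical character of each pathology at
# the level an ASV front-end can see:
#   dysphonia  - high jitter / shimmer / breathiness
#   CLP        - hypernasality (extra nasal resonance + antiresonance notch)
#   dysarthria - slowed articulation and reduced formant-transition depth
#   dysglossia - persistent formant-target displacement
# Each speaker carries a stable vocal signature (f0, formant pattern) so that
# identity exists to be verified; WRR is sampled independently of identity.

SAMPLE_RATE <- 16000L

#' Default per-group cohort table
#'
#' One row per (group, microphone) cohort with speaker count and the age/WRR
#' normal-distribution parameters the sampler draws from. Age and WRR moments
#' follow the corpus statistics of the study population (adult pathology
#' groups around 60 years; children 2-20 years; WRR means 48-74%).
#'
#' @param n_per_row Speaker counts, recycled across the 7 cohort rows.
#' @return A data frame usable as the `groups` field of [synth_config()].
#' @export
default_group_table <- function(n_per_row = c(6, 6, 6, 4, 4, 6, 8)) {
  df <- data.frame(
    group      = c("dysglossia", "dysarthria", "dysphonia",
                   "CLP", "CLP", "control", "control"),
    microphone = c("dnt", "plant", "logi", "dnt", "plant", "plant", "plant"),
    age_mean   = c(60.91, 62.70, 59.28, 9.69, 9.27, 23.93, 12.16),
    age_sd     = c(11.95, 15.29, 10.67, 3.98, 2.58, 15.62, 3.72),
    age_min    = c(21, 21, 21, 2, 2, 21, 2),
    age_max    = c(94, 94, 94, 20, 20, 94, 20),
    wrr_mean   = c(62.61, 69.11, 51.78, 48.28, 57.61, 73.72, 65.87),
    wrr_sd     = c(15.96, 12.70, 15.84, 17.30, 13.86, 15.69, 12.44),
    stringsAsFactors = FALSE
  )
  df$n <- as.integer(rep_len(n_per_row, nrow(df)))
  df
}

#' Synthetic corpus configuration
#'
#' @param groups Cohort table as from [default_group_table()].
#' @param utterances_per_speaker Utterances per speaker; a single count or a
#'   vector recycled across speakers.
#' @param duration_range Utterance duration range in seconds (includes the
#'   inserted silences).
#' @param silence_n Range (min, max) of silent gaps inserted per utterance.
#' @param silence_len Range of each silent gap's duration in seconds.
#' @param master_seed Integer seed; all speaker- and utterance-level seeds are
#'   derived from it, so any subset is reproducible independently.
#' @return A `synth_config` object.
#' @export
synth_config <- function(groups = default_group_table(),
                         utterances_per_speaker = 10L,
                         duration_range = c(3.2, 4.2),
                         silence_n = c(1L, 2L),
                         silence_len = c(0.1, 0.3),
                         master_seed = 1L) {
  stopifnot(all(groups$n >= 0), all(duration_range > 0),
            diff(duration_range) >= 0, all(utterances_per_speaker >= 0))
  structure(list(groups = groups,
                 utterances_per_speaker = utterances_per_speaker,
                 duration_range = duration_range,
                 silence_n = as.integer(silence_n),
                 silence_len = silence_len,
                 master_seed = as.integer(master_seed)),
            class = "synth_config")
}

#' Serialize / restore a synthetic-corpus configuration as JSON
#'
#' @param config A [synth_config()].
#' @param path JSON file path.
#' @return `write_synth_config` returns `path` invisibly; `read_synth_config`
#'   returns the restored `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth_config(groups = as.data.frame(x$groups, stringsAsFactors = FALSE),
               utterances_per_speaker = x$utterances_per_speaker,
               duration_range = x$duration_range,
               silence_n = x$silence_n,
               silence_len = x$silence_len,
               master_seed = x$master_seed)
}

# Group-typical voice-quality parameters; small per-speaker scatter is added
# around these in make_profiles().
pathology_defaults <- function(group) {
  switch(group,
    control    = list(jitter_pct = 0.4, shimmer_pct = 2,  breathiness = 0.05,
                      nasality = 0.05, articulation_slowdown = 1.0,
                      transition_depth = 1.0),
    dysphonia  = list(jitter_pct = 2.5, shimmer_pct = 10, breathiness = 0.45,
                      nasality = 0.05, articulation_slowdown = 1.0,
                      transition_depth = 1.0),
    dysarthria = list(jitter_pct = 0.8, shimmer_pct = 4,  breathiness = 0.10,
                      nasality = 0.05, articulation_slowdown = 1.7,
                      transition_depth = 0.35),
    CLP        = list(jitter_pct = 0.6, shimmer_pct = 3,  breathiness = 0.10,
                      nasality = 0.65, articulation_slowdown = 1.0,
                      transition_depth = 1.0),
    dysglossia = list(jitter_pct = 0.5, shimmer_pct = 3,  breathiness = 0.08,
                      nasality = 0.10, articulation_slowdown = 1.1,
                      transition_depth = 0.8),
    stop("unknown group: ", group)
  )
}

derive_seed <- function(master, idx, salt = 0L) {
  # deterministic per-entity seeds, kept below 2^31 - 1
  s <- (as.double(master) * 48271 + as.double(idx) * 12347 +
          as.double(salt) * 7919) %% 2147483646
  as.integer(s) + 1L
}

#' Draw the speaker profiles of a synthetic corpus
#'
#' Each profile fixes the speaker's stable vocal signature: base f0 (set by
#' sex and age), a formant pattern scaled by a per-speaker vocal-tract-length
#' factor with per-formant idiosyncrasy, speaking rate, voice-quality
#' (pathology) parameters, microphone, age and WRR. WRR is drawn
#' independently of all identity parameters.
#'
#' @param config A [synth_config()].
#' @return A list of `speaker_profile` objects (class `speaker_profiles`);
#'   empty list if the configured counts sum to zero.
#' @export
make_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$groups
  total <- sum(g$n)
  if (total == 0) return(structure(list(), class = "speaker_profiles"))
  profiles <- vector("list", total)
  idx <- 0L
  for (row in seq_len(nrow(g))) {
    for (k in seq_len(g$n[row])) {
      idx <- idx + 1L
      seed <- derive_seed(config$master_seed, idx)
      profiles[[idx]] <- withr::with_seed(seed, {
        group <- g$group[row]
        sex <- sample(c("m", "f"), 1)
        age <- min(max(rnorm(1, g$age_mean[row], g$age_sd[row]),
                       g$age_min[row]), g$age_max[row])
        wrr <- min(max(rnorm(1, g$wrr_mean[row], g$wrr_sd[row]), 0), 100)
        child <- age <= 20
        f0 <- if (child) runif(1, 200, 300)
              else if (sex == "m") runif(1, 90, 150) else runif(1, 160, 240)
        # vocal-tract-length factor: children's shorter tracts raise formants
        vtl <- if (child) runif(1, 1.08, 1.35) * (1.15 - 0.008 * age)
               else runif(1, 0.88, 1.12) * if (sex == "m") 0.96 else 1.05
        base_formants <- c(500, 1500, 2500, 3500)
        formants <- base_formants * vtl * runif(4, 0.93, 1.07)
        pd <- pathology_defaults(group)
        pathology <- list(
          jitter_pct = max(pd$jitter_pct * runif(1, 0.7, 1.3), 0),
          shimmer_pct = max(pd$shimmer_pct * runif(1, 0.7, 1.3), 0),
          breathiness = min(max(pd$breathiness * runif(1, 0.7, 1.3), 0), 1),
          nasality = min(max(pd$nasality * runif(1, 0.7, 1.3), 0), 1),
          articulation_slowdown = max(pd$articulation_slowdown *
                                        runif(1, 0.9, 1.1), 1),
          transition_depth = max(pd$transition_depth * runif(1, 0.8, 1.2), 0)
        )
        if (group == "dysglossia") {
          # structural articulation disorder: displaced formant targets
          formants <- formants * runif(4, 0.85, 1.15)
        }
        formants <- sort(formants)
        structure(list(
          speaker_id = sprintf("spk%04d", idx),
          f0_base = f0,
          formant_freqs = formants,
          formant_bandwidths = c(80, 100, 140, 180) * runif(4, 0.9, 1.1),
          speaking_rate = runif(1, 3.5, 5.0),
          group = group, sex = sex, age = age, wrr = wrr,
          microphone = g$microphone[row],
          pathology = pathology,
          rng_seed = seed
        ), class = "speaker_profile")
      })
    }
  }
  structure(profiles, class = "speaker_profiles")
}

# Second-order all-pole resonator (formant) applied via recursive filtering.
resonator <- function(x, freq, bw, fs = SAMPLE_RATE) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * freq / fs
  gain <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
  as.numeric(stats::filter(gain * x, c(2 * r * cos(theta), -r^2),
                           method = "recursive"))
}

# FIR antiresonance (spectral zero), mixed in with the given strength.
antiresonance <- function(x, freq, strength, fs = SAMPLE_RATE) {
  theta <- 2 * pi * freq / fs
  b <- c(1, -2 * cos(theta), 1) / (2 - 2 * cos(theta))
  notched <- as.numeric(signal::filter(b, 1, x))
  (1 - strength) * x + strength * notched
}

# One continuous voiced stretch: pulse-train excitation with jitter/shimmer,
# spectral tilt, aspiration noise, then per-syllable formant filtering.
synth_voiced <- function(profile, dur, fs = SAMPLE_RATE) {
  n <- round(dur * fs)
  if (n < 1) return(numeric(0))
  p <- profile$pathology
  f0 <- profile$f0_base
  n_pulse <- ceiling(dur * f0 * 1.5) + 4
  periods <- (fs / f0) * (1 + (p$jitter_pct / 100) * rnorm(n_pulse))
  periods[periods < fs / 500] <- fs / 500
  pos <- round(cumsum(periods))
  pos <- pos[pos >= 1 & pos <= n]
  amps <- 1 + (p$shimmer_pct / 100) * rnorm(length(pos))
  exc <- numeric(n)
  exc[pos] <- amps
  # glottal spectral tilt (~ -6 dB/oct)
  exc <- as.numeric(stats::filter(exc, 0.96, method = "recursive"))
  if (p$breathiness > 0) {
    noise <- rnorm(n)
    noise <- noise * (sd(exc) / max(sd(noise), 1e-12))
    exc <- (1 - 0.7 * p$breathiness) * exc + 1.2 * p$breathiness * noise
  }

  rate <- profile$speaking_rate / p$articulation_slowdown
  n_syll <- max(1L, round(dur * rate))
  bounds <- round(seq(0, n, length.out = n_syll + 1))
  spread <- c(0.18, 0.15, 0.08, 0.05) * p$transition_depth
  out <- numeric(n)
  for (s in seq_len(n_syll)) {
    seg <- (bounds[s] + 1):bounds[s + 1]
    if (length(seg) < 4) next
    targets <- profile$formant_freqs * (1 + spread * runif(4, -1, 1))
    y <- exc[seg]
    for (k in seq_along(targets)) {
      y <- resonator(y, targets[k], profile$formant_bandwidths[k], fs)
    }
    if (p$nasality > 0.01) {
      y <- y + p$nasality * 0.9 * resonator(exc[seg], 250, 100, fs)
      y <- antiresonance(y, 1000, p$nasality, fs)
    }
    out[seg] <- y
  }
  # 5 ms raised-cosine edges to avoid onset/offset clicks
  ramp <- min(round(0.005 * fs), floor(n / 2))
  if (ramp > 1) {
    w <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    out[seq_len(ramp)] <- out[seq_len(ramp)] * w
    out[(n - ramp + 1):n] <- out[(n - ramp + 1):n] * rev(w)
  }
  out
}

# Fixed coloration filter and noise floor per microphone label. The labels
# are arbitrary-but-fixed distinguishable channels, not measurements of the
# physical headsets.
MIC_CHANNELS <- list(
  dnt   = list(fir = c(0.85, 0.18, 0.06), noise_db = -55),
  plant = list(fir = c(1.00, -0.32, 0.08), noise_db = -58),
  logi  = list(fir = c(0.70, 0.32, -0.12, 0.05), noise_db = -52)
)

apply_microphone <- function(x, microphone) {
  ch <- MIC_CHANNELS[[microphone]]
  if (is.null(ch)) stop("unknown microphone label: ", microphone)
  y <- as.numeric(signal::filter(ch$fir, 1, x))
  y <- y / max(max(abs(y)), 1e-12) * 0.9
  y + rnorm(length(y)) * 0.9 * 10^(ch$noise_db / 20)
}

#' Synthesize one utterance for a speaker
#'
#' Voiced stretches generated by the speaker's source-filter model are
#' separated by silent gaps, the result is peak-normalized and passed through
#' the speaker's microphone channel (coloration FIR plus noise floor).
#' Deterministic given `(profile, utt_seed)`.
#'
#' @param profile A `speaker_profile` from [make_profiles()].
#' @param duration Total utterance duration in seconds (>= 0.5).
#' @param utt_seed Integer seed for this utterance.
#' @param silence_n Range (min, max) of silent gaps to insert.
#' @param silence_len Range of each gap's duration in seconds.
#' @return Numeric waveform at 16 kHz with peak amplitude <= 1.
#' @export
synth_utterance <- function(profile, duration, utt_seed,
                            silence_n = c(1L, 2L),
                            silence_len = c(0.1, 0.3)) {
  stopifnot(inherits(profile, "speaker_profile"), duration >= 0.5)
  fs <- SAMPLE_RATE
  n_total <- round(duration * fs)
  withr::with_seed(as.integer(utt_seed), {
    n_sil <- if (silence_n[2] > 0)
      sample(seq(silence_n[1], silence_n[2]), 1) else 0L
    sil_durs <- if (n_sil > 0) runif(n_sil, silence_len[1], silence_len[2])
                else numeric(0)
    # keep at least 70% of the utterance voiced
    if (sum(sil_durs) > 0.3 * duration)
      sil_durs <- sil_durs * (0.3 * duration / sum(sil_durs))
    voiced_total <- duration - sum(sil_durs)
    prop <- runif(n_sil + 1, 0.6, 1.4)
    chunk_durs <- voiced_total * prop / sum(prop)
    pieces <- vector("list", 2 * n_sil + 1)
    for (ci in seq_len(n_sil + 1)) {
      v <- synth_voiced(profile, chunk_durs[ci])
      v <- v / max(max(abs(v)), 1e-12)
      pieces[[2 * ci - 1]] <- v
      if (ci <= n_sil) pieces[[2 * ci]] <- numeric(round(sil_durs[ci] * fs))
    }
    x <- unlist(pieces)
    # pad/trim rounding drift so length is exactly duration * fs
    if (length(x) < n_total) x <- c(x, numeric(n_total - length(x)))
    x <- x[seq_len(n_total)]
    x <- x / max(max(abs(x)), 1e-12) * 0.9
    x <- apply_microphone(x, profile$microphone)
    pmax(pmin(x, 1), -1)
  })
}

#' Generate a synthetic corpus on disk
#'
#' Draws speaker profiles, synthesizes every utterance as a 16 kHz 16-bit
#' PCM WAV under `out_dir`, and writes `manifest.csv` alongside. Fully
#' reproducible from `config$master_seed`.
#'
#' @param config A [synth_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return The [corpus_manifest()] of the generated corpus (wav paths are
#'   relative to `out_dir`).
#' @export
synth_corpus <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  profiles <- make_profiles(config)
  n_utts <- rep_len(as.integer(config$utterances_per_speaker),
                    max(length(profiles), 1L))
  rows <- list()
  for (si in seq_along(profiles)) {
    pr <- profiles[[si]]
    for (ui in seq_len(n_utts[si])) {
      utt_seed <- derive_seed(pr$rng_seed, ui, salt = 101L)
      duration <- withr::with_seed(derive_seed(pr$rng_seed, ui, salt = 202L),
        runif(1, config$duration_range[1], config$duration_range[2]))
      x <- synth_utterance(pr, duration, utt_seed,
                           silence_n = config$silence_n,
                           silence_len = config$silence_len)
      fname <- sprintf("%s_utt%02d.wav", pr$speaker_id, ui)
      fpath <- file.path(out_dir, fname)
      if (inherits(try(write_wav(x, fpath), silent = TRUE), "try-error"))
        stop("failed to write WAV: ", fpath)
      rows[[length(rows) + 1L]] <- data.frame(
        speaker_id = pr$speaker_id,
        utterance_id = sprintf("%s_utt%02d", pr$speaker_id, ui),
        wav_path = fname,
        age = pr$age, sex = pr$sex, group = pr$group,
        microphone = pr$microphone, wrr = pr$wrr,
        quality_flag = "ok",
        duration_s = length(x) / SAMPLE_RATE,
        diagnosis_present = TRUE, environment_present = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(speaker_id = character(), utterance_id = character(),
               wav_path = character(), age = numeric(), sex = character(),
               group = character(), microphone = character(), wrr = numeric(),
               quality_flag = character(), duration_s = numeric(),
               diagnosis_present = logical(), environment_present = logical(),
               stringsAsFactors = FALSE)
  manifest <- corpus_manifest(df)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
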