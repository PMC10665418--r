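# Waveform conditioning and feature extraction: low-energy pruning, voice
# activity detection, partial-utterance extraction, 40-band log-mel features
# and training-batch assembly.

#' Front-end configuration
#'
#' @param prune_threshold_db Frames this many dB below the utterance's peak
#'   level are pruned (default 30; the reference is the utterance's own peak
#'   since absolute SPL is unrecoverable from digital samples).
#' @param vad_window_ms Energy window for voice activity detection (30 ms).
#' @param vad_max_silence_ms Silent gaps up to this length are bridged (6 ms).
#' @param vad_smoothing_ms Moving-average smoothing of the activity decision
#'   (8 ms).
#' @param vad_threshold_db Activity threshold relative to the peak envelope
#'   level (default 35 dB below peak).
#' @param min_partial_ms Minimum length of a partial utterance kept for
#'   training (1825 ms).
#' @param n_mels Number of mel bands (40).
#' @param win_ms,hop_ms STFT window and hop (25 ms / 10 ms).
#' @param n_fft FFT size (512).
#' @param sample_rate Sample rate in Hz (16000).
#' @param mel_style `"slaney"` (linear below 1 kHz, log above) or `"htk"`.
#' @param fmin,fmax Mel filterbank edge frequencies (0 Hz to Nyquist).
#' @return A `frontend_config` object.
#' @export
frontend_config <- function(prune_threshold_db = 30,
                            vad_window_ms = 30,
                            vad_max_silence_ms = 6,
                            vad_smoothing_ms = 8,
                            vad_threshold_db = 35,
                            min_partial_ms = 1825,
                            n_mels = 40L,
                            win_ms = 25,
                            hop_ms = 10,
                            n_fft = 512L,
                            sample_rate = 16000L,
                            mel_style = c("slaney", "htk"),
                            fmin = 0,
                            fmax = NULL) {
  mel_style <- match.arg(mel_style)
  if (is.null(fmax)) fmax <- sample_rate / 2
  win <- round(win_ms * sample_rate / 1000)
  hop <- round(hop_ms * sample_rate / 1000)
  stopifnot(win > hop, hop > 0, n_fft >= win, n_mels > 0)
  structure(list(prune_threshold_db = prune_threshold_db,
                 vad_window_ms = vad_window_ms,
                 vad_max_silence_ms = vad_max_silence_ms,
                 vad_smoothing_ms = vad_smoothing_ms,
                 vad_threshold_db = vad_threshold_db,
                 min_partial_ms = min_partial_ms,
                 n_mels = as.integer(n_mels),
                 win = as.integer(win), hop = as.integer(hop),
                 n_fft = as.integer(n_fft),
                 sample_rate = as.integer(sample_rate),
                 mel_style = mel_style, fmin = fmin, fmax = fmax),
            class = "frontend_config")
}

# moving average via cumulative sums (centered, partial windows at edges)
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1 || n == 0) return(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Prune low-energy intervals from a waveform
#'
#' Splits the waveform into 10 ms frames and removes frames whose RMS level is
#' more than `prune_threshold_db` below the utterance's peak frame level; the
#' surviving frames are concatenated in order.
#'
#' @param waveform Mono waveform in `[-1, 1]`.
#' @param config A [frontend_config()].
#' @return The pruned waveform (possibly empty if everything is below the
#'   threshold, e.g. digital silence).
#' @export
prune_low_energy <- function(waveform, config = frontend_config()) {
  n <- length(waveform)
  if (n == 0) return(numeric(0))
  fl <- round(0.010 * config$sample_rate)
  starts <- seq(1, n, by = fl)
  rms_db <- vapply(starts, function(s) {
    seg <- waveform[s:min(s + fl - 1, n)]
    20 * log10(sqrt(mean(seg^2)) + 1e-12)
  }, numeric(1))
  peak <- max(rms_db)
  if (peak <= 20 * log10(2e-12)) return(numeric(0)) # all-silent input
  keep <- rms_db > peak - config$prune_threshold_db
  idx <- unlist(lapply(which(keep), function(i)
    starts[i]:min(starts[i] + fl - 1, n)))
  waveform[idx]
}

#' Detect voice activity
#'
#' Short-time-energy VAD: an RMS envelope over `vad_window_ms` windows is
#' thresholded `vad_threshold_db` below its peak, the binary decision is
#' smoothed by a `vad_smoothing_ms` moving average, and silent gaps shorter
#' than `vad_max_silence_ms` are bridged.
#'
#' @param waveform Mono waveform.
#' @param config A [frontend_config()].
#' @return A data frame of half-open sample intervals (`start`, `end`),
#'   1-based, sorted and non-overlapping; zero rows for silent input.
#' @export
detect_voice_activity <- function(waveform, config = frontend_config()) {
  empty <- data.frame(start = integer(0), end = integer(0))
  n <- length(waveform)
  if (n == 0) return(empty)
  fs <- config$sample_rate
  wlen <- max(round(config$vad_window_ms * fs / 1000), 1)
  env <- sqrt(pmax(moving_average(waveform^2, wlen), 0))
  env_db <- 20 * log10(env + 1e-12)
  peak <- max(env_db)
  if (peak <= 20 * log10(2e-12)) return(empty)
  active <- as.numeric(env_db > peak - config$vad_threshold_db)
  smooth <- max(round(config$vad_smoothing_ms * fs / 1000), 1)
  active <- moving_average(active, smooth) > 0.5
  # bridge silent gaps shorter than the maximum silence length
  max_gap <- round(config$vad_max_silence_ms * fs / 1000)
  r <- rle(active)
  if (length(r$lengths) > 1) {
    gap <- !r$values & r$lengths <= max_gap
    gap[1] <- FALSE
    gap[length(gap)] <- FALSE
    r$values[gap] <- TRUE
    active <- inverse.rle(r)
    r <- rle(active)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep], end = ends[keep] + 1L) # half-open
}

#' Extract partial utterances
#'
#' Keeps the contiguous voiced stretches found by [detect_voice_activity()]
#' whose duration is at least `min_partial_ms` (29200 samples at 16 kHz for
#' the default 1825 ms) and returns them as waveforms.
#'
#' @param waveform Mono waveform the intervals refer to.
#' @param vad_intervals Data frame from [detect_voice_activity()].
#' @param config A [frontend_config()].
#' @return A list of waveform vectors (possibly empty).
#' @export
extract_partials <- function(waveform, vad_intervals,
                             config = frontend_config()) {
  min_len <- round(config$min_partial_ms * config$sample_rate / 1000)
  out <- list()
  for (i in seq_len(nrow(vad_intervals))) {
    s <- vad_intervals$start[i]
    e <- vad_intervals$end[i] - 1L
    if (e - s + 1L >= min_len) out[[length(out) + 1L]] <- waveform[s:e]
  }
  out
}

# mel <-> Hz conversions
hz_to_mel <- function(f, style) {
  if (style == "htk") return(2595 * log10(1 + f / 700))
  # Slaney: linear below 1 kHz, logarithmic above
  ifelse(f < 1000, f * 3 / 200, 15 + log(f / 1000) / (log(6.4) / 27))
}
mel_to_hz <- function(m, style) {
  if (style == "htk") return(700 * (10^(m / 2595) - 1))
  ifelse(m < 15, m * 200 / 3, 1000 * exp((m - 15) * log(6.4) / 27))
}

#' Triangular mel filterbank matrix
#'
#' @param config A [frontend_config()].
#' @return A `n_mels x (n_fft/2 + 1)` matrix of triangular weights
#'   (Slaney-style area normalization).
#' @export
mel_filterbank <- function(config = frontend_config()) {
  n_bins <- config$n_fft %/% 2 + 1
  freqs <- seq(0, config$sample_rate / 2, length.out = n_bins)
  mel_pts <- seq(hz_to_mel(config$fmin, config$mel_style),
                 hz_to_mel(config$fmax, config$mel_style),
                 length.out = config$n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts, config$mel_style)
  fb <- matrix(0, config$n_mels, n_bins)
  for (m in seq_len(config$n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / max(ce - lo, 1e-12)
    down <- (hi - freqs) / max(hi - ce, 1e-12)
    tri <- pmax(0, pmin(up, down))
    fb[m, ] <- tri * 2 / (hi - lo) # Slaney area normalization
  }
  fb
}

#' Log-mel filterbank energies
#'
#' Frames the waveform with a periodic Hann window (25 ms window, 10 ms hop,
#' no padding or centering), takes a 512-point power spectrum, applies the
#' triangular mel filterbank and a log with floor `1e-10`. The frame count is
#' `1 + floor((n_samples - win) / hop)`.
#'
#' @param waveform Mono waveform of at least one window (400 samples).
#' @param config A [frontend_config()].
#' @return A `T x n_mels` matrix of finite log-energies with attribute
#'   `utterance_id` if set on the input.
#' @export
log_mel <- function(waveform, config = frontend_config()) {
  n <- length(waveform)
  win <- config$win
  hop <- config$hop
  if (n < win)
    stop("waveform too short for feature extraction: ", n,
         " samples < one window of ", win)
  n_frames <- 1 + (n - win) %/% hop
  idx <- outer(seq_len(win), seq(0, n_frames - 1) * hop, "+")
  frames <- matrix(waveform[idx], nrow = win)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  frames <- frames * hann
  padded <- matrix(0, config$n_fft, n_frames)
  padded[seq_len(win), ] <- frames
  spec <- stats::mvfft(padded)[seq_len(config$n_fft %/% 2 + 1), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- mel_filterbank(config)
  feats <- t(log(pmax(fb %*% power, 1e-10)))
  feats
}

#' Condition an utterance and extract its partial-utterance features
#'
#' Runs the training-side pipeline: prune low-energy intervals, detect voice
#' activity, extract partial utterances of at least `min_partial_ms`, and
#' compute log-mel features for each. The evaluation-side variant
#' concatenates all partials before feature extraction.
#'
#' @param waveform Mono waveform.
#' @param config A [frontend_config()].
#' @param concatenate If `TRUE`, return a single feature matrix of the
#'   concatenated partials (evaluation convention) instead of a list.
#' @return A list of `T x n_mels` matrices (or one matrix when
#'   `concatenate = TRUE`); empty list / `NULL` when no partial survives.
#' @export
utterance_features <- function(waveform, config = frontend_config(),
                               concatenate = FALSE) {
  pruned <- prune_low_energy(waveform, config)
  if (length(pruned) < config$win) return(if (concatenate) NULL else list())
  intervals <- detect_voice_activity(pruned, config)
  partials <- extract_partials(pruned, intervals, config)
  if (length(partials) == 0) return(if (concatenate) NULL else list())
  if (concatenate) {
    log_mel(unlist(partials), config)
  } else {
    lapply(partials, log_mel, config = config)
  }
}

#' Assemble a GE2E training batch
#'
#' Samples `N` speakers without replacement and `M` distinct partial
#' utterances per speaker, draws one common crop length `L` (in frames)
#' uniformly from `crop_frames`, and randomly crops every partial to `L`
#' frames. Rows are grouped by speaker. Deterministic given the R RNG state.
#'
#' @param features_by_speaker Named list: speaker id -> list of `T x n_mels`
#'   partial feature matrices.
#' @param N Speakers per batch.
#' @param M Partials per speaker.
#' @param crop_frames Inclusive range the common crop length is drawn from.
#' @return A list with `features` (array `(N*M) x L x n_mels`, rows
#'   speaker-major), `speaker` (ids per row), `N`, `M`, `L`.
#' @export
make_training_batch <- function(features_by_speaker, N = 16L, M = 4L,
                                crop_frames = c(140L, 180L)) {
  eligible <- names(features_by_speaker)[
    vapply(features_by_speaker, length, integer(1)) >= M]
  if (length(eligible) < N)
    stop("need ", N, " speakers with >= ", M, " partials, have ",
         length(eligible))
  speakers <- sample(eligible, N)
  chosen <- lapply(speakers, function(s)
    features_by_speaker[[s]][sample(length(features_by_speaker[[s]]), M)])
  min_T <- min(vapply(unlist(chosen, recursive = FALSE), nrow, integer(1)))
  L <- sample(seq(crop_frames[1], crop_frames[2]), 1)
  L <- min(L, min_T)
  n_mels <- ncol(chosen[[1]][[1]])
  feats <- array(0, dim = c(N * M, L, n_mels))
  row <- 0L
  for (j in seq_len(N)) {
    for (i in seq_len(M)) {
      row <- row + 1L
      f <- chosen[[j]][[i]]
      start <- if (nrow(f) > L) sample(nrow(f) - L + 1L, 1) else 1L
      feats[row, , ] <- f[start:(start + L - 1L), ]
    }
  }
  list(features = feats, speaker = rep(speakers, each = M),
       N = as.integer(N), M = as.integer(M), L = as.integer(L))
}

#' Extract partial features for every utterance of a manifest
#'
#' Reads each WAV once and caches both the per-partial feature matrices
#' (training side) and the concatenated per-utterance features (evaluation
#' side).
#'
#' @param manifest A [corpus_manifest()].
#' @param audio_dir Directory `wav_path` entries are relative to.
#' @param config A [frontend_config()].
#' @return A list with `partials` (speaker id -> list of feature matrices
#'   pooled over the speaker's utterances) and `utterances` (speaker id ->
#'   named list of concatenated feature matrices, one per utterance).
#' @export
prepare_features <- function(manifest, audio_dir,
                             config = frontend_config()) {
  stopifnot(inherits(manifest, "corpus_manifest"))
  speakers <- unique(manifest$speaker_id)
  partials <- stats::setNames(vector("list", length(speakers)), speakers)
  utterances <- stats::setNames(vector("list", length(speakers)), speakers)
  for (r in seq_len(nrow(manifest))) {
    sid <- manifest$speaker_id[r]
    wav <- read_wav(file.path(audio_dir, manifest$wav_path[r]),
                    expected_rate = config$sample_rate)
    parts <- utterance_features(wav$samples, config)
    if (length(parts) == 0) next
    partials[[sid]] <- c(partials[[sid]], parts)
    utterances[[sid]][[manifest$utterance_id[r]]] <-
      do.call(rbind, parts)
  }
  list(partials = partials, utterances = utterances)
}
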