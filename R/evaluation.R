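# Enrollment/evaluation: sliding-window utterance d-vectors, cosine scoring,
# verification trials and equal error rate.

#' Evaluation configuration
#'
#' @param window_frames Sliding-window length over the utterance's feature
#'   frames (160).
#' @param overlap_pct Window overlap in percent (50).
#' @param eval_M Utterances per test speaker: `eval_M - 1` enroll and one
#'   probes (default 2, i.e. a single enrollment utterance; the probe is
#'   never part of its own speaker model).
#' @return An `eval_config` object.
#' @export
eval_config <- function(window_frames = 160L, overlap_pct = 50, eval_M = 2L) {
  stopifnot(window_frames > 0, overlap_pct > 0, overlap_pct < 100, eval_M >= 2)
  structure(list(window_frames = as.integer(window_frames),
                 overlap_pct = overlap_pct, eval_M = as.integer(eval_M)),
            class = "eval_config")
}

#' Utterance-level d-vector
#'
#' Slides a fixed window (160 frames, 50% overlap) over the utterance's
#' concatenated partial-utterance features, encodes each window, element-wise
#' averages the window d-vectors and re-normalizes to unit length. An
#' utterance shorter than one window is encoded as a single window of all its
#' frames.
#'
#' @param encoder A trained `ge2e_encoder`.
#' @param features `T x n_mels` feature matrix of the utterance.
#' @param config An [eval_config()].
#' @return A unit-norm embedding vector.
#' @export
utterance_dvector <- function(encoder, features, config = eval_config()) {
  T_frames <- nrow(features)
  if (is.null(T_frames) || T_frames < 1)
    stop("utterance has no feature frames to encode")
  win <- config$window_frames
  step <- max(1L, as.integer(round(win * (1 - config$overlap_pct / 100))))
  if (T_frames < win) {
    emb <- encode(encoder, features)
    return(as.numeric(emb[1, ]))
  }
  starts <- seq(1L, T_frames - win + 1L, by = step)
  wins <- array(0, dim = c(length(starts), win, ncol(features)))
  for (s in seq_along(starts))
    wins[s, , ] <- features[starts[s]:(starts[s] + win - 1L), ]
  emb <- encode(encoder, wins)
  as.numeric(l2_normalize(colMeans(emb)))
}

#' Cosine similarity score
#'
#' Normalized dot product between a test d-vector and a speaker model
#' (centroid); lies in `[-1, 1]`.
#'
#' @param e Test d-vector.
#' @param c_k Speaker-model vector (enrollment centroid).
#' @return The cosine score.
#' @export
cosine_score <- function(e, c_k) {
  ne <- sqrt(sum(e^2))
  nc <- sqrt(sum(c_k^2))
  if (ne < 1e-12 || nc < 1e-12) stop("zero-norm vector in cosine score")
  sum(e * c_k) / (ne * nc)
}

#' Build verification trials for a test set
#'
#' For each test speaker, `eval_M` of their utterance d-vectors are used:
#' `eval_M - 1` form the enrollment centroid (for the default `eval_M = 2`, a
#' single enrollment utterance) and one probes. Every probe is scored against
#' all enrollment centroids: its own speaker's centroid gives a genuine
#' score, every other speaker's an impostor score, so the evaluation batch
#' spans all test speakers.
#'
#' @param dvectors_by_speaker Named list: speaker id -> matrix of utterance
#'   d-vectors (rows). Speakers with fewer than `eval_M` rows are dropped
#'   with a warning.
#' @param config An [eval_config()].
#' @return A list with `genuine` and `impostor` score vectors (class
#'   `trial_scores`).
#' @export
build_trials <- function(dvectors_by_speaker, config = eval_config()) {
  M <- config$eval_M
  n_utt <- vapply(dvectors_by_speaker, nrow, integer(1))
  if (any(n_utt < M)) {
    warning(sum(n_utt < M), " speaker(s) with fewer than ", M,
            " utterances excluded from trials")
    dvectors_by_speaker <- dvectors_by_speaker[n_utt >= M]
  }
  n_spk <- length(dvectors_by_speaker)
  if (n_spk < 2) stop("need at least 2 test speakers for trials")
  enroll <- matrix(0, n_spk, ncol(dvectors_by_speaker[[1]]))
  probes <- matrix(0, n_spk, ncol(dvectors_by_speaker[[1]]))
  for (j in seq_len(n_spk)) {
    d <- dvectors_by_speaker[[j]]
    pick <- sample(nrow(d), M)
    probes[j, ] <- d[pick[1], ]
    enroll[j, ] <- colMeans(d[pick[-1], , drop = FALSE])
  }
  genuine <- numeric(n_spk)
  impostor <- numeric(n_spk * (n_spk - 1))
  ii <- 0L
  for (j in seq_len(n_spk)) {
    for (k in seq_len(n_spk)) {
      s <- cosine_score(probes[j, ], enroll[k, ])
      if (k == j) genuine[j] <- s
      else { ii <- ii + 1L; impostor[ii] <- s }
    }
  }
  structure(list(genuine = genuine, impostor = impostor),
            class = "trial_scores")
}

#' Equal error rate
#'
#' Sweeps all observed scores as decision thresholds (score >= threshold
#' accepts), computing the false acceptance rate FAR (impostors accepted) and
#' false rejection rate FRR (genuine rejected) at each; the EER is the common
#' value at the FAR/FRR crossing, linearly interpolated between the
#' bracketing thresholds where `FAR - FRR` changes sign (ties broken toward
#' the lower threshold). Reported in percent.
#'
#' @param scores A `trial_scores` list with non-empty `genuine` and
#'   `impostor` vectors.
#' @return A list with `eer` (percent) and `threshold`.
#' @export
compute_eer <- function(scores) {
  g <- scores$genuine
  im <- scores$impostor
  stopifnot(length(g) > 0, length(im) > 0)
  thr <- sort(unique(c(g, im)))
  far <- vapply(thr, function(t) mean(im >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(g < t), numeric(1))
  # sentinel above all scores: reject everything (FAR 0, FRR 1) so the
  # FAR/FRR crossing always exists within the sweep
  thr <- c(thr, thr[length(thr)] + 1)
  far <- c(far, 0)
  frr <- c(frr, 1)
  d <- far - frr
  i2 <- which(d <= 0)[1]
  if (d[i2] == 0 || i2 == 1)
    return(list(eer = 100 * far[i2], threshold = thr[i2]))
  i1 <- i2 - 1L
  alpha <- d[i1] / (d[i1] - d[i2])
  eer <- frr[i1] + alpha * (frr[i2] - frr[i1])
  list(eer = 100 * eer, threshold = thr[i1] + alpha * (thr[i2] - thr[i1]))
}
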