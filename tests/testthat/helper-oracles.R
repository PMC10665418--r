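# Independent scalar oracles used to cross-check the vectorized / compiled
# implementations. Deliberately naive: explicit loops, no log-sum-exp trick,
# no shared code with the package internals.

brute_cos <- function(u, v) {
  du <- 0; dv <- 0; dd <- 0
  for (q in seq_along(u)) {
    dd <- dd + u[q] * v[q]
    du <- du + u[q]^2
    dv <- dv + v[q]^2
  }
  dd / (sqrt(du) * sqrt(dv))
}

# scalar-by-scalar evaluation of the similarity matrix definition
brute_sim_matrix <- function(emb, N, M, w, b) {
  S <- array(NA_real_, dim = c(N, M, N))
  for (j in 1:N) {
    for (i in 1:M) {
      e <- emb[(j - 1) * M + i, ]
      for (k in 1:N) {
        if (k == j) {
          ck <- rep(0, ncol(emb))
          for (i2 in setdiff(1:M, i))
            ck <- ck + emb[(j - 1) * M + i2, ]
          ck <- ck / (M - 1)
        } else {
          ck <- rep(0, ncol(emb))
          for (i2 in 1:M) ck <- ck + emb[(k - 1) * M + i2, ]
          ck <- ck / M
        }
        S[j, i, k] <- w * brute_cos(e, ck) + b
      }
    }
  }
  S
}

# naive per-element loss (no numerical stabilization)
brute_ge2e_loss <- function(S) {
  N <- dim(S)[1]; M <- dim(S)[2]
  total <- 0
  for (j in 1:N) {
    for (i in 1:M) {
      sum_exp <- 0
      for (k in 1:N) sum_exp <- sum_exp + exp(S[j, i, k])
      total <- total + (-S[j, i, j] + log(sum_exp))
    }
  }
  total / (M * N)
}

# exhaustive threshold sweep for the equal error rate, with the same linear
# interpolation convention at the FAR/FRR crossing (counting done by loops)
brute_eer <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  thr <- c(thr, max(thr) + 1)
  far <- numeric(length(thr)); frr <- numeric(length(thr))
  for (ti in seq_along(thr)) {
    fa <- 0; fr <- 0
    for (s in impostor) if (s >= thr[ti]) fa <- fa + 1
    for (s in genuine) if (s < thr[ti]) fr <- fr + 1
    far[ti] <- fa / length(impostor)
    frr[ti] <- fr / length(genuine)
  }
  i2 <- NA
  for (ti in seq_along(thr)) {
    if (far[ti] - frr[ti] <= 0) { i2 <- ti; break }
  }
  if (far[i2] == frr[i2] || i2 == 1) return(100 * far[i2])
  i1 <- i2 - 1
  d1 <- far[i1] - frr[i1]; d2 <- far[i2] - frr[i2]
  alpha <- d1 / (d1 - d2)
  100 * (frr[i1] + alpha * (frr[i2] - frr[i1]))
}

random_unit_rows <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# a bare-bones speaker profile for controlled synthesis in tests
test_profile <- function(f0 = 120, jitter = 0, shimmer = 0, breath = 0,
                         nasality = 0, slowdown = 1, depth = 0,
                         microphone = "plant") {
  structure(list(
    speaker_id = "test", f0_base = f0,
    formant_freqs = c(500, 1500, 2500, 3500),
    formant_bandwidths = c(80, 100, 140, 180),
    speaking_rate = 4, group = "control", sex = "m", age = 30, wrr = 70,
    microphone = microphone,
    pathology = list(jitter_pct = jitter, shimmer_pct = shimmer,
                     breathiness = breath, nasality = nasality,
                     articulation_slowdown = slowdown,
                     transition_depth = depth),
    rng_seed = 1L), class = "speaker_profile")
}

# manifest construction without audio on disk
make_test_manifest <- function(speakers) {
  rows <- lapply(seq_along(speakers), function(si) {
    s <- speakers[[si]]
    n <- s$n_utt
    flags <- rep("ok", n)
    if (!is.null(s$flags)) flags[seq_along(s$flags)] <- s$flags
    data.frame(
      speaker_id = s$id, utterance_id = sprintf("%s_u%02d", s$id, 1:n),
      wav_path = sprintf("%s_u%02d.wav", s$id, 1:n),
      age = if (is.null(s$age)) 40 else s$age,
      sex = "f", group = if (is.null(s$group)) "control" else s$group,
      microphone = if (is.null(s$mic)) "plant" else s$mic,
      wrr = if (is.null(s$wrr)) 70 else s$wrr,
      quality_flag = flags, duration_s = 3,
      diagnosis_present = if (is.null(s$diag)) TRUE else s$diag,
      environment_present = if (is.null(s$env)) TRUE else s$env,
      stringsAsFactors = FALSE)
  })
  corpus_manifest(do.call(rbind, rows))
}

# random synthetic "partial features": speaker identity as a mean offset so
# GE2E training has structure to learn without audio synthesis
fake_partial_features <- function(n_speakers, n_partials, frames = 40,
                                  n_mels = 40, sep = 3) {
  out <- list()
  for (s in 1:n_speakers) {
    base <- rnorm(n_mels) * sep
    out[[sprintf("fs%02d", s)]] <- lapply(1:n_partials, function(i)
      matrix(rnorm(frames * n_mels, sd = 1), frames, n_mels) +
        matrix(base, frames, n_mels, byrow = TRUE))
  }
  out
}
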