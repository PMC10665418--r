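# The GE2E text-independent speaker-verification model: a stacked-LSTM
# encoder with a final linear projection to unit-norm d-vectors, the scaled
# cosine similarity matrix against speaker centroids (leave-one-out on the
# true speaker), the softmax GE2E loss, and a from-scratch Adam training loop
# with global gradient-norm clipping.

#' Encoder architecture configuration
#'
#' Defaults follow the full system (3 LSTM layers, 768 hidden units, 256-d
#' embeddings); all fields are overridable for desk-scale runs.
#'
#' @param num_recurrent_layers Number of stacked LSTM layers.
#' @param hidden_units Hidden units per layer.
#' @param embedding_dim Dimension of the projected d-vector.
#' @param n_mels Input feature dimension (40 log-mel bands).
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(num_recurrent_layers = 3L, hidden_units = 768L,
                           embedding_dim = 256L, n_mels = 40L) {
  stopifnot(num_recurrent_layers >= 1, hidden_units >= 1, embedding_dim >= 1)
  structure(list(num_recurrent_layers = as.integer(num_recurrent_layers),
                 hidden_units = as.integer(hidden_units),
                 embedding_dim = as.integer(embedding_dim),
                 n_mels = as.integer(n_mels)),
            class = "encoder_config")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate. The full architecture converges
#'   with rates between 1e-5 and 1e-4 (default 5e-5); reduced desk-scale
#'   encoders tolerate larger rates.
#' @param grad_clip_l2 Global L2 gradient-norm clip (default 3).
#' @param steps Number of optimization steps (fixed budget).
#' @param N,M Batch shape: speakers per batch and partials per speaker.
#' @param crop_frames Range the common batch crop length is drawn from.
#' @param init_w,init_b Initial similarity scale and offset (10, -5).
#' @param seed Integer seed covering initialization and batch sampling.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 5e-5, grad_clip_l2 = 3,
                         steps = 1000L, N = 16L, M = 4L,
                         crop_frames = c(140L, 180L),
                         init_w = 10, init_b = -5, seed = 1L) {
  stopifnot(learning_rate >= 0, grad_clip_l2 > 0, steps >= 0, N >= 2, M >= 2)
  structure(list(learning_rate = learning_rate, grad_clip_l2 = grad_clip_l2,
                 steps = as.integer(steps), N = as.integer(N),
                 M = as.integer(M), crop_frames = as.integer(crop_frames),
                 init_w = init_w, init_b = init_b, seed = as.integer(seed)),
            class = "train_config")
}

# Xavier-normal weights (sd = sqrt(2 / (fan_in + fan_out))), zero biases.
init_params <- function(encoder_cfg) {
  L <- encoder_cfg$num_recurrent_layers
  H <- encoder_cfg$hidden_units
  E <- encoder_cfg$embedding_dim
  xavier <- function(nr, nc)
    matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  W <- vector("list", L)
  U <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    D <- if (l == 1) encoder_cfg$n_mels else H
    W[[l]] <- xavier(D, 4 * H)
    U[[l]] <- xavier(H, 4 * H)
    b[[l]] <- numeric(4 * H)
  }
  list(W = W, U = U, b = b, P = xavier(H, E), pb = numeric(E))
}

#' Initialize an untrained GE2E encoder
#'
#' Xavier-normal weights, zero biases, similarity parameters at their initial
#' values.
#'
#' @param encoder_cfg An [encoder_config()].
#' @param train_cfg A [train_config()] (supplies the seed and initial (w, b)).
#' @return A `ge2e_encoder` object.
#' @export
init_encoder <- function(encoder_cfg = encoder_config(),
                         train_cfg = train_config()) {
  params <- withr::with_seed(train_cfg$seed, init_params(encoder_cfg))
  structure(list(params = params, sim_w = train_cfg$init_w,
                 sim_b = train_cfg$init_b, encoder_cfg = encoder_cfg,
                 train_cfg = train_cfg, loss_trace = numeric(0)),
            class = "ge2e_encoder")
}

#' @export
print.ge2e_encoder <- function(x, ...) {
  cfg <- x$encoder_cfg
  cat(sprintf(
    "<ge2e_encoder> %d LSTM layer(s) x %d hidden -> %d-d embedding\n",
    cfg$num_recurrent_layers, cfg$hidden_units, cfg$embedding_dim))
  cat(sprintf("  similarity w = %.4f, b = %.4f; %d training step(s)\n",
              x$sim_w, x$sim_b, length(x$loss_trace)))
  invisible(x)
}

# batch feature array (B x L x n_mels) -> cube (B x n_mels x L) for C++
batch_to_cube <- function(features) {
  if (is.matrix(features))
    features <- array(features, dim = c(1, nrow(features), ncol(features)))
  aperm(features, c(1, 3, 2))
}

#' Encode a batch of feature sequences into d-vectors
#'
#' Runs the stacked LSTM over each row, projects the top layer's final-frame
#' output to the embedding dimension and L2-normalizes it.
#'
#' @param encoder A `ge2e_encoder`.
#' @param features Array `B x L x n_mels` (or a single `T x n_mels` matrix).
#' @return A `B x embedding_dim` matrix of unit-norm d-vectors.
#' @export
encode <- function(encoder, features) {
  stopifnot(inherits(encoder, "ge2e_encoder"))
  emb <- cpp_encode(batch_to_cube(features), encoder$params)
  if (any(!is.finite(emb)))
    stop("non-finite activations while encoding; training diverged?")
  emb
}

#' GE2E similarity matrix
#'
#' Scaled cosine similarities `S[j, i, k] = w * cos(e_ji, c_k) + b` between
#' each embedding and all speaker centroids, with the leave-one-out centroid
#' of the true speaker on the diagonal blocks (`k == j`).
#'
#' @param embeddings `(N*M) x E` matrix, rows grouped speaker-major.
#' @param N,M Speakers and utterances per speaker.
#' @param w,b Similarity scale (> 0) and offset.
#' @return An `N x M x N` array `S[j, i, k]`.
#' @export
similarity_matrix <- function(embeddings, N, M, w = 1, b = 0) {
  stopifnot(nrow(embeddings) == N * M, N >= 2, M >= 2)
  norm1 <- function(v) v / max(sqrt(sum(v^2)), 1e-12)
  S <- array(NA_real_, dim = c(N, M, N))
  csum <- matrix(0, N, ncol(embeddings))
  for (j in seq_len(N))
    csum[j, ] <- colSums(embeddings[((j - 1) * M + 1):(j * M), , drop = FALSE])
  for (j in seq_len(N)) {
    for (i in seq_len(M)) {
      e <- embeddings[(j - 1) * M + i, ]
      eu <- norm1(e)
      for (k in seq_len(N)) {
        ck <- if (k == j) (csum[j, ] - e) / (M - 1) else csum[k, ] / M
        S[j, i, k] <- w * sum(eu * norm1(ck)) + b
      }
    }
  }
  S
}

#' GE2E loss
#'
#' `L_G = mean over (j, i) of [-S[j,i,j] + log sum_k exp(S[j,i,k])]`,
#' computed with a numerically stable log-sum-exp.
#'
#' @param S An `N x M x N` similarity array from [similarity_matrix()].
#' @return The scalar loss.
#' @export
ge2e_loss <- function(S) {
  stopifnot(length(dim(S)) == 3, all(is.finite(S)))
  N <- dim(S)[1]
  M <- dim(S)[2]
  total <- 0
  for (j in seq_len(N)) {
    for (i in seq_len(M)) {
      row <- S[j, i, ]
      mx <- max(row)
      total <- total + (-S[j, i, j] + mx + log(sum(exp(row - mx))))
    }
  }
  total / (M * N)
}

flatten_grads <- function(g) {
  c(unlist(g$dW), unlist(g$dU), unlist(g$db), as.numeric(g$dP),
    as.numeric(g$dpb), g$dw, g$dbias)
}

#' Train a GE2E encoder from scratch
#'
#' Adam optimization of the encoder and the similarity parameters `(w, b)`
#' on batches drawn by [make_training_batch()]; the global gradient L2 norm
#' is clipped at `grad_clip_l2` and `w` is kept positive. No pre-trained
#' weights are used. Deterministic given `train_cfg$seed`.
#'
#' @param features_by_speaker Named list: speaker id -> list of partial
#'   feature matrices (as `prepare_features()$partials`).
#' @param encoder_cfg An [encoder_config()].
#' @param train_cfg A [train_config()].
#' @return A trained `ge2e_encoder` with its per-step `loss_trace`.
#' @export
ge2e_train <- function(features_by_speaker,
                       encoder_cfg = encoder_config(),
                       train_cfg = train_config()) {
  withr::with_seed(train_cfg$seed, {
    params <- init_params(encoder_cfg)
    w <- train_cfg$init_w
    b <- train_cfg$init_b
    lr <- train_cfg$learning_rate
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    zero_like <- function(p) lapply(p, function(x)
      if (is.list(x)) lapply(x, function(y) y * 0) else x * 0)
    m_st <- zero_like(params); v_st <- zero_like(params)
    m_wb <- c(0, 0); v_wb <- c(0, 0)
    trace <- numeric(train_cfg$steps)
    for (step in seq_len(train_cfg$steps)) {
      batch <- make_training_batch(features_by_speaker, train_cfg$N,
                                   train_cfg$M, train_cfg$crop_frames)
      g <- cpp_loss_grad(batch_to_cube(batch$features), params,
                         batch$N, batch$M, w, b)
      if (!is.finite(g$loss))
        stop("training diverged (non-finite loss) at step ", step)
      trace[step] <- g$loss
      gnorm <- sqrt(sum(flatten_grads(g)^2))
      scale <- if (gnorm > train_cfg$grad_clip_l2)
        train_cfg$grad_clip_l2 / gnorm else 1
      corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
      upd <- function(theta, grad, state_m, state_v) {
        grad <- grad * scale
        state_m <- beta1 * state_m + (1 - beta1) * grad
        state_v <- beta2 * state_v + (1 - beta2) * grad^2
        theta <- theta - lr * corr * state_m / (sqrt(state_v) + eps)
        list(theta, state_m, state_v)
      }
      for (l in seq_along(params$W)) {
        r <- upd(params$W[[l]], g$dW[[l]], m_st$W[[l]], v_st$W[[l]])
        params$W[[l]] <- r[[1]]; m_st$W[[l]] <- r[[2]]; v_st$W[[l]] <- r[[3]]
        r <- upd(params$U[[l]], g$dU[[l]], m_st$U[[l]], v_st$U[[l]])
        params$U[[l]] <- r[[1]]; m_st$U[[l]] <- r[[2]]; v_st$U[[l]] <- r[[3]]
        r <- upd(params$b[[l]], as.numeric(g$db[[l]]), m_st$b[[l]],
                 v_st$b[[l]])
        params$b[[l]] <- r[[1]]; m_st$b[[l]] <- r[[2]]; v_st$b[[l]] <- r[[3]]
      }
      r <- upd(params$P, g$dP, m_st$P, v_st$P)
      params$P <- r[[1]]; m_st$P <- r[[2]]; v_st$P <- r[[3]]
      r <- upd(params$pb, as.numeric(g$dpb), m_st$pb, v_st$pb)
      params$pb <- r[[1]]; m_st$pb <- r[[2]]; v_st$pb <- r[[3]]
      r <- upd(w, g$dw, m_wb[1], v_wb[1])
      w <- max(r[[1]], 1e-6); m_wb[1] <- r[[2]]; v_wb[1] <- r[[3]]
      r <- upd(b, g$dbias, m_wb[2], v_wb[2])
      b <- r[[1]]; m_wb[2] <- r[[2]]; v_wb[2] <- r[[3]]
    }
    structure(list(params = params, sim_w = w, sim_b = b,
                   encoder_cfg = encoder_cfg, train_cfg = train_cfg,
                   loss_trace = trace),
              class = "ge2e_encoder")
  })
}
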