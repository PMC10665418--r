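# GE2E model: encoder contracts, similarity matrix, loss, gradients and the
# training loop.

small_encoder <- function(seed = 3) {
  init_encoder(encoder_config(2, 8, 4, n_mels = 6),
               train_config(N = 2, M = 2, seed = seed))
}

test_that("encoded d-vectors are unit-norm, one per row, deterministic", {
  enc <- small_encoder()
  withr::with_seed(4, X <- array(rnorm(5 * 20 * 6), dim = c(5, 20, 6)))
  E <- encode(enc, X)
  expect_equal(dim(E), c(5, 4))
  expect_equal(sqrt(rowSums(E^2)), rep(1, 5), tolerance = 1e-6)
  # identical input rows give identical embeddings
  X[2, , ] <- X[1, , ]
  E2 <- encode(enc, X)
  expect_equal(E2[1, ], E2[2, ])
  expect_equal(encode(enc, X), E2)
})

test_that("similarity matrix matches the brute-force oracle", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      N <- sample(2:4, 1); M <- sample(2:4, 1); d <- sample(2:8, 1)
      emb <- random_unit_rows(N * M, d)
      w <- runif(1, 0.5, 12); b <- runif(1, -6, 1)
      expect_equal(similarity_matrix(emb, N, M, w, b),
                   brute_sim_matrix(emb, N, M, w, b), tolerance = 1e-6)
    }
  })
  # identity parameters give plain cosines; identical embeddings give w + b
  e <- matrix(rep(c(1, 0), each = 4), 4, 2)
  S <- similarity_matrix(e, 2, 2, w = 3, b = -1)
  expect_equal(as.numeric(S), rep(3 - 1, 8))
  expect_error(similarity_matrix(e[1:2, , drop = FALSE], 2, 1), "M")
})

test_that("ge2e loss has its closed forms and matches the naive oracle", {
  expect_equal(ge2e_loss(array(0.7, dim = c(2, 3, 2))), log(2),
               tolerance = 1e-9)
  expect_equal(ge2e_loss(array(-4, dim = c(16, 2, 16))), log(16),
               tolerance = 1e-9)
  # saturated softmax: on-target +20, off-target -20
  S <- array(-20, dim = c(2, 2, 2))
  for (j in 1:2) S[j, , j] <- 20
  expect_lt(ge2e_loss(S), 1e-8)
  withr::with_seed(6, {
    for (rep in 1:20) {
      S <- array(rnorm(3 * 2 * 3, sd = 2), dim = c(3, 2, 3))
      expect_equal(ge2e_loss(S), brute_ge2e_loss(S), tolerance = 1e-6)
    }
  })
})

test_that("analytic embedding gradient matches finite differences", {
  withr::with_seed(7, {
    N <- 3; M <- 2; d <- 5
    E <- random_unit_rows(N * M, d)
    w <- 4; b <- -1
    g <- pathasv:::cpp_emb_loss_grad(E, N, M, w, b)
    expect_equal(g$loss, ge2e_loss(similarity_matrix(E, N, M, w, b)),
                 tolerance = 1e-10)
    eps <- 1e-6
    for (ii in sample(length(E), 8)) {
      Ep <- E; Ep[ii] <- Ep[ii] + eps
      Em <- E; Em[ii] <- Em[ii] - eps
      num <- (ge2e_loss(similarity_matrix(Ep, N, M, w, b)) -
                ge2e_loss(similarity_matrix(Em, N, M, w, b))) / (2 * eps)
      expect_equal(g$dE[ii], num, tolerance = 1e-4)
    }
  })
})

test_that("full backpropagated gradients match finite differences", {
  enc <- small_encoder(seed = 11)
  withr::with_seed(12, X <- array(rnorm(4 * 7 * 6), dim = c(4, 7, 6)))
  cube <- aperm(X, c(1, 3, 2))
  g <- pathasv:::cpp_loss_grad(cube, enc$params, 2, 2, 10, -5)
  f <- function(p) pathasv:::cpp_loss_grad(cube, p, 2, 2, 10, -5)$loss
  eps <- 1e-6
  withr::with_seed(13, {
    for (l in 1:2) for (nm in c("W", "U", "b")) {
      arr <- enc$params[[nm]][[l]]
      for (ii in sample(length(arr), min(4, length(arr)))) {
        p2 <- enc$params; p2[[nm]][[l]][ii] <- p2[[nm]][[l]][ii] + eps
        p3 <- enc$params; p3[[nm]][[l]][ii] <- p3[[nm]][[l]][ii] - eps
        expect_equal(g[[paste0("d", nm)]][[l]][ii],
                     (f(p2) - f(p3)) / (2 * eps), tolerance = 1e-4)
      }
    }
    for (nm in c("P", "pb")) {
      for (ii in sample(length(enc$params[[nm]]),
                        min(4, length(enc$params[[nm]])))) {
        p2 <- enc$params; p2[[nm]][ii] <- p2[[nm]][ii] + eps
        p3 <- enc$params; p3[[nm]][ii] <- p3[[nm]][ii] - eps
        expect_equal(g[[if (nm == "P") "dP" else "dpb"]][ii],
                     (f(p2) - f(p3)) / (2 * eps), tolerance = 1e-4)
      }
    }
  })
})

test_that("training reduces the loss on separable speakers", {
  withr::with_seed(21, feats <- fake_partial_features(8, 4, frames = 30))
  ec <- encoder_config(2, 16, 8)
  tc <- train_config(learning_rate = 2e-3, steps = 60, N = 4, M = 2,
                     crop_frames = c(20L, 28L), seed = 31)
  enc <- ge2e_train(feats, ec, tc)
  expect_length(enc$loss_trace, 60)
  expect_lt(mean(tail(enc$loss_trace, 5)), enc$loss_trace[1])
  expect_gt(enc$sim_w, 0)
  # within-speaker cosine exceeds between-speaker after training
  b <- withr::with_seed(32,
    make_training_batch(feats, N = 8, M = 4, crop_frames = c(25L, 25L)))
  E <- encode(enc, b$features)
  cos_all <- E %*% t(E)
  same <- outer(b$speaker, b$speaker, "==") & upper.tri(cos_all)
  diff_spk <- !outer(b$speaker, b$speaker, "==") & upper.tri(cos_all)
  expect_gt(mean(cos_all[same]) - mean(cos_all[diff_spk]), 0.1)
})

test_that("training is seed-deterministic and frozen at zero learning rate", {
  withr::with_seed(22, feats <- fake_partial_features(5, 3, frames = 25))
  ec <- encoder_config(1, 8, 4)
  tc <- train_config(learning_rate = 1e-3, steps = 8, N = 3, M = 2,
                     crop_frames = c(15L, 20L), seed = 41)
  e1 <- ge2e_train(feats, ec, tc)
  e2 <- ge2e_train(feats, ec, tc)
  expect_identical(e1$loss_trace, e2$loss_trace)
  expect_identical(e1$params, e2$params)
  tc0 <- tc; tc0$learning_rate <- 0
  e0 <- ge2e_train(feats, ec, tc0)
  init <- init_encoder(ec, tc0)
  expect_equal(e0$params, init$params)
  expect_equal(e0$sim_w, init$sim_w)
  expect_equal(e0$sim_b, init$sim_b)
})
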