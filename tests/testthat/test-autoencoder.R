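random_params <- function(filters, D, width, seed = 1) {
  set.seed(seed)
  ae_params(array(rnorm(filters * D * width, sd = 0.05), c(filters, D, width)),
            rnorm(filters, sd = 0.05))
}

test_that("encode/decode shape contracts hold at full size", {
  # 240 frames x 22 joints (66 dims) <-> 256 x 120 latent
  params <- random_params(256, 66, 25)
  sk <- skeleton("j1", 0L, NA, "axial", NA, NA)
  pos <- array(rnorm(240 * 22 * 3), c(240, 22, 3))
  skel22 <- skeleton(paste0("j", 1:22), c(0L, rep(1L, 21)), c(NA, rep(10, 21)),
                     rep("axial", 22), NA, NA)
  seq <- motion_sequence(skel22, pos, fps = 60)
  H <- encode_motion(seq, params)
  expect_equal(dim(H$values), c(256, 120))
  expect_true(all(H$values >= 0))
  out <- decode_latent(H, params)
  expect_equal(dim(out), c(240, 22, 3))
})

test_that("zero input with zero bias encodes to a zero latent", {
  params <- random_params(16, 6, 5)
  params$b[] <- 0
  sk <- skeleton(c("a", "b"), c(0L, 1L), c(NA, 1), rep("axial", 2), NA, NA)
  seq <- motion_sequence(sk, array(0, c(30, 2, 3)), fps = 60)
  H <- encode_motion(seq, params)
  expect_equal(max(abs(H$values)), 0)
})

test_that("inverse max-pooling replicates values into adjacent frames", {
  params <- random_params(4, 3, 3)
  params$b[] <- 0
  # length-1 pooled channel, even source count -> duplicated at both frames
  H <- matrix(c(1, 2, 3, 4), 4, 1)
  out <- decode_latent(H, params, frames = 2)
  env <- asNamespace("motionmend")
  V <- env$unpool_pairs(t(H), 2)
  expect_equal(V[1, ], V[2, ])
  # odd frame count truncates the final replica
  V3 <- env$unpool_pairs(matrix(1:8, 2, 4), 3)
  expect_equal(nrow(V3), 3)
  expect_equal(V3[3, ], V3[3, ])
  expect_equal(V3[1, ], V3[2, ])
})

test_that("decoder matches a direct-summation transposed-convolution oracle", {
  filters <- 5; D <- 6; width <- 7; m <- 10
  params <- random_params(filters, D, width, seed = 3)
  set.seed(4)
  H <- matrix(abs(rnorm(ceiling(m / 2) * filters)), ceiling(m / 2), filters)
  got <- decode_latent(t(H), params, frames = m)
  got_mat <- matrix(aperm(got, c(1, 3, 2)), m, D)
  # oracle: plain loops over the definition
  half <- (width - 1) / 2
  V <- matrix(0, m, filters)
  for (t in 1:m) V[t, ] <- H[ceiling(t / 2), ] - params$b
  Y <- matrix(0, m, D)
  W <- params$W  # filters x D x width
  for (t in 1:m) for (d in 1:D) {
    s <- 0
    for (w in 1:width) for (f in 1:filters) {
      src <- t - (w - 1 - half)
      if (src >= 1 && src <= m) s <- s + V[src, f] * W[f, d, w]
    }
    Y[t, d] <- s
  }
  expect_lt(max(abs(got_mat - Y)), 1e-9)
})

test_that("decode is linear in the latent code up to the bias term", {
  filters <- 6; D <- 6; width <- 5; m <- 12
  params <- random_params(filters, D, width, seed = 5)
  env <- asNamespace("motionmend")
  dec <- function(H) env$decode_internal(H, m, params)
  set.seed(6)
  H1 <- matrix(abs(rnorm(6 * filters)), 6, filters)
  H2 <- matrix(abs(rnorm(6 * filters)), 6, filters)
  a <- 0.3; b <- 1.7
  lhs <- dec(a * H1 + b * H2)
  affine <- dec(H1 * 0)  # pure bias response
  rhs <- a * dec(H1) + b * dec(H2) + (1 - a - b) * affine
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("ReLU and max-pooling commute", {
  set.seed(7)
  C <- matrix(rnorm(40), 10, 4)
  env <- asNamespace("motionmend")
  a <- pmax(env$pool_pairs(C)$values, 0)
  b <- env$pool_pairs(pmax(C, 0))$values
  expect_identical(a, b)
})

test_that("training is deterministic and reduces the loss", {
  skel <- skeleton_lower6()
  corpus <- lapply(generate_corpus(skel, 20, 120, 60, seed = 41),
                   add_phantom_joint)
  hy <- train_hyper(epochs = 8, seed = 5, batch_size = 8)
  m1 <- train_autoencoder(corpus, filters = 8, width = 15, hyper = hy)
  m2 <- train_autoencoder(corpus, filters = 8, width = 15, hyper = hy)
  expect_identical(m1$Wmat, m2$Wmat)
  expect_identical(m1$b, m2$b)
  ll <- attr(m1, "loss_log")
  expect_lt(ll[length(ll)], ll[1])
  expect_error(train_autoencoder(list(), filters = 8), "empty")
})

test_that("a single repeated clip is overfit without sparsity", {
  skel <- skeleton_lower6()
  clip <- add_phantom_joint(generate_motion(skel, 120, 60, gait_params(seed = 9)))
  corpus <- rep(list(clip), 4)
  model <- train_autoencoder(corpus, filters = 24, width = 15,
                             hyper = train_hyper(alpha = 0, epochs = 150,
                                                 dropout_rate = 0, seed = 6,
                                                 batch_size = 4))
  ll <- attr(model, "loss_log")
  expect_lt(ll[length(ll)], 0.1 * ll[1])
})

test_that("the trained manifold denoises held-out motion", {
  model <- test_model_small()
  ref <- test_clip(seed = 77)
  rec_clean <- reconstruct(ref, model)
  expect_equal(dim(rec_clean$positions), dim(ref$positions))
  cor <- corrupt_awgn(ref, 10, seed = 3)
  rec_err <- joint_rmse(rec_clean, ref)$mean
  cor_err <- joint_rmse(cor, ref)$mean
  expect_lt(rec_err, cor_err)
  # reconstruction of pure noise has a higher residual than in-manifold motion
  noise <- ref
  set.seed(8)
  noise$positions <- array(rnorm(length(ref$positions), sd = 30),
                           dim(ref$positions))
  res_noise <- mean((reconstruct(noise, model)$positions - noise$positions)^2)
  res_motion <- mean((rec_clean$positions - ref$positions)^2)
  expect_gt(res_noise, res_motion)
})

test_that("models survive a save/load round trip", {
  model <- test_model_small()
  path <- withr::local_tempfile(fileext = ".json")
  save_ae_model(model, path)
  back <- load_ae_model(path)
  expect_equal(back$Wmat, model$Wmat)
  expect_equal(back$b, model$b)
  expect_equal(back$norm_mean, model$norm_mean)
  ref <- test_clip(seed = 55)
  expect_equal(reconstruct(ref, back)$positions,
               reconstruct(ref, model)$positions, tolerance = 1e-12)
})
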