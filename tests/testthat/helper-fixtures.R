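# Shared fixtures: tiny deterministic sequences and memoized trained models.

.fixture_env <- new.env(parent = emptyenv())

# small lower-body model used by the unit tests (fast to train)
test_model_small <- function() {
  if (is.null(.fixture_env$small)) {
    skel <- skeleton_lower6()
    corpus <- lapply(generate_corpus(skel, 40, 240, 60, seed = 11),
                     add_phantom_joint)
    .fixture_env$small_corpus <- corpus
    .fixture_env$small <- train_autoencoder(
      corpus, filters = 32, width = 25,
      hyper = train_hyper(epochs = 80, seed = 12))
  }
  .fixture_env$small
}

test_corpus_small <- function() {
  test_model_small()
  .fixture_env$small_corpus
}

# full-body model used by the end-to-end benchmark checks
test_model_bench <- function() {
  if (is.null(.fixture_env$bench)) {
    skel <- skeleton_full21()
    corpus <- lapply(generate_corpus(skel, 120, 240, 60, seed = 21),
                     add_phantom_joint)
    .fixture_env$bench <- train_autoencoder(
      corpus, filters = 64, width = 25,
      hyper = train_hyper(epochs = 60, seed = 22))
  }
  .fixture_env$bench
}

# a short clean clip on the given skeleton (phantom added)
test_clip <- function(skeleton = skeleton_lower6(), frames = 240, seed = 99) {
  add_phantom_joint(generate_motion(skeleton, frames, 60,
                                    gait_params(seed = seed)))
}

# a trivial single-joint skeleton for filter-level tests
point_skeleton <- function() {
  skeleton("pt", 0L, NA, "axial", NA_integer_, NA_integer_)
}

point_sequence <- function(positions, fps = 60) {
  pos <- array(positions, dim = c(nrow(positions), 1, 3))
  motion_sequence(point_skeleton(), pos, fps = fps)
}

# independent linear Kalman filter oracle (textbook form, written without
# reference to the package internals)
linear_kf_oracle <- function(q, dt, sigma_a, sigma_r, x0, P0) {
  Fm <- diag(6); Fm[1, 4] <- Fm[2, 5] <- Fm[3, 6] <- dt
  H <- cbind(diag(3), matrix(0, 3, 3))
  Q <- matrix(0, 6, 6)
  for (a in 1:3) {
    Q[a, a] <- dt^4 / 4; Q[a, a + 3] <- Q[a + 3, a] <- dt^3 / 2
    Q[a + 3, a + 3] <- dt^2
  }
  Q <- Q * sigma_a^2
  R <- diag(sigma_r^2, 3)
  x <- x0; P <- P0
  out <- matrix(0, nrow(q), 3)
  out[1, ] <- x[1:3]
  for (k in 2:nrow(q)) {
    x <- Fm %*% x
    P <- Fm %*% P %*% t(Fm) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (q[k, ] - H %*% x)
    P <- (diag(6) - K %*% H) %*% P
    out[k, ] <- x[1:3]
  }
  out
}
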