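# Single-layer temporal convolutional autoencoder over flattened joint
# positions (M frames x 3N dims). The encoder is a stride-1 same-padded
# temporal convolution plus bias, temporal max-pooling by 2, and ReLU; the
# decoder inverts the chain: replicate-unpool, subtract bias, and convolve
# with the weight tensor reflected along the frame axis and transposed in the
# other two axes (the exact adjoint of the encoder convolution). All heavy
# lifting is phrased as im2col patch matrices times weight matrices so BLAS
# does the work.

# --- convolution primitives (internal) --------------------------------------

conv_patches <- function(Z, width) {
  m <- nrow(Z); D <- ncol(Z); half <- (width - 1L) %/% 2L
  Zp <- rbind(matrix(0, half, D), Z, matrix(0, half, D))
  P <- matrix(0, m, D * width)
  for (w in seq_len(width))
    P[, ((w - 1L) * D + 1L):(w * D)] <- Zp[w:(w + m - 1L), , drop = FALSE]
  P
}

conv_forward <- function(Z, Wmat, width) {
  conv_patches(Z, width) %*% Wmat
}

# adjoint of conv_forward in its data argument: overlap-add of V %*% t(Wmat)
conv_adjoint <- function(V, Wmat, width, D) {
  m <- nrow(V); half <- (width - 1L) %/% 2L
  G <- V %*% t(Wmat)                      # m x (D*width)
  Yp <- matrix(0, m + 2L * half, D)
  for (w in seq_len(width)) {
    rows <- w:(w + m - 1L)
    Yp[rows, ] <- Yp[rows, ] + G[, ((w - 1L) * D + 1L):(w * D)]
  }
  Yp[(half + 1L):(half + m), , drop = FALSE]
}

weight_matrix <- function(W) {
  # W[f, d, w] -> Wmat[(w-1)*D + d, f]
  d <- dim(W)
  Wm <- aperm(W, c(2, 3, 1))
  dim(Wm) <- c(d[2] * d[3], d[1])
  Wm
}

weight_array <- function(Wmat, filters, D, width) {
  Wm <- Wmat
  dim(Wm) <- c(D, width, filters)
  aperm(Wm, c(3, 1, 2))
}

pool_pairs <- function(C) {
  m <- nrow(C)
  o <- seq(1L, m, by = 2L)
  e <- pmin(o + 1L, m)
  A <- C[o, , drop = FALSE]; B <- C[e, , drop = FALSE]
  take_first <- A >= B
  list(values = pmax(A, B), take_first = take_first, o = o, e = e, m = m)
}

unpool_pairs <- function(H, m) {
  idx <- rep(seq_len(nrow(H)), each = 2L)[seq_len(m)]
  H[idx, , drop = FALSE]
}

normalize_clip <- function(seq, params) {
  Z <- sweep(sweep(flatten_positions(seq), 2, params$norm_mean), 2,
             params$norm_sd, "/")
  if (!all(seq$mask)) {
    obs3 <- seq$mask[, rep(seq_len(ncol(seq$mask)), each = 3), drop = FALSE]
    Z[!obs3] <- 0
  }
  Z
}

# --- hyperparameters --------------------------------------------------------

#' Training hyperparameters
#'
#' @param alpha L1 sparsity weight on the weights and biases.
#' @param learning_rate Adam step size.
#' @param adam_moments Adam decay rates (beta1, beta2).
#' @param dropout_rate Training-time dropout applied to the encoder input.
#' @param epochs Number of passes over the corpus.
#' @param batch_size Clips per gradient step.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `train_hyper` list.
#' @export
train_hyper <- function(alpha = 0.01, learning_rate = 0.001,
                        adam_moments = c(0.9, 0.999), dropout_rate = 0.2,
                        epochs = 200, batch_size = 16, seed = 1) {
  stopifnot(alpha >= 0, learning_rate > 0, learning_rate <= 1,
            dropout_rate >= 0, dropout_rate < 1, epochs >= 1, batch_size >= 1)
  structure(list(alpha = alpha, learning_rate = learning_rate,
                 adam_moments = adam_moments, dropout_rate = dropout_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_hyper")
}

#' Construct autoencoder parameters directly
#'
#' Mostly useful for tests and for loading externally trained weights;
#' [train_autoencoder()] is the usual way to obtain a model.
#'
#' @param W Weight array, filters x input_dims x width (width odd).
#' @param b Per-filter bias (length = filters).
#' @param norm_mean,norm_sd Per-dimension normalization statistics
#'   (`norm_sd` strictly positive).
#' @param joint_names Joint-name fingerprint of the skeleton.
#' @param hyper A [train_hyper()].
#' @return An `ae_params` object.
#' @export
ae_params <- function(W, b, norm_mean = NULL, norm_sd = NULL,
                      joint_names = NULL, hyper = train_hyper()) {
  d <- dim(W)
  if (length(d) != 3) stop("W must be filters x input_dims x width")
  if (d[3] %% 2 == 0) stop("width must be odd")
  if (length(b) != d[1]) stop("b must have one entry per filter")
  if (is.null(norm_mean)) norm_mean <- numeric(d[2])
  if (is.null(norm_sd)) norm_sd <- rep(1, d[2])
  if (any(norm_sd <= 0)) stop("norm_sd must be strictly positive")
  if (!all(is.finite(W)) || !all(is.finite(b))) stop("W and b must be finite")
  structure(
    list(W = W, Wmat = weight_matrix(W), b = b, norm_mean = norm_mean,
         norm_sd = norm_sd, pool_factor = 2L, filters = d[1],
         width = d[3], input_dims = d[2], joint_names = joint_names,
         hyper = hyper),
    class = "ae_params")
}

# --- encode / decode --------------------------------------------------------

#' Encode a motion sequence into the latent space
#'
#' Flattens positions to an `M x 3N` matrix, z-scores each dimension with the
#' training statistics (masked coordinates enter as 0 after normalization),
#' convolves with the filter bank (stride 1, same zero-padding), adds the
#' bias, max-pools adjacent frame pairs, and applies ReLU.
#'
#' @param seq A [motion_sequence()] with at least `width` frames.
#' @param params Trained `ae_params` from [train_autoencoder()].
#' @return A `latent_code`: list with `values` (filters x ceil(M/2),
#'   non-negative) and `frames` (source frame count M).
#' @export
encode_motion <- function(seq, params) {
  D <- params$input_dims
  if (3L * dim(seq$positions)[2] != D)
    stop(sprintf("sequence has %d dims but model expects %d",
                 3L * dim(seq$positions)[2], D))
  m <- n_frames(seq)
  if (m < params$width) stop("sequence shorter than the filter width")
  Z <- normalize_clip(seq, params)
  C <- conv_forward(Z, params$Wmat, params$width)
  C <- sweep(C, 2, params$b, "+")
  pooled <- pool_pairs(C)
  H <- pmax(pooled$values, 0)
  structure(list(values = t(H), frames = m), class = "latent_code")
}

#' Decode a latent code back to joint positions
#'
#' Inverse max-pooling replicates each pooled value into two adjacent frames
#' (the final replica is truncated for odd frame counts), the bias is
#' subtracted, the result is convolved with the reflected/transposed weight
#' tensor, and the output is denormalized.
#'
#' @param latent A `latent_code` (or a bare filters x pooled-frames matrix
#'   plus `frames`).
#' @param params Trained `ae_params`.
#' @param frames Frame count override when `latent` is a bare matrix.
#' @return An `M x N x 3` array of positions (cm).
#' @export
decode_latent <- function(latent, params, frames = NULL) {
  if (inherits(latent, "latent_code")) {
    H <- t(latent$values); m <- latent$frames
  } else {
    H <- t(latent); m <- frames
    if (is.null(m)) stop("frames must be given for a bare latent matrix")
  }
  if (ncol(H) != params$filters) stop("latent filter count mismatch")
  if (nrow(H) != ceiling(m / 2)) stop("latent length inconsistent with frame count")
  V <- sweep(unpool_pairs(H, m), 2, params$b)
  Ynorm <- conv_adjoint(V, params$Wmat, params$width, params$input_dims)
  Y <- sweep(sweep(Ynorm, 2, params$norm_sd, "*"), 2, params$norm_mean, "+")
  unflatten_positions(Y, params$input_dims %/% 3L)
}

#' Reconstruct a sequence through the motion manifold
#'
#' `decode(encode(seq))`: projects a sequence onto the learned motion
#' manifold. Out-of-manifold content (noise, drop-out fill) has no latent
#' representation and is suppressed.
#'
#' @param seq A [motion_sequence()].
#' @param params Trained `ae_params`.
#' @return A fully observed [motion_sequence()] of the same shape.
#' @export
reconstruct <- function(seq, params) {
  pos <- decode_latent(encode_motion(seq, params), params)
  motion_sequence(seq$skeleton, pos, fps = seq$fps)
}

# --- training ---------------------------------------------------------------

adam_step <- function(theta, g, state, lr, b1, b2, t, eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * g
  state$v <- b2 * state$v + (1 - b2) * g * g
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

clip_gradients <- function(Z_in, Z_target, Wmat, b, width, D, alpha) {
  m <- nrow(Z_in)
  P <- conv_patches(Z_in, width)
  C <- sweep(P %*% Wmat, 2, b, "+")
  pooled <- pool_pairs(C)
  Hpre <- pooled$values
  H <- pmax(Hpre, 0)
  V <- sweep(unpool_pairs(H, m), 2, b)
  Ynorm <- conv_adjoint(V, Wmat, width, D)
  resid <- Ynorm - Z_target
  loss <- sum(resid * resid)
  dY <- 2 * resid
  # decoder
  dG <- conv_patches(dY, width)                 # adjoint of overlap-add
  dW_dec <- crossprod(dG, V)                    # (D*width) x F
  dV <- conv_forward(dY, Wmat, width)
  db_dec <- -colSums(dV)
  # unpool / relu / pool
  u <- nrow(H)
  idx <- rep(seq_len(u), each = 2L)[seq_len(m)]
  dH <- rowsum(dV, idx)
  dHpre <- dH * (Hpre > 0)
  dC <- matrix(0, m, ncol(C))
  dC[pooled$o, ] <- dHpre * pooled$take_first
  add_second <- dHpre * (!pooled$take_first)
  dC[pooled$e, ] <- dC[pooled$e, , drop = FALSE] + add_second
  # encoder
  dW_enc <- crossprod(P, dC)
  db_enc <- colSums(dC)
  list(loss = loss,
       dW = dW_enc + dW_dec,
       db = db_enc + db_dec)
}

#' Train the convolutional autoencoder
#'
#' Minimizes the squared reconstruction error of each clip plus an L1
#' sparsity penalty on the parameters, by Adam at the configured moments and
#' learning rate, with training-time dropout on the encoder input.
#' Normalization statistics (per-dimension mean/sd) are computed from the
#' corpus before training; constant dimensions get unit scale. Training is
#' deterministic given `hyper$seed`.
#'
#' @param corpus List of [motion_sequence()] clips sharing one skeleton, each
#'   at least `width` frames long.
#' @param filters Number of convolutional filters (256 at full scale; reduce
#'   for desk-scale corpora).
#' @param width Temporal filter width in frames (odd; default 25).
#' @param hyper A [train_hyper()].
#' @param verbose Print per-epoch loss.
#' @return An `ae_params` object with elements `W` (filters x 3N x width),
#'   `b`, `norm_mean`, `norm_sd`, `pool_factor`, and a per-epoch `loss_log`
#'   attribute.
#' @export
train_autoencoder <- function(corpus, filters = 256, width = 25,
                              hyper = train_hyper(), verbose = FALSE) {
  if (length(corpus) == 0) stop("corpus is empty")
  if (width %% 2 == 0) stop("width must be odd")
  skel <- corpus[[1]]$skeleton
  D <- 3L * n_joints(skel)
  if (any(vapply(corpus, function(s) n_frames(s) < width, logical(1))))
    stop("every clip must be at least `width` frames long")
  flat <- lapply(corpus, flatten_positions)
  all_rows <- do.call(rbind, flat)
  norm_mean <- colMeans(all_rows)
  # one pooled scale for all dimensions: measurement noise is isotropic in
  # cm, so per-dimension scaling would blow it up in low-variance channels
  pooled_sd <- sqrt(mean(sweep(all_rows, 2, norm_mean)^2))
  norm_sd <- rep(max(pooled_sd, 1e-6), ncol(all_rows))
  Zs <- lapply(flat, function(x) sweep(sweep(x, 2, norm_mean), 2, norm_sd, "/"))

  b1 <- hyper$adam_moments[1]; b2 <- hyper$adam_moments[2]
  loss_log <- numeric(hyper$epochs)
  n_entries <- sum(vapply(Zs, length, numeric(1)))
  with_seed(hyper$seed, {
    Wmat <- matrix(stats::rnorm(D * width * filters, sd = sqrt(1 / (D * width))),
                   D * width, filters)
    b <- numeric(filters)
    stW <- list(m = Wmat * 0, v = Wmat * 0)
    stb <- list(m = b * 0, v = b * 0)
    step <- 0L
    keep <- 1 - hyper$dropout_rate
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(length(Zs))
      ep_loss <- 0
      for (start in seq(1L, length(ord), by = hyper$batch_size)) {
        batch <- ord[start:min(start + hyper$batch_size - 1L, length(ord))]
        gW <- Wmat * 0; gb <- b * 0; bl <- 0
        for (ci in batch) {
          Z <- Zs[[ci]]
          Zin <- if (hyper$dropout_rate > 0) {
            dm <- matrix(stats::rbinom(length(Z), 1L, keep), nrow(Z)) / keep
            Z * dm
          } else Z
          g <- clip_gradients(Zin, Z, Wmat, b, width, D, hyper$alpha)
          gW <- gW + g$dW; gb <- gb + g$db; bl <- bl + g$loss
        }
        gW <- gW + hyper$alpha * sign(Wmat)
        gb <- gb + hyper$alpha * sign(b)
        step <- step + 1L
        upW <- adam_step(Wmat, gW, stW, hyper$learning_rate, b1, b2, step)
        Wmat <- upW$theta; stW <- upW$state
        upb <- adam_step(b, gb, stb, hyper$learning_rate, b1, b2, step)
        b <- upb$theta; stb <- upb$state
        ep_loss <- ep_loss + bl
      }
      loss_log[ep] <- ep_loss / n_entries
      if (verbose) message(sprintf("epoch %3d  recon MSE %.6f", ep, loss_log[ep]))
    }
  })
  params <- structure(
    list(W = weight_array(Wmat, filters, D, width), Wmat = Wmat, b = b,
         norm_mean = norm_mean, norm_sd = norm_sd, pool_factor = 2L,
         filters = as.integer(filters), width = as.integer(width),
         input_dims = D, joint_names = skel$joint_names, hyper = hyper),
    class = "ae_params")
  attr(params, "loss_log") <- loss_log
  params
}

#' @export
print.ae_params <- function(x, ...) {
  cat(sprintf("ae_params: %d filters x %d dims x %d frames\n",
              x$filters, x$input_dims, x$width))
  invisible(x)
}

#' Save / load a trained model as structured text (JSON)
#'
#' The archive holds the weights, bias, normalization statistics,
#' architecture and the joint-name fingerprint of the training skeleton.
#'
#' @param params An `ae_params`.
#' @param path File path (.json).
#' @export
save_ae_model <- function(params, path) {
  obj <- list(filters = params$filters, width = params$width,
              input_dims = params$input_dims, pool_factor = params$pool_factor,
              joint_names = params$joint_names,
              norm_mean = params$norm_mean, norm_sd = params$norm_sd,
              b = params$b, Wmat = as.numeric(params$Wmat),
              hyper = unclass(params$hyper))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ae_model
#' @export
load_ae_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  Wmat <- matrix(x$Wmat, x$input_dims * x$width, x$filters)
  structure(
    list(W = weight_array(Wmat, x$filters, x$input_dims, x$width), Wmat = Wmat,
         b = as.numeric(x$b), norm_mean = as.numeric(x$norm_mean),
         norm_sd = as.numeric(x$norm_sd), pool_factor = x$pool_factor,
         filters = x$filters, width = x$width, input_dims = x$input_dims,
         joint_names = x$joint_names, hyper = do.call(train_hyper, x$hyper)),
    class = "ae_params")
}
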