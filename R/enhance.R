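# Latent-space optimization: the decoder is frozen and only the latent code
# is adjusted, so every enhanced output lies on the learned motion manifold
# by construction. Two paradigms: filter-assisted (the Tobit-filtered
# trajectory is the optimization target, for noisy data) and filter-refined
# (manifold reconstruction first, filter second, for missing data).

#' Enhancement configuration
#'
#' @param mode One of `"tkf_assisted"`, `"tkf_refined"`, `"ae_only"`,
#'   `"tkf_only"`, `"kf_assisted"`.
#' @param opt_learning_rate Adam step size for latent optimization.
#' @param opt_iterations Number of Adam iterations (>= 1). The default is
#'   deliberately moderate: the filter target is kinematically sound but not
#'   noise-free, and running the optimization to convergence transfers the
#'   target's residual bias onto the manifold; stopping early keeps the
#'   denoising benefit of both stages (see the methods vignette).
#' @param bone_weight Weight of the bone-length constraint (0 disables it;
#'   used by the structure-matching preprocessing step, not by default
#'   enhancement).
#' @param target_weight Weight of the Cartesian target term.
#' @param seed Integer seed.
#' @return An `enhance_config` list.
#' @export
enhance_config <- function(mode = c("tkf_assisted", "tkf_refined", "ae_only",
                                    "tkf_only", "kf_assisted"),
                           opt_learning_rate = 0.01, opt_iterations = 25,
                           bone_weight = 0, target_weight = 1, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(opt_iterations >= 1, bone_weight >= 0, target_weight >= 0)
  structure(list(mode = mode, opt_learning_rate = opt_learning_rate,
                 opt_iterations = as.integer(opt_iterations),
                 bone_weight = bone_weight, target_weight = target_weight,
                 seed = as.integer(seed)),
            class = "enhance_config")
}

# cost and position-space gradient of the bone-length term
bone_cost_grad <- function(pos, skeleton, lengths = skeleton$bone_lengths) {
  d <- dim(pos)
  grad <- array(0, d)
  cost <- 0
  ph <- skeleton$phantom_index
  for (j in seq_along(skeleton$parent_index)) {
    p <- skeleton$parent_index[j]
    if (p == 0L || (!is.na(ph) && j == ph)) next
    dv <- pos[, j, , drop = TRUE] - pos[, p, , drop = TRUE]
    len <- sqrt(rowSums(dv^2))
    err <- len - lengths[j]
    cost <- cost + sum(err^2)
    coef <- 2 * err / pmax(len, 1e-9)
    g <- dv * coef
    grad[, j, ] <- grad[, j, ] + g
    grad[, p, ] <- grad[, p, ] - g
  }
  list(cost = cost, grad = grad)
}

latent_adam <- function(H0, m, params, cost_grad_fn, lr, iters) {
  # H0: pooled x filters, kept >= 0 (projected steps); returns best iterate
  H <- H0
  st <- list(m = H * 0, v = H * 0)
  cg <- cost_grad_fn(H)
  best <- list(H = H, cost = cg$cost)
  costs <- numeric(iters + 1L)
  costs[1] <- cg$cost
  for (it in seq_len(iters)) {
    up <- adam_step(H, cg$gH, st, lr, 0.9, 0.999, it)
    H <- pmax(up$theta, 0)
    st <- up$state
    cg <- cost_grad_fn(H)
    costs[it + 1L] <- cg$cost
    if (cg$cost < best$cost) best <- list(H = H, cost = cg$cost)
  }
  list(H = best$H, cost = best$cost, costs = costs)
}

# shared machinery: decode H (internal pooled x filters layout) and its
# gradient pulled back from a position-space gradient
decode_internal <- function(H, m, params) {
  V <- sweep(unpool_pairs(H, m), 2, params$b)
  Ynorm <- conv_adjoint(V, params$Wmat, params$width, params$input_dims)
  sweep(sweep(Ynorm, 2, params$norm_sd, "*"), 2, params$norm_mean, "+")
}

latent_pullback <- function(dY, m, params) {
  dYnorm <- sweep(dY, 2, params$norm_sd, "*")
  dV <- conv_forward(dYnorm, params$Wmat, params$width)
  u <- ceiling(m / 2)
  idx <- rep(seq_len(u), each = 2L)[seq_len(m)]
  rowsum(dV, idx)
}

#' Optimize the latent code toward a Cartesian target
#'
#' The latent code is initialized from the input sequence, the decoder is
#' frozen, and Adam minimizes the squared Cartesian distance between the
#' decoded output and the target (optionally plus a weighted bone-length
#' constraint). The best iterate is returned, so the final cost never
#' exceeds the initial one.
#'
#' @param seq_in Input [motion_sequence()] (provides the starting latent
#'   code).
#' @param target Frame/joint-aligned target [motion_sequence()].
#' @param params Trained `ae_params`.
#' @param config An [enhance_config()].
#' @return The optimized [motion_sequence()] (`decode(H*)`) with the cost
#'   trace in `attr(, "costs")`.
#' @export
latent_optimize <- function(seq_in, target, params,
                            config = enhance_config()) {
  if (!all(is.finite(target$positions))) stop("target contains non-finite values")
  dI <- dim(seq_in$positions)
  if (!all(dI == dim(target$positions)))
    stop("target must be frame/joint aligned with the input")
  m <- dI[1]
  H0 <- t(encode_motion(seq_in, params)$values)
  r <- flatten_positions(target)
  skel <- seq_in$skeleton
  w_t <- config$target_weight; w_b <- config$bone_weight
  cg <- function(H) {
    Y <- decode_internal(H, m, params)
    resid <- Y - r
    cost <- w_t * sum(resid^2)
    dY <- 2 * w_t * resid
    if (w_b > 0) {
      bc <- bone_cost_grad(unflatten_positions(Y, dI[2]), skel)
      cost <- cost + w_b * bc$cost
      dY <- dY + w_b * matrix(aperm(bc$grad, c(1, 3, 2)), m, dI[2] * 3)
    }
    list(cost = cost, gH = latent_pullback(dY, m, params))
  }
  res <- latent_adam(H0, m, params, cg, config$opt_learning_rate,
                     config$opt_iterations)
  out <- motion_sequence(skel, unflatten_positions(decode_internal(res$H, m, params), dI[2]),
                         fps = seq_in$fps)
  attr(out, "costs") <- res$costs
  out
}

#' Fit a sequence to known bone lengths over the latent space
#'
#' Structure matching: the latent code is optimized so the decoded skeleton's
#' segment lengths approach the known constant bone lengths of the training
#' skeleton, optionally with a fidelity term holding the result near the
#' input. Used as a preprocessing step before enhancement of data captured
#' with a differently proportioned skeleton. The phantom floor bone (whose
#' length is not anatomically constant) is excluded from the constraint.
#'
#' @param seq Input [motion_sequence()].
#' @param params Trained `ae_params`.
#' @param skeleton Skeleton supplying the target bone lengths (default: the
#'   sequence's own).
#' @param config An [enhance_config()]; `bone_weight` (default 1 here) scales
#'   the constraint and `target_weight` the fidelity to `seq`.
#' @return The fitted [motion_sequence()].
#' @export
bone_constrained_fit <- function(seq, params, skeleton = seq$skeleton,
                                 config = enhance_config(bone_weight = 1,
                                                         target_weight = 0,
                                                         opt_iterations = 100)) {
  if (any(is.na(skeleton$bone_lengths[skeleton$parent_index != 0L])))
    stop("skeleton bone lengths must be known")
  d <- dim(seq$positions)
  m <- d[1]
  H0 <- t(encode_motion(seq, params)$values)
  x_in <- flatten_positions(seq)
  w_b <- if (config$bone_weight > 0) config$bone_weight else 1
  w_t <- config$target_weight
  cg <- function(H) {
    Y <- decode_internal(H, m, params)
    bc <- bone_cost_grad(unflatten_positions(Y, d[2]), skeleton)
    cost <- w_b * bc$cost
    dY <- w_b * matrix(aperm(bc$grad, c(1, 3, 2)), m, d[2] * 3)
    if (w_t > 0) {
      resid <- Y - x_in
      cost <- cost + w_t * sum(resid^2)
      dY <- dY + 2 * w_t * resid
    }
    list(cost = cost, gH = latent_pullback(dY, m, params))
  }
  res <- latent_adam(H0, m, params, cg, config$opt_learning_rate,
                     config$opt_iterations)
  out <- motion_sequence(seq$skeleton,
                         unflatten_positions(decode_internal(res$H, m, params), d[2]),
                         fps = seq$fps)
  attr(out, "costs") <- res$costs
  out
}

#' Filter-assisted enhancement (parallel paradigm, for noisy data)
#'
#' The seven-step pipeline: the input is filtered with the Tobit Kalman
#' filter to produce a kinematics-preserving target; in parallel the input is
#' encoded onto the motion manifold; the latent code is then optimized so the
#' decoded output approaches the filter target while remaining on the
#' manifold.
#'
#' @param seq Fully observed noisy [motion_sequence()].
#' @param params Trained `ae_params`.
#' @param tkf_cfg A [tkf_config()].
#' @param config An [enhance_config()].
#' @return Enhanced [motion_sequence()]; `attr(, "log")` records the stages.
#' @export
enhance_tkf_assisted <- function(seq, params, tkf_cfg = tkf_config(),
                                 config = enhance_config()) {
  if (!all(seq$mask))
    stop("the filter-assisted paradigm expects fully observed (noisy) data; use enhance_tkf_refined for drop-out")
  target <- tkf_filter(seq, tkf_cfg)$seq
  out <- latent_optimize(seq, target, params, config)
  attr(out, "log") <- c("tkf_target", "encode", "latent_optimize", "decode")
  out
}

#' Plain-KF-assisted enhancement (baseline)
#'
#' Identical to [enhance_tkf_assisted()] with censoring disabled
#' (`threshold_mode = "none"`), i.e. the target is a linear Kalman filter
#' trajectory.
#'
#' @inheritParams enhance_tkf_assisted
#' @export
enhance_kf_assisted <- function(seq, params, tkf_cfg = tkf_config(),
                                config = enhance_config(mode = "kf_assisted")) {
  tkf_cfg$threshold_mode <- "none"
  out <- enhance_tkf_assisted(seq, params, tkf_cfg, config)
  attr(out, "log") <- c("kf_target", "encode", "latent_optimize", "decode")
  out
}

#' Filter-refined enhancement (serial paradigm, for missing data)
#'
#' The autoencoder first fills the drop-out voids by projecting the masked
#' sequence onto the motion manifold; the Tobit Kalman filter then refines
#' the fully observed reconstruction.
#'
#' @param seq [motion_sequence()] with drop-out recorded in its mask.
#' @param params Trained `ae_params`.
#' @param tkf_cfg A [tkf_config()].
#' @return Enhanced [motion_sequence()]; `attr(, "log")` records the stage
#'   order.
#' @export
enhance_tkf_refined <- function(seq, params, tkf_cfg = tkf_config()) {
  recon <- reconstruct(seq, params)
  out <- tkf_filter(recon, tkf_cfg)$seq
  attr(out, "log") <- c("encode", "decode", "tkf_refine")
  out
}
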