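# Per-joint Tobit Kalman filter with a constant-velocity (CV) motion model
# and censoring limits adapted from the joint's observed velocity. Each joint
# is filtered independently with a 6-dim state [p_x p_y p_z v_x v_y v_z].
# With infinite thresholds every censoring probability is 1 and the update
# reduces exactly to the linear Kalman filter -- the property the tests pin.

#' Tobit Kalman filter configuration
#'
#' Builds the CV transition matrix, position-extracting observation matrix,
#' discrete white-noise-acceleration process covariance and isotropic
#' measurement covariance. The paper's source never states process or
#' measurement noise, so both are exposed: `sigma_a` is the acceleration
#' intensity (cm/s^2) of the CV process noise and `sigma_r` the measurement
#' noise standard deviation (cm).
#'
#' @param dt Sampling period in seconds (> 0).
#' @param sigma_a Process-noise acceleration intensity (cm/s^2); the default
#'   is of the order of peak limb accelerations in brisk human motion.
#' @param sigma_r Measurement noise sd (cm).
#' @param window_frames Velocity window (frames) for adaptive thresholds;
#'   50-80 covers a complete action at 60 fps (default 60).
#' @param threshold_mode `"adaptive"` (velocity-windowed limits), `"fixed"`
#'   (constant `t_lo`/`t_hi`), or `"none"` (infinite limits: plain linear KF).
#' @param t_lo,t_hi Fixed per-axis thresholds (length 3) for `"fixed"` mode.
#' @param causal Use only past frames in the velocity window.
#' @param x0_pos_var,x0_vel_var Initial state variances (cm^2, (cm/s)^2);
#'   the velocity default matches the variance of the finite-difference
#'   initializer, `2 * (sigma_r / dt)^2`.
#' @param Q,R Optional explicit covariance overrides (6x6 / 3x3).
#' @return A `tkf_config` list with elements `F`, `Hm`, `Q`, `R`, `dt`,
#'   `window_frames`, `threshold_mode`, `P0`.
#' @export
tkf_config <- function(dt = 1 / 60, sigma_a = 1000, sigma_r = 3,
                       window_frames = 60,
                       threshold_mode = c("adaptive", "fixed", "none"),
                       t_lo = NULL, t_hi = NULL, causal = FALSE,
                       x0_pos_var = NULL, x0_vel_var = NULL,
                       Q = NULL, R = NULL) {
  if (is.null(x0_pos_var)) x0_pos_var <- max(sigma_r^2, 1)
  if (is.null(x0_vel_var)) x0_vel_var <- 2 * (sigma_r / dt)^2
  threshold_mode <- match.arg(threshold_mode)
  if (dt <= 0) stop("dt must be > 0")
  if (window_frames < 1) stop("window_frames must be >= 1")
  Fm <- diag(6)
  Fm[1, 4] <- Fm[2, 5] <- Fm[3, 6] <- dt
  Hm <- cbind(diag(3), matrix(0, 3, 3))
  if (is.null(Q)) {
    Q <- matrix(0, 6, 6)
    q11 <- dt^4 / 4; q12 <- dt^3 / 2; q22 <- dt^2
    for (a in 1:3) {
      Q[a, a] <- q11; Q[a, a + 3] <- Q[a + 3, a] <- q12; Q[a + 3, a + 3] <- q22
    }
    Q <- Q * sigma_a^2
  }
  if (is.null(R)) R <- diag(sigma_r^2, 3)
  if (threshold_mode == "fixed") {
    if (is.null(t_lo) || is.null(t_hi)) stop("fixed mode needs t_lo and t_hi")
    if (any(t_lo > t_hi)) stop("t_lo must be <= t_hi elementwise")
  }
  structure(list(F = Fm, Hm = Hm, Q = Q, R = R, dt = dt,
                 sigma_a = sigma_a, sigma_r = sigma_r,
                 window_frames = as.integer(window_frames),
                 threshold_mode = threshold_mode, t_lo = t_lo, t_hi = t_hi,
                 causal = causal, x0_pos_var = x0_pos_var,
                 x0_vel_var = x0_vel_var,
                 P0 = diag(c(rep(x0_pos_var, 3), rep(x0_vel_var, 3)))),
            class = "tkf_config")
}

#' Adaptive censoring thresholds from windowed velocity
#'
#' Per axis, the maximum absolute finite-difference velocity of the measured
#' trajectory over a window of `window_frames` centered at frame `k - 1`
#' (truncated at the sequence edges; past-only when `causal`) sets the
#' half-width: `T = p_prev +/- |v_max| * dt`, with `p_prev` the filtered
#' position estimate from the previous step. A window with no valid
#' measurement pair yields infinite limits (no censoring).
#'
#' @param prev_pos Filtered position estimate at frame `k - 1` (length 3).
#' @param measured_positions Raw measured `M x 3` trajectory of the joint
#'   (unobserved frames as `NA`).
#' @param frame_k Current frame index (>= 2).
#' @param config A [tkf_config()].
#' @return `list(t_lo, t_hi)`, each length 3 (cm).
#' @export
compute_thresholds <- function(prev_pos, measured_positions, frame_k, config) {
  if (config$window_frames < 1) stop("window_frames must be >= 1")
  if (frame_k < 2) stop("frame_k must be >= 2")
  m <- nrow(measured_positions)
  vel <- abs(diff(measured_positions)) / config$dt   # (m-1) x 3
  if (config$causal) {
    lo <- max(1L, frame_k - config$window_frames)
    hi <- min(m - 1L, frame_k - 1L)
  } else {
    hw <- config$window_frames %/% 2L
    lo <- max(1L, frame_k - 1L - hw)
    hi <- min(m - 1L, frame_k - 1L + hw)
  }
  # the transition into frame k itself (velocity index k-1) is excluded, so a
  # measurement spike cannot raise its own censoring limit
  idx <- if (hi >= lo) setdiff(lo:hi, frame_k - 1L) else integer(0)
  vmax <- rep(Inf, 3)
  if (length(idx)) {
    w <- vel[idx, , drop = FALSE]
    for (a in 1:3) {
      va <- w[, a][is.finite(w[, a])]
      if (length(va)) vmax[a] <- max(va)
    }
  }
  list(t_lo = prev_pos - vmax * config$dt, t_hi = prev_pos + vmax * config$dt)
}

#' Censor a measurement against thresholds
#'
#' Per axis the observation is kept when strictly inside `(T_L, T_H)` and
#' replaced by the violated threshold otherwise.
#'
#' @param q Measurement (length 3).
#' @param thresholds `list(t_lo, t_hi)` from [compute_thresholds()].
#' @return The censored measurement `rho` (length 3).
#' @export
censor <- function(q, thresholds) {
  pmin(pmax(q, thresholds$t_lo), thresholds$t_hi)
}

#' Kalman prediction step (CV model)
#'
#' @param state `list(x, P)`: 6-vector state and 6x6 covariance.
#' @param config A [tkf_config()].
#' @return The predicted `list(x, P)`.
#' @export
tkf_predict <- function(state, config) {
  list(x = as.numeric(config$F %*% state$x),
       P = config$F %*% state$P %*% t(config$F) + config$Q)
}

#' Tobit measurement update
#'
#' Censoring probabilities per axis are Gaussian interval/tail masses of the
#' predicted measurement distribution at the thresholds. The expected
#' measurement combines the truncated-normal mean of the uncensored region
#' with threshold point masses; the gain uses the censored cross- and
#' measurement covariances `R_XY = P H' D`, `R_YY = D H P H' D + R` with
#' `D = diag(p_uc)`, which reduce exactly to the linear Kalman update when
#' nothing is censored and shut the gain off as censoring saturates.
#'
#' @param state_pred Predicted `list(x, P)` from [tkf_predict()].
#' @param rho Censored measurement from [censor()].
#' @param thresholds `list(t_lo, t_hi)`.
#' @param config A [tkf_config()].
#' @return `list(state = list(x, P), probs = list(p_uc, p_l, p_h))`.
#' @export
tobit_update <- function(state_pred, rho, thresholds, config) {
  H <- config$Hm
  x <- state_pred$x; P <- state_pred$P
  mu <- as.numeric(H %*% x)
  S <- H %*% P %*% t(H)
  s <- sqrt(pmax(diag(S) + diag(config$R), 1e-12))
  zl <- (thresholds$t_lo - mu) / s
  zh <- (thresholds$t_hi - mu) / s
  p_l <- stats::pnorm(zl)
  p_h <- 1 - stats::pnorm(zh)
  p_uc <- pmax(stats::pnorm(zh) - stats::pnorm(zl), 0)
  # truncated-normal mean of the uncensored region (0 when fully censored)
  trunc_term <- ifelse(p_uc > 1e-12,
                       mu + s * (stats::dnorm(zl) - stats::dnorm(zh)) / pmax(p_uc, 1e-12),
                       0)
  EY <- p_uc * trunc_term +
    ifelse(p_l > 0, p_l * thresholds$t_lo, 0) +   # guards 0 * Inf at open limits
    ifelse(p_h > 0, p_h * thresholds$t_hi, 0)
  Duc <- diag(p_uc, 3)
  RXY <- P %*% t(H) %*% Duc
  RYY <- Duc %*% S %*% Duc + config$R
  K <- tryCatch(RXY %*% solve(RYY), error = function(e) {
    warning("R_YY numerically singular; using regularized inverse")
    RXY %*% solve(RYY + diag(1e-9, 3))
  })
  xn <- x + as.numeric(K %*% (rho - EY))
  Pn <- (diag(6) - K %*% Duc %*% H) %*% P
  Pn <- (Pn + t(Pn)) / 2
  list(state = list(x = xn, P = Pn),
       probs = list(p_uc = p_uc, p_l = p_l, p_h = p_h))
}

#' Filter a motion sequence with the Tobit Kalman filter
#'
#' Each joint is filtered independently. The state initializes at the first
#' observed measurement with velocity from the first finite difference;
#' masked measurements are treated as fully censored (prediction only). With
#' `threshold_mode = "none"` the output is the plain linear-KF trajectory.
#'
#' @param seq A [motion_sequence()] with at least 2 frames.
#' @param config A [tkf_config()]; its `dt` is overridden by `1/seq$fps`.
#' @return `list(seq = filtered sequence, diagnostics = list(t_lo, t_hi,
#'   p_uc) of M x N x 3 arrays)`.
#' @export
tkf_filter <- function(seq, config = tkf_config()) {
  d <- dim(seq$positions)
  if (d[1] < 2) stop("at least two frames required")
  if (abs(config$dt - 1 / seq$fps) > 1e-12) {
    config <- tkf_config(dt = 1 / seq$fps, sigma_a = config$sigma_a,
                         sigma_r = config$sigma_r,
                         window_frames = config$window_frames,
                         threshold_mode = config$threshold_mode,
                         t_lo = config$t_lo, t_hi = config$t_hi,
                         causal = config$causal,
                         x0_pos_var = config$x0_pos_var,
                         x0_vel_var = config$x0_vel_var, R = config$R)
  }
  out <- seq
  diag_lo <- array(-Inf, d); diag_hi <- array(Inf, d); diag_puc <- array(NA_real_, d)
  for (j in seq_len(d[2])) {
    qj <- seq$positions[, j, , drop = TRUE]
    obs <- seq$mask[, j]
    qna <- qj; qna[!obs, ] <- NA
    if (!any(obs)) {
      warning(sprintf("joint %d has no observed frames; returning fill values", j))
      out$positions[, j, ] <- 0
      next
    }
    first <- which(obs)[1]
    x <- numeric(6)
    x[1:3] <- qj[first, ]
    nxt <- which(obs)[2]
    if (!is.na(nxt))
      x[4:6] <- (qj[nxt, ] - qj[first, ]) / ((nxt - first) * config$dt)
    P <- config$P0
    filt <- matrix(0, d[1], 3)
    filt[seq_len(first), ] <- matrix(x[1:3], first, 3, byrow = TRUE)
    state <- list(x = x, P = P)
    if (first < d[1]) for (k in (first + 1L):d[1]) {
      state <- tkf_predict(state, config)
      if (obs[k]) {
        th <- switch(config$threshold_mode,
          adaptive = compute_thresholds(state$x[1:3], qna, k, config),
          fixed = list(t_lo = config$t_lo, t_hi = config$t_hi),
          none = list(t_lo = rep(-Inf, 3), t_hi = rep(Inf, 3)))
        rho <- censor(qj[k, ], th)
        up <- tobit_update(state, rho, th, config)
        state <- up$state
        diag_lo[k, j, ] <- th$t_lo; diag_hi[k, j, ] <- th$t_hi
        diag_puc[k, j, ] <- up$probs$p_uc
      }
      filt[k, ] <- state$x[1:3]
    }
    out$positions[, j, ] <- filt
  }
  out$mask <- matrix(TRUE, d[1], d[2])
  list(seq = out, diagnostics = list(t_lo = diag_lo, t_hi = diag_hi,
                                     p_uc = diag_puc))
}
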