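test_that("adaptive thresholds follow the windowed-velocity rule", {
  cfg <- tkf_config(dt = 0.5, window_frames = 4)
  q <- matrix(0, 10, 3)
  q[, 1] <- cumsum(c(0, rep(1, 9)))  # |v| = 2 cm/s on x
  th <- compute_thresholds(c(10, 0, 0), q, frame_k = 5, cfg)
  expect_equal(th$t_lo[1], 9)
  expect_equal(th$t_hi[1], 11)
  # zero velocity -> limits collapse onto the previous position
  th0 <- compute_thresholds(c(3, 3, 3), matrix(7, 10, 3), 5, cfg)
  expect_equal(th0$t_lo, c(3, 3, 3))
  expect_equal(th0$t_hi, c(3, 3, 3))
  # early frames use only the available part of the window
  th1 <- compute_thresholds(c(0, 0, 0), q, frame_k = 2, cfg)
  expect_true(all(is.finite(th1$t_hi)))
  expect_error(tkf_config(window_frames = 0), ">= 1")
})

test_that("censoring clamps to the violated threshold", {
  th <- list(t_lo = rep(9, 3), t_hi = rep(11, 3))
  expect_equal(censor(c(10, 10, 10), th), c(10, 10, 10))
  expect_equal(censor(c(8, 10, 10), th), c(9, 10, 10))
  expect_equal(censor(c(10, 12, 10), th), c(10, 11, 10))
})

test_that("prediction follows the constant-velocity model", {
  cfg <- tkf_config(dt = 1 / 60, sigma_a = 0)
  st <- list(x = c(1, 2, 3, 120, 0, 0), P = diag(6))
  pred <- tkf_predict(st, cfg)
  expect_equal(pred$x[1], 1 + 2)  # 120 cm/s over 1/60 s = 2 cm
  expect_equal(pred$x[2:3], c(2, 3))
  # zero velocity, Q = 0 -> position unchanged
  st0 <- list(x = c(5, 5, 5, 0, 0, 0), P = diag(6))
  expect_equal(tkf_predict(st0, cfg)$x[1:3], c(5, 5, 5))
  # covariance trace grows when Q is PSD
  cfg2 <- tkf_config(dt = 1 / 60, sigma_a = 10)
  expect_gte(sum(diag(tkf_predict(st, cfg2)$P)), sum(diag(st$P)))
})

test_that("the tobit update degenerates to the linear KF with open thresholds", {
  cfg <- tkf_config(dt = 1 / 60, sigma_a = 100, sigma_r = 2)
  set.seed(3)
  st <- list(x = rnorm(6), P = crossprod(matrix(rnorm(36), 6)) + diag(6) * 0.1)
  pred <- tkf_predict(st, cfg)
  th <- list(t_lo = rep(-1e9, 3), t_hi = rep(1e9, 3))
  q <- rnorm(3)
  up <- tobit_update(pred, censor(q, th), th, cfg)
  expect_equal(up$probs$p_uc, rep(1, 3))
  # independent linear KF update
  H <- cbind(diag(3), matrix(0, 3, 3))
  S <- H %*% pred$P %*% t(H) + cfg$R
  K <- pred$P %*% t(H) %*% solve(S)
  x_kf <- pred$x + as.numeric(K %*% (q - H %*% pred$x))
  P_kf <- (diag(6) - K %*% H) %*% pred$P
  expect_equal(up$state$x, x_kf, tolerance = 1e-8)
  expect_equal(up$state$P, (P_kf + t(P_kf)) / 2, tolerance = 1e-8)
})

test_that("censoring probabilities partition and equal limits freeze the update", {
  cfg <- tkf_config(dt = 1 / 60)
  set.seed(4)
  for (i in 1:20) {
    st <- list(x = rnorm(6, sd = 5), P = crossprod(matrix(rnorm(36), 6)) + diag(6))
    pred <- tkf_predict(st, cfg)
    lims <- sort(rnorm(2, sd = 10))
    th <- list(t_lo = rep(lims[1], 3), t_hi = rep(lims[2], 3))
    up <- tobit_update(pred, censor(rnorm(3, sd = 5), th), th, cfg)
    expect_equal(up$probs$p_uc + up$probs$p_l + up$probs$p_h, rep(1, 3),
                 tolerance = 1e-9)
  }
  st <- list(x = c(0, 0, 0, 1, 1, 1), P = diag(6))
  pred <- tkf_predict(st, cfg)
  th_eq <- list(t_lo = c(2, 2, 2), t_hi = c(2, 2, 2))
  up <- tobit_update(pred, censor(c(9, 9, 9), th_eq), th_eq, cfg)
  expect_equal(up$probs$p_uc, rep(0, 3))
  expect_equal(up$state$P, pred$P, tolerance = 1e-12)
})

test_that("the full filter with open thresholds matches an independent KF", {
  set.seed(5)
  for (i in 1:100) {
    m <- 40
    q <- matrix(rnorm(m * 3, sd = 10), m, 3) +
      outer(seq_len(m), c(1, -0.5, 0.2))
    seq <- point_sequence(q, fps = 60)
    cfg <- tkf_config(dt = 1 / 60, sigma_a = 500, sigma_r = 4,
                      threshold_mode = "fixed",
                      t_lo = rep(-1e9, 3), t_hi = rep(1e9, 3))
    got <- tkf_filter(seq, cfg)$seq$positions[, 1, ]
    x0 <- c(q[1, ], (q[2, ] - q[1, ]) * 60)
    oracle <- linear_kf_oracle(q, 1 / 60, 500, 4, x0, cfg$P0)
    expect_equal(got, oracle, tolerance = 1e-8)
    # threshold_mode "none" gives the same plain-KF trajectory
    cfg_none <- tkf_config(dt = 1 / 60, sigma_a = 500, sigma_r = 4,
                           threshold_mode = "none")
    got2 <- tkf_filter(seq, cfg_none)$seq$positions[, 1, ]
    expect_equal(got2, oracle, tolerance = 1e-8)
  }
})

test_that("filtering reduces noise on a static joint and tracks constant velocity", {
  set.seed(6)
  m <- 400
  q <- matrix(rnorm(m * 3, sd = 3), m, 3) + 50
  seq <- point_sequence(q, fps = 60)
  cfg <- tkf_config(dt = 1 / 60, sigma_a = 20, sigma_r = 3)
  filt <- tkf_filter(seq, cfg)$seq$positions[, 1, ]
  burn <- 21:m
  expect_lt(mean(apply(filt[burn, ] - 50, 2, stats::var)),
            mean(apply(q[burn, ] - 50, 2, stats::var)))
  # noiseless constant velocity with vanishing process noise (censoring off:
  # exact CV motion sits exactly on the adaptive limits, a knife edge)
  qcv <- outer(seq_len(m) / 60, c(30, -10, 5))
  seqcv <- point_sequence(qcv, fps = 60)
  cfgcv <- tkf_config(dt = 1 / 60, sigma_a = 1e-6, sigma_r = 1,
                      threshold_mode = "none")
  fcv <- tkf_filter(seqcv, cfgcv)$seq$positions[, 1, ]
  expect_lt(max(abs(fcv[burn, ] - qcv[burn, ])), 1e-6)
})

test_that("filtering is equivariant under mirroring", {
  skel <- skeleton_lower6()
  seq <- corrupt_awgn(generate_motion(skel, 120, 60, gait_params(seed = 7)),
                      5, seed = 8)
  mir <- seq
  mir$positions[, , 1] <- -mir$positions[, , 1]
  cfg <- tkf_config(dt = 1 / 60)
  a <- tkf_filter(seq, cfg)$seq$positions
  b <- tkf_filter(mir, cfg)$seq$positions
  expect_equal(b[, , 1], -a[, , 1], tolerance = 1e-10)
  expect_equal(b[, , 2:3], a[, , 2:3], tolerance = 1e-10)
})

test_that("masked joints fall back to prediction; all-masked joints warn", {
  skel <- skeleton_lower6()
  seq <- corrupt_dropout(generate_motion(skel, 100, 60, gait_params(seed = 9)),
                         0.4, seed = 10)
  out <- tkf_filter(seq, tkf_config(dt = 1 / 60))
  expect_true(all(is.finite(out$seq$positions)))
  seq$mask[, 2] <- FALSE
  expect_warning(tkf_filter(seq, tkf_config(dt = 1 / 60)), "no observed")
})

test_that("censoring beats the plain KF under occlusion bursts", {
  skel <- skeleton_lower6()
  ref <- generate_motion(skel, 600, 60, gait_params(seed = 11))
  spec <- corruption_spec(jitter_sd = 1, burst_rate = 0.006, burst_bias = 25,
                          outlier_rate = 0, seed = 12)
  cor <- corrupt_dmocap_like(ref, spec)
  expect_gt(nrow(attr(cor, "bursts")), 0)
  # past-only velocity windows: at a burst onset the spike has not yet
  # entered the window, so the limits clamp it; by re-emergence it has, so
  # recovery is fast
  tkf <- tkf_filter(cor, tkf_config(dt = 1 / 60, sigma_r = 1.5,
                                    causal = TRUE))$seq
  kf <- tkf_filter(cor, tkf_config(dt = 1 / 60, sigma_r = 1.5,
                                   threshold_mode = "none"))$seq
  expect_lt(joint_rmse(tkf, ref)$mean, joint_rmse(kf, ref)$mean)
})
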