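test_that("joint position error follows its closed forms", {
  skel <- skeleton_lower6()
  ref <- generate_motion(skel, 60, 60, gait_params(seed = 1))
  expect_equal(joint_rmse(ref, ref)$mean, 0)
  est <- ref
  est$positions[, 3, 1] <- est$positions[, 3, 1] + 3
  est$positions[, 3, 2] <- est$positions[, 3, 2] + 4
  jr <- joint_rmse(est, ref)
  expect_equal(unname(jr$per_joint[3]), 5)
  expect_equal(unname(joint_rmse(est, ref, mean_distance = TRUE)$per_joint[3]), 5)
  expect_error(joint_rmse(subset_joints(ref, c("hip_l", "knee_l")), ref), "shape")
})

test_that("awgn at sigma = 10 yields about 10 cm mean joint RMSE", {
  skel <- skeleton_full21()
  ref <- generate_motion(skel, 4800, 60, gait_params(seed = 2))
  cor <- corrupt_awgn(ref, 10, seed = 3)
  expect_lt(abs(joint_rmse(cor, ref)$mean - 10), 0.3)
})

test_that("joint error is invariant under a common rigid transform", {
  skel <- skeleton_lower6()
  ref <- generate_motion(skel, 40, 60, gait_params(seed = 4))
  est <- corrupt_awgn(ref, 6, seed = 5)
  base <- joint_rmse(est, ref)$mean
  Ry <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)
  tr <- structure(list(rotation = Ry, translation = c(5, -2, 8)),
                  class = "rigid_transform")
  moved <- joint_rmse(apply_rigid_transform(est, tr),
                      apply_rigid_transform(ref, tr))$mean
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("bone length error follows its closed forms and an oracle", {
  skel <- skeleton_lower6()
  ref <- generate_motion(skel, 50, 60, gait_params(seed = 6))
  expect_equal(bone_length_error(ref, ref)$mean, 0)
  est <- ref
  est$positions <- est$positions * 1.1
  ble <- bone_length_error(est, ref)
  # a 10 cm bone scaled by 1.1 gains 1 cm
  knee_bone <- which(names(ble$per_bone) == "knee_l-hip_l")
  expect_equal(unname(ble$per_bone[knee_bone]), 0.1 * 42, tolerance = 1e-9)
  # brute-force per-frame oracle on a random perturbation
  est2 <- corrupt_awgn(ref, 4, seed = 7)
  got <- bone_length_error(est2, ref)
  js <- which(skel$parent_index != 0L)
  oracle <- sapply(js, function(j) {
    p <- skel$parent_index[j]
    mean(abs(sqrt(rowSums((est2$positions[, j, ] - est2$positions[, p, ])^2)) -
               sqrt(rowSums((ref$positions[, j, ] - ref$positions[, p, ])^2))))
  })
  expect_equal(unname(got$per_bone), oracle, tolerance = 1e-12)
  # invariant under independent rigid transforms of each sequence
  Ry <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)
  tr <- structure(list(rotation = Ry, translation = c(1, 2, 3)),
                  class = "rigid_transform")
  expect_equal(bone_length_error(apply_rigid_transform(est2, tr), ref)$mean,
               got$mean, tolerance = 1e-9)
})

test_that("gait angles satisfy the anchor poses", {
  # construct a standing pose: legs vertical, fully extended
  skel <- skeleton_lower6()
  pose <- generate_motion(skel, 2, 60,
                          gait_params(hip_amp = 0, knee_amp = 0, bob_amp = 0,
                                      sway_amp = 0, speed = 0))
  ang <- joint_angles(pose)
  expect_equal(max(abs(ang[, c("LKF", "RKF", "LHF", "RHF")])), 0,
               tolerance = 1e-9)
  # shank perpendicular to thigh -> knee flexion 90 degrees
  bent <- pose
  kj <- skel$gait_joints
  knee <- bent$positions[1, kj[["knee_l"]], ]
  bent$positions[, kj[["ankle_l"]], ] <-
    matrix(knee + c(0, 0, 40), 2, 3, byrow = TRUE)  # shank points forward
  expect_equal(unname(joint_angles(bent)[1, "LKF"]), 90, tolerance = 1e-9)
})

test_that("angles recover the generator's commanded trajectories within 1 degree", {
  seq <- generate_motion(skeleton_full21(), 300, 60,
                         gait_params(seed = 8, perturb_deg = 2))
  cmd <- attr(seq, "angles")
  ang <- joint_angles(seq)
  expect_lt(sqrt(mean((ang[, "LKF"] - cmd$knee_flex_l)^2)), 1)
  expect_lt(sqrt(mean((ang[, "RKF"] - cmd$knee_flex_r)^2)), 1)
  expect_lt(sqrt(mean((ang[, "LHF"] - cmd$hip_flex_l)^2)), 1)
  expect_lt(sqrt(mean((ang[, "RHF"] - cmd$hip_flex_r)^2)), 1)
})

test_that("angle error reports per-angle biases and matches a trace oracle", {
  skel <- skeleton_lower6()
  ref <- generate_motion(skel, 80, 60, gait_params(seed = 9))
  expect_equal(angle_error(ref, ref)$mean, 0)
  # rotate the whole left leg rigidly about the hip by 3 degrees in the
  # sagittal plane: hip flexion shifts by exactly 3, the knee angle not at all
  est <- ref
  kj <- skel$gait_joints
  hip <- ref$positions[, kj[["hip_l"]], ]
  th <- 3 * pi / 180
  rot_about_hip <- function(joint) {
    v <- ref$positions[, joint, ] - hip
    est$positions[, joint, ] <<- hip +
      cbind(v[, 1],
            v[, 2] * cos(th) + v[, 3] * sin(th),
            v[, 3] * cos(th) - v[, 2] * sin(th))
  }
  rot_about_hip(kj[["knee_l"]])
  rot_about_hip(kj[["ankle_l"]])
  ae <- angle_error(est, ref)
  expect_equal(unname(ae$per_angle["LHF"]), 3, tolerance = 1e-6)
  expect_equal(unname(ae$per_angle["LKF"]), 0, tolerance = 1e-6)
  expect_equal(unname(ae$per_angle["RHF"]), 0, tolerance = 1e-9)
  # independent oracle on noisy inputs
  est2 <- corrupt_awgn(ref, 2, seed = 10)
  got <- angle_error(est2, ref)
  oracle <- colMeans(abs(joint_angles(est2) - joint_angles(ref)))
  expect_equal(unname(got$per_angle), unname(oracle), tolerance = 1e-12)
})

test_that("quadrant summaries partition the body and localize error", {
  skel <- skeleton_full21()
  ref <- generate_motion(skel, 120, 60, gait_params(seed = 11))
  q <- skel$quadrant
  non_axial <- q != "axial"
  quads <- c("upper-left", "upper-right", "lower-left", "lower-right")
  expect_true(all(q[non_axial] %in% quads))
  # noise only in upper-body joints
  est <- ref
  up <- which(grepl("^upper", q))
  set.seed(12)
  est$positions[, up, ] <- est$positions[, up, ] +
    array(rnorm(length(est$positions[, up, ]), sd = 5), dim(est$positions[, up, , drop = FALSE]))
  rep <- quadrant_report(ref, est, estimates = list(same = ref))
  expect_gt(rep$corrupted_rmse[rep$group == "upper_body"],
            rep$corrupted_rmse[rep$group == "lower_body"])
  # est = ref rows: zero rmse and improvement equal to the corrupted rmse
  expect_equal(rep$same_rmse, rep(0, nrow(rep)))
  expect_equal(rep$same_improvement, rep$corrupted_rmse)
})
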