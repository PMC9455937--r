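# Evaluation metrics: joint-position RMSE, bone-length error against a
# reference, the six lower-body gait angles, and body-quadrant summaries.

#' Joint-position error
#'
#' Per joint, the root-mean-square over frames of the per-frame 3-D Euclidean
#' distance between estimate and reference; frames unobserved in the
#' reference mask are excluded. `mean_distance = TRUE` averages the distances
#' instead of taking the RMS.
#'
#' @param est,ref Frame/joint-aligned [motion_sequence()] objects.
#' @param mean_distance Use the mean Euclidean distance instead of the RMS.
#' @return `list(per_joint, mean)` in cm.
#' @export
joint_rmse <- function(est, ref, mean_distance = FALSE) {
  d <- dim(est$positions)
  if (!all(d == dim(ref$positions))) stop("est and ref must have the same shape")
  per_joint <- numeric(d[2])
  for (j in seq_len(d[2])) {
    keep <- ref$mask[, j]
    dv <- est$positions[keep, j, , drop = FALSE] - ref$positions[keep, j, , drop = FALSE]
    dist2 <- rowSums(matrix(dv, sum(keep), 3)^2)
    per_joint[j] <- if (mean_distance) mean(sqrt(dist2)) else sqrt(mean(dist2))
  }
  names(per_joint) <- est$skeleton$joint_names
  list(per_joint = per_joint, mean = mean(per_joint))
}

#' Bone-length error against a reference
#'
#' For every bone (tree edge), the mean over frames of the absolute
#' difference between the estimated segment length and the reference segment
#' length at the same frame.
#'
#' @param est,ref Aligned [motion_sequence()] objects sharing a skeleton.
#' @param skeleton Skeleton defining the bones (default: `est$skeleton`).
#' @return `list(per_bone, mean)` in cm.
#' @export
bone_length_error <- function(est, ref, skeleton = est$skeleton) {
  if (!all(dim(est$positions) == dim(ref$positions)))
    stop("est and ref must have the same shape")
  seg_len <- function(seq, j, p)
    sqrt(rowSums((seq$positions[, j, , drop = TRUE] -
                    seq$positions[, p, , drop = TRUE])^2))
  js <- which(skeleton$parent_index != 0L)
  per_bone <- numeric(length(js))
  for (i in seq_along(js)) {
    j <- js[i]; p <- skeleton$parent_index[j]
    per_bone[i] <- mean(abs(seg_len(est, j, p) - seg_len(ref, j, p)))
  }
  names(per_bone) <- paste0(skeleton$joint_names[js], "-",
                            skeleton$joint_names[skeleton$parent_index[js]])
  list(per_bone = per_bone, mean = mean(per_bone))
}

# per-frame anatomical axes from the pelvis: lateral = hip_l -> hip_r
# projected onto the floor plane, forward = lateral x up (y-up)
pelvis_axes <- function(seq) {
  skel <- seq$skeleton
  lat <- seq$positions[, skel$hip_right, , drop = TRUE] -
    seq$positions[, skel$hip_left, , drop = TRUE]
  lat[, 2] <- 0
  nrm <- sqrt(rowSums(lat^2))
  lat <- lat / pmax(nrm, 1e-9)
  # forward = lateral x up: (lx,0,lz) x (0,1,0) = (-lz, 0, lx)
  fwd <- cbind(-lat[, 3], 0 * nrm, lat[, 1])
  list(lateral = lat, forward = fwd, degenerate = nrm < 1e-9)
}

angle_deg <- function(x) x * 180 / pi

#' Gait joint angles
#'
#' Computes the six lower-body angles used in gait assessment, per frame and
#' in degrees:
#' * knee flexion (LKF/RKF): 180 deg minus the angle between the knee-to-hip
#'   and knee-to-ankle segments; 0 for a fully extended leg.
#' * hip flexion/extension (LHF/RHF): signed angle of the thigh projected
#'   onto the sagittal plane versus the downward vertical (flexion positive).
#' * hip abduction/adduction (LHA/RHA): the analogous frontal-plane angle
#'   (abduction positive).
#' Sagittal and frontal planes are rebuilt each frame from the hip-left to
#' hip-right axis projected onto the floor plane.
#'
#' @param seq A [motion_sequence()] whose skeleton defines `gait_joints`.
#' @return `M x 6` matrix with columns LKF, RKF, LHF, RHF, LHA, RHA (deg);
#'   frames with a degenerate segment are `NA`.
#' @export
joint_angles <- function(seq) {
  skel <- seq$skeleton
  gj <- skel$gait_joints
  if (is.null(gj)) stop("skeleton does not define gait_joints (hip/knee/ankle chains)")
  ax <- pelvis_axes(seq)
  up <- c(0, 1, 0)
  m <- n_frames(seq)
  out <- matrix(NA_real_, m, 6,
                dimnames = list(NULL, c("LKF", "RKF", "LHF", "RHF", "LHA", "RHA")))
  for (side in c("l", "r")) {
    hip <- seq$positions[, gj[[paste0("hip_", side)]], , drop = TRUE]
    knee <- seq$positions[, gj[[paste0("knee_", side)]], , drop = TRUE]
    ankle <- seq$positions[, gj[[paste0("ankle_", side)]], , drop = TRUE]
    v1 <- hip - knee; v2 <- ankle - knee
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    ok <- n1 > 1e-9 & n2 > 1e-9 & !ax$degenerate
    cosang <- pmin(pmax(rowSums(v1 * v2) / (n1 * n2), -1), 1)
    kf <- 180 - angle_deg(acos(cosang))
    thigh <- knee - hip
    tf <- rowSums(thigh * ax$forward)
    tl <- rowSums(thigh * ax$lateral)
    tdown <- -thigh[, 2]
    hf <- angle_deg(atan2(tf, tdown))
    ha_sign <- if (side == "l") -1 else 1
    ha <- angle_deg(atan2(ha_sign * tl, tdown))
    col_k <- if (side == "l") "LKF" else "RKF"
    col_f <- if (side == "l") "LHF" else "RHF"
    col_a <- if (side == "l") "LHA" else "RHA"
    out[ok, col_k] <- kf[ok]
    out[ok, col_f] <- hf[ok]
    out[ok, col_a] <- ha[ok]
  }
  out
}

#' Joint-angle error
#'
#' Mean absolute (default) or RMS difference of corresponding gait-angle
#' traces, per angle and averaged over the six angles.
#'
#' @param est,ref Aligned [motion_sequence()] objects.
#' @param rms Use RMS instead of the mean absolute difference.
#' @return `list(per_angle, mean)` in degrees.
#' @export
angle_error <- function(est, ref, rms = FALSE) {
  ae <- joint_angles(est); re <- joint_angles(ref)
  diffs <- abs(ae - re)
  per_angle <- apply(diffs, 2, function(x) {
    x <- x[is.finite(x)]
    if (rms) sqrt(mean(x^2)) else mean(x)
  })
  list(per_angle = per_angle, mean = mean(per_angle))
}

mean_joint_speed <- function(seq, joints) {
  v <- compute_velocities(seq)
  sp <- sqrt(apply(v[, joints, , drop = FALSE]^2, c(1, 2), sum))
  mean(sp)
}

#' Body-quadrant error and velocity summary
#'
#' For each body group (upper, lower, left, right and the four quadrants):
#' mean joint speed of the reference and of the corrupted input, the percent
#' velocity difference `(corrupted - reference) / corrupted * 100`, the
#' corrupted input's RMSE, each enhanced estimate's RMSE, and the improvement
#' (corrupted RMSE minus enhanced RMSE). Axial joints belong to no quadrant.
#'
#' @param ref Clean reference [motion_sequence()].
#' @param corrupted Corrupted input sequence.
#' @param estimates Named list of enhanced [motion_sequence()] objects.
#' @return A data frame, one row per group.
#' @export
quadrant_report <- function(ref, corrupted, estimates = list()) {
  skel <- ref$skeleton
  q <- skel$quadrant
  if (all(q == "axial")) stop("skeleton has no quadrant labels besides axial")
  groups <- list(
    upper_body = grepl("^upper", q), lower_body = grepl("^lower", q),
    left_side = grepl("left$", q), right_side = grepl("right$", q),
    upper_left = q == "upper-left", upper_right = q == "upper-right",
    lower_left = q == "lower-left", lower_right = q == "lower-right")
  rows <- lapply(names(groups), function(g) {
    joints <- which(groups[[g]])
    if (length(joints) == 0) return(NULL)
    vr <- mean_joint_speed(ref, joints)
    vc <- mean_joint_speed(corrupted, joints)
    rmse_grp <- function(est) {
      pj <- joint_rmse(est, ref)$per_joint
      mean(pj[joints])
    }
    rc <- rmse_grp(corrupted)
    row <- data.frame(group = g, ref_vel = vr, corrupted_vel = vc,
                      pct_vel_diff = (vc - vr) / vc * 100, corrupted_rmse = rc)
    for (nm in names(estimates)) {
      re <- rmse_grp(estimates[[nm]])
      row[[paste0(nm, "_rmse")]] <- re
      row[[paste0(nm, "_improvement")]] <- rc - re
    }
    row
  })
  do.call(rbind, rows)
}
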