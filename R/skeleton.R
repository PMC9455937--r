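#' Skeleton descriptor
#'
#' A `skeleton` describes the joint structure shared by all frames of a motion
#' sequence: joint names, the parent tree, bone lengths (cm, joint to parent),
#' a body-quadrant label per joint, and the indices of the reference hip
#' joints used for floor projection, scaling and gait angles.
#'
#' @param joint_names Character vector of unique joint labels.
#' @param parent_index Integer vector, same length; index of each joint's
#'   parent in `joint_names`, with `0` marking the single root.
#' @param bone_lengths Numeric vector of bone lengths in cm (joint to its
#'   parent); the root entry must be `NA`.
#' @param quadrant Character vector with entries in
#'   `c("upper-left", "upper-right", "lower-left", "lower-right", "axial")`.
#' @param hip_left,hip_right Indices of the left/right hip joints.
#' @param hip_center Index of the hip-center (pelvis) joint, or `NA` to use
#'   the midpoint of `hip_left`/`hip_right`.
#' @param phantom_index Index of the floor-projection phantom joint if the
#'   skeleton carries one, else `NA`.
#' @param gait_joints Optional named integer vector with entries
#'   `hip_l, knee_l, ankle_l, hip_r, knee_r, ankle_r`, required by
#'   [joint_angles()].
#' @param fps_default Default sampling rate (Hz) for sequences built on this
#'   skeleton.
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(joint_names, parent_index, bone_lengths, quadrant,
                     hip_left, hip_right, hip_center = NA_integer_,
                     phantom_index = NA_integer_, gait_joints = NULL,
                     fps_default = 60) {
  n <- length(joint_names)
  stopifnot(is.character(joint_names), n >= 1)
  if (anyDuplicated(joint_names)) stop("joint names must be unique")
  parent_index <- as.integer(parent_index)
  if (length(parent_index) != n || any(parent_index < 0 | parent_index > n))
    stop("parent_index must map every joint to a valid parent or 0 (root)")
  if (sum(parent_index == 0L) != 1L)
    stop("skeleton must have exactly one root")
  # tree check: walking up from every joint must reach the root, no cycles
  for (j in seq_len(n)) {
    seen <- logical(n); i <- j
    while (parent_index[i] != 0L) {
      i <- parent_index[i]
      if (seen[i]) stop("parent_index contains a cycle")
      seen[i] <- TRUE
    }
  }
  if (length(bone_lengths) != n) stop("bone_lengths must have one entry per joint")
  root <- which(parent_index == 0L)
  bl <- bone_lengths[-root]
  if (any(!is.finite(bl)) || any(bl <= 0))
    stop("bone_lengths must be strictly positive and finite for non-root joints")
  quad_levels <- c("upper-left", "upper-right", "lower-left", "lower-right", "axial")
  if (length(quadrant) != n || !all(quadrant %in% quad_levels))
    stop("quadrant labels must be one of: ", paste(quad_levels, collapse = ", "))
  for (idx in c(hip_left, hip_right))
    if (!is.na(idx) && (idx < 1 || idx > n)) stop("hip index out of range")
  if (!is.na(hip_left) && !is.na(hip_right) && hip_left == hip_right)
    stop("hip_left and hip_right must be distinct")
  structure(
    list(joint_names = joint_names,
         parent_index = parent_index,
         bone_lengths = as.numeric(bone_lengths),
         quadrant = quadrant,
         hip_left = as.integer(hip_left),
         hip_right = as.integer(hip_right),
         hip_center = as.integer(hip_center),
         phantom_index = as.integer(phantom_index),
         gait_joints = if (!is.null(gait_joints)) vapply(gait_joints, as.integer, integer(1)),
         fps_default = fps_default),
    class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d joints, root '%s'\n",
              length(x$joint_names), x$joint_names[x$parent_index == 0L]))
  invisible(x)
}

n_joints <- function(skel) length(skel$joint_names)

#' Built-in skeleton models
#'
#' Three homogeneous skeleton descriptors used throughout the package: a
#' 21-joint full-body model, a 16-joint model (head/neck/arms/legs, no spine
#' chain), and a 6-joint lower-body model (hips, knees, ankles) typical of
#' gait studies. Bone lengths are adult-scale values in cm.
#'
#' @return A [skeleton()].
#' @export
skeleton_full21 <- function() {
  jn <- c("pelvis",
          "hip_l", "knee_l", "ankle_l", "toe_l",
          "hip_r", "knee_r", "ankle_r", "toe_r",
          "spine", "chest", "neck", "head",
          "shoulder_l", "elbow_l", "wrist_l", "hand_l",
          "shoulder_r", "elbow_r", "wrist_r", "hand_r")
  parent <- c(0L,
              1L, 2L, 3L, 4L,
              1L, 6L, 7L, 8L,
              1L, 10L, 11L, 12L,
              11L, 14L, 15L, 16L,
              11L, 18L, 19L, 20L)
  bl <- c(NA,
          11, 42, 40, 15,
          11, 42, 40, 15,
          12, 15, 14, 12,
          19, 30, 26, 10,
          19, 30, 26, 10)
  quad <- c("axial",
            "lower-left", "lower-left", "lower-left", "lower-left",
            "lower-right", "lower-right", "lower-right", "lower-right",
            "axial", "axial", "axial", "axial",
            "upper-left", "upper-left", "upper-left", "upper-left",
            "upper-right", "upper-right", "upper-right", "upper-right")
  skeleton(jn, parent, bl, quad,
           hip_left = 2L, hip_right = 6L, hip_center = 1L,
           gait_joints = c(hip_l = 2L, knee_l = 3L, ankle_l = 4L,
                           hip_r = 6L, knee_r = 7L, ankle_r = 8L))
}

#' @rdname skeleton_full21
#' @export
skeleton_body16 <- function() {
  s21 <- skeleton_full21()
  keep <- c("head", "neck",
            "shoulder_l", "elbow_l", "wrist_l",
            "shoulder_r", "elbow_r", "wrist_r",
            "hip_l", "knee_l", "ankle_l", "toe_l",
            "hip_r", "knee_r", "ankle_r", "toe_r")
  ref <- generate_motion(s21, M = 2, fps = 60, params = gait_params(seed = 1))
  subset_joints(ref, keep)$skeleton
}

#' @rdname skeleton_full21
#' @export
skeleton_lower6 <- function() {
  s21 <- skeleton_full21()
  keep <- c("hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r")
  ref <- generate_motion(s21, M = 2, fps = 60, params = gait_params(seed = 1))
  subset_joints(ref, keep)$skeleton
}

#' Read / write a skeleton descriptor file (JSON)
#'
#' @param path File path.
#' @return [read_skeleton()] returns a [skeleton()]; [write_skeleton()]
#'   returns `path` invisibly.
#' @export
read_skeleton <- function(path) {
  x <- jsonlite::fromJSON(path)
  skeleton(x$joint_names, x$parent_index,
           ifelse(is.na(x$bone_lengths) | x$bone_lengths < 0, NA, x$bone_lengths),
           x$quadrant, x$hip_left, x$hip_right,
           hip_center = x$hip_center %||% NA_integer_,
           phantom_index = x$phantom_index %||% NA_integer_,
           gait_joints = if (!is.null(x$gait_joints)) unlist(x$gait_joints),
           fps_default = x$fps_default %||% 60)
}

#' @rdname read_skeleton
#' @param skel A [skeleton()].
#' @export
write_skeleton <- function(skel, path) {
  obj <- unclass(skel)
  if (!is.null(obj$gait_joints)) obj$gait_joints <- as.list(obj$gait_joints)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
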