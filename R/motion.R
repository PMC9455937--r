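#' Motion sequence container
#'
#' Positions of every skeleton joint over time: an `M x N x 3` array in cm
#' (y-up, right-handed), a sampling rate in Hz, and a logical `M x N` mask
#' (`TRUE` = observed). Masked (dropped-out) coordinates carry the fill
#' value 0.
#'
#' @param skeleton A [skeleton()].
#' @param positions Numeric array `M x N x 3` (frames x joints x xyz), cm.
#' @param fps Sampling rate in Hz (> 0).
#' @param mask Logical `M x N` matrix; defaults to all observed.
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(skeleton, positions, fps = skeleton$fps_default,
                            mask = NULL) {
  stopifnot(inherits(skeleton, "skeleton"))
  d <- dim(positions)
  if (length(d) != 3 || d[3] != 3)
    stop("positions must be an M x N x 3 array")
  if (d[2] != n_joints(skeleton))
    stop(sprintf("positions have %d joints but skeleton has %d", d[2], n_joints(skeleton)))
  if (d[1] < 1) stop("at least one frame required")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!is.logical(mask) || !all(dim(mask) == d[1:2]))
    stop("mask must be a logical M x N matrix")
  obs <- array(mask, dim = d)  # recycles over the xyz slab
  if (any(!is.finite(positions[obs])))
    stop("positions must be finite wherever the mask is TRUE")
  structure(list(skeleton = skeleton, fps = fps,
                 positions = positions, mask = mask),
            class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("motion_sequence: %d frames x %d joints @ %g fps (%.1f%% observed)\n",
              d[1], d[2], x$fps, 100 * mean(x$mask)))
  invisible(x)
}

n_frames <- function(seq) dim(seq$positions)[1]

#' Flatten positions to an M x 3N matrix (columns j1_x, j1_y, j1_z, j2_x, ...)
#' @keywords internal
flatten_positions <- function(seq) {
  d <- dim(seq$positions)
  out <- aperm(seq$positions, c(1, 3, 2))  # M x 3 x N
  dim(out) <- c(d[1], 3 * d[2])
  out
}

unflatten_positions <- function(mat, n_joints) {
  m <- nrow(mat)
  x <- mat
  dim(x) <- c(m, 3, n_joints)
  aperm(x, c(1, 3, 2))
}

#' Read and write motion files
#'
#' The motion-file dialect is UTF-8 delimited text with a header
#' `frame,<joint>_x,<joint>_y,<joint>_z,...`, one row per frame, coordinates
#' in cm. Missing (dropped-out) values are written as empty cells and read
#' back as mask `FALSE` with fill value 0.
#'
#' @param path File path.
#' @param skeleton The [skeleton()] the file must conform to.
#' @param fps Sampling rate to attach (Hz).
#' @return [read_motion()] returns a [motion_sequence()].
#' @export
read_motion <- function(path, skeleton, fps = skeleton$fps_default) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  expected <- c("frame", paste0(rep(skeleton$joint_names, each = 3),
                                c("_x", "_y", "_z")))
  if (length(hdr) != length(expected) || !all(hdr == expected)) {
    bad <- setdiff(hdr, expected)
    stop("motion file header does not match skeleton",
         if (length(bad)) paste0(": unknown column(s) ", paste(bad, collapse = ", ")))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  bad <- which(is.na(num) & m != "", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad[1, 1], colnames(raw)[bad[1, 2] + 1L]))
  missing <- m == ""
  num[missing] <- 0
  n <- n_joints(skeleton)
  pos <- unflatten_positions(num, n)
  miss3 <- unflatten_positions(missing + 0, n)
  mask <- apply(miss3 == 0, c(1, 2), all)
  motion_sequence(skeleton, pos, fps = fps, mask = mask)
}

#' @rdname read_motion
#' @param seq A [motion_sequence()].
#' @export
write_motion <- function(seq, path) {
  mat <- flatten_positions(seq)
  chr <- matrix(sprintf("%.10g", mat), nrow(mat), ncol(mat))
  # mask columns expand to j1,j1,j1,j2,... matching the flatten order
  miss <- !seq$mask[, rep(seq_len(ncol(seq$mask)), each = 3), drop = FALSE]
  chr[miss] <- ""
  hdr <- c("frame", paste0(rep(seq$skeleton$joint_names, each = 3),
                           c("_x", "_y", "_z")))
  rows <- apply(cbind(seq_len(nrow(mat)) - 1L, chr), 1, paste, collapse = ",")
  writeLines(c(paste(hdr, collapse = ","), rows), path)
  invisible(path)
}

#' Add the floor-projection phantom joint
#'
#' Appends one joint per frame at the projection of the hip center onto the
#' y = 0 floor plane, i.e. `(x_hip, 0, z_hip)`. The phantom anchors the
#' skeleton to the floor so a manifold trained on such data learns local body
#' motion rather than global translation.
#'
#' @param seq A [motion_sequence()] whose skeleton has no phantom yet.
#' @return A [motion_sequence()] with `N + 1` joints and
#'   `skeleton$phantom_index` set.
#' @export
add_phantom_joint <- function(seq) {
  skel <- seq$skeleton
  if (!is.na(skel$phantom_index)) stop("skeleton already has a phantom joint")
  hips <- hip_center_positions(seq)
  phantom <- hips
  phantom[, 2] <- 0
  d <- dim(seq$positions)
  pos <- array(0, dim = c(d[1], d[2] + 1L, 3))
  pos[, seq_len(d[2]), ] <- seq$positions
  pos[, d[2] + 1L, ] <- phantom
  root <- which(skel$parent_index == 0L)
  ph_len <- mean(sqrt(rowSums((seq$positions[, root, , drop = FALSE][, 1, ] - phantom)^2)))
  skel2 <- skel
  skel2$joint_names <- c(skel$joint_names, "phantom")
  skel2$parent_index <- c(skel$parent_index, root)
  skel2$bone_lengths <- c(skel$bone_lengths, max(ph_len, 1e-6))
  skel2$quadrant <- c(skel$quadrant, "axial")
  skel2$phantom_index <- d[2] + 1L
  skel2 <- do.call(skeleton, skel2[setdiff(names(skel2), "fps_default")])
  skel2$fps_default <- skel$fps_default
  motion_sequence(skel2, pos, fps = seq$fps,
                  mask = cbind(seq$mask, rep(TRUE, d[1])))
}

hip_center_positions <- function(seq) {
  skel <- seq$skeleton
  if (!is.na(skel$hip_center)) {
    seq$positions[, skel$hip_center, , drop = TRUE]
  } else {
    (seq$positions[, skel$hip_left, , drop = TRUE] +
       seq$positions[, skel$hip_right, , drop = TRUE]) / 2
  }
}

#' Scale a sequence by hip height
#'
#' Scales all coordinates by `reference_height_cm / subject_height_cm`, where
#' the subject height is the mean hip-center height (y) over the frames of
#' `seq` (typically a T-pose clip) unless given explicitly. Used to match a
#' subject's stature to the skeleton a manifold was trained on; the returned
#' factor allows exact inversion.
#'
#' @param seq A [motion_sequence()].
#' @param reference_height_cm Hip-to-floor distance of the reference skeleton.
#' @param subject_height_cm Optional explicit subject hip height.
#' @return `list(seq = scaled sequence, scale = factor)`.
#' @export
scale_by_hip_height <- function(seq, reference_height_cm,
                                subject_height_cm = NULL) {
  if (is.null(subject_height_cm)) {
    hips <- hip_center_positions(seq)
    subject_height_cm <- mean(hips[, 2])
  }
  if (!is.finite(subject_height_cm) || subject_height_cm <= 0)
    stop("subject hip height must be positive")
  if (!is.finite(reference_height_cm) || reference_height_cm <= 0)
    stop("reference hip height must be positive")
  s <- reference_height_cm / subject_height_cm
  out <- seq
  out$positions <- seq$positions * s
  list(seq = out, scale = s)
}

#' Subset and reorder joints
#'
#' Restricts a sequence to the named joints. The skeleton tree is re-rooted
#' consistently: each kept joint's parent becomes its nearest kept ancestor;
#' if several kept joints have no kept ancestor the first becomes the root
#' and the rest are attached to it. Bone lengths are recomputed from the
#' first frame of `seq`.
#'
#' @param seq A [motion_sequence()].
#' @param names Character vector of joint names to keep (order respected).
#' @return A [motion_sequence()] over the reduced skeleton.
#' @export
subset_joints <- function(seq, names) {
  skel <- seq$skeleton
  if (length(names) == 0) stop("empty joint request")
  idx <- match(names, skel$joint_names)
  if (anyNA(idx))
    stop("unknown joint name(s): ", paste(names[is.na(idx)], collapse = ", "))
  nearest_kept_ancestor <- function(j) {
    p <- skel$parent_index[j]
    while (p != 0L && !(p %in% idx)) p <- skel$parent_index[p]
    p
  }
  new_parent <- integer(length(idx))
  for (i in seq_along(idx)) {
    anc <- nearest_kept_ancestor(idx[i])
    new_parent[i] <- if (anc == 0L) 0L else match(anc, idx)
  }
  roots <- which(new_parent == 0L)
  if (length(roots) > 1) new_parent[roots[-1]] <- roots[1]
  pos <- seq$positions[, idx, , drop = FALSE]
  f1 <- pos[1, , ]
  bl <- rep(NA_real_, length(idx))
  for (i in seq_along(idx)) {
    if (new_parent[i] != 0L)
      bl[i] <- max(sqrt(sum((f1[i, ] - f1[new_parent[i], ])^2)), 1e-9)
  }
  remap <- function(old) {
    if (is.na(old) || !(old %in% idx)) NA_integer_ else match(old, idx)
  }
  gj <- NULL
  if (!is.null(skel$gait_joints)) {
    gj <- vapply(skel$gait_joints, remap, integer(1))
    if (anyNA(gj)) gj <- NULL
  }
  skel2 <- skeleton(names, new_parent, bl, skel$quadrant[idx],
                    hip_left = remap(skel$hip_left),
                    hip_right = remap(skel$hip_right),
                    hip_center = remap(skel$hip_center),
                    phantom_index = remap(skel$phantom_index),
                    gait_joints = gj,
                    fps_default = skel$fps_default)
  motion_sequence(skel2, pos, fps = seq$fps,
                  mask = seq$mask[, idx, drop = FALSE])
}

#' Finite-difference joint velocities
#'
#' Forward differences scaled by the sampling rate; the first frame
#' duplicates the second frame's value.
#'
#' @param seq A [motion_sequence()] with at least two frames.
#' @return An `M x N x 3` array of velocities in cm/s.
#' @export
compute_velocities <- function(seq) {
  d <- dim(seq$positions)
  if (d[1] < 2) stop("at least two frames required to compute velocities")
  v <- array(0, dim = d)
  v[2:d[1], , ] <- (seq$positions[2:d[1], , , drop = FALSE] -
                      seq$positions[seq_len(d[1] - 1), , , drop = FALSE]) * seq$fps
  v[1, , ] <- v[2, , ]
  v
}
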