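# Cleaning pipeline for depth-sensor skeletal data: Hampel outlier removal,
# rigid registration onto a reference via SVD, and per-joint bias removal.

#' Hampel outlier filter
#'
#' Sliding-window median filter with a robust rejection rule: for each sample
#' the window median `m` and the robust scale `sigma = 1.4826 * MAD` are
#' computed over a centered window (truncated at the series edges); the
#' sample is replaced by `m` when it deviates from it by more than
#' `n_sigmas * sigma`. When the window MAD is zero, any deviation from the
#' median is replaced.
#'
#' @param x Numeric vector (one scalar coordinate channel), or a
#'   [motion_sequence()] (filtered per joint and axis).
#' @param window Odd window length >= 3 (default 7 samples).
#' @param n_sigmas Rejection threshold in robust standard deviations.
#' @return Filtered object of the same type as `x`.
#' @export
hampel_filter <- function(x, window = 7, n_sigmas = 3) {
  UseMethod("hampel_filter")
}

#' @export
hampel_filter.numeric <- function(x, window = 7, n_sigmas = 3) {
  if (window %% 2 == 0) stop("window must be odd")
  if (window < 3) stop("window must be >= 3")
  n <- length(x)
  half <- (window - 1) %/% 2
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- x[lo:hi]
    m <- stats::median(w)
    sigma <- 1.4826 * stats::median(abs(w - m))
    dev <- abs(x[i] - m)
    if ((sigma == 0 && dev > 0) || (sigma > 0 && dev > n_sigmas * sigma))
      out[i] <- m
  }
  out
}

#' @export
hampel_filter.motion_sequence <- function(x, window = 7, n_sigmas = 3) {
  d <- dim(x$positions)
  out <- x
  for (j in seq_len(d[2]))
    for (a in 1:3)
      out$positions[, j, a] <- hampel_filter(x$positions[, j, a], window, n_sigmas)
  out
}

#' Rigid registration by singular value decomposition
#'
#' Aligns a mobile sequence onto a reference with a single global rotation
#' and translation. One centroid per sequence is computed over all joints and
#' frames, the 3 x 3 cross-covariance of the centered point sets is
#' decomposed by SVD, and the rotation is assembled from the singular
#' vectors with the reflection corrected so that `det(R) = +1` (skeletons
#' must never be mirrored). Relative joint geometry is untouched.
#'
#' @param mobile,reference [motion_sequence()] objects with identical frame
#'   and joint counts.
#' @return `list(transform = rigid_transform, seq = registered mobile)`.
#' @export
register_svd <- function(mobile, reference) {
  dm <- dim(mobile$positions); dr <- dim(reference$positions)
  if (!all(dm == dr)) stop("mobile and reference must have the same shape")
  M <- matrix(mobile$positions, dm[1] * dm[2], 3)
  Rf <- matrix(reference$positions, dr[1] * dr[2], 3)
  cm <- colMeans(M); cr <- colMeans(Rf)
  Mc <- sweep(M, 2, cm); Rc <- sweep(Rf, 2, cr)
  H <- crossprod(Mc, Rc)  # 3x3 cross-covariance, mobile vs reference
  sv <- svd(H)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1))
    stop("degenerate point configuration: rank < 2")
  V <- sv$v
  R <- V %*% t(sv$u)
  if (det(R) < 0) {           # reflection: flip the least-significant axis
    V[, 3] <- -V[, 3]
    R <- V %*% t(sv$u)
  }
  t <- cr - R %*% cm
  out <- mobile
  reg <- M %*% t(R) + matrix(t, dm[1] * dm[2], 3, byrow = TRUE)
  out$positions <- array(reg, dim = dm)
  transform <- structure(list(rotation = R, translation = as.numeric(t)),
                         class = "rigid_transform")
  list(transform = transform, seq = out)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n rotation:\n")
  print(round(x$rotation, 6))
  cat(" translation:", sprintf("%.4f", x$translation), "\n")
  invisible(x)
}

#' Apply a rigid transform to a motion sequence
#'
#' @param seq A [motion_sequence()].
#' @param transform A `rigid_transform` from [register_svd()].
#' @return The transformed [motion_sequence()].
#' @export
apply_rigid_transform <- function(seq, transform) {
  d <- dim(seq$positions)
  M <- matrix(seq$positions, d[1] * d[2], 3)
  out <- seq
  out$positions <- array(M %*% t(transform$rotation) +
                           matrix(transform$translation, d[1] * d[2], 3, byrow = TRUE),
                         dim = d)
  out
}

#' Per-joint bias removal
#'
#' Skeleton-definition offsets between two capture systems are constant per
#' joint; the bias is the per-joint mean (over frames) of the coordinate
#' differences between the registered mobile data and the reference, and is
#' subtracted from the mobile data.
#'
#' @param dmocap Registered mobile sequence.
#' @param mocap Frame/joint-aligned reference sequence.
#' @return `list(bias = N x 3 matrix (cm), seq = corrected sequence)`.
#' @export
remove_bias <- function(dmocap, mocap) {
  dd <- dim(dmocap$positions)
  if (!all(dd == dim(mocap$positions)))
    stop("dmocap and mocap must have the same shape")
  diff <- dmocap$positions - mocap$positions
  bias <- apply(diff, c(2, 3), mean)
  out <- dmocap
  for (j in seq_len(dd[2]))
    out$positions[, j, ] <- sweep(dmocap$positions[, j, , drop = TRUE], 2, bias[j, ])
  list(bias = bias, seq = out)
}
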