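# Synthetic gait corpora by forward kinematics, plus corruption operators
# emulating depth-sensor artifacts. The generator drives sinusoidal joint
# angles through exact rotations, so segment lengths are constant to machine
# precision -- the property every bone-length test leans on.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Gait parameters for the synthetic generator
#'
#' Amplitudes are joint-angle amplitudes in degrees, anatomically bounded;
#' speeds in cm/s. `perturb_deg` adds a slow seeded sinusoidal drift to each
#' angle trace so corpora are not strictly periodic.
#'
#' @param stride_frequency Stride rate in Hz (> 0).
#' @param hip_amp,knee_amp,arm_amp,elbow_amp Angle amplitudes (deg), in
#'   (0, 150).
#' @param speed Forward walking speed (cm/s).
#' @param bob_amp,sway_amp Vertical/lateral pelvis oscillation (cm).
#' @param phase Stride phase offset (radians).
#' @param perturb_deg Amplitude of slow angle drift (deg); 0 = strictly
#'   periodic.
#' @param seed Integer seed controlling the drift terms.
#' @return A `gait_params` list.
#' @export
gait_params <- function(stride_frequency = 1.0, hip_amp = 28, knee_amp = 45,
                        arm_amp = 25, elbow_amp = 20, speed = 90,
                        bob_amp = 2.5, sway_amp = 1.5, phase = 0,
                        perturb_deg = 0, seed = 1) {
  amps <- c(hip_amp, knee_amp, arm_amp, elbow_amp)
  if (any(amps < 0 | amps > 150)) stop("angle amplitudes must lie in [0, 150] degrees")
  if (stride_frequency <= 0) stop("stride_frequency must be > 0")
  structure(list(stride_frequency = stride_frequency, hip_amp = hip_amp,
                 knee_amp = knee_amp, arm_amp = arm_amp, elbow_amp = elbow_amp,
                 speed = speed, bob_amp = bob_amp, sway_amp = sway_amp,
                 phase = phase, perturb_deg = perturb_deg, seed = seed),
            class = "gait_params")
}

#' Generate a synthetic walking sequence
#'
#' Forward kinematics over the 21-joint full-body tree driven by sinusoidal
#' hip/knee/shoulder/elbow angle trajectories; all limb rotations are exact,
#' so bone lengths are constant across frames. The commanded angle traces are
#' attached as `attr(, "angles")` (degrees) for parameter-recovery tests.
#'
#' @param skeleton Target [skeleton()]; its joint names must be drawn from
#'   the [skeleton_full21()] vocabulary (subsets are generated on the full
#'   body, then reduced with [subset_joints()]).
#' @param M Number of frames (>= 2).
#' @param fps Sampling rate in Hz.
#' @param params A [gait_params()].
#' @return A [motion_sequence()].
#' @export
generate_motion <- function(skeleton, M, fps = 60, params = gait_params()) {
  if (M < 2) stop("M must be at least 2")
  full <- skeleton_full21()
  if (!all(skeleton$joint_names %in% full$joint_names))
    stop("skeleton joints must be drawn from the 21-joint generator vocabulary")
  p <- params
  t <- (seq_len(M) - 1) / fps
  phi <- 2 * pi * p$stride_frequency * t + p$phase
  drift <- function(which) {
    if (p$perturb_deg <= 0) return(0)
    with_seed(p$seed * 13L + which, {
      f2 <- stats::runif(1, 0.05, 0.25)
      ps <- stats::runif(1, 0, 2 * pi)
      p$perturb_deg * sin(2 * pi * f2 * t + ps)
    })
  }
  d2r <- pi / 180
  hip_l  <- p$hip_amp * sin(phi) + drift(1L)
  hip_r  <- p$hip_amp * sin(phi + pi) + drift(2L)
  knee_l <- p$knee_amp * (0.5 + 0.5 * sin(phi + 0.4 * pi)) + drift(3L)
  knee_r <- p$knee_amp * (0.5 + 0.5 * sin(phi + pi + 0.4 * pi)) + drift(4L)
  knee_l <- pmax(knee_l, 0); knee_r <- pmax(knee_r, 0)
  arm_l  <- p$arm_amp * sin(phi + pi) + drift(5L)
  arm_r  <- p$arm_amp * sin(phi) + drift(6L)
  elb_l  <- pmax(p$elbow_amp * (0.5 + 0.5 * sin(phi + pi + 0.3 * pi)) + drift(7L), 0)
  elb_r  <- pmax(p$elbow_amp * (0.5 + 0.5 * sin(phi + 0.3 * pi)) + drift(8L), 0)

  bl <- full$bone_lengths
  names(bl) <- full$joint_names
  leg_len <- bl[["knee_l"]] + bl[["ankle_l"]]
  # treadmill-style gait: the pelvis oscillates about the origin instead of
  # translating, so its floor projection stays near the origin (the phantom
  # joint convention); `speed` sets the fore-aft excursion of the pelvis.
  pelvis <- cbind(p$sway_amp * sin(phi),
                  leg_len + 6 + p$bob_amp * cos(2 * phi),
                  0.04 * p$speed * sin(2 * phi + 0.5))
  sagdir <- function(theta_deg) {  # unit vector: "down" rotated forward by theta
    th <- theta_deg * d2r
    cbind(0, -cos(th), sin(th))
  }
  pos <- array(0, dim = c(M, 21, 3))
  ji <- function(nm) match(nm, full$joint_names)
  set_j <- function(nm, xyz) pos[, ji(nm), ] <<- xyz
  set_j("pelvis", pelvis)
  lat <- function(sgn, len) cbind(sgn * len, 0 * phi, 0 * phi)
  set_j("hip_l", pelvis + lat(-1, bl[["hip_l"]]))
  set_j("hip_r", pelvis + lat(+1, bl[["hip_r"]]))
  foot0 <- c(0, -0.3, sqrt(1 - 0.3^2))  # foot direction in the shank frame
  leg <- function(side, hip_deg, knee_deg) {
    hipnm <- paste0("hip_", side)
    knee <- pos[, ji(hipnm), ] + bl[[paste0("knee_", side)]] * sagdir(hip_deg)
    shank_deg <- hip_deg - knee_deg
    ankle <- knee + bl[[paste0("ankle_", side)]] * sagdir(shank_deg)
    th <- shank_deg * d2r  # same x-axis rotation convention as sagdir()
    footdir <- cbind(0,
                     foot0[2] * cos(th) + foot0[3] * sin(th),
                     foot0[3] * cos(th) - foot0[2] * sin(th))
    toe <- ankle + bl[[paste0("toe_", side)]] * footdir
    set_j(paste0("knee_", side), knee)
    set_j(paste0("ankle_", side), ankle)
    set_j(paste0("toe_", side), toe)
  }
  leg("l", hip_l, knee_l)
  leg("r", hip_r, knee_r)
  up <- function(parent, nm) pos[, ji(parent), ] + lat(0, 0) + cbind(0 * phi, bl[[nm]] + 0 * phi, 0 * phi)
  set_j("spine", up("pelvis", "spine"))
  set_j("chest", up("spine", "chest"))
  set_j("neck",  up("chest", "neck"))
  set_j("head",  up("neck", "head"))
  set_j("shoulder_l", pos[, ji("chest"), ] + lat(-1, bl[["shoulder_l"]]))
  set_j("shoulder_r", pos[, ji("chest"), ] + lat(+1, bl[["shoulder_r"]]))
  arm <- function(side, arm_deg, elb_deg) {
    sh <- pos[, ji(paste0("shoulder_", side)), ]
    elbow <- sh + bl[[paste0("elbow_", side)]] * sagdir(arm_deg)
    fore <- sagdir(arm_deg + elb_deg)
    wrist <- elbow + bl[[paste0("wrist_", side)]] * fore
    hand <- wrist + bl[[paste0("hand_", side)]] * fore
    set_j(paste0("elbow_", side), elbow)
    set_j(paste0("wrist_", side), wrist)
    set_j(paste0("hand_", side), hand)
  }
  arm("l", arm_l, elb_l)
  arm("r", arm_r, elb_r)

  out <- motion_sequence(full, pos, fps = fps)
  if (!identical(skeleton$joint_names, full$joint_names))
    out <- subset_joints(out, skeleton$joint_names)
  attr(out, "angles") <- list(hip_flex_l = hip_l, hip_flex_r = hip_r,
                              knee_flex_l = knee_l, knee_flex_r = knee_r)
  out
}

#' Generate a corpus of synthetic clips
#'
#' Draws [gait_params()] from seeded realistic ranges (stride 0.7-1.2 Hz,
#' hip amplitude 18-35 deg, knee 30-60 deg, speed 50-130 cm/s, random phase,
#' slow angle drift up to 3 deg) and generates one clip per draw.
#'
#' @param skeleton Target [skeleton()].
#' @param n_clips Number of clips (0 gives an empty list).
#' @param frames_per_clip Frames per clip (default 240, i.e. four seconds at
#'   60 fps).
#' @param fps Sampling rate (Hz).
#' @param seed Integer seed.
#' @return A list of [motion_sequence()] objects.
#' @export
generate_corpus <- function(skeleton, n_clips, frames_per_clip = 240,
                            fps = 60, seed = 1) {
  if (n_clips < 0) stop("n_clips must be >= 0")
  if (n_clips == 0) return(list())
  draws <- with_seed(seed, {
    lapply(seq_len(n_clips), function(i)
      gait_params(stride_frequency = stats::runif(1, 0.7, 1.2),
                  hip_amp = stats::runif(1, 18, 35),
                  knee_amp = stats::runif(1, 30, 60),
                  arm_amp = stats::runif(1, 10, 40),
                  elbow_amp = stats::runif(1, 10, 35),
                  speed = stats::runif(1, 50, 130),
                  bob_amp = stats::runif(1, 1, 4),
                  sway_amp = stats::runif(1, 0.5, 3),
                  phase = stats::runif(1, 0, 2 * pi),
                  perturb_deg = stats::runif(1, 0, 3),
                  seed = seed * 1000L + i))
  })
  lapply(draws, function(p) generate_motion(skeleton, frames_per_clip, fps, p))
}

#' Corrupt a sequence with additive white Gaussian noise
#'
#' `sigma_cm` is, by default, the RMS 3-D displacement per joint, i.e. each
#' coordinate receives independent zero-mean noise with standard deviation
#' `sigma_cm / sqrt(3)`. Set `per_coordinate = TRUE` to interpret `sigma_cm`
#' as the per-coordinate standard deviation instead. Only observed (mask
#' TRUE) coordinates are perturbed.
#'
#' @param seq A [motion_sequence()].
#' @param sigma_cm Noise level (cm), >= 0.
#' @param seed Integer seed.
#' @param per_coordinate Interpret `sigma_cm` per coordinate.
#' @return A corrupted [motion_sequence()].
#' @export
corrupt_awgn <- function(seq, sigma_cm, seed = 1, per_coordinate = FALSE) {
  if (sigma_cm < 0) stop("sigma_cm must be >= 0")
  if (sigma_cm == 0) return(seq)
  sd <- if (per_coordinate) sigma_cm else sigma_cm / sqrt(3)
  d <- dim(seq$positions)
  noise <- with_seed(seed, array(stats::rnorm(prod(d), sd = sd), dim = d))
  obs <- array(seq$mask, dim = d)
  out <- seq
  out$positions <- seq$positions + noise * obs
  out
}

#' Corrupt a sequence with random joint-frame drop-out
#'
#' Each joint-frame (all three coordinates together) is removed independently
#' with probability `rate`; removed coordinates are set to the fill value 0
#' and the mask records them as unobserved.
#'
#' @param seq A [motion_sequence()].
#' @param rate Drop-out probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A [motion_sequence()] with updated mask.
#' @export
corrupt_dropout <- function(seq, rate, seed = 1) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (rate == 0) return(seq)
  d <- dim(seq$positions)
  drop <- with_seed(seed, matrix(stats::runif(d[1] * d[2]) < rate, d[1], d[2]))
  out <- seq
  out$mask <- seq$mask & !drop
  out$positions[array(!out$mask, dim = d)] <- 0
  out
}

#' Specification of a depth-sensor-like corruption
#'
#' Bundles the parameters of [corrupt_dmocap_like()]: small per-coordinate
#' jitter, contiguous occlusion bursts during which a joint is tracked at a
#' constant positional bias (producing a velocity spike when the joint
#' re-emerges), and sparse large outliers. Defaults emulate consumer depth
#' sensors: ~1 cm jitter, occasional half-second occlusions with ~15 cm bias,
#' 1% outliers of ~50 cm.
#'
#' @param jitter_sd Per-coordinate jitter standard deviation (cm).
#' @param burst_rate Per-joint-per-frame probability that an occlusion burst
#'   starts.
#' @param burst_length Integer range (frames) of burst durations.
#' @param burst_bias Magnitude (cm) of the constant positional bias during a
#'   burst.
#' @param outlier_rate Per-joint-frame probability of a spike outlier.
#' @param outlier_magnitude Spike magnitude (cm); must dominate the jitter so
#'   outliers exceed three robust standard deviations of a local window.
#' @param seed Integer seed.
#' @return A `corruption_spec` list.
#' @export
corruption_spec <- function(jitter_sd = 1, burst_rate = 0.002,
                            burst_length = c(10, 30), burst_bias = 15,
                            outlier_rate = 0.01, outlier_magnitude = 50,
                            seed = 1) {
  if (outlier_rate > 0 && outlier_magnitude < 10 * max(jitter_sd, 0.1))
    stop("outlier_magnitude must dominate jitter_sd for outliers to be detectable")
  structure(list(mode = "dmocap_like", jitter_sd = jitter_sd,
                 burst_rate = burst_rate, burst_length = burst_length,
                 burst_bias = burst_bias, outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude, seed = seed),
            class = "corruption_spec")
}

#' Corrupt a sequence with depth-sensor-like artifacts
#'
#' Applies jitter, occlusion bursts and outliers per [corruption_spec()].
#' Burst locations are attached as `attr(, "bursts")` (data frame with
#' `joint`, `start`, `end`) and outlier locations as `attr(, "outliers")`
#' for test assertions.
#'
#' @param seq A [motion_sequence()].
#' @param spec A [corruption_spec()].
#' @return A corrupted [motion_sequence()].
#' @export
corrupt_dmocap_like <- function(seq, spec) {
  stopifnot(inherits(spec, "corruption_spec"))
  d <- dim(seq$positions)
  out <- seq
  bursts <- list()
  outliers <- list()
  with_seed(spec$seed, {
    if (spec$jitter_sd > 0)
      out$positions <- out$positions +
        array(stats::rnorm(prod(d), sd = spec$jitter_sd), dim = d)
    if (spec$burst_rate > 0 && spec$burst_bias > 0) {
      for (j in seq_len(d[2])) {
        k <- 1L
        while (k <= d[1]) {
          if (stats::runif(1) < spec$burst_rate) {
            len <- sample(spec$burst_length[1]:spec$burst_length[2], 1)
            end <- min(k + len - 1L, d[1])
            dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
            out$positions[k:end, j, ] <-
              out$positions[k:end, j, , drop = FALSE] +
              rep(spec$burst_bias * dir, each = end - k + 1L)
            bursts[[length(bursts) + 1L]] <- data.frame(joint = j, start = k, end = end)
            k <- end + 1L
          } else k <- k + 1L
        }
      }
    }
    if (spec$outlier_rate > 0 && spec$outlier_magnitude > 0) {
      hit <- which(matrix(stats::runif(d[1] * d[2]) < spec$outlier_rate, d[1], d[2]),
                   arr.ind = TRUE)
      if (nrow(hit) > 0) {
        for (i in seq_len(nrow(hit))) {
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          out$positions[hit[i, 1], hit[i, 2], ] <-
            out$positions[hit[i, 1], hit[i, 2], ] + spec$outlier_magnitude * dir
        }
        outliers <- list(data.frame(frame = hit[, 1], joint = hit[, 2]))
      }
    }
  })
  # keep masked coordinates at their fill value
  out$positions[array(!out$mask, dim = d)] <- 0
  attr(out, "bursts") <- if (length(bursts)) do.call(rbind, bursts) else
    data.frame(joint = integer(), start = integer(), end = integer())
  attr(out, "outliers") <- if (length(outliers)) outliers[[1]] else
    data.frame(frame = integer(), joint = integer())
  out
}
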