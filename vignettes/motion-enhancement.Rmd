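---
title: "Enhancing depth-sensor motion capture: the model behind motionmend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing depth-sensor motion capture: the model behind motionmend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Skeletal joint trajectories estimated from consumer depth sensors ("D-Mocap")
are cheap to record but noisy: joints jitter, disappear behind the body and
re-emerge with a velocity spike, and occasional gross outliers appear.
Marker-based optical motion capture ("Mocap") is the clinical gold standard
but expensive and lab-bound. `motionmend` implements a pipeline that upgrades
depth-sensor trajectories toward Mocap quality by combining two complementary
models:

* a **per-joint Tobit Kalman filter (TKF)** that captures the *kinematics* of
  each joint — a constant-velocity state-space model whose measurement update
  accounts for censoring: when a measurement falls outside adaptive limits it
  is treated as clipped at the limit rather than trusted;
* a **convolutional motion manifold** — a single-layer temporal convolutional
  autoencoder trained on clean motion, whose latent space spans valid human
  motion and has no coordinates for sensor noise.

The two are fused by **latent-space optimization**: the decoder is frozen and
the latent code of a corrupted sequence is adjusted so the decoded output
approaches the TKF-filtered trajectory. The result is kinematically faithful
(it chased the filter target) yet guaranteed to lie on the motion manifold
(it is a decoder output by construction).

Two pipelines cover the two failure modes:

* **TKF-assisted** (parallel; for noisy but complete data): filter the input,
  then optimize the latent code toward the filtered target.
* **TKF-refined** (serial; for missing data): reconstruct through the
  manifold first — the manifold fills drop-out voids naturally — then filter
  the reconstruction.

## The autoencoder

A sequence of `M` frames and `N` joints is flattened to an `M x 3N` matrix,
mean-centered, and scaled. The encoder applies `F` temporal filters of width
25 frames (stride 1, zero same-padding), adds a per-filter bias, max-pools
adjacent frame pairs, and applies ReLU, giving a non-negative latent matrix
of size `F x ceil(M/2)`. The decoder inverts each step: pooled values are
replicated into both source frames, the bias is subtracted, and the result is
convolved with the weight tensor reflected along the frame axis and
transposed in the other two axes — exactly the adjoint of the encoder
convolution, which is how the gradient propagation stays simple and exact.

Training minimizes the squared reconstruction error plus an L1 penalty on
the parameters (weight `alpha`, default 0.01), with Adam (learning rate
0.001, moments 0.9/0.999) and dropout (rate 0.2) on the encoder input —
dropout doubles as denoising training and is why the manifold handles
drop-out voids well. Training is bit-deterministic given the seed.

**Normalization.** Dimensions are mean-centered and divided by one *pooled*
standard deviation rather than per-dimension scales. Sensor noise is
isotropic in centimetres; per-dimension scaling would blow noise up by an
order of magnitude in low-variance channels (a near-constant foot
coordinate, the phantom joint's height) and the reconstruction of corrupted
data then comes out worse than the corrupted input. With one pooled scale the
noise floor is uniform across channels and manifold projection removes it.

**The phantom joint.** Before training or enhancement, a joint is appended at
the floor projection of the hip center, `(x_hip, 0, z_hip)`. It anchors the
skeleton's height above the floor while the training motion itself is
in-place, so the network learns local body motion, not translation.

## The Tobit Kalman filter

Each joint is filtered independently with a 6-dimensional state (position and
velocity per axis) under a constant-velocity transition. Defaults, all
exposed in `tkf_config()`:

* `sigma_a = 1000` cm/s² — process-noise acceleration intensity, the order of
  peak limb accelerations in brisk human motion;
* `sigma_r = 3` cm — measurement noise sd; in simulation studies pass the
  known injected noise level (`sigma / sqrt(3)` per coordinate);
* `window_frames = 60` — the velocity window for the adaptive limits (50–80
  frames spans a complete action at 60 fps).

Censoring limits per axis are `p_prev ± |v_max| * dt`, where `p_prev` is the
previous filtered position and `|v_max|` the largest absolute
finite-difference velocity of the *measured* trajectory over the window
centered at the previous frame. Two numerical details matter:

* the velocity sample of the transition being tested is excluded from the
  window, otherwise a spike raises its own limit and censoring can never
  bind at an occlusion onset;
* with `causal = TRUE` the window uses only past frames. This is the setting
  under which censoring demonstrably beats the plain Kalman filter on
  occlusion bursts: at the onset the spike has not yet entered the window
  (the limit clamps it), while by re-emergence it has (recovery is fast).

The update computes per-axis censoring probabilities as Gaussian tail masses
of the predicted measurement distribution. The expected measurement combines
the truncated-normal mean of the uncensored region with point masses at the
limits, and the gain uses `R_XY = P H' D`, `R_YY = D H P H' D + R` with
`D = diag(p_uc)`. When nothing censors (`p_uc = 1`) this is *exactly* the
linear Kalman filter — the property the test suite pins against an
independently written KF — and the gain vanishes smoothly as censoring
saturates. Masked (dropped-out) measurements are treated as fully censored:
prediction only.

## Latent-space optimization and early stopping

`latent_optimize()` initializes the latent code from the corrupted input,
freezes the decoder, and runs projected Adam (latent kept non-negative) on
the squared Cartesian distance to the target, returning the best iterate so
the final cost never exceeds the initial one.

The iteration count (default 25, learning rate 0.01) is a deliberate
bias-variance choice, not a convergence budget. The filter target is
kinematically sound but not noise-free: it carries the causal filter's lag
bias, which — unlike jitter — *is* representable on the manifold. Running the
optimization to convergence therefore transfers that bias onto the output,
and the assisted result ends up worse than the plain reconstruction. With
moderate iteration counts the optimization first removes the reconstruction's
noise leakage (the component aligned with the kinematically correct target)
and stops before absorbing the target's own bias; measured error against
ground truth has its minimum at roughly 10–25 iterations at both calibrated
noise levels. For the same reason the *target* filters in `run_experiment()`
use a lightly smoothed setting (`sigma_a = 3000`): residual jitter in the
target is discarded by the manifold, whereas the lag bias of a heavily
smoothed target would be kept.

The same machinery drives `bone_constrained_fit()`, which penalizes the
squared deviation of each decoded segment length from the skeleton's known
bone lengths (the phantom's floor link, whose length is not anatomically
constant, is excluded) — used as structure matching before enhancing data
captured with a differently proportioned skeleton.

## Preprocessing

Real depth-sensor data passes through three cleaning stages before
enhancement. The Hampel filter slides a 7-sample window per scalar channel
and replaces a sample by the window median when it deviates by more than 3
robust standard deviations (`1.4826 * MAD`); windows truncate at the series
edges, and when the window MAD is zero any deviation from the median is
replaced. Rigid registration estimates one global rotation/translation by
SVD of the pooled cross-covariance (all joints and frames contribute to a
single centroid pair), with the reflection corrected so `det(R) = +1` —
skeletons must never be mirrored. Per-joint bias removal subtracts the
per-joint mean offset between the registered data and the reference, which
absorbs systematic differences in how two skeleton conventions define joint
centers.

## The synthetic generator: what it does and does not emulate

`generate_motion()` drives a 21-joint skeleton by forward kinematics from
sinusoidal hip/knee/shoulder/elbow angle trajectories, with vertical bob,
lateral sway, optional slow angle drift, and exact rotations — segment
lengths are constant to machine precision, which is what makes bone-length
assertions meaningful. The gait is treadmill-style: the pelvis oscillates
about the origin instead of translating, so the phantom joint stays near the
origin, consistent with the floor-anchored, translation-free convention the
manifold expects. `generate_corpus()` draws parameters from realistic ranges
(stride 0.7–1.2 Hz, hip amplitude 18–35°, knee 30–60°, random phase, up to
3° slow drift).

Corruption operators emulate the studied artifacts: `corrupt_awgn()` adds
white noise whose `sigma` is, by convention, the RMS 3-D displacement per
joint (per-coordinate sd `sigma/sqrt(3)`) — this convention makes the
corrupted-versus-clean mean joint RMSE numerically equal to `sigma`;
`corrupt_dropout()` removes joint-frames at a given rate (fill value 0, mask
carried separately); `corrupt_dmocap_like()` adds jitter, biased occlusion
bursts and sparse outliers, logging their locations for tests.

What passing tests on this corpus show: the algebra and the relative
orderings of the methods under controlled corruption. What they do not show:
performance on real depth-sensor data, whose noise is neither white nor
stationary, whose skeleton conventions differ from the reference, and whose
motion is far richer than parametric gait. The synthetic manifold is also
easier to learn than a real motion corpus, so absolute error levels here are
optimistic; in particular the serial (refined) pipeline contributes little
on this corpus because the denoising-trained reconstruction is already
smooth.

## Problem sizes and numerical choices

The packaged benchmark (`run_experiment()`, also what `scripts/acceptance.R`
runs) trains a 64-filter model on 200 clips of 240 frames for 60 epochs and
evaluates 10 held-out clips — about seven minutes on one CPU core; the test
suite trains smaller models (32–64 filters, 40–120 clips). The full-scale
architecture of 256 filters is exercised for its shape contracts and remains
available through `train_autoencoder()`.

Other numerical choices: odd clip lengths pool to `ceil(M/2)` and the final
replica is truncated on decode; max-pool ties take the earlier frame;
`R_YY` is regularized (with a warning) if numerically singular; velocity at
the first frame duplicates the second; a joint with no observed frames
yields fill values and a warning. Known limitations: enhancement is offline
by construction (the latent code covers the whole clip); the filter is
causal but the adaptive window is centered unless `causal = TRUE`; no
heterogeneous-skeleton retargeting — `subset_joints()` plus hip-height
scaling and structure matching is the supported route.
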