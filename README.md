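# motionmend

Enhancement of skeletal joint-trajectory data from low-cost depth sensors
("D-Mocap"). Depth-sensor skeletons are attractive for clinical gait
assessment and rehabilitation because they are markerless and cheap, but they
jitter, lose joints to self-occlusion, and produce gross outliers.
`motionmend` upgrades such trajectories toward optical-Mocap quality by
combining two complementary models and fusing them in a learned latent
space.

## The method

**Tobit Kalman filter (TKF).** Each joint is tracked independently with a
constant-velocity state-space model,

    x_k = F x_{k-1} + w_k,    x = (p_x, p_y, p_z, v_x, v_y, v_z)

whose measurement update follows a Tobit (censored-measurement) model: per
axis, a measurement outside the limits `T = p_prev ± |v_max| Δt` is treated
as clipped at the limit, with the limits adapted from the joint's windowed
velocity. Censoring probabilities are Gaussian tail masses of the predicted
measurement; with nothing censored the update reduces exactly to the linear
Kalman filter.

**Convolutional motion manifold.** A single-layer temporal convolutional
autoencoder (filters of width 25 frames, max-pool by 2, ReLU) is trained on
clean motion, so its latent space spans valid human motion and has no
coordinates for sensor noise:

    H = ReLU(S(X * W + b)),      X̂ = (S⁻¹(H) − b) * W̃

**Latent-space optimization.** With the decoder frozen, the latent code of a
corrupted sequence is adjusted by Adam to minimize
`Σ_j Σ_k ‖X̂(H)_{k,j} − r_{k,j}‖²` against a target `r`. Two pipelines:

* `enhance_tkf_assisted()` — the TKF output of the noisy input is the
  target (parallel paradigm, for noisy data);
* `enhance_tkf_refined()` — manifold reconstruction fills drop-out voids
  first, the TKF then refines it (serial paradigm, for missing data).

The package also ships the supporting pipeline: a forward-kinematic gait
generator and corruption operators (white noise, drop-out, occlusion bursts,
outliers), preprocessing (Hampel outlier removal, SVD rigid registration,
per-joint bias removal, hip-height scaling, bone-constrained structure
matching), and the evaluation metrics used in this field (per-joint RMSE,
bone-length error, six lower-body gait angles, body-quadrant summaries).

## Worked example

Train a small manifold on synthetic gait, corrupt a held-out clip with heavy
noise, and compare the enhancement modes:

```r
library(motionmend)

skel   <- skeleton_lower6()                      # hips, knees, ankles
corpus <- lapply(generate_corpus(skel, 40, 240, 60, seed = 1),
                 add_phantom_joint)
model  <- train_autoencoder(corpus, filters = 32,
                            hyper = train_hyper(epochs = 80, seed = 2))

ref   <- add_phantom_joint(generate_motion(skel, 240, 60, gait_params(seed = 99)))
noisy <- corrupt_awgn(ref, 10, seed = 3)         # 10 cm RMS displacement
cfg   <- tkf_config(dt = 1/60, sigma_a = 3000, sigma_r = 10 / sqrt(3))

enhanced <- enhance_tkf_assisted(noisy, model, cfg)

for (s in list(corrupted = noisy, tkf_only = tkf_filter(noisy, cfg)$seq,
               ae_only = reconstruct(noisy, model), tkf_assisted = enhanced))
  cat(sprintf("rmse %5.2f cm   bone error %4.2f cm   angle error %5.2f deg\n",
              joint_rmse(s, ref)$mean, bone_length_error(s, ref)$mean,
              angle_error(s, ref)$mean))
```

```
rmse 10.06 cm   bone error 6.74 cm   angle error 12.53 deg   # corrupted
rmse  6.13 cm   bone error 4.02 cm   angle error  7.34 deg   # tkf_only
rmse  5.35 cm   bone error 3.46 cm   angle error  6.05 deg   # ae_only
rmse  4.19 cm   bone error 2.77 cm   angle error  4.65 deg   # tkf_assisted
```

Either filter or manifold alone roughly halves the error; optimizing the
manifold's latent code toward the filter target beats both, and the
bone-length and joint-angle errors improve alongside the positional one.
`run_experiment()` chains the whole benchmark (generate, train, corrupt,
enhance with every mode, evaluate) into one report, and
`inst/cli/motionmend.R` exposes each stage as a shell subcommand
(`synth`, `corrupt`, `preprocess`, `train`, `enhance`, `evaluate`,
`experiment`).

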