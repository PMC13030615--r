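# ptzmocap

Markerless 3D motion capture of an athlete in a large outdoor volume from
several **pan–tilt–zoom (PTZ) cameras**, in R. Because the cameras pan and
zoom to follow the athlete, their projection matrices change every frame; the
package implements the full chain needed to deal with that, plus a synthetic
scene generator with exact ground truth so every stage can be validated.

## The scientific problem

Fixed-camera motion capture does not scale to a ski slope: to keep the
athlete large enough in the image over a 100 m corridor, cameras must pan
and zoom, which invalidates any one-off calibration. The pipeline here
solves the resulting chain of problems:

1. **Sub-frame synchronization.** Consumer cameras cannot be genlocked. At
   speed *v* and frame rate *f* a half-frame offset displaces the athlete by
   *v* / (2 *f*) — 0.30 m at 15 m/s and 25 Hz — so offsets must be recovered
   to a fraction of a frame. A cube dropped in view of all cameras gives a
   common event: quadratics are fitted to the free-fall and bounce windows
   of the vertical pixel track and the impact is their intersection.
2. **Reference-point association.** Surveyed calibration cubes carry
   fiducial markers. Detections are boxes; identities come separately and
   drop out often. Identities are matched by marker-centroid containment and
   recovered over time by projecting identified points along the camera's
   global image shift (median flow), with an adaptive acceptance radius and
   a forward + backward pass.
3. **Frame-wise DLT calibration.** For every camera-frame, the 15 identified
   reference points nearest the athlete are used to estimate the 3×4
   projection matrix P from the homogeneous system
   u(p₃·X) − p₁·X = 0, v(p₃·X) − p₂·X = 0 (two rows per correspondence,
   SVD null-space solution with isotropic normalization), followed by
   iterative outlier rejection (drop the worst point while the mean
   reprojection error improves ≥ 5%, floor of 6 points).
4. **Reconstruction.** Each keypoint is triangulated by SVD from all
   calibrated views; *every* camera subset of size ≥ 2 (11 subsets for 4
   cameras) is evaluated by mean reprojection error and the best one is used
   for the whole trial — a biased camera excludes itself. Trajectories are
   smoothed with a zero-phase 4th-order Butterworth low-pass (10 Hz at
   25 Hz).
5. **Evaluation.** True anatomical segment lengths are constant, so the SD
   of reconstructed segment lengths across frames measures 3D consistency
   without manual ground truth. Standard 2D metrics (PCK, OKS-based mAP,
   MPJPE), run-level t confidence intervals and paired Wilcoxon tests are
   included.

## Worked example

Simulate a 4-camera trial with fractional frame offsets, synchronize,
calibrate frame-wise, reconstruct and evaluate:

```r
library(ptzmocap)

cfg <- scene_config(n_cameras = 4, n_refpoints = 120, n_frames = 40,
                    frame_offsets = c(0, 0.3, -0.45, 0.2), rng_seed = 2)
bundle <- generate_scene(cfg)                  # detections + ground truth
tracks <- render_drop_event(cfg, noise_sd = 0) # the filmed cube drop

res <- run_pipeline(bundle, drop_tracks = tracks)

round(res$sync$offsets, 4)
#> cam01 cam02 cam03 cam04
#>  0.00  0.30 -0.45  0.20

res$segments
#>      segment n_frames    mean_m        sd_cm
#>  upper_arm_L       40 0.2799927 0.0003049524
#>  upper_arm_R       40 0.2799937 0.0007085229
#>    forearm_L       40 0.2499879 0.0007070326
#>    forearm_R       40 0.2499899 0.0009059530
#>      thigh_L       40 0.4499876 0.0005490548
#>      thigh_R       40 0.4499888 0.0006239571
#>      shank_L       40 0.4299883 0.0006947956
#>      shank_R       40 0.4299920 0.0005266269
#> overall segment-length SD: 0.00 cm

head(res$poses, 4)
#>   frame     keypoint           x         y           z n_views
#> 1     1         head  0.29936586 0.1406069 1.517284680       3
#> 2     1   left_ankle -0.08478062 0.1254852 0.089474950       3
#> 3     1 left_big_toe  0.06656378 0.1967651 0.006385691       3
#> 4     1     left_ear  0.26528355 0.2019384 1.508462544       3
```

The noise-free trial reconstructs with micrometre-level segment-length
variation; under realistic annotation noise the segment SD becomes the
outcome measure of the 2×2 experiment below.

### Command line

Every stage also runs on versioned text files:

```sh
ptzmocap pipeline  --dir trial01 --seed 2       # simulate + all stages
ptzmocap sync      --dir trial01                # or stage by stage
ptzmocap calibrate --dir trial01
```

(`inst/cli/ptzmocap` is the launcher; `ptzmocap_cli()` is the R entry
point.) Outputs: `sync.json`, `refpoints.jsonl`, `calibration.json`,
`poses.csv`, `evaluation.json`, plus the resolved configuration in
`config_resolved.yaml`.

### Annotation-noise experiment

```r
ex <- annotation_experiment(n_seeds = 20)
summary(ex)     # mean overall segment-length SD (cm) per 2x2 cell
```

Reference points and skier keypoints each get "automatic" (more precise) or
"manual" (less precise) annotation noise; across seeds, automatic
annotation gives lower segment-length SD for both factors.

## Package layout

- `R/scene.R`, `R/skeleton.R`, `R/geometry.R` — synthetic scene, articulated
  skier, projective geometry.
- `R/sync.R` — drop-event fitting, offsets, stream resampling.
- `R/refpoints.R` — association and temporal identity recovery.
- `R/calibration.R` — DLT, outlier rejection, trial calibration.
- `R/reconstruction.R` — triangulation, subset selection, smoothing.
- `R/evaluation.R` — segment lengths, PCK / mAP / MPJPE, run statistics.
- `R/pipeline.R`, `R/experiment.R` — end-to-end runs and the 2×2 experiment.
- `R/io.R`, `R/cli.R` — versioned text formats and the CLI stages.

See the vignette (`vignettes/methods.Rmd`) for the method details and the
reasoning behind parameter defaults.
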