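---
title: "Methods: pose annotation and evaluation for cattle heads and ears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose annotation and evaluation for cattle heads and ears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cowpose)
```

## The problem

Head and ear orientation are established behavioral indicators of stress and
pain in cattle: stressed animals preferentially monitor threats with the left
eye (turning the head), and ear posture grades from forward (no pain) through
pulled back to hanging down (severe pain). Quantifying these signals from
farm imagery requires (a) ground-truth 3D orientation labels for 2D images,
(b) detection and pose-error metrics to evaluate automated pipelines, and
(c) the pixelwise feature-scoring machinery used by fine-grained pose
regressors. `cowpose` implements all three as a reusable, fully testable
toolkit, together with a synthetic-scene generator that closes the loop:
every numerical claim in the package is validated end-to-end on scenes with
known ground truth.

## Orientation model and conventions

A pose is the triple (yaw, pitch, roll) in degrees:

* **yaw** — rotation about the vertical axis (turning left/right),
* **pitch** — rotation about the side-to-side axis (nodding up/down),
* **roll** — rotation about the front-to-back (muzzle) axis (tilting).

The working frame is the image convention: x right, y down, z forward,
right-handed. Rotations compose as
\( R = R_y(\mathrm{yaw})\, R_x(\mathrm{pitch})\, R_z(\mathrm{roll}) \)
— intrinsic yaw-then-pitch-then-roll, the common head-pose convention. The
axis names are standard in this literature but the composition *order* is a
genuine design choice: sources describing such systems rarely state it, so
recovered angles from other tools may differ by a fixed convention change.
The order is fixed here, documented, and used consistently by the solver,
the generator and the metrics, which is what the toolkit's internal
consistency requires.

Canonical ranges are yaw, roll in [−180°, 180°) and pitch in [−90°, 90°].
At |pitch| = 90° (gimbal lock) only yaw − roll (or yaw + roll) is
observable; the canonical form sets roll = 0 and lets yaw absorb the free
angle. Decomposition validates orthonormality at 1e−6 — looser than the
1e−9 the package's own matrices satisfy — so rotations perturbed by
downstream numerics still decompose while corrupt inputs are rejected.

```{r}
angles_from_rotation(rotation_from_angles(30, -10, 5))
```

## Landmark schemes

Two fixed schemes are committed with the package:

* **Head (21 landmarks)** — mandible points, four points around each eye,
  three across the external nose, the two ear-root attachments, three along
  the mouth, and the jaw, mirroring the 21-landmark AFLW human-face layout.
  `aflw_mapping()` records the correspondence: 7 one-to-one rows (nose,
  mouth, chin/jaw) and 14 closest-analog rows. Two published landmark names
  collide ("Left Eye Right Lower Corner" appears twice); they are
  disambiguated here as "(medial)"/"(lateral)" to keep 21 unique labels.
* **Left ear (13 landmarks)** — apex to base over a curved patch. No
  standardized bovine ear landmarks exist, so the 13 points are spread in
  four rows below the apex along the pinna.

The original digitized 3D models behind such schemes are generally not
published, so the canonical coordinates here are **authored, stylized
fixtures**: the head is a bilaterally symmetric arrangement with unit head
length (muzzle toward −z, so the identity pose faces the camera) and
centroid origin; the ear is an elliptic-paraboloid patch of unit length.
Model units are dimensionless: the pose solver recovers scale jointly, so
units affect translation only, never angles. Both schemes are verifiably
non-coplanar (smallest/largest singular value ratio of the centred
coordinate matrix > 1e−3), which pose-from-correspondence requires. Users
with their own digitized models can substitute them via
`read_scheme_json()`.

Each landmark carries a committed outward unit normal used by the
generator's self-occlusion rule. Head normals point away from a pole behind
the head, a deliberate choice with a visible consequence: at the frontal
pose every landmark faces the camera, so a zero-noise frontal sample has all
21 landmarks visible, while profile views occlude the far side.

## The POSIT solver

`solve_posit()` implements the classic pose-from-orthography-and-scaling
iteration for ≥ 4 visible, non-coplanar 2D–3D correspondences:

1. assume scaled-orthographic projection (perspective correction factors
   \(\varepsilon_i = 0\));
2. solve the linear pose equations via the pseudoinverse of the centred
   model-point matrix;
3. orthonormalize the two recovered pose rows into a proper rotation
   (cross-product completion, then nearest rotation by polar decomposition,
   tie-broken to det +1);
4. update \(\varepsilon_i\) from the implied depths; repeat until
   \(\max_i |\Delta\varepsilon_i| <\) `tol` (default 1e−6, `max_iter` 50).

At the fixed point the recovered pose satisfies the exact perspective
equations, so noiseless correspondences are solved to numerical precision;
the test-suite verifies the solver against an independent
reprojection-minimizing search. Occluded landmarks are simply excluded:
the solver runs on the visible subset, which mirrors how an annotator can
only click visible points. Degenerate inputs raise typed errors
(`insufficient_landmarks`, `degenerate_geometry`, `non_convergence` when
\(|\varepsilon|\) exceeds 10).

Camera intrinsics are rarely recorded for field images, so the CLI defaults
to focal length = image width and principal point = image centre — a
documented stand-in, not a calibration.

```{r}
cam <- camera_model(800, c(640, 480))
sch <- head_scheme()
p2d <- project_points(sch$landmarks, rotation_from_angles(20, -10, 5),
                      c(0, 0, 10), cam)
corr <- tibble::tibble(label = sch$landmarks$label, x = p2d$x, y = p2d$y)
fit <- solve_posit(corr, sch, cam)
glance(fit)
tidy(fit)
```

## Synthetic scenes: what they emulate, and what they do not

`generate_sample()` projects a scheme at a known pose, adds seeded Gaussian
pixel noise, drops landmarks at random (environmental occlusion) and by the
normal rule (self-occlusion), and derives detection ground truth: the
axis-aligned box around visible landmarks padded 5% per side (a stand-in
for anatomical ROI definitions such as "including the lower jaw, excluding
the neck") and their convex hull as mask polygon. `generate_dataset()` draws
poses uniformly, defaults yaw ±90°, pitch ±60°, roll ±60° — the pose
distribution of real opportunistic handheld acquisition is unreported, so
these ranges are a configurable, one-time choice. Splits are assigned by a
seeded shuffle with `round(n·p)` records for validation and test and the
remainder in train, so 1000 samples give exactly 600/200/200 under the
60/20/20 default.

The default generator camera is 96 × 96 px with a 192 px focal length at
object depth 4 model units: the object then fills roughly 60% of the frame
and stays inside it across the default pose ranges.

`rasterize_sample()` renders a deterministic grayscale image: mask filled
mid-gray, one Gaussian blob (σ = 2 px) per visible landmark with a distinct
per-landmark peak intensity, black outside the padded box.

These scenes validate *geometry and bookkeeping*: projection, visibility,
solver inversion (the generator–solver loop closes to < 1e−3° at zero
noise), splits, file formats, metric arithmetic. They do **not** emulate
coat color, illumination, background clutter, motion blur, soft tissue
deformation, or annotator error beyond isotropic noise — so passing tests
here say nothing about detection robustness on real farm imagery; they say
the measuring instruments are correct.

## Evaluation metrics

* **Box IoU** uses half-open pixel rectangles \([x_0, x_1) \times [y_0,
  y_1)\), so results agree exactly with integer pixel enumeration; mask IoU
  (convex polygon clipping) is available alongside, but box IoU is the
  default detection criterion at threshold 0.5.
* **Matching** is greedy and one-to-one in descending score order: a
  prediction is a true positive iff its best-overlapping unmatched truth
  reaches the IoU threshold. Precision = TP/(TP+FP), recall = TP/(TP+FN).
  The canonical worked example — five objects, three detections, two correct
  — yields precision 66.7% (2/3) and recall 40% (2/5).
* **Average precision** is the all-points interpolated area under the
  precision envelope versus recall over pooled score-ranked detections.
  With one object and one prediction per image, thresholding only accepts or
  rejects the single prediction, the PR curve degenerates to a flat line,
  and AP reduces to precision at the threshold — which is why a single mAP
  number (not a curve) is the meaningful summary in that regime.
* **Pose MAE** wraps per-angle differences into (−180°, 180°] before taking
  magnitudes (unwrapped differences would corrupt MAE near ±180°). Two
  norms are implemented and labelled, because the field's printed formula
  and its benchmark convention differ: `"per-angle"` (default; the head-pose
  benchmark convention, mean of the three absolute angle errors) and
  `"l2"` (the printed vector-norm formula \( \frac{1}{N}\sum_n \|\tilde y_n -
  y_n\| \)). For a single pose error of (3°, 4°, 0°) they give 7/3 and 5
  respectively.

## Pixelwise scoring and the toy regressor

Three scoring functions assign importance \(\Phi(u)\) to each cell of an
h × w × c feature map:

| variant  | \(\Phi(u)\) | reading |
|----------|-------------|---------|
| uniform  | 1 | no spatial preference ("without fine-grained feature mapping") |
| variance | \(\sum_i (u_i - \mu)^2,\; \mu = \tfrac{1}{c}\sum_i u_i\) | prefer variable features |
| conv1x1  | \(\sigma(w \cdot u)\) | learnable 1 × 1 convolution + sigmoid |

Capsule-style aggregation is replaced by a documented simplification:
score-weighted top-k mean (k = 9 of 36 cells by default), ties broken by
row-major position, weights renormalized to sum to one. The output provably
lies in the convex hull of the selected features.

The toy regressor exists solely to exercise the three variants under
identical, deterministic conditions, the shape of a scoring-function
ablation. Features are 6 × 6 grids of 8-bin magnitude-weighted
gradient-orientation histograms of the synthetic raster; the regression
design concatenates the aggregated vector with the score-weighted per-cell
features; yaw/pitch/roll are fitted by closed-form ridge regression
(λ = 1 on standardized columns). The conv1x1 kernel is fitted jointly by
seeded BFGS (25 iterations) on the training MSE. The experiment conditions
are 1000 samples → 600 train / 200 test, yaw ±60°, pitch/roll ±30°
(narrower, as handheld acquisition rarely approaches gimbal), 1 px landmark
noise. Against a predict-the-training-mean baseline (per-angle MAE ≈ 20°
under these ranges) all three variants cut the error by well over half;
their MAEs are distinct, which is the report-structure contract
`compare_scoring()` emits. Nothing here should be read as reproducing any
full-scale deep pose regressor: that requires real images, pretrained
backbones and GPU training, all out of scope.

```{r, eval = FALSE}
ds <- generate_dataset(
  1000,
  pose_ranges = list(yaw = c(-60, 60), pitch = c(-30, 30), roll = c(-30, 30)),
  noise = noise_config(pixel_sigma = 1), seed = 42
)
compare_scoring(ds, seed = 42)
```

## Numerical choices and degenerate inputs

* Coplanarity guard: singular-value ratio 1e−3 on the centred visible
  model points, both at scheme construction and per solve.
* POSIT divergence guard: any \(|\varepsilon_i| > 10\) aborts with a typed
  error; convergence tolerance 1e−6 on \(\Delta\varepsilon\).
* Orthonormalization by SVD polar decomposition, det forced to +1.
* Gimbal tie-break: roll = 0; decomposition tolerance 1e−9 on
  \(|R_{2,3}| = 1\).
* Top-k ties: row-major order; zero score mass falls back to equal weights.
* Empty evaluation inputs return a flagged degenerate report (precision =
  recall = 0, mAP NA) rather than NaN arithmetic.
* Seeds: every stochastic step (poses, noise, dropout, splits, kernel
  initialization) flows from explicit integer seeds; identical seeds give
  byte-identical manifests and identical fits.

Problem sizes in the test-suite and the acceptance script (100-pose solver
sweeps, 1000-sample datasets, 25 BFGS iterations, 96 × 96 rasters) were
chosen as the smallest sizes at which the compared quantities are stable;
they are the package's own defaults, and all scale up by argument.

## Known limitations

* The committed scheme coordinates are stylized, not digitized anatomy;
  absolute angles from real annotations depend on the true model geometry
  and its frame, so cross-tool comparisons should expect a fixed offset.
* Classic POSIT requires non-coplanar models and one fully visible
  reference landmark set; it does not refine under lens distortion.
* The self-occlusion rule is per-landmark normal visibility, not true
  ray-casting against a mesh.
* VIA support is pinned to the 2.x project dialect, polygon and rect
  regions only; other shapes are rejected loudly rather than skipped.
* Multi-class and IoU-sweep mAP (e.g. COCO's @[.5:.95]) are out of scope;
  the evaluation targets the single-class, fixed-threshold regime.
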