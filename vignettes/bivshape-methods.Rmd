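---
title: "Methods: automated biventricular shape modeling in bivshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated biventricular shape modeling in bivshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(bivshape)
```

This vignette documents the models, conventions and numerical choices
behind the package. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The pipeline and its contracts

A cine CMR study is a set of image series, each a `n_frames x rows x cols`
intensity stack with plane geometry (origin, row/column direction cosines,
pixel spacings) in a right-handed LPS patient frame in millimetres, the
DICOM convention. Pixel indices are 0-based `(row, col)` pairs referring
to pixel centers; cardiac frame indices are 0-based as well, matching the
field's phase numbering. The image-to-patient map is affine:
`x = origin + row*rs*row_dir + col*cs*col_dir`.

The pipeline runs five stages in a fixed order — view classification,
short-axis slice selection, end-systolic phase selection, landmark
localization, myocardial segmentation — then converts stage outputs into
labeled 3D guide points, fits the biventricular template, and derives
measurements and atlas scores. Each stage's output can be replaced by an
override before the next stage runs; every override lands in a ledger that
reports per-landmark intervention rates.

Two conventions the pipeline fixes itself, because clinical acquisition
leaves them implicit:

* **ED is frame 0.** Acquisition is ECG-gated starting at end-diastole;
  the package takes the first cine frame as ED.
* **ES is the frame of minimal LV cavity volume**, estimated by the phase
  stage and decoded as the argmax of the slice-averaged phase curve, ties
  breaking toward the earlier frame.

## Supervision codecs

* *Phase curve*: a per-frame value `exp(-(t - t_ES)^2 / (2*4^2))`. The
  curve is **peak-normalized** (maximum exactly 1 at ES), not unit-sum:
  the supervision signal is meant to rise to 1 during systole.
* *Landmark heatmaps*: per landmark `exp(-||x - x_L||^2 / (2*12^2))` on
  the pixel grid, peak-normalized likewise. Decoding finds the global
  maximum and refines it to sub-pixel precision with a log-parabolic fit
  through the maximum and its axis neighbours — exact for Gaussian peaks,
  including peaks clipped by the image border, which keeps the round trip
  of an encoded fractional landmark below 0.25 px everywhere. Where the
  fit is undefined (border maxima, plateaus) the decoder falls back to the
  intensity-weighted centroid of the half-maximum region inside the peak's
  8-connected component, with weights taken above the threshold (the
  variant that is insensitive to boundary-pixel quantization). An all-zero
  map decodes as "absent" with confidence 0.
* *Class maps*: 2Ch LT segments LV cavity + LV myocardium; 2Ch RT and
  RVOT segment the RV pair; 3Ch, 4Ch and SAx segment all four structures.
  LVOT and "other" series are never segmented. Papillary muscles and
  trabeculae belong to the blood pool.
* *Landmark sets*: 3Ch gives mitral and aortic inserts; 4Ch mitral and
  tricuspid inserts plus the LV apex; RVOT pulmonary inserts; SAx the RV
  inserts.

Slice selection is a binary decision (optimal / non-optimal). Softmax
ties resolve to non-optimal — the conservative choice, since a wrongly
included slice perturbs the fit while a wrongly dropped one only loses a
little support.

## Stage networks

The stage networks are small, CPU-trainable and written directly on the
package's conv/pool/upsample kernels; their input/output contracts (not
their capacity) follow the pipeline design:

* view/slice: four 3x3 conv + max-pool blocks (8/16/32/32 channels) and a
  dense softmax head on 128 px inputs, standardized per image (mean 0,
  sd 1 — the zero-centered input contract without pretrained channel
  statistics);
* phase: a shared two-block conv encoder applied per frame (32 px frames,
  global average pooling) feeding a bidirectional tanh RNN (hidden 16)
  whose states — concatenated with the frame features through a direct
  skip path — drive a sigmoid head emitting one curve value per frame.
  Phase inputs are center-cropped to the central half of the frame
  (mid-ventricular short-axis frames are heart-centred, and the crop
  quadruples the blood pool's share of the input) and each frame has the
  cine's temporal mean frame subtracted, which cancels static anatomy and
  makes the contracting pool the dominant signal; inputs are zero-padded
  to 30 phases with a validity mask, and padded frames are excluded from
  both the loss and the decoding;
* landmark/segmentation: a 3-level U-net (8/16/32 encoder channels,
  48-channel bottleneck, skip connections), receptive field roughly 60 px
  at 128 px resolution — enough context to separate the two bright
  cavities and localize valve corners.

Losses follow the stage definitions: categorical cross-entropy for
view/slice, mean squared error for the phase curve (weighted `1 + 5*y`
toward the systolic peak), cross-entropy plus soft Dice for segmentation.
The landmark loss is mean squared error on the heatmaps **weighted**
`1 + 30*y` toward the Gaussian peaks: heatmap targets are sparse, and the
unweighted loss has a strong local optimum at the best-constant map into
which a sigmoid-output network readily collapses. The optimizer is plain
SGD with momentum 0.9, a global gradient-norm clip of 5, and a step decay
that halves the learning rate at one and two thirds of training; training
is exactly reproducible under the config seed. Defaults
(`train_config()`): learning rate 0.02 for the classifiers and 0.05 for
the dense-prediction stages, 16-40 epochs depending on the stage. These
are sized for the package's from-scratch networks; a reference protocol
built on large pretrained backbones would use far smaller rates (1e-5 to
1e-2) and more epochs, and all values remain configurable.

Small from-scratch networks on sparse targets occasionally settle into
the constant-output optimum regardless of the weighting — frequently in a
single output channel whose sigmoid saturates while its siblings train
fine (a dead unit). `train_stage()` counters this at two levels. During
landmark training, any heatmap channel whose map never rises above 0.2 in
an entire epoch has its head weights re-initialized (the shared encoder
and the healthy channels continue undisturbed). On top of that it applies
**seeded restarts with training-set quality gates**:
after training, the phase model must reach a training-set AAFD of 1.5
frames and the landmark model a training-set mean decode error of 5 px,
else the network is re-initialized (deterministically, `seed + 1000k`)
up to `max_restarts` times (default 3 for those two stages, 0 elsewhere);
collapsed heatmap attempts are abandoned early once the loss plateaus at
the constant-map value. The gates look only at training data — no
held-out information leaks into model selection. Landmark decoding at
inference additionally ignores a 4 px border margin, where convolution
padding artifacts can produce spurious maxima.

Augmentation supports random rotations, zooms, translations, mirroring,
brightness/contrast jitter, additive noise, crops, and cyclic time-rolls;
geometric transforms are applied identically to images and spatial labels
(masks nearest-neighbour, heatmaps bilinearly, points analytically), and a
time-roll shifts the ES label with the frames.

## Phantom: the synthetic study generator

The phantom emulates the *structure* of a clinical biventricular cine
study, not pathology-specific morphology: the pipeline's contracts are
under test, not anatomical realism.

Geometry (all lengths mm, defaults in parentheses): the LV cavity is a
truncated ellipsoid with in-plane semi-axis `a` (25) and apex-to-base
length 85, truncated at the basal plane at 35% of the long semi-axis; the
wall (8) is a concentric shell whose epicardial ellipsoid is static over
the cycle — contraction is absorbed by wall thickening, which matches the
small epicardial excursion of real hearts and keeps the cavity volume
analytic. The RV is a crescent of angular extent 3.2 rad and maximal
thickness 28 wrapped around the LV epicardium with a 5 mm free wall; its
horns are the RV inserts. Valve rings: the mitral ring is the LV
endocardial basal rim, the tricuspid ring the RV basal rim, and the aortic
and pulmonary rings are circles at the roots of bright aortic/pulmonary
trunks above the base. Bright atria and a dim elliptical torso cylinder
provide the basal and background context that makes slice selection and
view classification non-trivial.

The contraction curve scales the cavity's in-plane radii by a piecewise
raised cosine `s(t)` with `s(0) = 1` and minimum `s_min = sqrt(1 - EF)` at
the ES frame, so the target ejection fraction holds exactly by
construction and the volume curve has a unique minimum at ES. Cines are
periodic.

Default imaging: 128 px matrix at 1.5 mm in-plane spacing, an 8 mm
short-axis stack extending beyond both apex and base (so non-optimal
slices exist on both sides), one series per long-axis view, two axial
"other" series through the torso, 30 frames, additive Gaussian noise of
sd 4 on a 0-255 intensity scale (blood 185, myocardium 95, torso 55,
air 15). Ground truth includes view labels, slice flags, the ES frame,
per-frame landmark pixels (consistent with the 3D rings through each
plane's affine), label masks, analytic volumes (closed forms for the LV,
separable high-resolution quadrature for the RV crescent), and dense
triangulated true surfaces.

What the phantom does **not** emulate — and hence what passing tests do
not show about real data: MRI physics (no k-space artifacts, banding,
flow, coil shading), anatomical variability beyond its parameter ranges
(no disease-specific RV remodeling, no trabeculation, no arrhythmia or
LV/RV dyssynchrony), inter-observer label noise, and vendor metadata
diversity. Stage networks trained on phantoms are validated only as
implementations, not as clinically deployable models.

The study-condition population used by the tests and the acceptance run
draws LV radius 22-28 mm, wall 7-10 mm, RV thickness 24-32 mm, EF
0.4-0.6, ES frame 10-14, noise sd 3-6 — around 25% relative spread about
the defaults, the scale of normal adult variation.

## Contour extraction and guide points

Contours are traced on the (hole-filled) label masks as ordered sub-pixel
polylines — marching-squares isolines at level 0.5 via
`grDevices::contourLines`. The LV endocardium is the cavity boundary;
the epicardium the outer boundary of the union of all labeled structures;
the septum the part of the LV outer boundary adjacent (within 1.3 px,
i.e. 8-connectivity plus the half-pixel offset of sub-pixel boundaries)
to RV tissue; the RV endocardium the RV cavity boundary with that septal
interface removed. The septal contour is carried on the **LV side** of
the interface: the published figures show a single septal contour and do
not fix a side, and the LV-side choice matches the template's septal
sheet (below). Class sets are pairwise disjoint by construction.

Polylines are resampled to ~2 mm arc-length spacing before fitting — a
balance between the linear system's size and fidelity. Resampling splits
a polyline at gaps larger than 3 px and treats the runs independently;
interpolating across a gap (e.g. where the septal run was cut out of the
RV loop) would fabricate guide points on a chord through the cavity.
After lifting to patient coordinates, contour points above the valve base
plane (estimated from the MV/TV landmarks and the apex direction, with a
1 mm margin) are discarded: in long-axis views the traced region boundary
includes the basal cut line, which is not anatomical surface.

## Template and non-rigid fit

The template is generated programmatically from the phantom's mean
geometry at ED (`biv_template()`): three closed, outward-oriented
surfaces — LV endocardium, RV endocardium, epicardium — whose basal
openings are closed by valve-plane caps, plus free-standing aortic and
pulmonary ring loops and a named apex vertex. All fitted models share its
topology (~3.4k vertices). The septal surface is the RV-endocardium
region's inner sheet; septum guides match that septal band, RV-endo
guides the free-wall sheet, valve inserts their ring vertices, and caps
are never matched.

Fitting runs in two steps:

1. **Landmark registration**: closed-form orthogonal-Procrustes
   similarity transform (rotation, translation, isotropic scale; proper
   rotation enforced) from the template's apex + ring centers to the
   corresponding guide landmarks, with raw inserts aggregated into ring
   centers.
2. **Regularized non-rigid fit**: iterated linear least squares over all
   vertex positions. Each iteration matches every guide point to the
   exact closest point on its class's surface (barycentric attachment to
   the triangle), drops correspondences farther than 15 mm, and solves

   `min  sum_g w_g || A V - p_g ||^2 + lambda ||L (V - V0)||^2 + mu ||V - V0||^2`

   with `L` the random-walk-normalized graph Laplacian (ring loops
   connected as cycles), `lambda = 1`, landmark weight 10 (landmarks are
   sparse but authoritative — valve anatomy is highly sensitive to insert
   placement), and a small ridge `mu = 0.01` toward the registered
   template `V0`. The ridge matters: components with little or no guide
   support (the free rings, the RV apex region between imaged slices)
   otherwise leave near-null smooth modes in the normal equations, and
   the iteration turns that indeterminacy into a slow drift. Per-iteration
   vertex displacement is capped at 2 mm; the fit stops after 20
   iterations or when the RMS vertex change falls below 0.01 mm. The
   smoothness penalty acts on the *total* displacement from `V0`, so the
   solution at each iteration is a fresh global optimum given the current
   correspondences, and unconstrained vertices follow their neighbours
   smoothly instead of accumulating error.

Per-class weights are uniform by default (the per-class weighting of
short-axis epicardial vs septal contours is exposed but not differentiated
— no evidence in the source workflow fixes a ratio).

## Measurements

Region volumes are signed divergence-theorem sums `V = 1/6 sum_f v1 .
(v2 x v3)` over the closed region surfaces, positive for outward
orientation. `SV = EDV - ESV` and `EF = 100 SV / EDV` hold by definition.
Masses use myocardial density 1.05 g/mL (the standard CMR convention) at
ED, with the septum assigned to the LV — both conventions chosen by the
package, since neither is fixed by the workflow it implements. Because
the fitted model has only three closed surfaces, the LV-epicardial closed
surface needed for the mass split is reconstructed by a template-level
pairing: every epicardial vertex covered by the RV bulge stores the index
of its matching septal-sheet vertex, and substituting those positions
"de-bulges" the epicardium back to the LV epicardial shell. LV wall
volume is then `V(LV epi) - V(LV cavity)` and the RV free wall
`V(epi) - V(LV epi) - V(RV cavity)`; total wall volume is exact by
additivity, and the split is accurate to the pairing approximation at the
crescent edges (a few percent — good enough for the package's synthetic
validation, and configurable at template build time).

## Shape atlas

`build_atlas()` rigidly aligns each subject's ED model to the population
mean (a few alternating mean/alignment passes), applies the same
transform to the ES model, and concatenates the ED and ES vertex
coordinates into one shape vector. **No scaling** is used in the
alignment: heart size is a real feature of cardiac shape atlases. PCA
uses the 1/(n-1) covariance convention; scores are standardized by
`sqrt(lambda_k)`, so `z_k = phi_k' (s - s_mean) / sqrt(lambda_k)` is in
training-population standard deviations, training scores have mean 0 and
sd 1 per mode, and projecting the mean gives all zeros. ED and ES live in
a single concatenated atlas by default (`z` captures joint ED/ES shape);
modes with eigenvalue below 1e-12 are excluded from projection with a
warning. Z-scores divide by `sqrt(lambda_k)` rather than the sample sd of
scores; the two coincide for training data under the stated convention.

## Evaluation metrics

Dice is `2|A n B| / (|A| + |B|)` (two empty masks define 1); Hausdorff is
the classical symmetric maximum with an optional percentile variant
(HD95), computed over traced contour points in pixel units for 2D and mm
for 3D; AAFD is the mean absolute frame difference. Model-to-model
comparison aligns with a no-scale Procrustes (reflections rejected), then
measures exact point-to-triangle distances from automatic vertices to the
manual surface of the same region, signed positive outside (along the
matched face's outward normal). Valve-region errors use the ring vertices
against the manual ring polyline. The global MAE is the mean over all
surface vertices, not the mean of regional means. Bland-Altman reports
bias, 1.96-sd limits of agreement, R^2 and the paired-t p-value; Z-score
comparisons report per-mode mean |dz| with two-sample Kolmogorov-Smirnov
tests under Holm-Bonferroni correction at alpha 0.05.

## Problem sizes and numerical choices

The validation experiments are sized for a single CPU: oracle round trips
use 5 phantoms; the wall-thickness atlas experiment uses 30 phantoms with
ED/ES-only rendering and the six fitted views; stage training uses 6
training + 1 held-out phantoms (~200-300 images per classifier stage, 60
segmentation images, 60 landmark stacks) at 128 px with the epochs listed
above. Metric oracles run 1000 random trials. Determinism: every
stochastic step (phantom noise, parameter draws, weight init, shuffling,
augmentation) is seeded; the nearest-triangle search uses warm-started
exact distance queries, so fits are bit-reproducible given identical
inputs.

Known limitations: the fit has no explicit fold-prevention (the step cap
and Laplacian smoothing approximate it; no flipped faces are observed in
the test conditions, and region orientation is asserted); Loop
subdivision is implemented for closed manifolds only; the mass split
degrades if a fitted RV deviates grossly from the template's crescent
topology; and the phantom's idealized geometry means stage-performance
numbers should not be read as clinical performance.
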