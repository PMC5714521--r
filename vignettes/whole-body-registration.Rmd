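---
title: "Whole-body multimodal registration: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body multimodal registration: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nmireg)
```

This vignette is the package's own account of its science: the transform
and similarity model, why each default is what it is, what the synthetic
phantom does and does not emulate, and the numerical choices a maintainer
would otherwise have to reverse-engineer from the code.

## The registration model

Registration is treated as estimation: given a fixed volume $F$ (CT, the
reference) and a moving volume $M$ (MR), we estimate a transform chain
$T_\theta$ mapping fixed-domain physical points $x$ (mm) into the moving
domain, by maximizing a similarity functional. The chain has two stages:

1. **Rigid**: $r(x) = R\,(x - c) + c + t$ with Euler angles applied in
   fixed order X, then Y, then Z, rotation center $c$ at the fixed image's
   intensity center of mass, translation $t$ in mm. Six free parameters.
2. **Free-form deformation (FFD)**: a displacement field on the rigidly
   aligned frame, $T(x) = q + d(q)$ with $q = r(x)$ and
   $d(q) = \sum_{ijk} c_{ijk}\, B^3\!\big((q - x_{ijk})/h\big)$, a
   tensor-product cubic B-spline on a uniform control grid of spacing $h$.
   The field is $C^2$, local (each point depends on its 4×4×4 control
   neighborhood), and a partition of unity, so the displacement is bounded
   by the largest coefficient magnitude.

All geometry is physical: voxel indices are 0-based, the center of voxel
$(0,0,0)$ sits at the volume origin, and transforms and metrics operate in
mm throughout. This matters because the intended data are strongly
anisotropic (CT $1.367\times1.367\times2.5$ mm, MR
$1.875\times1.875\times6$ mm): voxel-space distances would be meaningless.
Only axis-aligned volumes are supported; a NIfTI or MetaImage header
encoding a genuine rotation is rejected at read time rather than silently
mishandled (axis *flips* are canonicalized).

### Similarity: normalized mutual information

$\mathrm{NMI} = (H_F + H_M)/H_{F,M}$ with entropies in nats from a
$32\times32$ joint histogram. NMI ranges over $[1, 2]$ — 1 for independent
marginals, 2 for a deterministic intensity relation — and is invariant
under any relabeling of moving-intensity classes, which is exactly the
property needed when CT and MR intensities are related non-monotonically
(bone: bright CT, dark MR).

The histogram is built from random spatial samples, fresh each iteration
(stochastic subsampling). Two windows are available:

* `"parzen"` (default, used by the optimizer): cubic B-spline window on
  the moving axis, linear on the fixed axis. The histogram is then
  differentiable in the transform parameters; the moving-axis bin position
  is mapped into $[1, b-2]$ so the kernel support never leaves the
  histogram and mass is conserved exactly.
* `"nearest"`: plain counting, used when the exact limits matter (a
  diagonal histogram and NMI $= 2$ for identical discretized images).

The analytic gradient chains $\partial \mathrm{NMI}/\partial P_{ij}$
through the Parzen window derivative and the spatial gradient of the
moving-image interpolant; it is exercised against central finite
differences in the test suite. Binning ranges are the robust 0.5th–99.5th
intensity percentiles, fixed per resolution level, so a handful of extreme
voxels cannot stretch the histogram mid-optimization. Samples mapping
outside the moving volume are dropped (the metric refuses to evaluate if
more than 80% drop); intensities beyond the binning range are clamped to
the edge bins, where their gradient contribution is zero.

### Optimizer and schedule

Both stages use multiresolution stochastic steepest ascent with the
decaying gain $\mathrm{step}(k) = a/(A + k + 1)^\alpha$. The published
whole-body defaults are reproduced exactly by `reg_config()`: five rigid
levels (downsampling 16, 8, 4, 2, 1; $a = 4000$, $A = 50$,
$\alpha = 0.6$), five elastic levels (8, 4, 4, 2, 2;
$a = 2000, 7000, 20000, 20000, 30000$, $\alpha = 0.602$), iterations
4096, 2048, 1024, 512, 256 per stage (7936 ≈ 8000 in total), 5000/4096
metric samples, a control grid of 8 fixed-image voxels, and 5000 randomly
selected control points updated per elastic iteration. Pyramid levels are
Gaussian-smoothed ($\sigma = \mathrm{factor}/2$ voxels) then subsampled;
the factor-1 level uses the original image. During optimization the moving
image is interpolated with order 1 (trilinear); the final resampling uses
order 3 (cubic B-spline with the standard recursive prefilter, so the
interpolant passes through the voxel values).

Two conventions the published description leaves open are fixed here:
rotation gradients are scaled by the squared half-diagonal of the fixed
image so one gain unit moves corner voxels comparably for rotations and
translations; and the elastic schedule's two trailing "factor 2" entries
are taken at face value as repeated levels (resolutions above the original
grid are not supported). The gain-rule formula itself follows the decaying
step behavior its source describes (large steps first, shrinking with
$k$).

### Scaled-down study configuration

The 64³ phantom experiments use `phantom_config()`: rigid factors
8/4/2/1 × 300/200/150/100 iterations with the published $a = 4000$;
elastic factors 4/2/2 × 200/150/100 with $a = 500, 1500, 3000$ and the
published $\alpha$. Two deviations from the full-scale defaults, both
problem-size driven: the factor-16 level is dropped (a 4³ image carries no
usable structure), and the elastic gains are smaller — raw NMI gradient
magnitudes depend on image content and size, and at this scale the
published gains overdeform (the same failure mode the full-scale protocol
reports when pyramid levels or iterations are pushed too high). The gains
were calibrated once on the phantom by repetition, exactly how the
full-scale step sizes were chosen, and are fixed thereafter.

## The phantom: what it emulates, what it does not

`generate_anatomy()` builds a procedural whole body on a 64³, 2.5 mm CT
grid: torso and head ellipsoids with cylindrical arms, a brain filling the
cranial cavity (its surface is the inner skull table — anatomically, there
is no soft-tissue shell between brain and bone, and modeling one would
make the brain boundary invisible to CT), a bony skull and spine, two
lungs and two kidneys, with class-typical CT numbers (air −1000, lung
−800, soft 40, bone 700 HU), seeded class jitter and voxel noise.
`mr_from_ct()` renders the same anatomy on a coarser anisotropic MR grid
(3.0 × 3.0 × 4.5 mm — the axial-coarser direction of the clinical
protocol, mildened so that label discretization remains a secondary error
source at this scale) with a per-class intensity map that is deliberately
non-monotone versus CT, a smooth multiplicative bias field (amplitude
0.15) and Gaussian noise (sd 25, about 3% of range). `warp_case()` draws
the ground truth: a rigid offset (translation bounded at 10 mm, rotations
scaled to comparable corner motion) plus a smoothed random FFD whose
coefficients are scaled to a chosen bound (8 mm by default — also at most
0.4 of the control spacing, which guarantees injectivity and convergence
of the fixed-point inversion used to render the warped MR side). The
truth is stored as an exact `transform_chain`, so every evaluation has a
reference.

Deliberate design choices:

* The truth deformation lives in the same FFD parameterization the
  registrar optimizes, so failure isolates optimization rather than
  transform-model mismatch. `model_mismatch = TRUE` draws the truth on a
  twice-finer control grid instead, for honesty about that choice.
* The 16-site landmark roster reuses the whole-body protocol's site names
  (lung apices, kidney tips, liver borders, vertebrae); sites with no
  phantom analogue (liver, adrenal, celiac trunk, vertebrae) sit at
  defined body-axis positions.
* Labels use one code per voxel with organ codes taking precedence; the
  whole-body region is "any labeled voxel" via the label volume's
  `nested_root` field, since organs are nested inside the body.

What the phantom does **not** emulate: real tissue texture and
intra-organ contrast, metal artifacts, respiratory and cardiac motion,
partial-volume mixing at boundaries, and inter-patient anatomical
variability. Passing the phantom experiment therefore demonstrates that
the transform model, metric, optimizer and evaluation machinery are
correct and consistent — not that the pipeline reaches any particular
accuracy on clinical data. Two quantitative consequences of the geometry
are worth knowing. First, label discretization alone bounds the
achievable Dice under the *true* transform: the mask round-trip through
the coarse MR grid costs several percent for small organs (the package
asserts ≥ 0.95 for the whole body but only ≥ 0.85 for organs under the
truth chain; the residual is purely grid quantization). Second, landmarks
placed in CT-featureless interior tissue have in-principle-unobservable
displacement, so per-landmark errors there may not improve — the cohort
pooled mean is the meaningful recovery statistic, mirroring grouped
clinical reporting.

## Evaluation framework

`evaluate_case()` maps the moving-side labels onto the fixed grid by
nearest-neighbour resampling through the chain (the label-interpolation
rule is a package convention) and reports, per region: TO, DC, JC, FN, FP
by exact voxel counting; VS signed as $2(|S|-|T|)/(|S|+|T|)$ (the sign is
needed for under- versus over-segmentation direction); and DE/HD from an
exact anisotropic Euclidean distance transform (separable lower-envelope
algorithm) of the target *boundary*, sampled at source boundary voxel
centers. Boundaries are 6-connectivity face boundaries with the array
border counting as boundary. The Hausdorff distance is directed
source→target as defined; a symmetrized variant is exported under its own
name. A region present in only one volume yields a flagged record with
`NA` metrics rather than a silent omission, and cohort rows reduce `n`
accordingly (the clinical analogue: kidneys indistinguishable on some
MR studies).

The Dice agreement bands are poor < 0.2, fair 0.2–0.4, good 0.6–0.8,
excellent 0.8–1.0; the published band list leaves 0.4–0.6 unnamed, and
this package returns `"moderate"` there as an explicit repository
convention.

Cohort statistics follow the box-whisker conventions of the reporting
format: quartiles by linear interpolation between order statistics (the
convention is recorded in the table's metadata because quartile values
depend on it), outliers beyond 1.5 IQR from the quartiles, whiskers as
min/max of the remainder, and the 95% median notch half-width
$\Delta = 1.57\,\mathrm{IQR}/\sqrt{n}$ — McGill's rule, chosen because the
source names only "a statistical test on groups" at 95% significance
without a formula.

## Numerical choices and degenerate inputs

* **Interpolation**: trilinear gradients are exact almost everywhere;
  gradient-correctness tests use the order-3 interpolant, which is smooth,
  so central differences converge cleanly. Cubic interpolation uses the
  recursive prefilter (pole $\sqrt3 - 2$, mirror boundaries, horizon at
  $10^{-14}$).
* **Out-of-volume**: metric samples are dropped and counted; resampled
  voxels take the moving-image minimum (air) unless configured otherwise;
  FFD evaluation outside the grid's full-support region is an error for
  `chain_apply()` but displacement-zero during resampling (the grid always
  covers the mapped fixed domain during registration, so this arises only
  for user-supplied points).
* **Degenerate metrics**: a histogram with fewer than 2 usable samples is
  an error; a single-cell histogram has zero joint entropy and NMI is
  defined as 2; empty overlap denominators raise errors naming the metric
  (or return flagged `NA`s in `partial` mode).
* **Determinism**: all randomness flows through R's RNG from the
  configuration seed; identical seeds give bit-identical transform files,
  resampled volumes and metric tables. Transform files store parameters
  at full `%.17g` precision so a round trip is exact.
* **Chain inversion** (phantom rendering only): fixed-point iteration
  $q \leftarrow y - d(q)$, at most 50 iterations, tolerance $10^{-9}$ mm;
  contractive because the truth field obeys the 0.4-spacing bound.

## Problem sizes

The test suite and the acceptance script run everything at phantom scale:
64³ CT / 58×58×39 MR volumes, five registration cases, plus property
tests on 8³–12³ masks (1000 pairs for the metric identities, 200 for the
surface-distance oracle) and 20 finite-difference gradient cases at 12³.
These sizes were chosen so the full suite exercises every code path,
including complete registrations, in a few minutes on one CPU; the
package itself handles clinical-scale volumes with the same code paths.

## Known limitations

Inverse transforms are not estimated (CT→MR would need its own
registration); no diffeomorphic constraint is enforced beyond the
magnitude bound on the *synthetic* truth (the estimated field is
unconstrained, as in the original protocol); multi-level B-spline grids
and non-axis-aligned orientations are out of scope; and the elastic
"factor 2, twice" schedule entries reflect an ambiguity in the source
protocol that is resolved here as repeated levels.
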