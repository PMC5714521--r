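# nmireg — whole-body MR→CT deformable registration and its validation

`nmireg` registers paired 3D volumes from different modalities — the
motivating case is whole-body MR onto CT for building MR–CT atlases used in
MR-guided attenuation correction on hybrid PET/MRI systems — and ships the
complete evaluation framework needed to validate such registrations:
landmark error, volume overlap, overlay error, surface distances, and
cohort box-whisker statistics. Because clinical paired whole-body data
cannot be redistributed, the package also includes a seeded generator of
paired pseudo-CT/pseudo-MR phantoms with organ labels, a 16-site landmark
roster and a *known* ground-truth deformation, so the whole pipeline can be
exercised end to end with a measurable truth.

## The method

Registration estimates a transform chain `T = T_ffd ∘ T_rigid` mapping
fixed-image (CT) physical coordinates into the moving image (MR):

* **Rigid stage** — six parameters (three Euler angles about the fixed
  image's center of mass, three translations in mm).
* **Deformable stage** — a free-form deformation: a displacement field
  `d(x) = Σ_ijk c_ijk B³((x − x_ijk)/h)` parameterized by cubic B-spline
  coefficients `c_ijk` on a uniform control grid (default spacing: 8
  fixed-image voxels), added in the rigidly aligned frame.

Both stages maximize **normalized mutual information**,
`NMI = (H_F + H_M) / H_{F,M}`, estimated from a 32×32 joint histogram of
random spatial samples (5000 per rigid iteration, 4096 per elastic
iteration) with a differentiable Parzen window — cubic B-spline along the
moving axis, linear along the fixed axis. NMI depends only on the
statistical relationship between intensities, not its shape, which is what
makes MR↔CT matching possible. The optimizer is multiresolution stochastic
steepest ascent with the decaying gain

    step(k) = a / (A + k + 1)^α

per level (rigid: factors 16, 8, 4, 2, 1 with a = 4000, α = 0.6; elastic:
factors 8, 4, 4, 2, 2 with a = 2000…30000, α = 0.602; 7936 iterations per
stage — see `reg_config()`), with an analytic NMI gradient obtained by
chaining the Parzen window through the moving-image interpolant.

Validation metrics (per segmented region, source S resampled onto the
target T's grid): target overlap `TO = |S∩T|/|T|`, Dice
`DC = 2|S∩T|/(|S|+|T|)`, Jaccard `JC = |S∩T|/|S∪T|` (with
`DC = 2JC/(1+JC)`), false negative/positive fractions, signed volume
similarity `VS = 2(|S|−|T|)/(|S|+|T|)`, and — from an exact anisotropic
Euclidean distance map of the target boundary — the mean surface distance
`DE` and the directed Hausdorff distance `HD`.

## Worked example

```r
library(nmireg)

anatomy <- generate_anatomy(seed = 7)          # 64^3 pseudo-CT + labels + landmarks
case    <- warp_case(anatomy, seed = 7)        # draws a hidden ground-truth warp
case
#> <phantom_case> seed 7
#>   CT 64x64x64 @ 2.5x2.5x2.5 mm | MR 58x58x39 @ 3.0x3.0x4.5 mm
#>   truth: |t| = 5.67 mm, max |FFD coef| = 8.00 mm

fit <- nmi_register(case$ct, case$mr, phantom_config(seed = 107))
fit
#> Two-stage NMI registration
#>   rigid: translation ( 0.874, -3.647, -5.851) mm, rotation ( 0.377, -0.467, -1.507) deg
#>   FFD: 13x13x12 control points, max displacement 5.48 mm
#>   final NMI 1.23817 after 750+450 iterations

evaluate_case(case$ct_labels, case$mr_labels, fit$chain,
              case$ct_landmarks, case$mr_landmarks)
#>    region    TO    DC    JC     FN     FP     VS DE_mm HD_mm agreement
#> 1    body 0.966 0.959 0.921 0.0343 0.0475 0.0137 1.055  5.00 excellent
#> 2   brain 0.946 0.891 0.803 0.0541 0.1584 0.1166 1.394  4.33 excellent
#> 3   lungs 0.945 0.930 0.869 0.0552 0.0843 0.0313 0.891  3.54 excellent
#> 4 kidneys 0.916 0.903 0.823 0.0841 0.1094 0.0280 0.877  3.54 excellent
#> landmark error: mean 0.70 mm, max 1.58 mm over 16 points
```

The pre-registration landmark error for this case is 6.0 mm, so the fitted
chain removes about 88% of the point error; every region lands in the
"excellent" Dice band (≥ 0.8). `coef()`, `predict()` (map points or
resample a volume), `residuals()` (landmark errors) and `plot()` (metric
trace) work on the fit as on any fitted model. Cohorts of cases are
summarized with `cohort_table()` in the Minimum / Q1 / Median±Δ / Q3 /
Maximum convention (1.5·IQR outlier fences, Δ = 1.57·IQR/√n median notch).

A command-line dispatcher is installed as `exec/nmireg` with subcommands
`phantom`, `register`, `transform`, `evaluate`, `report`; every run writes
a JSON manifest sufficient to reproduce it.

## Limitations

The phantom is geometric (stacked ellipsoids), so passing its experiment
demonstrates correct mechanics of the optimizer, transform model and
metrics — not clinical-grade accuracy on real anatomy; see the methods
vignette (`vignettes/whole-body-registration.Rmd`) for what the generator
does and does not emulate, and for every numerical design decision.
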