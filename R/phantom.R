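#' Seeded paired-modality whole-body phantom
#'
#' The test harness for the registration pipeline: procedurally generated
#' pseudo-CT / pseudo-MR volume pairs with organ labels (body, brain,
#' lungs, kidneys), a 16-site landmark roster, and a known ground-truth
#' transform between the two frames.  The two modalities differ in grid
#' (the MR grid is coarser and anisotropic), in intensity mapping (the
#' CT-to-MR intensity relation is deliberately non-monotone, so only an
#' intensity-relationship-free similarity measure such as NMI can align
#' them), in smooth multiplicative bias, and in noise.
#'
#' `generate_anatomy()` builds the anatomy: a body of stacked ellipsoids
#' (torso, head, cylindrical arms), a spherical brain inside a bony skull
#' shell, two ellipsoidal lungs, two small ellipsoidal kidneys and a bony
#' spine, with class-typical CT numbers (air -1000, lung -800, soft
#' tissue 40, bone 700 HU) plus seeded class jitter and voxel noise.
#'
#' @param seed integer seed; the same seed reproduces identical arrays.
#' @param shape CT grid size per axis (>= 32).
#' @param spacing CT voxel spacing, mm.
#' @param hu_noise_sd CT voxel noise (HU).
#' @return list of class `"phantom_anatomy"`: `ct` ([volume()]), `labels`
#'   ([label_volume()]), `landmarks` ([landmark_set()], the 16-site
#'   roster), and the geometric parameters.
#' @export
generate_anatomy <- function(seed = 1L, shape = c(64L, 64L, 64L),
                             spacing = c(2.5, 2.5, 2.5), hu_noise_sd = 15) {
  shape <- as.integer(shape)
  if (any(shape < 32L))
    stop("config error: phantom grid must be >= 32 per axis", call. = FALSE)
  set.seed(seed)
  L <- (shape - 1L) * spacing
  sc <- L / c(157.5, 157.5, 157.5)  # reference layout designed at 64^3 x 2.5mm
  geom <- phantom_geometry(sc)
  # voxel center coordinate arrays
  gx <- (seq_len(shape[1]) - 1) * spacing[1]
  gy <- (seq_len(shape[2]) - 1) * spacing[2]
  gz <- (seq_len(shape[3]) - 1) * spacing[3]
  ax <- array(rep(gx, times = shape[2] * shape[3]), shape)
  ay <- array(rep(rep(gy, each = shape[1]), times = shape[3]), shape)
  az <- array(rep(gz, each = shape[1] * shape[2]), shape)
  cls <- classify_phantom(geom, ax, ay, az)
  hu_means <- c(air = -1000, soft = 40, brain = 45, lung = -800,
                kidney = 35, bone = 700)
  hu_jitter <- rnorm(length(hu_means), 0, 10)
  hu <- hu_means + hu_jitter
  ct <- array(hu[["air"]], shape)
  ct[cls == 1L] <- hu[["soft"]]
  ct[cls == 2L] <- hu[["brain"]]
  ct[cls == 3L] <- hu[["lung"]]
  ct[cls == 4L] <- hu[["kidney"]]
  ct[cls == 5L] <- hu[["bone"]]
  ct <- ct + rnorm(length(ct), 0, hu_noise_sd)
  labels <- phantom_labels(cls)
  structure(list(ct = volume(ct, spacing = spacing),
                 labels = label_volume(labels, phantom_regions(),
                                       spacing = spacing) |> set_nested_root(),
                 landmarks = phantom_landmarks(geom),
                 geometry = geom, shape = shape, spacing = spacing,
                 hu = hu, seed = seed),
            class = "phantom_anatomy")
}

set_nested_root <- function(lab) {
  lab$nested_root <- "body"
  lab
}

phantom_regions <- function() c(body = 1L, brain = 2L, lungs = 3L, kidneys = 4L)

# geometric layout, mm, scaled componentwise from the 157.5 mm reference
phantom_geometry <- function(sc) {
  s3 <- function(x, y, z) c(x, y, z) * sc
  list(
    torso_c = s3(79, 76, 62),  torso_s = s3(46, 34, 46),
    head_c  = s3(79, 76, 118), head_r  = 21.5 * min(sc),
    # the brain fills the cranial cavity: its surface is the inner skull
    # table, with a scalp layer outside the bone
    brain_r = 16 * min(sc),
    skull_outer = 19.5 * min(sc),
    arm_dx = 50 * sc[1], arm_r = 8 * min(sc[1:2]),
    arm_z = c(20, 95) * sc[3],
    lung_dx = 20 * sc[1], lung_c = s3(0, 74, 80), lung_s = s3(14, 15, 18),
    kid_dx = 17 * sc[1],  kid_c  = s3(0, 86, 40), kid_s  = s3(11, 10, 15),
    spine_y = 96 * sc[2], spine_r = 6 * min(sc[1:2]),
    spine_z = c(20, 104) * sc[3])
}

in_ellipsoid <- function(x, y, z, c3, s3) {
  ((x - c3[1]) / s3[1])^2 + ((y - c3[2]) / s3[2])^2 + ((z - c3[3]) / s3[3])^2 <= 1
}

# tissue classes: 0 air, 1 soft, 2 brain, 3 lung, 4 kidney, 5 bone
classify_phantom <- function(g, x, y, z) {
  torso <- in_ellipsoid(x, y, z, g$torso_c, g$torso_s)
  head <- (x - g$head_c[1])^2 + (y - g$head_c[2])^2 + (z - g$head_c[3])^2 <=
    g$head_r^2
  arms <- (((x - (g$torso_c[1] - g$arm_dx))^2 + (y - g$torso_c[2])^2 <= g$arm_r^2) |
           ((x - (g$torso_c[1] + g$arm_dx))^2 + (y - g$torso_c[2])^2 <= g$arm_r^2)) &
    z >= g$arm_z[1] & z <= g$arm_z[2]
  body <- torso | head | arms
  cls <- array(0L, dim(x))
  cls[body] <- 1L
  rhead2 <- (x - g$head_c[1])^2 + (y - g$head_c[2])^2 + (z - g$head_c[3])^2
  skull <- body & rhead2 <= g$skull_outer^2 & rhead2 > g$brain_r^2
  brain <- body & rhead2 <= g$brain_r^2
  lungs <- body & (in_ellipsoid(x, y, z, g$lung_c + c(g$torso_c[1] - g$lung_dx, 0, 0), g$lung_s) |
                   in_ellipsoid(x, y, z, g$lung_c + c(g$torso_c[1] + g$lung_dx, 0, 0), g$lung_s))
  kids <- body & (in_ellipsoid(x, y, z, g$kid_c + c(g$torso_c[1] - g$kid_dx, 0, 0), g$kid_s) |
                  in_ellipsoid(x, y, z, g$kid_c + c(g$torso_c[1] + g$kid_dx, 0, 0), g$kid_s))
  spine <- torso & (x - g$torso_c[1])^2 + (y - g$spine_y)^2 <= g$spine_r^2 &
    z >= g$spine_z[1] & z <= g$spine_z[2]
  cls[skull | spine] <- 5L
  cls[lungs] <- 3L
  cls[kids] <- 4L
  cls[brain] <- 2L
  cls
}

# label codes from tissue classes (bone belongs to the body region)
phantom_labels <- function(cls) {
  lab <- array(0L, dim(cls))
  lab[cls == 1L | cls == 5L] <- 1L
  lab[cls == 2L] <- 2L
  lab[cls == 3L] <- 3L
  lab[cls == 4L] <- 4L
  lab
}

# the 16-site roster: anatomical names mapped onto the phantom; sites with
# no phantom analogue (liver, adrenal, celiac trunk, vertebrae) sit at
# defined body-axis positions
phantom_landmarks <- function(g) {
  cx <- g$torso_c[1]
  lungs_top <- g$lung_c[3] + g$lung_s[3]
  kt <- g$kid_c[3] + g$kid_s[3]
  kb <- g$kid_c[3] - g$kid_s[3]
  pts <- rbind(
    apex_right_lung = c(cx + g$lung_dx, g$lung_c[2], lungs_top),
    apex_left_lung = c(cx - g$lung_dx, g$lung_c[2], lungs_top),
    liver_dome = c(cx + 16, g$torso_c[2] + 4, g$lung_c[3] - g$lung_s[3] - 4),
    anterior_right_liver_border = c(cx + 21, g$torso_c[2] - 21, g$kid_c[3] + 12),
    anterior_left_liver_border = c(cx - 9, g$torso_c[2] - 21, g$kid_c[3] + 12),
    lateral_liver_border = c(cx + 36, g$torso_c[2], g$kid_c[3] + 12),
    posterior_liver_border = c(cx + 16, g$torso_c[2] + 24, g$kid_c[3] + 12),
    inferior_liver_border = c(cx + 16, g$torso_c[2] + 4, g$kid_c[3] - 6),
    right_adrenal = c(cx + g$kid_dx, g$kid_c[2], kt + 2),
    celiac_trunk = c(cx, g$kid_c[2] - 4, g$kid_c[3] + 14),
    upper_tip_right_kidney = c(cx + g$kid_dx, g$kid_c[2], kt),
    upper_tip_left_kidney = c(cx - g$kid_dx, g$kid_c[2], kt),
    lower_tip_right_kidney = c(cx + g$kid_dx, g$kid_c[2], kb),
    lower_tip_left_kidney = c(cx - g$kid_dx, g$kid_c[2], kb),
    t10_vertebra = c(cx, g$spine_y, g$lung_c[3] - 10),
    l5_vertebra = c(cx, g$spine_y, g$spine_z[1] + 4))
  landmark_set(pts, names = rownames(pts))
}

#' Pseudo-MR image from phantom anatomy
#'
#' Builds the MR-contrast rendering of the anatomy on a coarser
#' anisotropic MR-like grid.  The per-class intensity remap is nonlinear
#' and non-order-preserving with respect to CT numbers (bone maps dark,
#' soft tissue bright), so the CT-MR intensity relation is non-affine and
#' non-monotone.  A smooth low-frequency multiplicative bias field and
#' additive Gaussian noise emulate MR shading and noise.  When a `chain`
#' is given (the ground-truth transform of [warp_case()]), the anatomy is
#' rendered in the warped frame: each MR voxel reads the tissue class at
#' the numerically inverted chain position.
#'
#' @param anatomy a [generate_anatomy()] result.
#' @param seed integer seed.
#' @param bias_amplitude relative amplitude of the bias field (0 disables).
#' @param noise_sd additive Gaussian noise (intensity units; 0 disables).
#' @param mr_spacing,mr_margin MR grid spacing (mm) and extra physical
#'   margin (mm) beyond the CT extent.
#' @param chain optional [transform_chain()] mapping CT to MR frame.
#' @return list: `mr` ([volume()]), `labels` ([label_volume()] on the MR
#'   grid).
#' @export
mr_from_ct <- function(anatomy, seed = 1L, bias_amplitude = 0.15,
                       noise_sd = 25, mr_spacing = c(3, 3, 4.5),
                       mr_margin = 6, chain = NULL) {
  stopifnot(inherits(anatomy, "phantom_anatomy"))
  set.seed(seed + 1000L)
  Lct <- (anatomy$shape - 1L) * anatomy$spacing
  origin <- rep(-mr_margin, 3)
  mdim <- as.integer(ceiling((Lct + 2 * mr_margin) / mr_spacing) + 1L)
  gx <- origin[1] + (seq_len(mdim[1]) - 1) * mr_spacing[1]
  gy <- origin[2] + (seq_len(mdim[2]) - 1) * mr_spacing[2]
  gz <- origin[3] + (seq_len(mdim[3]) - 1) * mr_spacing[3]
  pts <- cbind(rep(gx, times = mdim[2] * mdim[3]),
               rep(rep(gy, each = mdim[1]), times = mdim[3]),
               rep(gz, each = mdim[1] * mdim[2]))
  src <- if (is.null(chain)) pts else chain_invert(chain, pts)
  cls <- classify_phantom(anatomy$geometry,
                          array(src[, 1], mdim), array(src[, 2], mdim),
                          array(src[, 3], mdim))
  # non-monotone class intensity map (vs CT: bone high->dark, soft low->bright)
  mr_means <- c(air = 15, soft = 650, brain = 800, lung = 380,
                kidney = 720, bone = 120)
  img <- array(mr_means[["air"]], mdim)
  img[cls == 1L] <- mr_means[["soft"]]
  img[cls == 2L] <- mr_means[["brain"]]
  img[cls == 3L] <- mr_means[["lung"]]
  img[cls == 4L] <- mr_means[["kidney"]]
  img[cls == 5L] <- mr_means[["bone"]]
  if (bias_amplitude > 0) {
    ph <- runif(3, 0, 2 * pi)
    bias <- 1 + bias_amplitude *
      array(cos(2 * pi * pts[, 1] / (1.7 * Lct[1]) + ph[1]) *
            cos(2 * pi * pts[, 2] / (1.9 * Lct[2]) + ph[2]) *
            cos(2 * pi * pts[, 3] / (2.3 * Lct[3]) + ph[3]), mdim)
    img <- img * bias
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  labels <- phantom_labels(cls)
  list(mr = volume(img, spacing = mr_spacing, origin = origin),
       labels = label_volume(labels, phantom_regions(), spacing = mr_spacing,
                             origin = origin) |> set_nested_root())
}

#' Full phantom case with known ground-truth deformation
#'
#' Draws a random rigid offset and a smooth random free-form deformation
#' (seeded), renders the MR side of the phantom in the deformed frame, and
#' stores the exact transform chain as ground truth.  The truth is
#' expressed in the same FFD parameterization the registration optimizes
#' (control spacing 8 CT voxels), so registration failure isolates the
#' optimizer rather than transform-model mismatch; set
#' `model_mismatch = TRUE` for an additional sinusoidal displacement that
#' the registration grid cannot represent exactly.
#'
#' @param anatomy a [generate_anatomy()] result (or `NULL` to generate one
#'   from `seed`).
#' @param seed integer seed.
#' @param rigid_magnitude maximum rigid offset, mm (translation norm bound;
#'   rotations are drawn so corner displacement stays comparable).
#' @param ffd_magnitude maximum FFD displacement, mm; must stay below 0.4
#'   of the control spacing to keep the mapping injective.
#' @param grid_spacing_voxels truth control-grid spacing in CT voxels.
#' @param model_mismatch add a non-representable sinusoidal field.
#' @param ... passed to [mr_from_ct()].
#' @return list of class `"phantom_case"`: `ct`, `mr`, `ct_labels`,
#'   `mr_labels`, `ct_landmarks`, `mr_landmarks`, `truth`
#'   ([transform_chain()]), `seed`.
#' @export
warp_case <- function(anatomy = NULL, seed = 1L, rigid_magnitude = 10,
                      ffd_magnitude = 8, grid_spacing_voxels = 8,
                      model_mismatch = FALSE, ...) {
  if (is.null(anatomy)) anatomy <- generate_anatomy(seed)
  set.seed(seed + 2000L)
  ct <- anatomy$ct
  # mismatch mode: truth drawn on a twice-finer grid than the registration
  # default, so the optimizer's transform model cannot represent it exactly
  if (model_mismatch) grid_spacing_voxels <- grid_spacing_voxels / 2
  gspc <- grid_spacing_voxels * ct$spacing
  if (ffd_magnitude > 0.4 * min(gspc))
    stop("config error: ffd_magnitude ", ffd_magnitude,
         " exceeds the injectivity bound 0.4 * control spacing = ",
         0.4 * min(gspc), call. = FALSE)
  e <- volume_extent(ct)
  halfdiag <- sqrt(sum(((e[2, ] - e[1, ]) / 2)^2))
  trans <- runif(3, -rigid_magnitude / sqrt(3), rigid_magnitude / sqrt(3))
  angles <- runif(3, -0.5 * rigid_magnitude / halfdiag,
                  0.5 * rigid_magnitude / halfdiag)
  if (rigid_magnitude == 0) { trans <- rep(0, 3); angles <- rep(0, 3) }
  rigid <- rigid_transform(trans, angles, center = volume_center(ct))
  ffd <- NULL
  if (ffd_magnitude > 0) {
    corners <- as.matrix(expand.grid(e[, 1], e[, 2], e[, 3]))
    mapped <- rigid_apply(rigid, corners)
    grid <- grid_covering(apply(mapped, 2, min), apply(mapped, 2, max), gspc)
    coef <- array(rnorm(prod(grid$shape) * 3), c(grid$shape, 3L))
    coef <- smooth_grid_coef(coef)
    # scale so max |coefficient| = ffd_magnitude: the tensor-product weights
    # are a partition of unity, so the realized displacement is bounded by
    # ffd_magnitude everywhere (and injectivity by the 0.4 x spacing rule)
    coef <- coef * (ffd_magnitude / max(abs(coef)))
    ffd <- bspline_grid(grid$shape, grid$spacing, grid$origin, coef)
  }
  truth <- transform_chain(rigid, ffd)
  mr <- mr_from_ct(anatomy, seed = seed, chain = truth, ...)
  mr_lm <- landmark_set(chain_apply(truth, landmark_points(anatomy$landmarks),
                                    outside = "zero"),
                        names = anatomy$landmarks$name)
  structure(list(ct = ct, mr = mr$mr, ct_labels = anatomy$labels,
                 mr_labels = mr$labels, ct_landmarks = anatomy$landmarks,
                 mr_landmarks = mr_lm, truth = truth, seed = seed,
                 model_mismatch = model_mismatch),
            class = "phantom_case")
}

# 1-2-1 smoothing of control coefficients along each grid axis
smooth_grid_coef <- function(coef) {
  d <- dim(coef)
  for (ax in 1:3) {
    n <- d[ax]
    lo <- c(1L, seq_len(n - 1L))
    hi <- c(seq_len(n)[-1L], n)
    idx <- function(ord) {
      sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), seq_len(d[4]))
      sel[[ax]] <- ord
      coef[sel[[1]], sel[[2]], sel[[3]], sel[[4]], drop = FALSE]
    }
    coef <- (idx(lo) + 2 * coef + idx(hi)) / 4
  }
  coef
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d\n  CT %s @ %s mm | MR %s @ %s mm\n",
              x$seed, paste(dim(x$ct$data), collapse = "x"),
              paste(format(x$ct$spacing), collapse = "x"),
              paste(dim(x$mr$data), collapse = "x"),
              paste(format(x$mr$spacing), collapse = "x")))
  r <- x$truth$rigid
  cat(sprintf("  truth: |t| = %.2f mm, max |FFD coef| = %.2f mm\n",
              sqrt(sum(r$translation^2)),
              if (is.null(x$truth$ffd)) 0 else max(abs(x$truth$ffd$coefficients))))
  invisible(x)
}
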