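#' Optimizer step-size schedule entry
#'
#' One multiresolution level: the per-axis downsampling factor, the number
#' of steepest-descent iterations, and the parameters of the decaying gain
#' sequence `step(k) = a / (A + k + 1)^alpha`.
#'
#' @param factor integer >= 1 downsampling per axis.
#' @param iterations integer > 0.
#' @param a,A,alpha gain-rule scalars: `a > 0`, `A >= 0`, `0 < alpha <= 1`.
#' @return list of class `"schedule_entry"`.
#' @export
schedule_entry <- function(factor, iterations, a, A = 50, alpha = 0.6) {
  factor <- as.integer(factor)
  iterations <- as.integer(iterations)
  if (factor < 1L) stop("config error: factor must be >= 1", call. = FALSE)
  if (iterations <= 0L) stop("config error: iterations must be > 0", call. = FALSE)
  if (!(a > 0)) stop("config error: a must be > 0", call. = FALSE)
  if (A < 0) stop("config error: A must be >= 0", call. = FALSE)
  if (!(alpha > 0 && alpha <= 1))
    stop("config error: alpha must be in (0, 1]", call. = FALSE)
  structure(list(factor = factor, iterations = iterations, a = a, A = A,
                 alpha = alpha),
            class = "schedule_entry")
}

#' Decaying optimizer gain
#'
#' `step(k) = a / (A + k + 1)^alpha`, the standard decaying gain sequence
#' for stochastic steepest descent: large steps at the start, strictly
#' decreasing with the iteration index `k` (0-based).
#'
#' @param k iteration index, `>= 0` (vectorized).
#' @param a,A,alpha gain parameters as in [schedule_entry()].
#' @return step size(s).
#' @examples
#' step_size(0, a = 4000, A = 50, alpha = 0.6)  # 4000 / 51^0.6
#' @export
step_size <- function(k, a, A = 50, alpha = 0.6) {
  schedule_entry(1, 1, a = a, A = A, alpha = alpha)  # parameter validation
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  a / (A + k + 1)^alpha
}

#' Registration configuration
#'
#' Default values are the tuned whole-body MR-to-CT settings: five rigid
#' levels (factors 16, 8, 4, 2, 1; `a = 4000`, `A = 50`, `alpha = 0.6`) and
#' five elastic levels (factors 8, 4, 4, 2, 2; per-level
#' `a = 2000, 7000, 20000, 20000, 30000`, `alpha = 0.602`), iterations
#' 4096, 2048, 1024, 512, 256 per stage (7936 in total, about 8000), a
#' 32-bin NMI metric with 5000 random samples per rigid iteration and 4096
#' per elastic iteration, a control grid of 8 fixed-image voxels, 5000
#' randomly selected control points updated per iteration, trilinear
#' interpolation of the moving image during optimization and cubic
#' B-spline interpolation for the final resampling.
#'
#' @param rigid_schedule,elastic_schedule lists of [schedule_entry()]s.
#' @param bins histogram bins per axis.
#' @param samples_rigid,samples_elastic random metric samples per iteration.
#' @param grid_spacing_voxels control-point spacing in fixed-image voxels.
#' @param control_points_per_iter number of randomly selected control
#'   points updated per elastic iteration (all of them when the grid is
#'   smaller).
#' @param interim_order,final_order moving-image interpolation orders
#'   during optimization and for the final resampling (1 or 3).
#' @param seed integer seed governing all random sampling.
#' @param default_intensity intensity for resampled voxels falling outside
#'   the moving volume; `NULL` means the moving image minimum (air).
#' @return list of class `"reg_config"`.
#' @export
reg_config <- function(rigid_schedule = NULL, elastic_schedule = NULL,
                       bins = 32L, samples_rigid = 5000L,
                       samples_elastic = 4096L, grid_spacing_voxels = 8,
                       control_points_per_iter = 5000L, interim_order = 1L,
                       final_order = 3L, seed = 1L,
                       default_intensity = NULL) {
  if (is.null(rigid_schedule)) {
    f <- c(16L, 8L, 4L, 2L, 1L)
    it <- c(4096L, 2048L, 1024L, 512L, 256L)
    rigid_schedule <- Map(schedule_entry, f, it, a = 4000, A = 50, alpha = 0.6)
  }
  if (is.null(elastic_schedule)) {
    f <- c(8L, 4L, 4L, 2L, 2L)
    it <- c(4096L, 2048L, 1024L, 512L, 256L)
    a <- c(2000, 7000, 20000, 20000, 30000)
    elastic_schedule <- Map(schedule_entry, f, it, a = a, A = 50, alpha = 0.602)
  }
  stopifnot(all(vapply(rigid_schedule, inherits, TRUE, "schedule_entry")),
            all(vapply(elastic_schedule, inherits, TRUE, "schedule_entry")))
  if (!interim_order %in% c(1L, 3L) || !final_order %in% c(1L, 3L))
    stop("config error: interpolation orders must be 1 or 3", call. = FALSE)
  structure(list(rigid_schedule = rigid_schedule,
                 elastic_schedule = elastic_schedule,
                 bins = as.integer(bins),
                 samples_rigid = as.integer(samples_rigid),
                 samples_elastic = as.integer(samples_elastic),
                 grid_spacing_voxels = grid_spacing_voxels,
                 control_points_per_iter = as.integer(control_points_per_iter),
                 interim_order = as.integer(interim_order),
                 final_order = as.integer(final_order),
                 seed = as.integer(seed),
                 default_intensity = default_intensity),
            class = "reg_config")
}

#' Scaled-down phantom study configuration
#'
#' The registration configuration used for the package's 64^3 phantom
#' experiments: the published whole-body schedule scaled to the phantom's
#' problem size.  The coarsest rigid level (factor 16) is dropped because
#' a 4^3 image carries no usable structure; iteration counts are scaled to
#' the smaller volume; the elastic gains were calibrated once on the
#' phantom (the same step-size calibration-by-repetition the full-scale
#' protocol uses), since raw NMI gradient magnitudes depend on image size
#' and content.  Histogram, sampling, grid-spacing and interpolation
#' settings are the published defaults of [reg_config()].
#'
#' @param seed integer seed.
#' @return a [reg_config()].
#' @export
phantom_config <- function(seed = 1L) {
  reg_config(
    rigid_schedule = list(schedule_entry(8, 300, a = 4000),
                          schedule_entry(4, 200, a = 4000),
                          schedule_entry(2, 150, a = 4000),
                          schedule_entry(1, 100, a = 4000)),
    elastic_schedule = list(schedule_entry(4, 200, a = 500, alpha = 0.602),
                            schedule_entry(2, 150, a = 1500, alpha = 0.602),
                            schedule_entry(2, 100, a = 3000, alpha = 0.602)),
    seed = seed)
}

#' @export
print.reg_config <- function(x, ...) {
  sched <- function(s)
    paste(vapply(s, function(e) sprintf("%dx(%d it, a=%g)", e$factor,
                                        e$iterations, e$a), ""), collapse = " ")
  cat("<reg_config>\n")
  cat("  rigid:  ", sched(x$rigid_schedule), "\n")
  cat("  elastic:", sched(x$elastic_schedule), "\n")
  cat(sprintf("  %d bins, %d/%d samples, grid %g voxels, seed %d\n", x$bins,
              x$samples_rigid, x$samples_elastic, x$grid_spacing_voxels, x$seed))
  invisible(x)
}

#' Multiresolution pyramid level
#'
#' Gaussian smoothing (sigma = factor/2 voxels per axis) followed by
#' subsampling by `factor` per axis.  Factor 1 returns the original,
#' unsmoothed volume so the finest level sees full resolution.
#'
#' @param vol a [volume()].
#' @param factor integer >= 1.
#' @return a [volume()] with spacing multiplied by `factor`.
#' @export
build_pyramid <- function(vol, factor) {
  stopifnot(is_volume(vol))
  factor <- as.integer(factor)
  if (factor < 1L) stop("config error: factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(vol)
  if (any(factor > dim(vol$data)))
    stop("config error: pyramid factor exceeds an axis extent", call. = FALSE)
  sm <- cpp_gauss_smooth(as.vector(vol$data), dim(vol$data), factor / 2)
  arr <- array(sm, dim(vol$data))
  idx <- lapply(dim(vol$data), function(n) seq(1L, n, by = factor))
  volume(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         spacing = vol$spacing * factor, origin = vol$origin)
}

# intensity-weighted center of mass (weights shifted to be nonnegative)
center_of_mass <- function(vol) {
  w <- vol$data - min(vol$data)
  tw <- sum(w)
  if (tw <= 0) return(volume_center(vol))
  d <- dim(vol$data)
  cx <- sum(rowSums(w, dims = 1) * (seq_len(d[1]) - 1))
  iy <- colSums(w, dims = 1)          # d2 x d3
  cy <- sum(rowSums(iy) * (seq_len(d[2]) - 1))
  cz <- sum(colSums(iy) * (seq_len(d[3]) - 1))
  vol$origin + c(cx, cy, cz) / tw * vol$spacing
}

new_trace <- function() {
  list(level = integer(0), k = integer(0), value = numeric(0),
       step = numeric(0), gnorm = numeric(0))
}

trace_df <- function(tr) {
  data.frame(level = tr$level, k = tr$k, value = tr$value, step = tr$step,
             gnorm = tr$gnorm)
}

#' Rigid registration stage
#'
#' Multiresolution stochastic steepest ascent on NMI over the six rigid
#' parameters.  Each iteration draws a fresh set of random sample points,
#' evaluates the analytic NMI gradient and takes a step with the decaying
#' gain of the level's [schedule_entry()].  Rotation gradients are scaled
#' by the squared half-diagonal of the fixed image so rotations and
#' translations move corner voxels by comparable amounts.
#'
#' @param fixed,moving [volume()]s (fixed = target/CT, moving = source/MR).
#' @param config a [reg_config()].
#' @param init optional initial [rigid_transform()]; its center is kept.
#' @param verbose print per-level progress.
#' @return a [rigid_transform()] with attribute `"trace"` (data.frame of
#'   the metric value, step size and gradient norm at every iteration).
#' @export
register_rigid <- function(fixed, moving, config = reg_config(), init = NULL,
                           verbose = FALSE) {
  stopifnot(is_volume(fixed), is_volume(moving))
  set.seed(config$seed)
  center <- center_of_mass(fixed)
  par <- if (is.null(init)) rep(0, 6) else c(init$rotation, init$translation)
  if (!is.null(init)) center <- init$center
  e <- volume_extent(fixed)
  halfdiag <- sqrt(sum(((e[2, ] - e[1, ]) / 2)^2))
  tr <- new_trace()
  for (lev in seq_along(config$rigid_schedule)) {
    sch <- config$rigid_schedule[[lev]]
    fpyr <- build_pyramid(fixed, sch$factor)
    mpyr <- build_pyramid(moving, sch$factor)
    if (config$interim_order == 3L) mpyr <- prefilter_volume(mpyr)
    frange <- intensity_range(fpyr)
    mrange <- intensity_range(mpyr)
    for (k in seq_len(sch$iterations) - 1L) {
      pts <- sample_points(fpyr, config$samples_rigid)
      chain <- transform_chain(rigid_transform(par[4:6], par[1:3], center))
      res <- metric_call(fpyr, mpyr, chain, pts, config$bins, frange, mrange,
                         config$interim_order, 1L)
      if (res$used < 2 || is.null(res$grad)) {
        if (k == 0L && lev == 1L)
          stop("registration error: degenerate metric at start (no overlap?)",
               call. = FALSE)
        next
      }
      g <- res$grad
      st <- step_size(k, sch$a, sch$A, sch$alpha)
      par[1:3] <- par[1:3] + st * g[1:3] / halfdiag^2
      par[4:6] <- par[4:6] + st * g[4:6]
      tr$level <- c(tr$level, lev); tr$k <- c(tr$k, k)
      tr$value <- c(tr$value, res$value); tr$step <- c(tr$step, st)
      tr$gnorm <- c(tr$gnorm, sqrt(sum(g^2)))
    }
    if (verbose)
      message(sprintf("rigid level %d (factor %d): NMI %.5f", lev, sch$factor,
                      tr$value[length(tr$value)]))
  }
  out <- rigid_transform(par[4:6], par[1:3], center)
  attr(out, "trace") <- trace_df(tr)
  out
}

#' B-spline deformable registration stage
#'
#' Multiresolution stochastic steepest ascent on NMI over the free-form
#' deformation coefficients, starting from a rigid pre-alignment.  The
#' control grid (default spacing: 8 fixed-image voxels) is shared across
#' levels and covers the rigidly mapped fixed domain with one spare
#' control cell on each side.  Each iteration draws fresh random metric
#' samples and updates a random subset of control points.
#'
#' @inheritParams register_rigid
#' @param init the rigid pre-alignment ([rigid_transform()]).
#' @return a [transform_chain()] with attribute `"trace"`.
#' @export
register_bspline <- function(fixed, moving, init, config = reg_config(),
                             verbose = FALSE) {
  stopifnot(is_volume(fixed), is_volume(moving),
            inherits(init, "rigid_transform"))
  if (any(!is.finite(c(init$translation, init$rotation))))
    stop("registration error: non-finite initial rigid transform", call. = FALSE)
  set.seed(config$seed + 1L)
  e <- volume_extent(fixed)
  corners <- as.matrix(expand.grid(e[, 1], e[, 2], e[, 3]))
  mapped <- rigid_apply(init, corners)
  gspc <- config$grid_spacing_voxels * fixed$spacing
  grid <- grid_covering(apply(mapped, 2, min), apply(mapped, 2, max), gspc)
  coef <- grid$coefficients
  ncp <- prod(grid$shape)
  nsub <- min(config$control_points_per_iter, ncp)
  tr <- new_trace()
  for (lev in seq_along(config$elastic_schedule)) {
    sch <- config$elastic_schedule[[lev]]
    fpyr <- build_pyramid(fixed, sch$factor)
    mpyr <- build_pyramid(moving, sch$factor)
    if (config$interim_order == 3L) mpyr <- prefilter_volume(mpyr)
    frange <- intensity_range(fpyr)
    mrange <- intensity_range(mpyr)
    for (k in seq_len(sch$iterations) - 1L) {
      pts <- sample_points(fpyr, config$samples_elastic)
      chain <- transform_chain(init, bspline_grid(grid$shape, grid$spacing,
                                                  grid$origin, coef))
      res <- metric_call(fpyr, mpyr, chain, pts, config$bins, frange, mrange,
                         config$interim_order, 2L)
      if (res$used < 2 || is.null(res$grad)) next
      g <- array(res$grad, c(grid$shape, 3L))
      st <- step_size(k, sch$a, sch$A, sch$alpha)
      if (nsub < ncp) {
        sel <- sample.int(ncp, nsub)
        mask <- array(FALSE, grid$shape)
        mask[sel] <- TRUE
        upd <- array(0, c(grid$shape, 3L))
        for (cc in 1:3) upd[, , , cc] <- ifelse(mask, g[, , , cc], 0)
        coef <- coef + st * upd
      } else {
        coef <- coef + st * g
      }
      tr$level <- c(tr$level, lev); tr$k <- c(tr$k, k)
      tr$value <- c(tr$value, res$value); tr$step <- c(tr$step, st)
      tr$gnorm <- c(tr$gnorm, sqrt(sum(g^2)))
    }
    if (verbose)
      message(sprintf("elastic level %d (factor %d): NMI %.5f", lev, sch$factor,
                      tr$value[length(tr$value)]))
  }
  out <- transform_chain(init, bspline_grid(grid$shape, grid$spacing,
                                            grid$origin, coef))
  attr(out, "trace") <- trace_df(tr)
  out
}

#' Resample a moving volume onto a reference grid
#'
#' Each output voxel reads the moving image at `chain_apply(voxel center)`
#' with the requested B-spline interpolation order (0 = nearest neighbour,
#' for label volumes; 1 = trilinear; 3 = cubic with prefiltering).  Voxels
#' mapping outside the moving volume take `default_value`.
#'
#' @param moving a [volume()].
#' @param chain a [transform_chain()].
#' @param reference a [volume()] or [label_volume()] providing the output
#'   grid.
#' @param order 0, 1 or 3.
#' @param default_value intensity for out-of-volume voxels; defaults to
#'   the moving-image minimum.
#' @return a [volume()] on the reference grid.
#' @export
resample <- function(moving, chain, reference, order = 3L,
                     default_value = NULL) {
  stopifnot(is_volume(moving), inherits(chain, "transform_chain"))
  order <- as.integer(order)
  if (!order %in% c(0L, 1L, 3L))
    stop("order must be 0, 1 or 3", call. = FALSE)
  geo <- as_geometry(reference)
  if (is.null(default_value)) default_value <- min(moving$data)
  marr <- if (order == 3L) attr_prefiltered(moving) else as.vector(moving$data)
  has <- !is.null(chain$ffd)
  g <- chain$ffd
  out <- cpp_resample(marr, dim(moving$data), moving$spacing, moving$origin,
                      geo$dim, geo$spacing, geo$origin,
                      chain$rigid$rotation, chain$rigid$center,
                      chain$rigid$translation, has,
                      if (has) as.vector(g$coefficients) else numeric(0),
                      if (has) g$shape else integer(3),
                      if (has) g$spacing else rep(1, 3),
                      if (has) g$origin else rep(0, 3),
                      order, default_value)
  volume(array(out, geo$dim), spacing = geo$spacing, origin = geo$origin)
}

#' Two-stage whole-body registration
#'
#' The full pipeline: rigid pre-alignment followed by B-spline free-form
#' deformation, both multiresolution stochastic steepest ascent on
#' normalized mutual information, then a final cubic resampling of the
#' moving image onto the fixed grid.
#'
#' @param fixed target [volume()] (CT in the whole-body protocol).
#' @param moving source [volume()] (MR) to be deformed onto `fixed`.
#' @param config a [reg_config()].
#' @param rigid_only skip the deformable stage.
#' @param verbose print per-level progress.
#' @return An object of class `"nmi_registration"`: list with the fitted
#'   `chain` ([transform_chain()]), the `registered` volume on the fixed
#'   grid, per-stage optimization `trace`s, and the `config`.
#' @seealso [predict.nmi_registration()], [residuals.nmi_registration()]
#' @export
nmi_register <- function(fixed, moving, config = reg_config(),
                         rigid_only = FALSE, verbose = FALSE) {
  stopifnot(is_volume(fixed), is_volume(moving))
  rigid <- register_rigid(fixed, moving, config, verbose = verbose)
  if (rigid_only) {
    chain <- transform_chain(rigid)
    elastic_trace <- NULL
  } else {
    chain <- register_bspline(fixed, moving, rigid, config, verbose = verbose)
    elastic_trace <- attr(chain, "trace")
    attr(chain, "trace") <- NULL
  }
  registered <- resample(moving, chain, fixed, order = config$final_order,
                         default_value = config$default_intensity)
  structure(list(chain = chain, registered = registered,
                 rigid_trace = attr(rigid, "trace"),
                 elastic_trace = elastic_trace, config = config,
                 fixed_geometry = as_geometry(fixed),
                 call = match.call()),
            class = "nmi_registration")
}

#' @export
print.nmi_registration <- function(x, ...) {
  cat("Two-stage NMI registration\n")
  r <- x$chain$rigid
  cat(sprintf("  rigid: translation (%s) mm, rotation (%s) deg\n",
              paste(format(r$translation, digits = 3), collapse = ", "),
              paste(format(r$rotation * 180 / pi, digits = 3), collapse = ", ")))
  if (!is.null(x$chain$ffd))
    cat(sprintf("  FFD: %s control points, max displacement %.2f mm\n",
                paste(x$chain$ffd$shape, collapse = "x"),
                max(abs(x$chain$ffd$coefficients))))
  v <- if (!is.null(x$elastic_trace)) x$elastic_trace$value else x$rigid_trace$value
  cat(sprintf("  final NMI %.5f after %d+%d iterations\n", v[length(v)],
              nrow(x$rigid_trace),
              if (is.null(x$elastic_trace)) 0L else nrow(x$elastic_trace)))
  invisible(x)
}

#' @export
summary.nmi_registration <- function(object, ...) {
  print(object)
  cat("\nRigid stage trace (last iteration per level):\n")
  tr <- object$rigid_trace
  print(do.call(rbind, lapply(split(tr, tr$level), function(d) d[nrow(d), ])))
  if (!is.null(object$elastic_trace)) {
    cat("\nElastic stage trace (last iteration per level):\n")
    tr <- object$elastic_trace
    print(do.call(rbind, lapply(split(tr, tr$level), function(d) d[nrow(d), ])))
  }
  invisible(object)
}

#' @export
coef.nmi_registration <- function(object, ...) {
  r <- object$chain$rigid
  out <- c(rx = r$rotation[1], ry = r$rotation[2], rz = r$rotation[3],
           tx = r$translation[1], ty = r$translation[2], tz = r$translation[3])
  if (!is.null(object$chain$ffd))
    attr(out, "ffd_coefficients") <- object$chain$ffd$coefficients
  out
}

#' Map points or resample a volume through a fitted registration
#'
#' @param object an [nmi_register()] fit.
#' @param newdata an n x 3 matrix of fixed-domain physical points (mapped
#'   through the chain), a [volume()] (resampled onto the fixed grid), or
#'   `NULL` (returns the stored registered volume).
#' @param order interpolation order when resampling.
#' @param ... unused.
#' @return mapped points or a resampled [volume()].
#' @export
predict.nmi_registration <- function(object, newdata = NULL, order = 3L, ...) {
  if (is.null(newdata)) return(object$registered)
  if (is_volume(newdata)) {
    geo <- object$fixed_geometry
    ref <- volume(array(0, geo$dim), geo$spacing, geo$origin)
    return(resample(newdata, object$chain, ref, order = order))
  }
  chain_apply(object$chain, newdata, outside = "zero")
}

#' Landmark residuals of a fitted registration
#'
#' Maps the fixed-space landmarks through the fitted chain and returns the
#' Euclidean distances to their moving-space counterparts (mm).
#'
#' @param object an [nmi_register()] fit.
#' @param fixed_landmarks,moving_landmarks paired [landmark_set()]s.
#' @param ... unused.
#' @return named numeric vector of distances, mm.
#' @export
residuals.nmi_registration <- function(object, fixed_landmarks,
                                       moving_landmarks, ...) {
  le <- landmark_errors(fixed_landmarks, moving_landmarks,
                        chain = object$chain)
  stats::setNames(le$error_mm, le$name)
}

#' Plot the optimization trace of a registration
#'
#' NMI metric value against iteration, one panel per stage, with level
#' boundaries marked.
#'
#' @param x an [nmi_register()] fit.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.nmi_registration <- function(x, ...) {
  traces <- Filter(Negate(is.null),
                   list(rigid = x$rigid_trace, elastic = x$elastic_trace))
  op <- graphics::par(mfrow = c(1, length(traces)))
  on.exit(graphics::par(op))
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    plot(seq_len(nrow(tr)), tr$value, type = "l", xlab = "iteration",
         ylab = "NMI", main = paste(nm, "stage"), ...)
    graphics::abline(v = cumsum(rle(tr$level)$lengths), lty = 3)
  }
  invisible(x)
}
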