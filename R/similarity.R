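#' Robust intensity range for histogram binning
#'
#' The binning range used by the NMI metric: the 0.5th-99.5th intensity
#' percentiles, which keeps a handful of extreme voxels (metal, spikes)
#' from stretching the histogram.  Fixed once per resolution level.
#'
#' @param vol a [volume()].
#' @param probs lower/upper percentile probabilities.
#' @return length-2 numeric range.
#' @export
intensity_range <- function(vol, probs = c(0.005, 0.995)) {
  stopifnot(is_volume(vol))
  r <- as.numeric(quantile(vol$data, probs = probs, names = FALSE))
  if (r[2] <= r[1]) r[2] <- r[1] + 1e-6
  r
}

#' Draw uniform random sample points in a volume's physical domain
#'
#' Uses R's RNG, so sampling is reproducible under `set.seed()`.
#'
#' @param vol a [volume()].
#' @param n number of points.
#' @return n x 3 matrix of physical coordinates (mm).
#' @export
sample_points <- function(vol, n) {
  e <- volume_extent(vol)
  cbind(runif(n, e[1, 1], e[2, 1]),
        runif(n, e[1, 2], e[2, 2]),
        runif(n, e[1, 3], e[2, 3]))
}

metric_call <- function(fixed, moving, chain, points, bins, fixed_range,
                        moving_range, order, grad_mode) {
  has <- !is.null(chain$ffd)
  g <- chain$ffd
  marr <- moving$data
  if (order == 3) marr <- attr_prefiltered(moving)
  cpp_nmi_metric(as.vector(fixed$data), dim(fixed$data), fixed$spacing,
                 fixed$origin, as.vector(marr), dim(moving$data),
                 moving$spacing, moving$origin, as.integer(order),
                 points, chain$rigid$rotation, chain$rigid$center,
                 chain$rigid$translation, has,
                 if (has) as.vector(g$coefficients) else numeric(0),
                 if (has) g$shape else integer(3),
                 if (has) g$spacing else rep(1, 3),
                 if (has) g$origin else rep(0, 3),
                 as.integer(bins), fixed_range, moving_range,
                 as.integer(grad_mode))
}

# cache the cubic-interpolation prefilter on the volume object
attr_prefiltered <- function(vol) {
  pf <- attr(vol, "prefiltered")
  if (is.null(pf))
    pf <- cpp_bspline_prefilter(as.vector(vol$data), dim(vol$data))
  pf
}

prefilter_volume <- function(vol) {
  attr(vol, "prefiltered") <- cpp_bspline_prefilter(as.vector(vol$data),
                                                    dim(vol$data))
  vol
}

#' Joint intensity histogram from random spatial samples
#'
#' For each sample point the fixed intensity is read at the point and the
#' moving intensity is interpolated at `chain_apply(point)`.  The pair is
#' deposited with a cubic B-spline Parzen window along the moving axis and
#' a linear window along the fixed axis, so the histogram is differentiable
#' in the transform parameters and its total mass equals the number of
#' usable samples exactly.  Samples mapping outside the moving volume (or
#' outside the FFD support) are skipped and counted.
#'
#' @param fixed,moving [volume()]s.
#' @param chain a [transform_chain()] mapping fixed to moving coordinates.
#' @param points n x 3 matrix of fixed-domain sample points (mm), e.g. from
#'   [sample_points()].
#' @param bins number of bins per axis (>= 2); 32 by default.
#' @param order interpolation order for the moving image: 1 (trilinear) or
#'   3 (cubic B-spline).
#' @param fixed_range,moving_range intensity ranges used for binning;
#'   default [intensity_range()] of each volume.
#' @param window `"parzen"` (the default, differentiable: cubic B-spline
#'   window on the moving axis, linear on the fixed axis) or `"nearest"`
#'   (exact counting: each pair lands in a single cell, so identical
#'   discretized volumes give a diagonal histogram and NMI exactly 2).
#' @return A `"joint_histogram"`: list with `counts` (bins x bins, fixed
#'   intensities on rows), the ranges, `used` and `skipped` sample counts.
#' @export
build_joint_histogram <- function(fixed, moving, chain, points, bins = 32L,
                                  order = 1L, fixed_range = NULL,
                                  moving_range = NULL,
                                  window = c("parzen", "nearest")) {
  stopifnot(is_volume(fixed), is_volume(moving),
            inherits(chain, "transform_chain"))
  window <- match.arg(window)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  if (is.null(fixed_range)) fixed_range <- intensity_range(fixed)
  if (is.null(moving_range)) moving_range <- intensity_range(moving)
  pts <- rbind_points(points)
  if (window == "nearest") {
    fres <- cpp_interp_points(as.vector(fixed$data), dim(fixed$data),
                              fixed$spacing, fixed$origin, pts, 1L, 0)
    y <- chain_apply(chain, pts, outside = "zero")
    marr <- if (order == 3L) attr_prefiltered(moving) else as.vector(moving$data)
    mres <- cpp_interp_points(marr, dim(moving$data), moving$spacing,
                              moving$origin, y, as.integer(order), 0)
    ok <- fres$inside & mres$inside
    used <- sum(ok)
    skipped <- nrow(pts) - used
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    iF <- round(clamp01((fres$values[ok] - fixed_range[1]) /
                          diff(fixed_range)) * (bins - 1))
    iM <- round(clamp01((mres$values[ok] - moving_range[1]) /
                          diff(moving_range)) * (bins - 1))
    counts <- matrix(tabulate(1L + iF + bins * iM, nbins = bins * bins),
                     bins, bins)
    res <- list(hist = counts, used = used, skipped = skipped)
  } else {
    res <- metric_call(fixed, moving, chain, pts, bins, fixed_range,
                       moving_range, order, 0L)
  }
  if (res$used < 2)
    stop("degenerate sample: fewer than 2 usable sample points", call. = FALSE)
  if (res$skipped > 0.8 * nrow(pts))
    stop("metric invalid: more than 80% of samples fall outside the moving volume",
         call. = FALSE)
  structure(list(counts = res$hist, fixed_range = fixed_range,
                 moving_range = moving_range, used = res$used,
                 skipped = res$skipped, window = window),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> %dx%d bins, %d samples (%d skipped), NMI %.4f\n",
              nrow(x$counts), ncol(x$counts), x$used, x$skipped, nmi(x)))
  invisible(x)
}

#' Normalized mutual information of a joint histogram
#'
#' `NMI = (H_fixed + H_moving) / H_joint`, entropies in nats computed from
#' the normalized histogram; empty bins contribute zero.  NMI lies in
#' `[1, 2]`: 1 for independent marginals, 2 for identical discretized
#' images.  A histogram whose entire mass sits in a single cell has zero
#' joint entropy and returns the defined degenerate value 2.
#'
#' @param h a [build_joint_histogram()] result, or a plain counts matrix.
#' @return scalar NMI.
#' @export
nmi <- function(h) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  total <- sum(counts)
  if (total <= 0) stop("histogram has no mass", call. = FALSE)
  p <- counts / total
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  hj <- ent(p)
  if (hj == 0) return(2)
  (ent(rowSums(p)) + ent(colSums(p))) / hj
}

#' Analytic gradient of NMI with respect to transform parameters
#'
#' Differentiates the Parzen-window joint histogram through the
#' moving-image interpolant (chain rule).  For `wrt = "rigid"` the chain
#' must be rigid-only and the result is the 6-vector
#' `d(NMI)/d(rx, ry, rz, tx, ty, tz)`.  For `wrt = "ffd"` the result has
#' the shape of the coefficient array `grid shape x 3`.
#'
#' @inheritParams build_joint_histogram
#' @param wrt `"rigid"` or `"ffd"`.
#' @return gradient vector/array; attribute `"value"` carries the NMI.
#' @export
nmi_gradient <- function(fixed, moving, chain, points, wrt = c("rigid", "ffd"),
                         bins = 32L, order = 1L, fixed_range = NULL,
                         moving_range = NULL) {
  wrt <- match.arg(wrt)
  stopifnot(is_volume(fixed), is_volume(moving),
            inherits(chain, "transform_chain"))
  if (wrt == "ffd" && is.null(chain$ffd))
    stop("chain has no FFD to differentiate", call. = FALSE)
  if (is.null(fixed_range)) fixed_range <- intensity_range(fixed)
  if (is.null(moving_range)) moving_range <- intensity_range(moving)
  res <- metric_call(fixed, moving, chain, rbind_points(points), bins,
                     fixed_range, moving_range, order,
                     if (wrt == "rigid") 1L else 2L)
  if (res$used < 2 || is.null(res$grad))
    stop("degenerate histogram: gradient unavailable", call. = FALSE)
  grad <- res$grad
  if (wrt == "rigid") {
    names(grad) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  } else {
    grad <- array(grad, c(chain$ffd$shape, 3L))
  }
  attr(grad, "value") <- res$value
  grad
}
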