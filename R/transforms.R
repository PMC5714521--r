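#' Six-parameter rigid transform
#'
#' Maps a physical point `p` to `R (p - center) + center + translation`,
#' where `R` is the Euler rotation composed in fixed axis order X, then Y,
#' then Z.  The rotation center is a convention of the package (the
#' registration driver uses the fixed image's center of mass) and is not an
#' optimized parameter.
#'
#' @param translation length-3 numeric, mm.
#' @param rotation length-3 numeric, Euler angles in radians (about X, Y, Z).
#' @param center length-3 numeric, rotation center in mm.
#' @return An object of class `"rigid_transform"`.
#' @examples
#' t <- rigid_transform(rotation = c(0, 0, pi / 2))
#' rigid_apply(t, c(1, 0, 0))  # ~ (0, 1, 0)
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(rotation) == 3, length(center) == 3)
  if (any(!is.finite(c(translation, rotation, center))))
    stop("rigid parameters must be finite", call. = FALSE)
  structure(list(translation = translation, rotation = rotation,
                 center = center),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation) {
  cx <- cos(rotation[1]); sx <- sin(rotation[1])
  cy <- cos(rotation[2]); sy <- sin(rotation[2])
  cz <- cos(rotation[3]); sz <- sin(rotation[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to physical points
#'
#' @param t a [rigid_transform()].
#' @param p length-3 point or n x 3 matrix, mm.
#' @return mapped point(s), same shape as `p`.
#' @export
rigid_apply <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  pts <- rbind_points(p)
  R <- rotation_matrix(t$rotation)
  out <- t(R %*% (t(pts) - t$center) + t$center + t$translation)
  drop_points(out, p)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> translation (%s) mm, rotation (%s) rad, center (%s) mm\n",
              paste(format(x$translation, digits = 4), collapse = ", "),
              paste(format(x$rotation, digits = 4), collapse = ", "),
              paste(format(x$center, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Cubic B-spline basis weights
#'
#' The four cubic B-spline basis values at fractional offset `u` in
#' `[0, 1)`, weighting the control points at cell offsets -1, 0, +1, +2.
#' The weights are a partition of unity.
#'
#' @param u numeric in `[0, 1)` (vectorized).
#' @return length-4 vector, or n x 4 matrix for vector input.
#' @examples
#' bspline_weights(0)    # 1/6, 4/6, 1/6, 0
#' bspline_weights(0.5)  # 1/48, 23/48, 23/48, 1/48
#' @export
bspline_weights <- function(u) {
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)", call. = FALSE)
  w <- cbind((1 - u)^3 / 6,
             (3 * u^3 - 6 * u^2 + 4) / 6,
             (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
             u^3 / 6)
  if (length(u) == 1) as.numeric(w) else w
}

#' Cubic B-spline free-form deformation grid
#'
#' A uniform control-point lattice carrying one 3-vector displacement
#' coefficient (mm) per node.  The displacement at a physical point is the
#' tensor-product cubic B-spline sum over its 4x4x4 control-point
#' neighborhood, so the grid must extend at least one node beyond the
#' domain it deforms on every side.
#'
#' @param shape integer length-3, number of control points per axis (>= 4).
#' @param spacing length-3 numeric, control-point spacing in mm.
#' @param origin length-3 numeric, physical position of control point
#'   `(0,0,0)` in mm.
#' @param coefficients 4D numeric array `shape x 3` of displacement
#'   coefficients (mm); defaults to all zero (identity field).
#' @return An object of class `"bspline_grid"`.
#' @export
bspline_grid <- function(shape, spacing, origin, coefficients = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 4L))
    stop("grid shape must be >= 4 per axis (cubic support)", call. = FALSE)
  if (any(spacing <= 0)) stop("grid spacing must be positive", call. = FALSE)
  if (is.null(coefficients)) coefficients <- array(0, c(shape, 3L))
  coefficients <- as.array(coefficients)
  if (!identical(dim(coefficients), c(shape, 3L)))
    stop("coefficients must have dim c(shape, 3)", call. = FALSE)
  storage.mode(coefficients) <- "double"
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 coefficients = coefficients),
            class = "bspline_grid")
}

#' @export
print.bspline_grid <- function(x, ...) {
  cat(sprintf("<bspline_grid> %s control points, spacing %s mm, max |disp| %.3g mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              max(abs(x$coefficients))))
  invisible(x)
}

# Build a grid whose full-support region covers the physical box
# [lower, upper] with one spare control cell on each side.
grid_covering <- function(lower, upper, spacing) {
  n <- pmax(ceiling((upper - lower) / spacing) + 4L, 4L)
  origin <- lower - spacing  # control point index 1 sits at `lower`
  bspline_grid(shape = as.integer(n), spacing = spacing, origin = origin)
}

#' Evaluate the FFD displacement field
#'
#' @param g a [bspline_grid()].
#' @param p length-3 point or n x 3 matrix of physical points (mm); every
#'   point must lie inside the grid's full-support region.
#' @return displacement(s) in mm, same shape as `p`.
#' @export
ffd_displacement <- function(g, p) {
  stopifnot(inherits(g, "bspline_grid"))
  pts <- rbind_points(p)
  res <- cpp_ffd_points(as.vector(g$coefficients), g$shape, g$spacing,
                        g$origin, pts)
  if (!all(res$inside))
    stop("point outside the B-spline grid support", call. = FALSE)
  drop_points(res$disp, p)
}

#' Two-stage transform chain (rigid then free-form)
#'
#' The resampling-direction transform: maps fixed-domain physical points
#' into the moving domain.  A point `p` is first mapped rigidly to
#' `q = rigid(p)`; the B-spline displacement field, defined in that rigidly
#' aligned frame, is then added: `chain(p) = q + d(q)`.
#'
#' @param rigid a [rigid_transform()].
#' @param ffd a [bspline_grid()] or `NULL` for a rigid-only chain.
#' @return An object of class `"transform_chain"`.
#' @export
transform_chain <- function(rigid = rigid_transform(), ffd = NULL) {
  stopifnot(inherits(rigid, "rigid_transform"))
  if (!is.null(ffd)) stopifnot(inherits(ffd, "bspline_grid"))
  structure(list(rigid = rigid, ffd = ffd), class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("<transform_chain>\n  ")
  print(x$rigid)
  if (is.null(x$ffd)) cat("  (no free-form deformation)\n") else { cat("  "); print(x$ffd) }
  invisible(x)
}

#' Map fixed-domain points through a transform chain
#'
#' @param chain a [transform_chain()].
#' @param p length-3 point or n x 3 matrix (mm).
#' @param outside how to treat points whose rigid image falls outside the
#'   FFD support: `"error"` (default) or `"zero"` (no displacement there,
#'   the convention used during resampling).
#' @return mapped point(s) in the moving domain, mm.
#' @export
chain_apply <- function(chain, p, outside = c("error", "zero")) {
  stopifnot(inherits(chain, "transform_chain"))
  outside <- match.arg(outside)
  pts <- rbind_points(p)
  has <- !is.null(chain$ffd)
  g <- chain$ffd
  out <- cpp_chain_points(pts, chain$rigid$rotation, chain$rigid$center,
                          chain$rigid$translation, has,
                          if (has) as.vector(g$coefficients) else numeric(0),
                          if (has) g$shape else integer(3),
                          if (has) g$spacing else rep(1, 3),
                          if (has) g$origin else rep(0, 3),
                          if (outside == "error") 0L else 1L)
  drop_points(out, p)
}

#' Numerically invert a transform chain
#'
#' Finds the fixed-domain preimages of moving-domain points by fixed-point
#' iteration on the displacement field (the rigid part is inverted in
#' closed form).  Converges provided the FFD is injective, i.e. its
#' displacement stays below about 0.4 of the control spacing.
#'
#' @param chain a [transform_chain()].
#' @param y length-3 point or n x 3 matrix in the moving domain (mm).
#' @param maxit,tol iteration controls.
#' @return preimage point(s), mm.
#' @export
chain_invert <- function(chain, y, maxit = 50L, tol = 1e-9) {
  stopifnot(inherits(chain, "transform_chain"))
  pts <- rbind_points(y)
  has <- !is.null(chain$ffd)
  g <- chain$ffd
  out <- cpp_invert_chain(pts, chain$rigid$rotation, chain$rigid$center,
                          chain$rigid$translation, has,
                          if (has) as.vector(g$coefficients) else numeric(0),
                          if (has) g$shape else integer(3),
                          if (has) g$spacing else rep(1, 3),
                          if (has) g$origin else rep(0, 3),
                          as.integer(maxit), tol)
  drop_points(out, y)
}

fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' ASCII transform-parameter file
#'
#' A human-readable key-value file holding the six rigid parameters, the
#' rotation center, and (for a deformable chain) the control-grid geometry
#' plus every B-spline coefficient, flattened x-fastest per displacement
#' component.  Round-tripping reproduces the chain to full printed
#' precision.
#'
#' Keys: `Transform` (`rigid` or `rigid+bspline`), `RigidParameters`
#' (rx ry rz tx ty tz: radians then mm), `RigidCenter`, and for the FFD
#' `GridShape`, `GridSpacing`, `GridOrigin`, `Coefficients`.
#'
#' @param chain a [transform_chain()].
#' @param path file path.
#' @return `read_transform_file()`: a [transform_chain()].
#' @export
write_transform_file <- function(chain, path) {
  stopifnot(inherits(chain, "transform_chain"))
  r <- chain$rigid
  lines <- c(
    sprintf("Transform = %s", if (is.null(chain$ffd)) "rigid" else "rigid+bspline"),
    sprintf("RigidParameters = %s", fmt_nums(c(r$rotation, r$translation))),
    sprintf("RigidCenter = %s", fmt_nums(r$center)))
  if (!is.null(chain$ffd)) {
    g <- chain$ffd
    lines <- c(lines,
               sprintf("GridShape = %s", paste(g$shape, collapse = " ")),
               sprintf("GridSpacing = %s", fmt_nums(g$spacing)),
               sprintf("GridOrigin = %s", fmt_nums(g$origin)),
               sprintf("Coefficients = %s", fmt_nums(as.vector(g$coefficients))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform_file
#' @export
read_transform_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("parse error in ", path, ": malformed line '", ln, "'", call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  need <- function(k, n = NULL) {
    if (is.null(kv[[k]]))
      stop("parse error in ", path, ": missing key ", k, call. = FALSE)
    v <- suppressWarnings(as.numeric(strsplit(kv[[k]], "\\s+")[[1]]))
    if (any(is.na(v)))
      stop("parse error in ", path, ": non-numeric value for key ", k,
           call. = FALSE)
    if (!is.null(n) && length(v) != n)
      stop("parse error in ", path, ": key ", k, " expects ", n,
           " numbers, got ", length(v), call. = FALSE)
    v
  }
  type <- kv[["Transform"]]
  if (is.null(type))
    stop("parse error in ", path, ": missing key Transform", call. = FALSE)
  rp <- need("RigidParameters", 6)
  center <- need("RigidCenter", 3)
  rigid <- rigid_transform(translation = rp[4:6], rotation = rp[1:3],
                           center = center)
  if (identical(type, "rigid"))
    return(transform_chain(rigid))
  if (!identical(type, "rigid+bspline"))
    stop("parse error in ", path, ": unknown Transform type '", type, "'",
         call. = FALSE)
  shape <- as.integer(need("GridShape", 3))
  spacing <- need("GridSpacing", 3)
  origin <- need("GridOrigin", 3)
  coefs <- need("Coefficients")
  if (length(coefs) != prod(shape) * 3)
    stop("parse error in ", path, ": key Coefficients expects ",
         prod(shape) * 3, " numbers, got ", length(coefs), call. = FALSE)
  transform_chain(rigid,
                  bspline_grid(shape, spacing, origin,
                               array(coefs, c(shape, 3L))))
}
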