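#' 3D scalar volume with physical geometry
#'
#' The basic unit everything in the package operates on: a rank-3 array of
#' intensities together with the voxel spacing (mm) and the physical
#' position of the center of voxel `(0,0,0)` (mm).  Only axis-aligned
#' volumes are supported; all transforms and metrics work in physical
#' millimetres, so anisotropic voxels (e.g. CT at 1.367x1.367x2.5 mm) are
#' handled correctly.
#'
#' Voxel indices are 0-based in the coordinate mapping: the center of voxel
#' `index` sits at `origin + index * spacing`.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel size in mm; strictly positive.
#' @param origin numeric length-3, physical position (mm) of the first
#'   voxel center.
#' @return An object of class `"volume"`.
#' @examples
#' v <- volume(array(0, c(8, 8, 8)), spacing = c(1.367, 1.367, 2.5))
#' voxel_to_physical(v, c(1, 1, 1))
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a rank-3 array", call. = FALSE)
  if (any(dim(data) == 0L))
    stop("volume data has a degenerate (size-0) axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

#' Physical extent helpers
#'
#' `volume_extent()` returns the physical coordinates (mm) of the first and
#' last voxel centers; `volume_center()` the midpoint of that box.
#'
#' @param vol a [volume()].
#' @return `volume_extent()`: 2x3 matrix (rows: lower, upper);
#'   `volume_center()`: length-3 numeric.
#' @export
volume_extent <- function(vol) {
  stopifnot(is_volume(vol))
  lo <- vol$origin
  hi <- vol$origin + (dim(vol$data) - 1) * vol$spacing
  rbind(lower = lo, upper = hi)
}

#' @rdname volume_extent
#' @export
volume_center <- function(vol) {
  e <- volume_extent(vol)
  as.numeric((e[1, ] + e[2, ]) / 2)
}

#' Convert between voxel indices and physical coordinates
#'
#' Voxel indices are 0-based; the center of voxel `(0,0,0)` lies at the
#' volume origin.  `physical_to_voxel()` returns continuous (non-rounded)
#' voxel coordinates, so the two functions are mutual inverses.
#'
#' @param vol a [volume()] (or [label_volume()]).
#' @param index integer 3-vector (or n x 3 matrix) of 0-based voxel indices.
#' @param point numeric 3-vector (or n x 3 matrix) of physical mm
#'   coordinates.
#' @return n x 3 matrix (or length-3 vector for a single input).
#' @export
voxel_to_physical <- function(vol, index) {
  geo <- as_geometry(vol)
  idx <- rbind_points(index)
  if (any(idx < 0) || any(t(t(idx) - (geo$dim - 1)) > 0))
    stop("voxel index out of bounds", call. = FALSE)
  out <- t(geo$origin + t(idx) * geo$spacing)
  drop_points(out, index)
}

#' @rdname voxel_to_physical
#' @export
physical_to_voxel <- function(vol, point) {
  geo <- as_geometry(vol)
  pts <- rbind_points(point)
  out <- t((t(pts) - geo$origin) / geo$spacing)
  drop_points(out, point)
}

# geometry accessor shared by volume / label_volume
as_geometry <- function(x) {
  if (is_volume(x))
    return(list(dim = dim(x$data), spacing = x$spacing, origin = x$origin))
  if (inherits(x, "label_volume"))
    return(list(dim = dim(x$labels), spacing = x$spacing, origin = x$origin))
  stop("expected a volume or label_volume", call. = FALSE)
}

rbind_points <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(p)
  }
  matrix(as.numeric(p), ncol = 3L)
}

drop_points <- function(out, input) {
  if (is.matrix(input)) out else as.numeric(out)
}

#' Integer-coded organ mask sharing a volume's geometry
#'
#' @param labels integer 3D array; 0 is background.
#' @param regions named integer vector mapping region names to label codes
#'   (e.g. `c(body = 1, brain = 2, lungs = 3, kidneys = 4)`); every nonzero
#'   value in `labels` must appear in it.
#' @param spacing,origin geometry, as for [volume()]; must match the
#'   companion intensity volume.
#' @return An object of class `"label_volume"`.
#' @export
label_volume <- function(labels, regions, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("labels must be a rank-3 array", call. = FALSE)
  storage.mode(labels) <- "integer"
  regions <- as.integer(regions) |> stats::setNames(names(regions))
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named integer vector", call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, regions)
  if (length(missing))
    stop("label codes not in the region map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  structure(list(labels = labels, regions = regions, spacing = spacing,
                 origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cts <- table(factor(x$labels[x$labels != 0L], levels = x$regions,
                      labels = names(x$regions)))
  cat(sprintf("<label_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  for (nm in names(cts)) cat(sprintf("  %-10s %d voxels\n", nm, cts[[nm]]))
  invisible(x)
}

#' Extract one region of a label volume as a logical mask
#'
#' @param lab a [label_volume()].
#' @param region region name (must be present in the region map).
#' @return logical 3D array.
#' @export
region_mask <- function(lab, region) {
  stopifnot(inherits(lab, "label_volume"))
  if (!region %in% names(lab$regions))
    stop("unknown region: ", region, call. = FALSE)
  # a nested root region (e.g. the whole body with organs inside it)
  # covers every labeled voxel, since organ codes take precedence in the
  # single-code array
  if (!is.null(lab$nested_root) && identical(region, lab$nested_root))
    return(lab$labels != 0L)
  lab$labels == lab$regions[[region]]
}

#' Named physical landmark set
#'
#' An ordered set of named points in physical mm.  Paired sets (the same
#' anatomy identified on both modalities) must share names and order.
#'
#' @param points n x 3 numeric matrix of physical coordinates (mm).
#' @param names character vector of unique point names; defaults to
#'   `P01..Pnn`.
#' @return A `"landmark_set"`: data.frame with columns name, x, y, z.
#' @export
landmark_set <- function(points, names = NULL) {
  points <- rbind_points(points)
  n <- nrow(points)
  if (is.null(names)) names <- sprintf("P%02d", seq_len(n))
  names <- as.character(names)
  if (length(names) != n) stop("one name per point required", call. = FALSE)
  if (anyDuplicated(names))
    stop("landmark names must be unique", call. = FALSE)
  structure(data.frame(name = names, x = points[, 1], y = points[, 2],
                       z = points[, 3], stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

#' @rdname landmark_set
#' @param ls a landmark set.
#' @export
landmark_points <- function(ls) as.matrix(ls[, c("x", "y", "z")])

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points (mm)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
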