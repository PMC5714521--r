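#' Read and write 3D volumes (NIfTI-1 and MetaImage)
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`), read and written
#' through the RNifti package, and MetaImage (`.mha` single file, or
#' `.mhd` header + `.raw` block).  Spacing and origin are taken from the
#' file header.  Only axis-aligned volumes are supported: a NIfTI affine
#' (or MetaImage TransformMatrix) encoding a non-trivial rotation is
#' rejected with a format error rather than silently mishandled.  Pure
#' axis flips are canonicalized by reordering the data so spacing stays
#' positive.
#'
#' @param path file path; format chosen by extension.
#' @param vol a [volume()] to write.
#' @return `read_volume()`: a [volume()].  `write_volume()`: `path`,
#'   invisibly.  Round-tripping preserves data, spacing and origin to
#'   format precision.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti_volume(path))
  if (grepl("\\.(mha|mhd)$", lp)) return(read_meta_volume(path))
  stop("unrecognized volume format (expected .nii/.nii.gz/.mha/.mhd): ",
       path, call. = FALSE)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    write_nifti_volume(vol, path)
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    write_meta_volume(vol, path)
  } else {
    stop("unrecognized volume format (expected .nii/.nii.gz/.mha/.mhd): ",
         path, call. = FALSE)
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  arr <- array(as.numeric(img), d)  # drop RNifti bookkeeping attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    stop("format error in ", path, ": expected a 3D volume, got rank ",
         length(dim(arr)), call. = FALSE)
  xf <- RNifti::xform(img)
  A <- xf[1:3, 1:3]
  offdiag <- A - diag(diag(A))
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(A))))
    stop("format error in ", path,
         ": affine encodes a non-axis-aligned rotation (unsupported)",
         call. = FALSE)
  spacing <- diag(A)
  origin <- xf[1:3, 4]
  # canonicalize axis flips so spacing is positive
  for (ax in 1:3) {
    if (spacing[ax] < 0) {
      n <- dim(arr)[ax]
      idx <- list(seq_len(dim(arr)[1]), seq_len(dim(arr)[2]), seq_len(dim(arr)[3]))
      idx[[ax]] <- rev(idx[[ax]])
      arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      origin[ax] <- origin[ax] + (n - 1) * spacing[ax]
      spacing[ax] <- -spacing[ax]
    }
  }
  if (any(spacing == 0))
    stop("format error in ", path, ": zero spacing in affine", call. = FALSE)
  volume(arr, spacing = spacing, origin = origin)
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::`pixdim<-`(img, vol$spacing) -> img
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

meta_type_map <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                   MET_SHORT = "integer", MET_USHORT = "integer",
                   MET_INT = "integer", MET_UINT = "integer",
                   MET_FLOAT = "double", MET_DOUBLE = "double")
meta_type_size <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
                    MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_meta_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  keys <- list()
  nbytes <- 0L
  repeat {
    line <- character(0)
    ch <- readBin(con, "raw", 1)
    while (length(ch) && ch != as.raw(10)) {
      line <- c(line, rawToChar(ch))
      ch <- readBin(con, "raw", 1)
    }
    nbytes <- nbytes + length(line) + 1L
    line <- paste(line, collapse = "")
    if (!nzchar(trimws(line))) next
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3)
      stop("format error in ", path, ": malformed header line '", line, "'",
           call. = FALSE)
    keys[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  list(keys = keys, data_offset = nbytes)
}

read_meta_volume <- function(path) {
  hdr <- read_meta_header(path)
  keys <- hdr$keys
  need <- function(k) {
    if (is.null(keys[[k]]))
      stop("format error in ", path, ": missing header field ", k, call. = FALSE)
    keys[[k]]
  }
  if (!is.null(keys$NDims) && as.integer(keys$NDims) != 3L)
    stop("format error in ", path, ": NDims must be 3", call. = FALSE)
  if (!is.null(keys$CompressedData) &&
      tolower(keys$CompressedData) %in% c("true", "1"))
    stop("format error in ", path, ": CompressedData is unsupported",
         call. = FALSE)
  if (!is.null(keys$TransformMatrix)) {
    tm <- as.numeric(strsplit(keys$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - as.vector(diag(3)))) > 1e-6)
      stop("format error in ", path,
           ": TransformMatrix encodes a rotation (unsupported)", call. = FALSE)
  }
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin <- if (!is.null(keys$Offset))
    as.numeric(strsplit(keys$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- need("ElementType")
  if (!type %in% names(meta_type_map))
    stop("format error in ", path, ": ElementType ", type, " unsupported",
         call. = FALSE)
  endian <- "little"
  if (!is.null(keys$BinaryDataByteOrderMSB) &&
      tolower(keys$BinaryDataByteOrderMSB) %in% c("true", "1"))
    endian <- "big"
  n <- prod(dims)
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, hdr$data_offset)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop("format error in ", path, ": ElementDataFile not found: ",
           datafile, call. = FALSE)
    con <- file(rawpath, "rb")
    on.exit(close(con))
  }
  what <- meta_type_map[[type]]
  size <- meta_type_size[[type]]
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT")
  vals <- readBin(con, what = what, n = n, size = size, endian = endian,
                  signed = if (size < 4) signed else TRUE)
  if (length(vals) != n)
    stop("format error in ", path, ": expected ", n, " voxels, read ",
         length(vals), call. = FALSE)
  arr <- array(as.numeric(vals), dim = dims)
  volume(arr, spacing = spacing, origin = origin)
}

write_meta_volume <- function(vol, path) {
  is_mhd <- grepl("\\.mhd$", tolower(path))
  rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g", vol$spacing[1], vol$spacing[2],
            vol$spacing[3]),
    sprintf("DimSize = %d %d %d", dim(vol$data)[1], dim(vol$data)[2],
            dim(vol$data)[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", if (is_mhd) rawname else "LOCAL"))
  if (is_mhd) {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(as.vector(vol$data), con, size = 8, endian = "little")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(as.vector(vol$data), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read and write plain-text landmark point files
#'
#' The dialect is elastix-style: line 1 is the literal word `point` (physical
#' mm coordinates) or `index` (0-based voxel indices, converted through
#' `reference`); line 2 is the integer point count; then one whitespace
#' separated coordinate triple per line.  The file carries no names, so
#' names are assigned on read (`P01..Pnn` by default).
#'
#' @param path file path.
#' @param names optional character vector of point names.
#' @param reference a [volume()], required to convert an `index` file to
#'   physical coordinates.
#' @param lm a [landmark_set()] to write.
#' @return `read_landmarks()`: a [landmark_set()] in physical mm.
#' @export
read_landmarks <- function(path, names = NULL, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("parse error in ", path, " line 1: expected 'point' or 'index' header",
         call. = FALSE)
  mode <- tolower(lines[1])
  if (!mode %in% c("point", "index"))
    stop("parse error in ", path, " line 1: expected 'point' or 'index', got '",
         lines[1], "'", call. = FALSE)
  n <- suppressWarnings(as.integer(lines[2]))
  if (is.na(n) || n < 0)
    stop("parse error in ", path, " line 2: expected a point count", call. = FALSE)
  body <- lines[-(1:2)]
  if (length(body) != n)
    stop("parse error in ", path, ": count line says ", n, " points but file has ",
         length(body), call. = FALSE)
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\\s+")[[1]]))
    if (length(v) != 3 || any(is.na(v)))
      stop("parse error in ", path, " line ", i + 2,
           ": expected three numbers", call. = FALSE)
    pts[i, ] <- v
  }
  if (mode == "index") {
    if (is.null(reference))
      stop("an 'index' landmark file needs a reference volume", call. = FALSE)
    pts <- voxel_to_physical(reference, pts)
  }
  landmark_set(pts, names = names)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("point", as.character(nrow(lm))), con)
  writeLines(sprintf("%.17g %.17g %.17g", lm$x, lm$y, lm$z), con)
  invisible(path)
}
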