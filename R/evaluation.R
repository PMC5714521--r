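#' Volume overlap and overlay-error metrics for one region
#'
#' Exact voxel-counting figures of merit between a source mask `S` (the
#' registered/resampled segmentation) and a target mask `T` (the reference
#' segmentation on the same grid):
#' target overlap `TO = |S∩T|/|T|`, Dice `DC = 2|S∩T|/(|S|+|T|)`, Jaccard
#' `JC = |S∩T|/|S∪T|`, false negative `FN = |T\\S|/|T|`, false positive
#' `FP = |S\\T|/|S|`, and the signed volume similarity
#' `VS = 2(|S|-|T|)/(|S|+|T|)` (alignment-independent).  `TO + FN = 1` and
#' `DC = 2 JC / (1 + JC)` hold identically.
#'
#' @param S,T logical 3D arrays on a shared grid.
#' @param spacing voxel spacing (mm) used to also report volumes in mm^3.
#' @param region optional region name carried into the record.
#' @return A one-row data.frame (class `"overlap_record"`) with the six
#'   metrics, voxel counts and mm^3 volumes.  A metric whose denominator
#'   is empty raises an undefined-metric error naming the metric unless
#'   `partial = TRUE`, in which case it is set `NA` and flagged.
#' @param partial return NA (flagged) instead of erroring on empty
#'   denominators.
#' @export
overlap_suite <- function(S, T, spacing = c(1, 1, 1), region = NA_character_,
                          partial = FALSE) {
  if (!identical(dim(S), dim(T)))
    stop("masks must share a grid", call. = FALSE)
  S <- as.logical(S); T <- as.logical(T)
  nS <- sum(S); nT <- sum(T)
  nI <- sum(S & T); nU <- nS + nT - nI
  vox_mm3 <- prod(spacing)
  fail <- function(metric) {
    if (!partial)
      stop("undefined metric ", metric, ": empty denominator", call. = FALSE)
    NA_real_
  }
  TO <- if (nT > 0) nI / nT else fail("TO")
  FN <- if (nT > 0) (nT - nI) / nT else fail("FN")
  FP <- if (nS > 0) (nS - nI) / nS else fail("FP")
  JC <- if (nU > 0) nI / nU else fail("JC")
  DC <- if (nS + nT > 0) 2 * nI / (nS + nT) else fail("DC")
  VS <- if (nS + nT > 0) 2 * (nS - nT) / (nS + nT) else fail("VS")
  structure(data.frame(region = region, TO = TO, DC = DC, JC = JC, FN = FN,
                       FP = FP, VS = VS, n_S = nS, n_T = nT,
                       n_intersect = nI, vol_S_mm3 = nS * vox_mm3,
                       vol_T_mm3 = nT * vox_mm3,
                       undefined = anyNA(c(TO, DC, JC, FN, FP, VS))),
            class = c("overlap_record", "data.frame"))
}

#' Dice from Jaccard
#'
#' The exact identity `DC = 2 JC / (1 + JC)` relating the two overlap
#' coefficients.
#'
#' @param jc Jaccard coefficient(s) in `[0, 1]`.
#' @return Dice coefficient(s).
#' @export
dc_from_jc <- function(jc) {
  if (any(jc < 0 | jc > 1)) stop("jc must lie in [0, 1]", call. = FALSE)
  2 * jc / (1 + jc)
}

#' Qualitative agreement category for a Dice coefficient
#'
#' The conventional interpretation bands: below 0.2 poor, 0.2-0.4 fair,
#' 0.6-0.8 good, 0.8-1.0 excellent.  The published band list leaves
#' 0.4-0.6 unnamed; this package returns `"moderate"` there.
#'
#' @param dc Dice coefficient(s) in `[0, 1]`.
#' @return factor with levels poor, fair, moderate, good, excellent.
#' @export
agreement_category <- function(dc) {
  if (any(dc < 0 | dc > 1)) stop("dc must lie in [0, 1]", call. = FALSE)
  cut(dc, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("poor", "fair", "moderate", "good", "excellent"))
}

#' Boundary voxel centers of a binary mask
#'
#' A labeled voxel belongs to the boundary when at least one of its six
#' face neighbours is unlabeled or outside the array (the volume border
#' counts as boundary).
#'
#' @param mask logical 3D array.
#' @param spacing,origin grid geometry (mm).
#' @return n x 3 matrix of physical boundary-point coordinates (mm);
#'   attribute `"index"` holds the 0-based voxel indices.
#' @export
boundary_points <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  mask <- as.array(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("empty region: mask has no voxels", call. = FALSE)
  b <- boundary_mask(mask)
  idx <- which(b, arr.ind = TRUE) - 1L
  pts <- t(origin + t(idx) * spacing)
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "index") <- idx
  pts
}

boundary_mask <- function(mask) {
  d <- dim(mask)
  # nb_all: TRUE where all six face neighbours exist and are labeled
  nb_all <- array(TRUE, d)
  for (ax in 1:3) for (by in c(1L, -1L)) {
    n <- d[ax]
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    # src[i] = i - by, NA where the neighbour falls outside the array
    src <- if (by > 0) c(NA_integer_, seq_len(n - 1L))
           else c(seq_len(n)[-1L], NA_integer_)
    shifted <- array(FALSE, d)
    ok <- which(!is.na(src))
    if (length(ok)) {
      sel_dst <- idx; sel_dst[[ax]] <- ok
      sel_src <- idx; sel_src[[ax]] <- src[ok]
      shifted[sel_dst[[1]], sel_dst[[2]], sel_dst[[3]]] <-
        mask[sel_src[[1]], sel_src[[2]], sel_src[[3]]]
    }
    nb_all <- nb_all & shifted
  }
  mask & !nb_all
}

#' Surface distance measures between two regions
#'
#' The distance error `DE` is the mean, and the directed Hausdorff
#' distance `HD` the maximum, of the minimum Euclidean distance from each
#' source boundary point to the target boundary.  Distances are computed
#' in physical mm (anisotropic spacing respected) from an exact Euclidean
#' distance map of the target boundary sampled at the source boundary
#' voxel centers.  Directed source-to-target, as reported; use
#' [surface_distances_symmetric()] for the symmetrized variant.
#'
#' @param S,T logical 3D arrays on a shared grid (both nonempty).
#' @param spacing,origin grid geometry (mm).
#' @param region optional region name carried into the record.
#' @return one-row data.frame (class `"surface_record"`) with `DE_mm`,
#'   `HD_mm` and the boundary point counts.
#' @export
surface_distances <- function(S, T, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                              region = NA_character_) {
  if (!identical(dim(S), dim(T)))
    stop("masks must share a grid", call. = FALSE)
  if (!any(S) || !any(T))
    stop("empty region: surface distances need nonempty masks", call. = FALSE)
  sb <- boundary_mask(array(as.logical(S), dim(S)))
  tb <- boundary_mask(array(as.logical(T), dim(T)))
  dmap <- distance_map(tb, spacing)
  d <- dmap[sb]
  structure(data.frame(region = region, DE_mm = mean(d), HD_mm = max(d),
                       n_source_boundary = sum(sb),
                       n_target_boundary = sum(tb)),
            class = c("surface_record", "data.frame"))
}

#' @rdname surface_distances
#' @export
surface_distances_symmetric <- function(S, T, spacing = c(1, 1, 1),
                                        origin = c(0, 0, 0),
                                        region = NA_character_) {
  st <- surface_distances(S, T, spacing, origin, region)
  ts <- surface_distances(T, S, spacing, origin, region)
  structure(data.frame(region = region,
                       DE_mm = (st$DE_mm * st$n_source_boundary +
                                ts$DE_mm * ts$n_source_boundary) /
                               (st$n_source_boundary + ts$n_source_boundary),
                       HD_mm = max(st$HD_mm, ts$HD_mm),
                       n_source_boundary = st$n_source_boundary,
                       n_target_boundary = st$n_target_boundary),
            class = c("surface_record", "data.frame"))
}

#' Euclidean distance map of a point set
#'
#' Per-voxel minimum Euclidean distance (mm) to the nonzero voxels of
#' `mask`, exact on anisotropic grids (separable lower-envelope distance
#' transform).
#'
#' @param mask logical/integer 3D array.
#' @param spacing voxel spacing, mm.
#' @return numeric 3D array of distances, mm.
#' @export
distance_map <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as.array(mask)
  d <- dim(mask)
  m <- array(as.integer(mask != 0), d)
  if (!any(m == 1L)) stop("empty region: mask has no voxels", call. = FALSE)
  array(sqrt(cpp_edt_sq(as.vector(m), d, as.numeric(spacing))), d)
}

#' Landmark registration errors
#'
#' Euclidean distances (mm) between paired landmarks.  When a chain is
#' given, each fixed-space landmark is first mapped through it (the
#' registration's prediction of where the point lies in the moving
#' domain); otherwise the raw pairwise distances are returned.
#'
#' @param fixed_set,moving_set paired [landmark_set()]s: same names, same
#'   order.
#' @param chain optional [transform_chain()].
#' @return data.frame with columns `name` and `error_mm`.
#' @export
landmark_errors <- function(fixed_set, moving_set, chain = NULL) {
  stopifnot(inherits(fixed_set, "landmark_set"),
            inherits(moving_set, "landmark_set"))
  if (!identical(fixed_set$name, moving_set$name))
    stop("pairing error: landmark sets differ in names or order", call. = FALSE)
  p <- landmark_points(fixed_set)
  if (!is.null(chain)) p <- chain_apply(chain, p, outside = "zero")
  q <- landmark_points(moving_set)
  data.frame(name = fixed_set$name,
             error_mm = sqrt(rowSums((p - q)^2)))
}

#' Full per-case registration evaluation
#'
#' Computes, for every region shared by the two label volumes, the volume
#' overlap and overlay-error suite and the surface-distance measures, plus
#' the landmark error table: the three kinds of validation metric (point,
#' surface, volume).  The source labels (moving-domain segmentation) are
#' mapped into the fixed grid by nearest-neighbour resampling through the
#' chain before voxel counting.
#'
#' @param fixed_labels [label_volume()] on the fixed grid (reference).
#' @param source_labels [label_volume()] on the moving grid.
#' @param chain [transform_chain()] mapping fixed to moving coordinates
#'   (use an identity chain for a pre-registration baseline).
#' @param fixed_landmarks,moving_landmarks optional paired
#'   [landmark_set()]s.
#' @param case optional case identifier carried into the tables.
#' @return list of class `"case_evaluation"`: `metrics` (one row per
#'   region: TO, DC, JC, FN, FP, VS, DE, HD, agreement category, flags)
#'   and `landmarks` (per-landmark errors, or `NULL`).  A region present
#'   in only one volume yields a flagged record, not a silent omission.
#' @export
evaluate_case <- function(fixed_labels, source_labels, chain,
                          fixed_landmarks = NULL, moving_landmarks = NULL,
                          case = NA_character_) {
  stopifnot(inherits(fixed_labels, "label_volume"),
            inherits(source_labels, "label_volume"),
            inherits(chain, "transform_chain"))
  src <- resample(volume(array(as.double(source_labels$labels),
                               dim(source_labels$labels)),
                         source_labels$spacing, source_labels$origin),
                  chain, fixed_labels, order = 0L, default_value = 0)
  src_lab <- source_labels
  src_lab$labels <- array(as.integer(round(src$data)), dim(src$data))
  src_lab$spacing <- fixed_labels$spacing
  src_lab$origin <- fixed_labels$origin
  regions <- union(names(fixed_labels$regions), names(source_labels$regions))
  rows <- list()
  for (rg in regions) {
    Tm <- if (rg %in% names(fixed_labels$regions))
      region_mask(fixed_labels, rg) else array(FALSE, dim(fixed_labels$labels))
    Sm <- if (rg %in% names(source_labels$regions))
      region_mask(src_lab, rg) else array(FALSE, dim(src_lab$labels))
    ov <- overlap_suite(Sm, Tm, fixed_labels$spacing, region = rg,
                        partial = TRUE)
    if (any(Sm) && any(Tm)) {
      sd <- surface_distances(Sm, Tm, fixed_labels$spacing,
                              fixed_labels$origin, region = rg)
      de <- sd$DE_mm; hd <- sd$HD_mm
    } else {
      de <- NA_real_; hd <- NA_real_
    }
    rows[[rg]] <- data.frame(case = case, region = rg, ov[-1],
                             DE_mm = de, HD_mm = hd,
                             agreement = if (is.na(ov$DC)) NA else
                               as.character(agreement_category(ov$DC)))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  lms <- NULL
  if (!is.null(fixed_landmarks) && !is.null(moving_landmarks)) {
    lms <- landmark_errors(fixed_landmarks, moving_landmarks, chain)
    lms <- data.frame(case = case, lms)
  }
  structure(list(metrics = metrics, landmarks = lms),
            class = "case_evaluation")
}

#' @export
print.case_evaluation <- function(x, ...) {
  cat("<case_evaluation>\n")
  print(x$metrics[, c("region", "TO", "DC", "JC", "FN", "FP", "VS", "DE_mm",
                      "HD_mm", "agreement")], digits = 3)
  if (!is.null(x$landmarks))
    cat(sprintf("landmark error: mean %.2f mm, max %.2f mm over %d points\n",
                mean(x$landmarks$error_mm), max(x$landmarks$error_mm),
                nrow(x$landmarks)))
  invisible(x)
}

#' Write a case evaluation to CSV / JSON
#'
#' @param ev a [evaluate_case()] result.
#' @param path output path; `.csv` writes the metric table (landmarks to a
#'   sibling `*_landmarks.csv`), `.json` writes both tables in one file.
#' @return `path`, invisibly.
#' @export
write_case_evaluation <- function(ev, path) {
  stopifnot(inherits(ev, "case_evaluation"))
  if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(list(metrics = ev$metrics, landmarks = ev$landmarks),
                         path, dataframe = "rows", na = "null", digits = NA)
  } else {
    write.csv(ev$metrics, path, row.names = FALSE)
    if (!is.null(ev$landmarks))
      write.csv(ev$landmarks,
                sub("\\.csv$", "_landmarks.csv", path, ignore.case = TRUE),
                row.names = FALSE)
  }
  invisible(path)
}
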