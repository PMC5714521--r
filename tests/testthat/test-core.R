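test_that("voxel/physical mapping follows the voxel-center convention", {
  v <- volume(array(0, c(8, 8, 8)), spacing = c(1.367, 1.367, 2.5))
  expect_equal(voxel_to_physical(v, c(0, 0, 0)), c(0, 0, 0))
  expect_equal(voxel_to_physical(v, c(1, 1, 1)), c(1.367, 1.367, 2.5))
  w <- volume(array(0, c(8, 8, 8)), spacing = c(1.875, 1.875, 6),
              origin = c(10, 0, 0))
  expect_equal(voxel_to_physical(w, c(2, 0, 0)), c(13.75, 0, 0))
  expect_error(voxel_to_physical(v, c(8, 0, 0)), "out of bounds")
})

test_that("voxel_to_physical and physical_to_voxel are mutual inverses", {
  v <- volume(array(0, c(12, 10, 8)), spacing = c(1.367, 1.875, 2.5),
              origin = c(-3, 4, 11))
  set.seed(1)
  idx <- cbind(runif(50, 0, 11), runif(50, 0, 9), runif(50, 0, 7))
  p <- t(v$origin + t(idx) * v$spacing)
  expect_lt(max(abs(physical_to_voxel(v, p) - idx)), 1e-9)
})

test_that("volume construction validates geometry", {
  expect_error(volume(matrix(0, 3, 3)), "rank-3")
  expect_error(volume(array(0, c(3, 0, 3))), "degenerate")
  expect_error(volume(array(0, c(3, 3, 3)), spacing = c(1, -1, 1)),
               "positive")
})

test_that("volume I/O round-trips across formats", {
  set.seed(2)
  v <- volume(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1.367, 1.367, 2.5),
              origin = c(-5, 2, 7.5))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f)
    expect_equal(v2$data, v$data, tolerance = 0, info = ext)
    expect_equal(v2$spacing, v$spacing, info = ext)
    expect_equal(v2$origin, v$origin, info = ext)
  }
  # integer data round-trips bit-exactly
  vi <- volume(array(as.double(sample.int(100, 8^3, TRUE)), c(8, 8, 8)))
  f <- tempfile(fileext = ".mha")
  write_volume(vi, f)
  expect_identical(read_volume(f)$data, vi$data)
})

test_that("MetaImage header fields are honoured and validated", {
  f <- tempfile(fileext = ".mha")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "ElementSpacing = 2 2 2", "DimSize = 2 2 2",
           "ElementType = MET_SHORT", "ElementDataFile = LOCAL")
  con <- file(f, "wb")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.integer(1:8), con, size = 2, endian = "little")
  close(con)
  v <- read_volume(f)
  expect_equal(v$spacing, c(2, 2, 2))
  expect_equal(as.vector(v$data), as.numeric(1:8))
  # rotated TransformMatrix is a format error
  f2 <- tempfile(fileext = ".mha")
  hdr2 <- sub("ElementSpacing = 2 2 2",
              "TransformMatrix = 0 1 0 -1 0 0 0 0 1\nElementSpacing = 2 2 2",
              hdr)
  con <- file(f2, "wb")
  writeBin(charToRaw(paste0(paste(hdr2, collapse = "\n"), "\n")), con)
  writeBin(as.integer(1:8), con, size = 2, endian = "little")
  close(con)
  expect_error(read_volume(f2), "rotation")
})

test_that("NIfTI with a non-axis-aligned affine is rejected", {
  arr <- array(rnorm(4^3), c(4, 4, 4))
  img <- RNifti::asNifti(arr)
  th <- 0.3
  aff <- rbind(c(cos(th), -sin(th), 0, 0), c(sin(th), cos(th), 0, 0),
               c(0, 0, 1, 0), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "non-axis-aligned")
})

test_that("landmark files parse, validate, and round-trip", {
  f <- tempfile()
  writeLines(c("point", "2", "1 2 3", "4.5 5 6"), f)
  lm <- read_landmarks(f)
  expect_equal(nrow(lm), 2)
  expect_equal(as.numeric(lm[2, c("x", "y", "z")]), c(4.5, 5, 6))
  # count mismatch
  writeLines(c("point", "3", "1 2 3", "4 5 6"), f)
  expect_error(read_landmarks(f), "count line says 3")
  # malformed coordinate line carries the line number
  writeLines(c("point", "2", "1 2 3", "4 five 6"), f)
  expect_error(read_landmarks(f), "line 4")
  # round trip of a named 16-point set
  set.seed(3)
  lm16 <- landmark_set(matrix(rnorm(48), ncol = 3))
  f2 <- tempfile()
  write_landmarks(lm16, f2)
  lm16b <- read_landmarks(f2, names = lm16$name)
  expect_equal(landmark_points(lm16b), landmark_points(lm16))
  expect_identical(lm16b$name, lm16$name)
  # duplicate names rejected
  expect_error(landmark_set(matrix(0, 2, 3), names = c("a", "a")), "unique")
  # index-mode file converts through the reference geometry
  v <- volume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2), origin = c(1, 1, 1))
  writeLines(c("index", "1", "2 0 1"), f)
  expect_equal(as.numeric(read_landmarks(f, reference = v)[1, c("x", "y", "z")]),
               c(5, 1, 3))
})

test_that("label volumes validate region codes and expose masks", {
  lab <- array(0L, c(4, 4, 4))
  lab[2, 2, 2] <- 1L
  lab[3, 3, 3] <- 2L
  lv <- label_volume(lab, c(body = 1, brain = 2))
  expect_true(region_mask(lv, "brain")[3, 3, 3])
  expect_error(label_volume(lab, c(body = 1)), "not in the region map")
  expect_error(region_mask(lv, "liver"), "unknown region")
})
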