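test_that("overlap suite matches direct count arithmetic", {
  d <- c(10, 10, 10)
  S <- array(FALSE, d); T <- array(FALSE, d)
  S[1:4, , 1:5] <- TRUE  # 200
  ov <- overlap_suite(S, S)
  expect_equal(c(ov$TO, ov$DC, ov$JC, ov$FN, ov$FP, ov$VS),
               c(1, 1, 1, 0, 0, 0))
  T[5:8, , 6:10] <- TRUE  # disjoint
  ov2 <- overlap_suite(S, T)
  expect_equal(c(ov2$TO, ov2$DC, ov2$JC, ov2$FN, ov2$FP),
               c(0, 0, 0, 1, 1))
  # |S|=100, |T|=100, |S∩T|=50
  S2 <- array(FALSE, d); T2 <- array(FALSE, d)
  S2[1:10, 1:10, 1] <- TRUE
  T2[1:10, 1:5, 1:2] <- TRUE
  ov3 <- overlap_suite(S2, T2, spacing = c(2, 2, 2))
  expect_equal(c(ov3$TO, ov3$DC, ov3$JC, ov3$FN, ov3$FP, ov3$VS),
               c(0.5, 0.5, 1 / 3, 0.5, 0.5, 0))
  expect_equal(ov3$DC, dc_from_jc(ov3$JC))
  expect_equal(ov3$vol_S_mm3, 100 * 8)
  # empty denominators raise undefined-metric errors naming the metric
  none <- array(FALSE, d)
  expect_error(overlap_suite(S, none), "TO|FN")
  expect_error(overlap_suite(none, T), "FP")
  flagged <- overlap_suite(S, none, partial = TRUE)
  expect_true(flagged$undefined)
})

test_that("overlap identities and symmetries hold over random mask pairs", {
  set.seed(20)
  for (i in 1:40) {
    S <- random_mask(c(9, 9, 9)); T <- random_mask(c(9, 9, 9))
    if (!any(S) || !any(T)) next
    st <- overlap_suite(S, T); ts <- overlap_suite(T, S)
    expect_lt(abs(st$DC - dc_from_jc(st$JC)), 1e-12)
    expect_lt(abs(st$TO + st$FN - 1), 1e-12)
    expect_equal(st$DC, ts$DC)
    expect_equal(st$JC, ts$JC)
    expect_equal(st$FN, ts$FP)
    expect_equal(st$VS, -ts$VS)
  }
})

test_that("dc_from_jc and agreement categories follow the published bands", {
  expect_equal(dc_from_jc(c(0, 1, 1 / 3)), c(0, 1, 0.5))
  expect_error(dc_from_jc(1.2), "\\[0, 1\\]")
  expect_equal(as.character(agreement_category(c(0.85, 0.65, 0.5, 0.3, 0.1))),
               c("excellent", "good", "moderate", "fair", "poor"))
  expect_equal(as.character(agreement_category(c(0.8, 0.2, 1))),
               c("excellent", "fair", "excellent"))
})

test_that("boundary extraction uses 6-connectivity with border counted", {
  d <- c(7, 7, 7)
  one <- array(FALSE, d); one[4, 4, 4] <- TRUE
  bp <- boundary_points(one, spacing = c(2, 2, 2))
  expect_equal(nrow(bp), 1L)
  expect_equal(as.numeric(bp), c(6, 6, 6))
  blk <- array(FALSE, d); blk[3:5, 3:5, 3:5] <- TRUE
  expect_equal(nrow(boundary_points(blk)), 26L)  # all but the center
  full <- array(TRUE, c(4, 4, 4))
  expect_equal(nrow(boundary_points(full)), 64L - 8L)  # faces of the array
  expect_error(boundary_points(array(FALSE, d)), "empty region")
})

test_that("surface distances match hand geometry and the pairwise oracle", {
  d <- c(8, 8, 8)
  S <- array(FALSE, d); S[3:5, 3:5, 3:5] <- TRUE
  r <- surface_distances(S, S)
  expect_equal(c(r$DE_mm, r$HD_mm), c(0, 0))
  # single voxels 3-4-5 triangle
  A <- array(FALSE, d); A[1, 1, 1] <- TRUE
  B <- array(FALSE, d); B[4, 5, 1] <- TRUE
  r2 <- surface_distances(A, B, spacing = c(1, 1, 1))
  expect_equal(c(r2$DE_mm, r2$HD_mm), c(5, 5))
  # random masks vs the exhaustive O(N*M) oracle, anisotropic spacing
  set.seed(21)
  for (i in 1:30) {
    dims <- sample(5:12, 3, TRUE)
    S <- random_mask(dims); T <- random_mask(dims)
    if (!any(S) || !any(T)) next
    spc <- runif(3, 0.5, 3)
    got <- surface_distances(S, T, spc)
    want <- brute_surface(S, T, spc)
    expect_lt(abs(got$DE_mm - want$DE), 1e-6)
    expect_lt(abs(got$HD_mm - want$HD), 1e-6)
    expect_gte(got$HD_mm, got$DE_mm)
  }
  expect_error(surface_distances(S, array(FALSE, dim(S))), "empty region")
})

test_that("directed Hausdorff is asymmetric; symmetric variant is the max", {
  d <- c(10, 10, 10)
  S <- array(FALSE, d); S[2:9, 2:9, 2:9] <- TRUE
  T <- array(FALSE, d); T[4:6, 4:6, 4:6] <- TRUE
  st <- surface_distances(S, T)
  ts <- surface_distances(T, S)
  expect_false(isTRUE(all.equal(st$HD_mm, ts$HD_mm)))
  sym <- surface_distances_symmetric(S, T)
  expect_equal(sym$HD_mm, max(st$HD_mm, ts$HD_mm))
})

test_that("landmark errors pair by name and map through chains", {
  a <- landmark_set(rbind(c(0, 0, 0), c(1, 1, 1)), c("p", "q"))
  expect_equal(landmark_errors(a, a)$error_mm, c(0, 0))
  b <- landmark_set(rbind(c(0, 0, 6), c(1, 1, 7)), c("p", "q"))
  expect_equal(landmark_errors(a, b)$error_mm, c(6, 6))
  ch <- transform_chain(rigid_transform(translation = c(0, 0, 6)))
  expect_equal(landmark_errors(a, b, ch)$error_mm, c(0, 0))
  bad <- landmark_set(rbind(c(0, 0, 0), c(1, 1, 1)), c("q", "p"))
  expect_error(landmark_errors(a, bad), "pairing error")
})

test_that("evaluate_case produces per-region records and flags missing regions", {
  pc <- cached_phantom(7)
  ev <- evaluate_case(pc$ct_labels, pc$ct_labels, transform_chain(),
                      case = "self")
  expect_equal(sort(ev$metrics$region),
               sort(c("body", "brain", "lungs", "kidneys")))
  expect_true(all(ev$metrics$DC == 1))
  expect_true(all(ev$metrics$DE_mm == 0 & ev$metrics$HD_mm == 0))
  # a region present only in the fixed labels yields a flagged record
  src <- pc$ct_labels
  src$labels[src$labels == 4L] <- 1L
  src$regions <- src$regions[c("body", "brain", "lungs")]
  ev2 <- evaluate_case(pc$ct_labels, src, transform_chain())
  kid <- ev2$metrics[ev2$metrics$region == "kidneys", ]
  expect_true(kid$undefined)
  expect_true(is.na(kid$DE_mm))
  # serialization
  f <- tempfile(fileext = ".csv")
  write_case_evaluation(ev, f)
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(nrow(back), 4L)
  fj <- tempfile(fileext = ".json")
  write_case_evaluation(ev, fj)
  expect_equal(length(jsonlite::read_json(fj)$metrics), 4L)
})

test_that("evaluation under the truth chain is near-perfect on the phantom", {
  pc <- cached_phantom(7)
  ev <- evaluate_case(pc$ct_labels, pc$mr_labels, pc$truth,
                      pc$ct_landmarks, pc$mr_landmarks, case = "truth")
  m <- ev$metrics
  # residual is label-resampling discretization only
  expect_gte(m$DC[m$region == "body"], 0.95)
  expect_true(all(m$DC >= 0.85))
  expect_true(all(m$DE_mm <= 2.5))  # <= one CT voxel
  expect_lt(max(ev$landmarks$error_mm), 1e-6)
})
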