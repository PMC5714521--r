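test_that("anatomy generation is deterministic and anatomically consistent", {
  a1 <- generate_anatomy(42)
  a2 <- generate_anatomy(42)
  expect_identical(a1$ct$data, a2$ct$data)
  expect_identical(a1$labels$labels, a2$labels$labels)
  a3 <- generate_anatomy(43)
  expect_false(identical(a1$ct$data, a3$ct$data))
  # census: all four regions present, kidneys smallest
  counts <- table(factor(a1$labels$labels[a1$labels$labels != 0],
                         levels = 1:4,
                         labels = c("body", "brain", "lungs", "kidneys")))
  expect_true(all(counts > 0))
  expect_true(counts[["kidneys"]] < min(counts[["body"]], counts[["brain"]],
                                        counts[["lungs"]]))
  # organs nested inside the body mask (single-code array: any organ voxel
  # is inside the body by the nested_root convention)
  body <- region_mask(a1$labels, "body")
  for (rg in c("brain", "lungs", "kidneys"))
    expect_true(all(body[region_mask(a1$labels, rg)]))
  expect_error(generate_anatomy(1, shape = c(16, 16, 16)), "config error")
})

test_that("left/right paired organs are disjoint connected blobs", {
  a <- generate_anatomy(2)
  for (rg in c("lungs", "kidneys")) {
    m <- region_mask(a$labels, rg)
    idx <- which(m, arr.ind = TRUE)
    cx <- dim(m)[1] / 2
    left <- idx[, 1] < cx
    expect_gt(sum(left), 0)
    expect_gt(sum(!left), 0)
    # a gap separates the two sides at the midline
    expect_false(any(abs(idx[, 1] - cx) < 1))
  }
})

test_that("pseudo-MR rendering has the stated contrast properties", {
  a <- generate_anatomy(3)
  clean <- mr_from_ct(a, seed = 3, bias_amplitude = 0, noise_sd = 0)
  # piecewise-constant: exactly one intensity per tissue class
  expect_lte(length(unique(as.vector(clean$mr$data))), 6L)
  # same seed reproduces the noisy image exactly
  n1 <- mr_from_ct(a, seed = 3)
  n2 <- mr_from_ct(a, seed = 3)
  expect_identical(n1$mr$data, n2$mr$data)
  # CT->MR class-mean relation is non-monotone (bone: bright CT, dark MR)
  ct_on_mr <- sapply(1:4, function(code) {
    m <- clean$labels$labels == code
    if (!any(m)) return(NA_real_)
    mean(clean$mr$data[m])
  })
  # order by label code is not order-preserving vs the CT class means
  lab_ct <- c(40, 45, -800, 35)  # soft, brain, lung, kidney nominal HU
  expect_lt(suppressWarnings(cor(ct_on_mr, lab_ct, method = "spearman",
                                 use = "complete.obs")), 0.99)
  # MR grid is coarser and anisotropic
  expect_true(all(clean$mr$spacing >= a$ct$spacing))
  expect_gt(clean$mr$spacing[3] / clean$mr$spacing[1], 1)
})

test_that("warp_case stores an exact, invertible ground truth", {
  pc <- cached_phantom(7)
  # landmarks: truth maps CT-space points onto the MR-space roster exactly
  mapped <- chain_apply(pc$truth, landmark_points(pc$ct_landmarks),
                        outside = "zero")
  expect_lt(max(abs(mapped - landmark_points(pc$mr_landmarks))), 1e-9)
  # same seed reproduces the full case
  pc2 <- warp_case(generate_anatomy(7), seed = 7)
  expect_identical(pc2$mr$data, pc$mr$data)
  expect_identical(pc2$truth$ffd$coefficients, pc$truth$ffd$coefficients)
  # magnitude bounds are honoured by the realized field
  probe <- sample_points(pc$ct, 500)
  q <- rigid_apply(pc$truth$rigid, probe)
  dis <- chain_apply(pc$truth, probe, outside = "zero") - q
  expect_lte(max(abs(dis)), 8 + 1e-6)
  expect_lte(sqrt(sum(pc$truth$rigid$translation^2)), 10 + 1e-9)
  # injectivity bound enforced
  expect_error(warp_case(generate_anatomy(8), seed = 8, ffd_magnitude = 9),
               "config error")
})

test_that("zero-magnitude warp yields an identity truth and unit overlap", {
  an <- generate_anatomy(11)
  pc0 <- warp_case(an, seed = 11, rigid_magnitude = 0, ffd_magnitude = 0)
  expect_equal(pc0$truth$rigid$translation, c(0, 0, 0))
  expect_equal(pc0$truth$rigid$rotation, c(0, 0, 0))
  expect_null(pc0$truth$ffd)
  le <- landmark_errors(pc0$ct_landmarks, pc0$mr_landmarks)
  expect_lt(max(le$error_mm), 1e-9)
  ev <- evaluate_case(pc0$ct_labels, pc0$mr_labels, pc0$truth)
  expect_gte(min(ev$metrics$DC), 0.85)  # residual: grid discretization only
  expect_gte(ev$metrics$DC[ev$metrics$region == "body"], 0.95)
})

test_that("pure translation moves every landmark by the same distance", {
  an <- generate_anatomy(12)
  pc <- warp_case(an, seed = 12, rigid_magnitude = 0, ffd_magnitude = 0)
  tr <- transform_chain(rigid_transform(translation = c(5, 0, 0)))
  lm2 <- landmark_set(chain_apply(tr, landmark_points(pc$ct_landmarks)),
                      names = pc$ct_landmarks$name)
  le <- landmark_errors(pc$ct_landmarks, lm2)
  expect_true(all(abs(le$error_mm - 5) < 1e-9))
})

test_that("model-mismatch mode draws truth on a finer control grid", {
  an <- generate_anatomy(13)
  pcm <- warp_case(an, seed = 13, ffd_magnitude = 3.5, model_mismatch = TRUE)
  pcr <- warp_case(an, seed = 13, ffd_magnitude = 3.5)
  expect_lt(min(pcm$truth$ffd$spacing), min(pcr$truth$ffd$spacing))
})
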