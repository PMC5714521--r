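test_that("joint histogram conserves mass and handles degenerate images", {
  set.seed(10)
  fx <- smooth_volume(16)
  mv <- smooth_volume(16, scale = 0.6, offset = 0.3)
  pts <- sample_points(fx, 3000)
  h <- build_joint_histogram(fx, mv, transform_chain(), pts)
  expect_lt(abs(sum(h$counts) - h$used), 1e-6)
  expect_equal(h$used + h$skipped, 3000L)
  # constant fixed volume: all mass in a single fixed-bin row pair
  cf <- volume(array(5, c(16, 16, 16)), spacing = c(2, 2, 2))
  hc <- build_joint_histogram(cf, mv, transform_chain(), pts,
                              fixed_range = c(0, 10))
  expect_lt(sum(rowSums(hc$counts) > 0), 3)  # linear window spans <= 2 rows
  # too few usable samples
  far <- volume(array(1, c(4, 4, 4)), origin = c(1e5, 1e5, 1e5))
  expect_error(build_joint_histogram(fx, far, transform_chain(), pts),
               "80%|degenerate")
})

test_that("identical discretized volumes give a diagonal histogram, NMI 2", {
  set.seed(11)
  v <- volume(array(sample(0:7, 12^3, TRUE) * 100, c(12, 12, 12)),
              spacing = c(2, 2, 2))
  idx <- as.matrix(expand.grid(0:11, 0:11, 0:11))
  pts <- voxel_to_physical(v, idx)
  h <- build_joint_histogram(v, v, transform_chain(), pts, window = "nearest",
                             fixed_range = c(0, 700), moving_range = c(0, 700))
  expect_true(all(h$counts[row(h$counts) != col(h$counts) &
                             upper.tri(h$counts, diag = FALSE) |
                             lower.tri(h$counts)] >= 0))
  offdiag <- sum(h$counts) - sum(diag(h$counts))
  expect_equal(offdiag, 0)
  expect_equal(nmi(h), 2, tolerance = 1e-12)
})

test_that("nmi matches closed-form entropy arithmetic", {
  # product of independent marginals
  hm <- outer(c(0.2, 0.3, 0.5), c(0.1, 0.4, 0.5))
  expect_lt(abs(nmi(hm) - 1), 1e-9)
  # diagonal
  expect_equal(nmi(diag(c(0.4, 0.6))), 2)
  # hand-built 2x2
  p <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  expect_equal(nmi(p), (ent(rowSums(p)) + ent(colSums(p))) / ent(p))
  # single occupied cell: degenerate value 2
  one <- matrix(0, 4, 4); one[2, 3] <- 5
  expect_equal(nmi(one), 2)
  expect_error(nmi(matrix(0, 3, 3)), "no mass")
})

test_that("NMI lies in [1,2] and is invariant to moving-bin relabeling", {
  set.seed(12)
  for (i in 1:25) {
    h <- matrix(rexp(64), 8, 8)
    v <- nmi(h)
    expect_gte(v, 1 - 1e-12)
    expect_lte(v, 2 + 1e-12)
    expect_equal(nmi(h[, sample(8)]), v, tolerance = 1e-12)
  }
})

test_that("checkerboard joint histogram matches the per-voxel pairing oracle", {
  n <- 8
  chk <- array(as.double((outer(0:(n - 1), 0:(n - 1), "+") %% 2)), c(n, n, 1))
  chk <- array(rep(chk, n), c(n, n, n))
  for (k in seq_len(n)) chk[, , k] <- (chk[, , k] + k - 1) %% 2
  a <- volume(chk * 10, spacing = c(1, 1, 1))
  b <- volume((1 - chk) * 10, spacing = c(1, 1, 1))  # shifted half a period
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  pts <- voxel_to_physical(a, idx)
  h <- build_joint_histogram(a, b, transform_chain(), pts, bins = 2L,
                             window = "nearest", fixed_range = c(0, 10),
                             moving_range = c(0, 10))
  # oracle: exhaustive per-voxel pairing
  oracle <- table(factor(as.vector(a$data), c(0, 10)),
                  factor(as.vector(b$data), c(0, 10)))
  expect_equal(matrix(h$counts, 2), matrix(as.numeric(oracle), 2))
  expect_equal(nmi(h), 2)  # anti-correlated is still a deterministic relation
})

test_that("NMI translation scan of a volume against itself peaks at zero", {
  v <- smooth_volume(20)
  idx <- as.matrix(expand.grid(0:19, 0:19, 0:19))
  pts <- voxel_to_physical(v, idx)
  fr <- intensity_range(v)
  vals <- sapply(seq(-4, 4, by = 1), function(tx) {
    ch <- transform_chain(rigid_transform(translation = c(tx, 0, 0)))
    nmi(build_joint_histogram(v, v, ch, pts, fixed_range = fr,
                              moving_range = fr))
  })
  expect_equal(which.max(vals), 5L)  # tx = 0
})

test_that("analytic NMI gradients agree with central finite differences", {
  set.seed(13)
  fx <- smooth_volume(16)
  mv <- smooth_volume(16, ripple = 0.15, scale = 0.7, offset = 0.2)
  fr <- intensity_range(fx); mr <- intensity_range(mv)
  pts <- sample_points(fx, 1500)
  par0 <- c(0.02, -0.01, 0.03, 1.0, -0.5, 0.8)
  ctr <- volume_center(fx)
  mk <- function(p) transform_chain(rigid_transform(p[4:6], p[1:3], ctr))
  g <- nmi_gradient(fx, mv, mk(par0), pts, wrt = "rigid", order = 3,
                    fixed_range = fr, moving_range = mr)
  fd <- sapply(1:6, function(i) {
    h <- 1e-4; e <- rep(0, 6); e[i] <- h
    f <- function(p) nmi(build_joint_histogram(fx, mv, mk(p), pts, order = 3,
                                               fixed_range = fr,
                                               moving_range = mr))
    (f(par0 + e) - f(par0 - e)) / (2 * h)
  })
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-3)
})

test_that("gradient near a symmetric optimum is small relative to off-optimum", {
  v <- smooth_volume(16)
  fr <- intensity_range(v)
  set.seed(14)
  pts <- sample_points(v, 4000)
  ctr <- volume_center(v)
  g0 <- nmi_gradient(v, v, transform_chain(rigid_transform(center = ctr)),
                     pts, wrt = "rigid", order = 3, fixed_range = fr,
                     moving_range = fr)
  g1 <- nmi_gradient(v, v,
                     transform_chain(rigid_transform(c(2, 0, 0), c(0, 0, 0), ctr)),
                     pts, wrt = "rigid", order = 3, fixed_range = fr,
                     moving_range = fr)
  expect_lt(sqrt(sum(g0[4:6]^2)), 0.2 * sqrt(sum(g1[4:6]^2)))
  # off-center: the translation gradient points back toward alignment
  expect_lt(g1[["tx"]], 0)
})
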