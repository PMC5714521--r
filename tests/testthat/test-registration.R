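test_that("step size follows the decaying gain rule", {
  expect_equal(step_size(0, a = 1, A = 0, alpha = 1), 1)
  expect_equal(step_size(0, a = 4000, A = 50, alpha = 0.6), 4000 / 51^0.6)
  expect_lt(step_size(1e15, a = 4000, A = 50, alpha = 0.6), 1e-4)
  k <- 0:500
  s <- step_size(k, a = 2000, A = 50, alpha = 0.602)
  expect_true(all(diff(s) < 0))
  expect_error(step_size(0, a = -1), "config error")
  expect_error(step_size(-1, a = 1), ">= 0")
})

test_that("default configuration reproduces the published schedule", {
  cfg <- reg_config()
  expect_equal(vapply(cfg$rigid_schedule, `[[`, 1L, "factor"),
               c(16L, 8L, 4L, 2L, 1L))
  expect_equal(vapply(cfg$elastic_schedule, `[[`, 1L, "factor"),
               c(8L, 4L, 4L, 2L, 2L))
  its <- c(4096L, 2048L, 1024L, 512L, 256L)
  expect_equal(vapply(cfg$rigid_schedule, `[[`, 1L, "iterations"), its)
  expect_equal(vapply(cfg$elastic_schedule, `[[`, 1L, "iterations"), its)
  expect_equal(sum(its), 7936L)  # "about 8000" per stage
  expect_true(all(vapply(cfg$rigid_schedule, `[[`, 1, "a") == 4000))
  expect_equal(vapply(cfg$elastic_schedule, `[[`, 1, "a"),
               c(2000, 7000, 20000, 20000, 30000))
  expect_true(all(vapply(cfg$rigid_schedule, `[[`, 1, "alpha") == 0.6))
  expect_true(all(vapply(cfg$elastic_schedule, `[[`, 1, "alpha") == 0.602))
  expect_true(all(vapply(c(cfg$rigid_schedule, cfg$elastic_schedule),
                         `[[`, 1, "A") == 50))
  expect_equal(cfg$bins, 32L)
  expect_equal(cfg$samples_rigid, 5000L)
  expect_equal(cfg$samples_elastic, 4096L)
  expect_equal(cfg$grid_spacing_voxels, 8)
  expect_equal(cfg$control_points_per_iter, 5000L)
  expect_equal(c(cfg$interim_order, cfg$final_order), c(1L, 3L))
})

test_that("pyramid levels smooth, subsample and rescale geometry", {
  v <- volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1.5, 1.5, 3))
  p1 <- build_pyramid(v, 1)
  expect_identical(p1$data, v$data)
  p2 <- build_pyramid(v, 2)
  expect_equal(dim(p2$data), c(8L, 8L, 8L))
  expect_equal(p2$spacing, c(3, 3, 6))
  expect_equal(p2$origin, v$origin)
  cv <- volume(array(7, c(16, 16, 16)))
  expect_lt(max(abs(build_pyramid(cv, 4)$data - 7)), 1e-12)
  expect_error(build_pyramid(v, 32), "config error")
})

test_that("resampling honours interpolation orders and defaults", {
  ramp <- volume(array(rep(seq(0, 19) * 2, times = 400), c(20, 20, 20)),
                 spacing = c(2, 2, 2))
  same <- resample(ramp, transform_chain(), ramp, order = 1)
  expect_equal(same$data, ramp$data)
  cst <- volume(array(3.5, c(10, 10, 10)), spacing = c(2, 2, 2))
  rc <- resample(cst, transform_chain(rigid_transform(c(1, 1, 1))), cst,
                 order = 1)
  inside <- rc$data[1:9, 1:9, 1:9]
  expect_lt(max(abs(inside - 3.5)), 1e-12)
  # linear ramp under pure translation, order 1: analytically shifted
  sh <- resample(ramp, transform_chain(rigid_transform(c(3, 0, 0))), ramp,
                 order = 1)
  expect_lt(max(abs(sh$data[1:17, , ] - (ramp$data[1:17, , ] + 3))), 1e-6)
  # out-of-volume voxels take the default (minimum) intensity
  expect_equal(unique(as.vector(sh$data[19:20, , ])), min(ramp$data))
  expect_error(resample(ramp, transform_chain(), ramp, order = 2), "order")
})

test_that("rigid registration of an already-aligned pair stays near identity", {
  v <- smooth_volume(24, spacing = c(2.5, 2.5, 2.5))
  cfg <- reg_config(rigid_schedule = list(schedule_entry(2, 60, a = 600),
                                          schedule_entry(1, 60, a = 300)),
                    samples_rigid = 4000L, seed = 3L)
  rt <- register_rigid(v, v, cfg)
  expect_lt(max(abs(rt$translation)), 1.25)          # half a voxel
  expect_lt(max(abs(rt$rotation)), 0.5 * pi / 180)   # half a degree
  tr <- attr(rt, "trace")
  expect_true(all(is.finite(tr$value)))
  expect_equal(nrow(tr), 120L)
})

test_that("rigid registration recovers a known translation", {
  pc <- cached_phantom(7)
  an <- generate_anatomy(7)
  shifted <- warp_case(an, seed = 7, rigid_magnitude = 6, ffd_magnitude = 0)
  cfg <- reg_config(rigid_schedule = list(schedule_entry(8, 200, a = 4000),
                                          schedule_entry(4, 150, a = 4000)),
                    seed = 21L)
  rt <- register_rigid(shifted$ct, shifted$mr, cfg)
  # compare mappings at landmarks rather than raw parameters (centers differ)
  p <- landmark_points(shifted$ct_landmarks)
  err <- sqrt(rowSums((rigid_apply(rt, p) -
                         chain_apply(shifted$truth, p))^2))
  expect_lt(mean(err), 10)  # within one coarse (factor-4) voxel
})

test_that("elastic stage with an empty schedule returns init plus zero FFD", {
  v <- smooth_volume(16)
  cfg <- reg_config(elastic_schedule = list(), seed = 5L)
  init <- rigid_transform(c(1, 0, 0))
  ch <- register_bspline(v, v, init, cfg)
  expect_equal(ch$rigid$translation, init$translation)
  expect_equal(max(abs(ch$ffd$coefficients)), 0)
})

test_that("registration is deterministic under a fixed seed", {
  pc <- cached_phantom(7)
  cfg <- tiny_config(seed = 9L)
  f1 <- nmi_register(pc$ct, pc$mr, cfg)
  f2 <- nmi_register(pc$ct, pc$mr, cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$chain$ffd$coefficients, f2$chain$ffd$coefficients)
  expect_identical(f1$rigid_trace$value, f2$rigid_trace$value)
})

test_that("the fitted model interface exposes coef/predict/residuals/plot", {
  pc <- cached_phantom(7)
  fit <- nmi_register(pc$ct, pc$mr, tiny_config(seed = 4L))
  cf <- coef(fit)
  expect_named(cf, c("rx", "ry", "rz", "tx", "ty", "tz"))
  expect_true(is.array(attr(cf, "ffd_coefficients")))
  # predict on points equals chain_apply
  p <- landmark_points(pc$ct_landmarks)
  expect_equal(predict(fit, p), chain_apply(fit$chain, p, outside = "zero"))
  # predict with no newdata returns the registered volume on the fixed grid
  reg <- predict(fit)
  expect_equal(dim(reg$data), dim(pc$ct$data))
  r <- residuals(fit, pc$ct_landmarks, pc$mr_landmarks)
  expect_length(r, 16L)
  expect_true(all(r >= 0))
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
  expect_output(print(fit), "Two-stage")
  expect_output(summary(fit), "trace")
})
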