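# Focus metric, autofocus and the raster-scan controller.

test_that("focus metric matches a hand-convolved Laplacian oracle", {
  # uniform image: Laplacian of a constant is zero everywhere
  expect_identical(focus_metric(matrix(0.37, 32, 32)), 0)
  expect_identical(focus_metric(matrix(0L, 16, 16) + 200L / 255), 0)

  # single bright pixel: oracle convolves the 3x3 kernel explicitly
  m <- matrix(0, 9, 9)
  m[5, 5] <- 1
  kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- matrix(0, 7, 7)  # valid interior
  for (i in 2:8) for (j in 2:8) {
    lap[i - 1, j - 1] <- sum(m[(i - 1):(i + 1), (j - 1):(j + 1)] * kernel)
  }
  oracle <- mean((lap - mean(lap))^2)
  expect_equal(focus_metric(m), oracle, tolerance = 1e-12)

  # adding a constant to all pixels changes nothing
  expect_equal(focus_metric(m + 0.25), focus_metric(m), tolerance = 1e-12)

  # sharp checkerboard beats its smoothed version
  cb <- matrix(rep(c(0, 1), length.out = 32 * 32), 32, 32)
  smooth <- cb
  for (i in 2:31) for (j in 2:31) {
    smooth[i, j] <- mean(cb[(i - 1):(i + 1), (j - 1):(j + 1)])
  }
  expect_gt(focus_metric(cb), focus_metric(smooth))

  # degenerate inputs are rejected
  expect_error(focus_metric(matrix(numeric(0), 0, 0)), "zero pixels")
  expect_error(focus_metric(matrix(1, 2, 2)), "too small")
})

test_that("autofocus recovers a known focus height", {
  # true focal surface: flat plane at z* = 12 um
  sl <- test_slide(seed = 9, target_coverage = 0.5,
                   focal_coef = c(12, 0, 0, 0, 0))
  opt <- small_optics(96)
  zs <- z_search(coarse_range = 30, coarse_step = 6,
                 fine_range = 5, fine_step = 1, focus_window = NULL)
  af <- autofocus(sl, opt, 1000, 500, zs = zs, warm_start = 0)
  expect_s3_class(af, "focus_result")
  expect_equal(af$status, "ok")
  expect_lte(abs(af$best_z - 12), 1)
  expect_true(af$best_z %in% af$evaluated$z)
  # bounded work: coarse count + fine count
  expect_lte(nrow(af$evaluated), 11 + 11)

  # oracle: exhaustive evaluation over the same grid must agree
  metric_at <- vapply(af$evaluated$z, function(z) {
    focus_metric(render_field(sl, opt, 1000, 500, z))
  }, numeric(1))
  expect_equal(af$evaluated$metric, metric_at, tolerance = 1e-12)

  # single candidate z: best_z is that z, status ok
  one <- autofocus(sl, opt, 1000, 500,
                   zs = z_search(coarse_range = 0, coarse_step = 6,
                                 fine_range = 0, fine_step = 1,
                                 focus_window = NULL),
                   warm_start = 11)
  expect_identical(one$best_z, 11)
  expect_equal(one$status, "ok")
  expect_identical(nrow(one$evaluated), 1L)
})

test_that("content-free fields are reported flat", {
  blank <- test_slide(target_coverage = 0)
  opt <- small_optics(64, noise_sigma = 0)
  af <- autofocus(blank, opt, 1000, 500, warm_start = 2)
  expect_equal(af$status, "flat")
  expect_identical(af$best_z, 2)  # keeps the warm start
  # with default sensor noise the metric is flat across z too
  af2 <- autofocus(blank, small_optics(64), 1000, 500)
  expect_equal(af2$status, "flat")
})

test_that("scans follow the plan in serpentine order, reproducibly", {
  sl <- test_slide(seed = 4, target_coverage = 0.5,
                   focal_coef = c(2, 0.002, 0, 0, 0))
  opt <- small_optics(64)
  plan <- scan_plan(rows = 5, cols = 5, spacing = 70, serpentine = TRUE)
  scan <- execute_scan(sl, opt, plan)
  expect_length(scan$fields, 25)
  expect_identical(nrow(scan$log), 25L)
  # serpentine: x-coordinates of row 2 reverse row 1
  r1 <- scan$log$x[scan$log$row == 1]
  r2 <- scan$log$x[scan$log$row == 2]
  expect_identical(r2, rev(r1))
  expect_true(all(vapply(scan$fields, function(f) f$capture_mode,
                         character(1)) == "automated"))
  expect_true(all(!is.na(scan$log$metric)))

  # full reproducibility under the fixed slide seed
  scan2 <- execute_scan(sl, opt, plan)
  expect_identical(scan$log, scan2$log)
  expect_identical(lapply(scan$fields, `[[`, "pixels"),
                   lapply(scan2$fields, `[[`, "pixels"))

  # plans outside the slide are rejected
  bad <- scan_plan(positions = data.frame(x = -100, y = 50))
  expect_error(execute_scan(sl, opt, bad), "outside")

  # refocus_every > 1 reuses the previous best focus between stops
  scan3 <- execute_scan(sl, opt, scan_plan(rows = 2, cols = 3,
                                           spacing = 70,
                                           refocus_every = 3))
  expect_identical(scan3$log$status[2], "reused")
  expect_identical(scan3$log$best_z[2], scan3$log$best_z[1])
})

test_that("autofocus tracks a tilted focal surface across a scan", {
  sl <- test_slide(seed = 6, target_coverage = 0.55,
                   extent = c(2500, 1200),
                   focal_coef = c(0, 0.02, 0, 0, 0))
  opt <- small_optics(96)
  plan <- scan_plan(rows = 3, cols = 6, spacing = 100)
  scan <- execute_scan(sl, opt, plan)
  err <- abs(scan$log$best_z - focal_z(sl, scan$log$x, scan$log$y))
  ok <- scan$log$status == "ok"
  expect_gt(mean(err[ok] <= 1), 0.95)
})

test_that("manual capture mirrors the technician's sparse-slide fallback", {
  sl <- test_slide(seed = 15, target_coverage = 0.12,
                   extent = c(2500, 1200))
  opt <- small_optics(64)
  expect_identical(manual_capture(sl, opt, data.frame(x = numeric(0),
                                                      y = numeric(0))),
                   list())
  # same position twice: identical images under the fixed seed
  two <- manual_capture(sl, opt, data.frame(x = c(1200, 1200),
                                            y = c(600, 600)))
  expect_identical(two[[1]]$pixels, two[[2]]$pixels)
  expect_true(all(vapply(two, function(f) f$capture_mode,
                         character(1)) == "manual"))

  # picking the densest regions beats the slide average coverage
  cand <- expand.grid(x = seq(600, 1900, by = 130),
                      y = seq(350, 850, by = 125))
  best <- densest_fields(sl, opt, cand, k = 5)
  imgs <- manual_capture(sl, opt, best)
  mean_best <- mean(vapply(imgs, function(f) f$ground_truth$coverage,
                           numeric(1)))
  mean_all <- mean(vapply(seq_len(nrow(cand)), function(i) {
    true_coverage(sl, opt, cand$x[i], cand$y[i])
  }, numeric(1)))
  expect_gte(mean_best, mean_all)
})
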