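# Stereo rectification, disparity and depth.

mk_K <- function(f = 400, cx = 110, cy = 80) {
  matrix(c(f, 0, 0, 0, f, 0, cx, cy, 1), 3, 3)
}

test_that("disparity/depth conversion is an exact involution with flags", {
  expect_equal(depth_to_disparity(120, 50, 1176.5), 490.2, tolerance = 0.05)
  expect_equal(disparity_to_depth(490.2083, 50, 1176.5), 120, tolerance = 1e-4)
  z <- seq(20, 2000, length.out = 50)
  expect_equal(disparity_to_depth(depth_to_disparity(z, 50, 1176.5), 50, 1176.5),
               z, tolerance = 1e-12)
  expect_true(all(is.na(disparity_to_depth(c(0, -2), 50, 1176.5))))
  # reciprocal law: doubling disparity halves depth
  expect_equal(disparity_to_depth(20, 50, 1000), 2 * disparity_to_depth(40, 50, 1000))
})

test_that("already-rectified pair passes through up to resampling", {
  K <- mk_K()
  calib <- stereo_calibration(K, K, translation_mm = c(-50, 0, 0),
                              image_size = c(160, 220))
  img <- with_seed_test(5, matrix(runif(160 * 220), 160, 220))
  r <- rectify_pair(img, img, calib)
  inner <- 20:140
  expect_lt(max(abs(r$left_rect[inner, 30:190] - img[inner, 30:190])), 1e-6)
  expect_equal(r$rectified_calib$baseline_mm, 50)
})

test_that("rectification aligns epipolar rows on random synthetic calibrations", {
  worst <- 0
  for (i in 1:100) {
    cal <- with_seed_test(100 + i, {
      K1 <- mk_K(380 + runif(1, 0, 40), 105 + runif(1, -5, 5), 78 + runif(1, -4, 4))
      K2 <- mk_K(380 + runif(1, 0, 40), 105 + runif(1, -5, 5), 78 + runif(1, -4, 4))
      R <- rot3(runif(3, -1, 1), runif(1, 0, 10))
      T <- c(-50, 0, 0) + runif(3, -3, 3)
      d1 <- c(runif(2, -0.1, 0.1), runif(2, -0.01, 0.01), runif(1, -0.05, 0.05))
      d2 <- c(runif(2, -0.1, 0.1), runif(2, -0.01, 0.01), runif(1, -0.05, 0.05))
      pts <- cbind(runif(10, -30, 30), runif(10, -25, 25), runif(10, 100, 300))
      list(calib = stereo_calibration(K1, K2, d1, d2, R, T, c(160, 220)),
           pts = pts)
    })
    rect <- multivein:::rectification_transforms(cal$calib)
    for (k in seq_len(nrow(cal$pts))) {
      X <- cal$pts[k, ]
      pl <- oracle_project(X, cal$calib$K_left, cal$calib$dist_left)
      pr <- oracle_project(X, cal$calib$K_right, cal$calib$dist_right,
                           cal$calib$rotation, cal$calib$translation_mm)
      ql <- multivein:::rectified_pixel(cal$calib, rect, "left", rbind(pl))
      qr <- multivein:::rectified_pixel(cal$calib, rect, "right", rbind(pr))
      worst <- max(worst, abs(ql[1, "y"] - qr[1, "y"]))
    }
  }
  expect_lt(worst, 0.5)
})

test_that("rotated right camera (5 deg about y) still rectifies to equal rows", {
  K <- mk_K()
  calib <- stereo_calibration(K, K, rotation = rot3(c(0, 1, 0), 5),
                              translation_mm = c(-48, 0, 0),
                              image_size = c(160, 220))
  rect <- multivein:::rectification_transforms(calib)
  pts <- with_seed_test(9, cbind(runif(20, -30, 30), runif(20, -25, 25),
                                 runif(20, 90, 250)))
  for (k in seq_len(nrow(pts))) {
    X <- pts[k, ]
    pl <- oracle_project(X, K, rep(0, 5))
    pr <- oracle_project(X, K, rep(0, 5), calib$rotation, calib$translation_mm)
    ql <- multivein:::rectified_pixel(calib, rect, "left", rbind(pl))
    qr <- multivein:::rectified_pixel(calib, rect, "right", rbind(pr))
    expect_lt(abs(ql[1, "y"] - qr[1, "y"]), 0.5)
  }
})

test_that("block matching recovers a pure integer shift", {
  st <- render_stereo_pair(c(12, 0, 0), seed = 1)
  dm <- compute_disparity(st$left, st$right, max_disparity = 32)
  expect_lt(abs(median(dm$disparity[dm$valid]) - 12), 0.5)
  expect_gt(mean(dm$valid), 0.5)
})

test_that("slanted-plane disparity is recovered to sub-pixel accuracy", {
  st <- render_stereo_pair(c(25, -0.05, 0.02), seed = 2)
  dm <- compute_disparity(st$left, st$right, max_disparity = 48)
  err <- abs(dm$disparity - st$disparity_true)[dm$valid]
  expect_lt(median(err), 1)
  d <- dm$disparity
  xs <- matrix(seq_len(ncol(d)), nrow(d), ncol(d), byrow = TRUE)
  ys <- matrix(seq_len(nrow(d)), nrow(d), ncol(d))
  fit <- lm(as.vector(d) ~ as.vector(xs) + as.vector(ys))
  expect_equal(unname(coef(fit)[2]), -0.05, tolerance = 0.05)
})

test_that("untextured input yields a mostly-invalid map with a warning", {
  flat <- matrix(0.5, 80, 100)
  expect_warning(dm <- compute_disparity(flat, flat, max_disparity = 16),
                 "invalid")
  expect_lt(mean(dm$valid), 0.1)
})

test_that("align_view is the identity for the reference camera itself", {
  K <- mk_K()
  calib <- stereo_calibration(K, K, translation_mm = c(-50, 0, 0),
                              image_size = c(120, 160))
  rect <- multivein:::rectification_transforms(calib)
  img <- with_seed_test(7, matrix(runif(120 * 160), 120, 160))
  depth <- matrix(150, 120, 160)
  src_calib <- list(K = K, dist = rep(0, 5), rotation = diag(3),
                    translation_mm = c(0, 0, 0))
  av <- align_view(img, depth, src_calib, rect)
  inner <- cbind(rep(20:100, 5), rep(seq(20, 140, 30), each = 81))
  expect_lt(max(abs(av$image[inner] - img[inner])), 1e-6)
})

test_that("lateral source camera offset shows up as the projected constant shift", {
  K <- mk_K(f = 400)
  calib <- stereo_calibration(K, K, translation_mm = c(-50, 0, 0),
                              image_size = c(120, 160))
  rect <- multivein:::rectification_transforms(calib)
  z <- 200
  shift_px <- 400 * 10 / z   # f * offset / depth = 20 px
  img <- with_seed_test(8, matrix(runif(120 * 160), 120, 160))
  depth <- matrix(z, 120, 160)
  src_calib <- list(K = K, dist = rep(0, 5), rotation = diag(3),
                    translation_mm = c(-10, 0, 0))   # source 10 mm to the right
  av <- align_view(img, depth, src_calib, rect)
  # sampled source pixel = reference pixel shifted by -shift_px in x
  ys <- 30:90; xs <- 40:120
  expect_lt(max(abs(av$image[ys, xs] - img[ys, xs - shift_px])), 1e-6)
})

test_that("all-invalid depth flags every output pixel as a hole", {
  K <- mk_K(cx = 25, cy = 20)
  calib <- stereo_calibration(K, K, translation_mm = c(-50, 0, 0),
                              image_size = c(40, 50))
  rect <- multivein:::rectification_transforms(calib)
  av <- align_view(matrix(0.5, 40, 50), matrix(NA_real_, 40, 50),
                   list(K = K, dist = rep(0, 5), rotation = diag(3),
                        translation_mm = c(0, 0, 0)), rect)
  expect_equal(av$n_holes, 40 * 50)
})

test_that("calibration invariants are enforced", {
  K <- mk_K(cx = 50, cy = 50)
  R_bad <- diag(3); R_bad[1, 2] <- 1e-4
  expect_error(stereo_calibration(K, K, rotation = R_bad,
                                  translation_mm = c(-50, 0, 0),
                                  image_size = c(100, 100)), "orthonormal")
  expect_error(stereo_calibration(K, K, translation_mm = c(0, 0, 0),
                                  image_size = c(100, 100)), "baseline")
  calib <- stereo_calibration(K, K, translation_mm = c(-50, 0, 0),
                              image_size = c(100, 100))
  expect_error(rectify_pair(matrix(0, 50, 50), matrix(0, 50, 50), calib),
               "dimensions")
})
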