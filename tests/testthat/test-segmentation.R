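# Foreground masking, finger extraction, reordering, rotation normalization.

test_that("Otsu threshold separates a bimodal image and opening removes specks", {
  img <- matrix(10 / 255, 60, 60)
  img[, 31:60] <- 200 / 255
  m <- foreground_mask(img, opening_radius = 0)
  expect_true(all(m[, 31:60]) && !any(m[, 1:30]))

  img2 <- bar_image(h = 100, w = 80, x0 = 30, x1 = 50)
  img2[10:12, 65:67] <- 0.9        # 3 px speck on background
  m2 <- foreground_mask(img2, opening_radius = 5)
  expect_false(any(m2[1:100, 60:80]))
  expect_true(any(m2[, 30:50]))
  expect_error(foreground_mask(matrix(0.5, 10, 10)), "constant")
})

test_that("hand mask matches the generator silhouette closely", {
  r <- render_hand(make_identity(2), render_params(), sample_seed = 3)
  m <- foreground_mask(r$image)
  dice <- 2 * sum(m & r$truth$silhouette) / (sum(m) + sum(r$truth$silhouette))
  expect_gte(dice, 0.98)
})

test_that("four disjoint bars are extracted tallest-first with exact tips", {
  img <- matrix(0.05, 200, 200)
  tops <- c(40, 10, 20, 30)            # tallest is bar 2
  lefts <- c(20, 70, 120, 170)
  for (i in 1:4) img[tops[i]:160, lefts[i]:(lefts[i] + 20)] <- 0.8
  res <- extract_fingers(img, mask = img > 0.5)
  expect_true(res$complete)
  tip_rows <- vapply(res$fingers, function(f) f$origin_rc[1] + 5, numeric(1))
  expect_equal(tip_rows, sort(tops))   # extraction order = tip height
  # all bar pixels are recovered; nothing left in the residual
  expect_equal(sum(vapply(res$fingers, function(f) sum(f$mask), numeric(1))),
               sum(img > 0.5))
})

test_that("foreground pixels are conserved between fingers and residual", {
  r <- render_hand(make_identity(4), render_params(), sample_seed = 8)
  m <- foreground_mask(r$image)
  res <- extract_fingers(r$image, m)
  traced <- sum(vapply(res$fingers, function(f) sum(f$mask), numeric(1)))
  expect_equal(traced + sum(res$residual_mask), sum(m))
})

test_that("a three-finger hand is reported incomplete, not an error", {
  img <- matrix(0.05, 150, 150)
  for (l in c(20, 60, 100)) img[30:100, l:(l + 18)] <- 0.8
  res <- extract_fingers(img)
  expect_false(res$complete)
  expect_length(res$fingers, 3)
  expect_error(reorder_fingers(res, "RH"), "cannot tell")
})

test_that("reordering assigns anatomical labels by centroid and hand", {
  img <- matrix(0.05, 150, 200)
  for (l in c(20, 65, 110, 155)) img[30:100, l:(l + 15)] <- 0.8
  rh <- reorder_fingers(extract_fingers(img), "RH")
  expect_equal(vapply(rh$fingers, `[[`, character(1), "finger_label"),
               c("index", "middle", "ring", "little"))
  expect_true(all(diff(vapply(rh$fingers, function(f) f$centroid_xy[1],
                              numeric(1))) > 0))
  lh <- reorder_fingers(extract_fingers(img), "LH")
  expect_true(all(diff(vapply(lh$fingers, function(f) f$centroid_xy[1],
                              numeric(1))) < 0))
  # palm-up flips the orientation
  rh_up <- reorder_fingers(extract_fingers(img), "RH", palm_down = FALSE)
  expect_true(all(diff(vapply(rh_up$fingers, function(f) f$centroid_xy[1],
                              numeric(1))) < 0))
})

test_that("label assignment is invariant to the stored finger order", {
  img <- matrix(0.05, 150, 200)
  for (l in c(20, 65, 110, 155)) img[30:100, l:(l + 15)] <- 0.8
  res <- extract_fingers(img)
  perm <- res
  perm$fingers <- perm$fingers[c(3, 1, 4, 2)]
  a <- reorder_fingers(res, "RH")
  b <- reorder_fingers(perm, "RH")
  expect_equal(lapply(a$fingers, `[[`, "centroid_xy"),
               lapply(b$fingers, `[[`, "centroid_xy"))
})

test_that("rotation normalization recovers injected tilts", {
  # axis-aligned bar: no rotation applied
  f0 <- finger_image(bar_image(), bar_image() > 0.5)
  n0 <- normalize_finger(f0)
  expect_lt(abs(n0$rotation_deg), 0.1)
  # synthetic finger with a known tilt
  p <- render_params(rotation_jitter_deg = 10, translation_jitter_px = 1e-9,
                     gain_jitter = 1e-9, illumination_gradient = 1e-9,
                     noise_sd = 1e-9)
  for (seed in 1:3) {
    sf <- synth_finger(3, seed, params = p)
    truth_rot <- sf$truth$rotations_deg[2]
    expect_lt(abs(sf$finger$rotation_deg - (-truth_rot)), 0.5)
  }
  # idempotence: a second normalization changes nearly nothing
  sf <- synth_finger(3, 4, params = p)
  again <- normalize_finger(sf$finger)
  expect_lt(abs(again$rotation_deg - sf$finger$rotation_deg), 0.2)
})

test_that("over-rotated crops and short masks are rejected", {
  m <- matrix(FALSE, 80, 80)
  for (r in 1:60) m[10 + r, pmax(1, pmin(80, (r + 5):(r + 12)))] <- TRUE  # ~45 deg
  f <- finger_image(m * 0.8, m)
  expect_error(normalize_finger(f, max_angle = 30), "non-finger")
  short <- finger_image(matrix(0.5, 10, 10), matrix(TRUE, 10, 10))
  expect_error(normalize_finger(short), "20 rows")
})

test_that("finger_image enforces its invariants", {
  expect_error(finger_image(matrix(0, 5, 5), matrix(FALSE, 5, 5)), "empty")
  expect_error(finger_image(matrix(0, 5, 5), matrix(TRUE, 4, 4)), "shapes")
  expect_error(finger_image(matrix(0, 5, 5), matrix(TRUE, 5, 5),
                            rotation_deg = 50), "non-finger")
})
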