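# Enhancement and maximum-curvature template extraction.

test_that("identity enhancer returns the input bit-exactly; unknown ids fail", {
  f <- ridge_finger()
  expect_identical(enhance_veins(f, "none"), f)
  expect_error(enhance_veins(f, "rcae"), "unknown enhancer")
  # registry extension point
  doubled <- enhance_veins(f, "twice", extra_methods = list(
    twice = function(fi, p) { fi$image <- 2 * fi$image; fi }))
  expect_equal(doubled$image, 2 * f$image)
})

test_that("baseline enhancement flattens a multiplicative illumination gradient", {
  base <- ridge_finger(h = 120, w = 80)
  grad <- matrix(seq(0.7, 1.3, length.out = 80), 120, 80, byrow = TRUE)
  lit <- base
  lit$image <- base$image * grad
  enh <- enhance_veins(lit, "baseline")
  # the illumination residual is the smooth linear trend of the column means,
  # measured on interior off-ridge columns (away from edge effects)
  trend <- function(img, cols) {
    cm <- colMeans(img)[cols]
    unname(abs(coef(lm(cm ~ cols))[2])) * length(cols) / mean(cm)
  }
  off <- c(15:28, 52:65)
  expect_gt(trend(lit$image, off) / trend(enh$image, off), 5)
})

test_that("flat input produces flat output with no hallucinated structure", {
  f <- finger_image(matrix(0.5, 60, 40), matrix(TRUE, 60, 40))
  enh <- enhance_veins(f, "baseline")
  expect_lte(sd(enh$image), sd(f$image) + 1e-12)
  expect_error(extract_mc(enh), "flat profile")
})

test_that("a single vertical ridge concentrates active pixels at its centre", {
  t <- extract_mc(ridge_finger(center = 40), erode_margin = 3)
  idx <- which(t$feature_map, arr.ind = TRUE)
  frac <- mean(idx[, 2] >= 39 & idx[, 2] <= 41)
  expect_gte(frac, 0.9)
})

test_that("two parallel ridges give two disjoint near-vertical components", {
  xs <- matrix(seq_len(80), 100, 80, byrow = TRUE)
  img <- 0.8 * (1 - 0.4 * exp(-(xs - 30)^2 / 18) - 0.4 * exp(-(xs - 50)^2 / 18))
  f <- finger_image(img, matrix(TRUE, 100, 80))
  t <- extract_mc(f)
  idx <- which(t$feature_map, arr.ind = TRUE)
  expect_true(all(abs(idx[, 2] - 30) <= 3 | abs(idx[, 2] - 50) <= 3))
  expect_gt(sum(abs(idx[, 2] - 30) <= 3), 10)
  expect_gt(sum(abs(idx[, 2] - 50) <= 3), 10)
})

test_that("templates are exactly invariant to affine intensity transforms", {
  f <- synth_finger(6, 11)$finger
  t1 <- extract_mc(f)
  g <- f
  g$image <- 1.7 * f$image + 0.12
  t2 <- extract_mc(g)
  expect_identical(t1$feature_map, t2$feature_map)
})

test_that("background padding translates the template without changing it", {
  # mask strictly inside the crop so padding never touches masked context
  f0 <- ridge_finger(h = 100, w = 80, center = 40)
  mask <- matrix(FALSE, 100, 80)
  mask[13:88, 13:68] <- TRUE
  f <- finger_image(f0$image, mask)
  t1 <- extract_mc(f)
  pad <- 7
  img2 <- matrix(0.1, 100 + pad, 80 + pad)   # arbitrary background
  img2[(pad + 1):(100 + pad), (pad + 1):(80 + pad)] <- f$image
  mask2 <- matrix(FALSE, 100 + pad, 80 + pad)
  mask2[(pad + 1):(100 + pad), (pad + 1):(80 + pad)] <- f$mask
  t2 <- extract_mc(finger_image(img2, mask2))
  shifted <- matrix(FALSE, 100 + pad, 80 + pad)
  shifted[(pad + 1):(100 + pad), (pad + 1):(80 + pad)] <- t1$feature_map
  expect_identical(t2$feature_map, shifted)
})

test_that("active template pixels lie near true vein centerlines", {
  # fingers rendered without tilt so crop and source coordinates stay parallel
  p <- render_params(rotation_jitter_deg = 1e-9, translation_jitter_px = 1e-9,
                     gain_jitter = 1e-9, illumination_gradient = 1e-9,
                     noise_sd = 0.01, visibility_jitter = 1e-9)
  dists <- c()
  for (seed in 1:6) {
    id <- make_identity(200 + seed)
    r <- render_hand(id, p, sample_seed = seed)
    seg <- reorder_fingers(extract_fingers(r$image), "RH")
    for (slot in 1:4) {
      f <- seg$fingers[[slot]]
      t <- extract_mc(enhance_veins(f))
      idx <- which(t$feature_map, arr.ind = TRUE)
      # centerline points in crop coordinates
      cl <- do.call(rbind, lapply(r$truth$vein_centerlines[[slot]], function(p2) {
        steps <- seq(0, 1, length.out = 400)
        i <- pmin(nrow(p2) - 1, floor(steps * (nrow(p2) - 1)) + 1)
        fr <- steps * (nrow(p2) - 1) - (i - 1)
        cbind(p2[i, 1] + fr * (p2[pmin(i + 1, nrow(p2)), 1] - p2[i, 1]),
              p2[i, 2] + fr * (p2[pmin(i + 1, nrow(p2)), 2] - p2[i, 2]))
      }))
      cl[, 1] <- cl[, 1] - f$origin_rc[1] + 1
      cl[, 2] <- cl[, 2] - f$origin_rc[2] + 1
      d <- vapply(seq_len(nrow(idx)), function(i)
        sqrt(min((cl[, 1] - idx[i, 1])^2 + (cl[, 2] - idx[i, 2])^2)), numeric(1))
      dists <- c(dists, mean(d))
    }
  }
  expect_lte(max(dists), 2)
})

test_that("template invariants are enforced", {
  expect_error(vein_template(matrix(FALSE, 10, 10)), "empty-template")
  expect_error(vein_template(matrix(TRUE, 10, 10)), "30%")
  f <- finger_image(matrix(0.5, 50, 30), matrix(c(TRUE, rep(FALSE, 1499)), 50, 30))
  expect_error(extract_mc(ridge_finger(), directions = "sideways"), "unknown scan")
})
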