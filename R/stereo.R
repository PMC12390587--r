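#' Stereo calibration parameters
#'
#' Intrinsics (3x3 camera matrix and 5-coefficient radial/tangential
#' distortion, OpenCV ordering k1 k2 p1 p2 k3) per camera, plus extrinsics of
#' the right camera with respect to the left: `x_right = R x_left + T`.
#'
#' @param K_left,K_right 3x3 camera matrices (pixel units).
#' @param dist_left,dist_right length-5 distortion vectors.
#' @param rotation 3x3 orthonormal rotation of the right camera w.r.t. left.
#' @param translation_mm length-3 translation in mm.
#' @param image_size `c(rows, cols)` of the camera images.
#' @return Object of class `stereo_calibration`; `baseline_mm` is the norm of
#'   the translation.
#' @export
stereo_calibration <- function(K_left, K_right, dist_left = rep(0, 5),
                               dist_right = rep(0, 5), rotation = diag(3),
                               translation_mm, image_size) {
  R <- as.matrix(rotation)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stopf("calibration error: rotation is not orthonormal within 1e-8")
  T <- as.numeric(translation_mm)
  B <- sqrt(sum(T^2))
  if (B <= 0) stopf("calibration error: baseline must be positive")
  for (K in list(K_left, K_right)) {
    if (K[1, 3] < 0 || K[1, 3] > image_size[2] || K[2, 3] < 0 || K[2, 3] > image_size[1])
      stopf("calibration error: principal point outside image bounds")
  }
  structure(list(K_left = K_left, K_right = K_right,
                 dist_left = as.numeric(dist_left), dist_right = as.numeric(dist_right),
                 rotation = R, translation_mm = T, baseline_mm = B,
                 image_size = as.integer(image_size)),
            class = "stereo_calibration")
}

# Brown distortion of normalized pinhole coordinates (x, y).
distort_points <- function(x, y, d) {
  r2 <- x^2 + y^2
  rad <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- x * rad + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * rad + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  list(x = xd, y = yd)
}

# Inverse of distort_points by fixed-point iteration.
undistort_points <- function(xd, yd, d, iters = 25) {
  x <- xd; y <- yd
  for (i in seq_len(iters)) {
    r2 <- x^2 + y^2
    rad <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
    dx <- 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
    dy <- d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
    x <- (xd - dx) / rad
    y <- (yd - dy) / rad
  }
  list(x = x, y = y)
}

# Rectifying rotations and shared pinhole for a calibrated pair.
rectification_transforms <- function(calib) {
  R <- calib$rotation; T <- calib$translation_mm
  b <- as.numeric(-t(R) %*% T)     # right camera centre in left frame
  e1 <- b / sqrt(sum(b^2))
  e2 <- c(-e1[2], e1[1], 0)
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R_rect <- rbind(e1, e2, e3)
  K_new <- calib$K_left
  K_new[1, 2] <- 0
  K_new[2, 2] <- K_new[1, 1]        # square pixels in the rectified frame
  list(R_left = R_rect, R_right = R_rect %*% t(R), K_new = K_new,
       baseline_mm = sqrt(sum(b^2)), focal_px = K_new[1, 1])
}

# Map original (distorted) pixel coordinates of one camera into the rectified
# frame.  `xy` is an n x 2 matrix of (x, y) pixels.
rectified_pixel <- function(calib, rect, camera = c("left", "right"), xy) {
  camera <- match.arg(camera)
  K <- if (camera == "left") calib$K_left else calib$K_right
  d <- if (camera == "left") calib$dist_left else calib$dist_right
  Rr <- if (camera == "left") rect$R_left else rect$R_right
  xd <- (xy[, 1] - K[1, 3]) / K[1, 1]
  yd <- (xy[, 2] - K[2, 3]) / K[2, 2]
  u <- undistort_points(xd, yd, d)
  rays <- rbind(u$x, u$y, 1)
  rot <- Rr %*% rays
  Kn <- rect$K_new
  cbind(x = Kn[1, 1] * rot[1, ] / rot[3, ] + Kn[1, 3],
        y = Kn[2, 2] * rot[2, ] / rot[3, ] + Kn[2, 3])
}

#' Rectify a calibrated stereo pair
#'
#' Resamples both images so that epipolar lines become horizontal and
#' corresponding points share the same row: each output pixel is inverse-mapped
#' through the rectifying rotation and the lens distortion model into the
#' source image and sampled bilinearly.
#'
#' @param left,right 2-D numeric matrices matching the calibration image size.
#' @param calib a [stereo_calibration()].
#' @return list with `left_rect`, `right_rect` and `rectified_calib` (new
#'   shared camera matrix, rectifying rotations, `baseline_mm`, `focal_px`).
#' @export
rectify_pair <- function(left, right, calib) {
  stopifnot(inherits(calib, "stereo_calibration"))
  if (!all(dim(left) == calib$image_size) || !all(dim(right) == calib$image_size))
    stopf("validation error: image dimensions do not match calibration (%d x %d)",
          calib$image_size[1], calib$image_size[2])
  rect <- rectification_transforms(calib)
  h <- nrow(left); w <- ncol(left)
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  Kn <- rect$K_new
  rays <- rbind((g$x - Kn[1, 3]) / Kn[1, 1], (g$y - Kn[2, 3]) / Kn[2, 2], 1)
  warp_one <- function(img, K, d, Rr) {
    src <- t(Rr) %*% rays
    x <- src[1, ] / src[3, ]
    y <- src[2, ] / src[3, ]
    dd <- distort_points(x, y, d)
    px <- K[1, 1] * dd$x + K[1, 3]
    py <- K[2, 2] * dd$y + K[2, 3]
    matrix(bilinear_sample(img, py, px, fill = 0), h, w)
  }
  list(left_rect = warp_one(left, calib$K_left, calib$dist_left, rect$R_left),
       right_rect = warp_one(right, calib$K_right, calib$dist_right, rect$R_right),
       rectified_calib = rect)
}

#' Convert disparity to metric depth (and back)
#'
#' `z = B f / d` for baseline `B` (mm), focal length `f` (pixels) and
#' disparity `d` (pixels).  Non-positive disparities have undefined depth and
#' map to `NA`.
#'
#' @param d_px disparity in pixels.
#' @param baseline_mm stereo baseline in mm.
#' @param focal_px focal length in pixels.
#' @return depth in mm (`NA` where `d_px <= 0`).
#' @export
disparity_to_depth <- function(d_px, baseline_mm, focal_px) {
  z <- baseline_mm * focal_px / d_px
  z[!is.finite(d_px) | d_px <= 0] <- NA_real_
  z
}

#' @rdname disparity_to_depth
#' @param z_mm depth in mm.
#' @export
depth_to_disparity <- function(z_mm, baseline_mm, focal_px) {
  d <- baseline_mm * focal_px / z_mm
  d[!is.finite(z_mm) | z_mm <= 0] <- NA_real_
  d
}

#' Dense disparity by block matching with sub-pixel refinement
#'
#' Sum-of-absolute-differences block matching over an integer disparity range
#' (disparity convention `d = x_left - x_right >= 0`, left image is the
#' reference), winner-take-all minimum with parabola-fit sub-pixel
#' refinement.  Pixels with insufficient local texture, at the disparity
#' search border, or failing a uniqueness check are flagged invalid.
#'
#' @param left_rect,right_rect rectified pair.
#' @param max_disparity largest disparity searched (pixels).
#' @param block odd block size for the SAD window (default 9).
#' @param texture_min minimum local intensity standard deviation for a pixel
#'   to be considered matchable.
#' @param uniqueness best cost must be below `uniqueness` times the
#'   second-best (non-adjacent) cost.
#' @return Object of class `disparity_map`: `disparity` (numeric matrix, `NA`
#'   where invalid), `valid` (logical matrix), plus the search parameters.
#' @export
compute_disparity <- function(left_rect, right_rect, max_disparity = 64,
                              block = 9, texture_min = 0.01, uniqueness = 0.98) {
  h <- nrow(left_rect); w <- ncol(left_rect)
  nd <- max_disparity + 1
  costs <- array(Inf, dim = c(h, w, nd))
  for (d in 0:max_disparity) {
    shifted <- shift_matrix(right_rect, 0, d, fill = NA)
    diffim <- abs(left_rect - shifted)
    diffim[is.na(diffim)] <- 1e3    # heavy penalty outside the overlap
    costs[, , d + 1] <- box_sum(diffim, block)
  }
  flat <- matrix(costs, nrow = h * w, ncol = nd)
  best <- max.col(-flat, ties.method = "first")
  bestcost <- flat[cbind(seq_len(h * w), best)]
  # uniqueness: second-best cost outside +-1 of the winner
  second <- rep(Inf, h * w)
  for (d in seq_len(nd)) {
    m <- abs(d - best) > 1
    second[m] <- pmin(second[m], flat[m, d])
  }
  # sub-pixel parabola through the three costs around the winner
  dsub <- as.numeric(best - 1)
  interior <- best > 1 & best < nd
  if (any(interior)) {
    i <- which(interior)
    c0 <- flat[cbind(i, best[i] - 1)]
    c1 <- flat[cbind(i, best[i])]
    c2 <- flat[cbind(i, best[i] + 1)]
    denom <- c0 - 2 * c1 + c2
    ok <- denom > 0
    dsub[i[ok]] <- (best[i] - 1)[ok] + 0.5 * ((c0 - c2)[ok] / denom[ok])
  }
  texture <- sqrt(pmax(0, box_sum(left_rect^2, block) / block^2 -
                         (box_sum(left_rect, block) / block^2)^2))
  valid <- matrix(TRUE, h, w)
  valid[texture < texture_min] <- FALSE
  valid <- valid & matrix(bestcost < uniqueness * second | second == Inf, h, w)
  # exclude the left margin: columns where the full search range cannot be
  # evaluated latch onto spurious matches
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  valid <- valid & (xs - matrix(dsub, h, w) >= 1)
  valid <- valid & (xs > max_disparity + block %/% 2)
  valid <- valid & matrix(is.finite(bestcost) & bestcost < 1e3 * block^2 / 2, h, w)
  if (mean(valid) < 0.1)
    warnf("disparity map mostly invalid (%.1f%% valid): insufficient texture?",
          100 * mean(valid))
  disp <- matrix(dsub, h, w)
  disp[!valid] <- NA_real_
  structure(list(disparity = disp, valid = valid,
                 max_disparity = max_disparity, block = block),
            class = "disparity_map")
}

#' @export
print.disparity_map <- function(x, ...) {
  cat(sprintf("disparity_map: %d x %d, %.1f%% valid, median %.2f px\n",
              nrow(x$disparity), ncol(x$disparity), 100 * mean(x$valid),
              median(x$disparity[x$valid])))
  invisible(x)
}

#' Align another camera view onto the left rectified frame
#'
#' Forward-projects every left-rectified pixel to 3-D through the depth map,
#' reprojects it into the source camera (e.g. the RGB camera) and samples the
#' source image there.  Pixels without valid depth, or projecting outside the
#' source image, become holes.
#'
#' @param src source image (2-D matrix).
#' @param depth_map depth in mm per left-rectified pixel (`NA` = invalid).
#' @param src_calib list with `K`, `dist`, `rotation`, `translation_mm` of the
#'   source camera w.r.t. the *original left* camera
#'   (`x_src = R x_left + T`).
#' @param rectified_calib rectified calibration from [rectify_pair()].
#' @return list with `image` (holes are `NA`), `valid`, `n_holes`.
#' @export
align_view <- function(src, depth_map, src_calib, rectified_calib) {
  h <- nrow(depth_map); w <- ncol(depth_map)
  Kn <- rectified_calib$K_new
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  z <- as.vector(depth_map)
  ok <- is.finite(z) & z > 0
  out <- rep(NA_real_, h * w)
  if (any(ok)) {
    xr <- (g$x[ok] - Kn[1, 3]) / Kn[1, 1] * z[ok]
    yr <- (g$y[ok] - Kn[2, 3]) / Kn[2, 2] * z[ok]
    X_rect <- rbind(xr, yr, z[ok])
    X_left <- t(rectified_calib$R_left) %*% X_rect
    X_src <- src_calib$rotation %*% X_left + src_calib$translation_mm
    x <- X_src[1, ] / X_src[3, ]
    y <- X_src[2, ] / X_src[3, ]
    dd <- distort_points(x, y, src_calib$dist)
    px <- src_calib$K[1, 1] * dd$x + src_calib$K[1, 3]
    py <- src_calib$K[2, 2] * dd$y + src_calib$K[2, 3]
    v <- bilinear_sample(src, py, px, fill = NA)
    out[ok] <- v
  }
  img <- matrix(out, h, w)
  valid <- is.finite(img)
  list(image = img, valid = valid, n_holes = sum(!valid))
}

#' Export a depth map as 32-bit float TIFF
#' @param depth numeric matrix (mm); `NA` written as 0.
#' @param path output path.
#' @param scale divisor bringing depths into [0, 1] for the float container.
#' @export
write_depth_map <- function(depth, path, scale = max(depth, na.rm = TRUE)) {
  d <- depth / scale
  d[!is.finite(d)] <- 0
  tiff::writeTIFF(d, path, bits.per.sample = 32)
  invisible(path)
}
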