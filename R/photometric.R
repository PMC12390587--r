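#' Photometric-stereo light rig
#'
#' Holds the unit direction vectors of the directional light sources (pointing
#' from the surface towards each light) and, optionally, one flat-field
#' reference image per source (a constant-albedo plane captured under that
#' source, used to cancel illumination falloff).
#'
#' @param directions numeric matrix, one row per source, 3 columns; each row
#'   must be unit-norm (within 1e-9 it is renormalized, beyond that it is an
#'   error).  At least 3 sources, and the direction matrix must have rank 3.
#' @param flat_fields optional list of reference images (2-D matrices), one
#'   per source.
#' @return Object of class `light_rig`.
#' @export
light_rig <- function(directions, flat_fields = NULL) {
  L <- as.matrix(directions)
  if (ncol(L) != 3 || nrow(L) < 3)
    stopf("need at least 3 light directions as rows of an n x 3 matrix")
  nrm <- sqrt(rowSums(L^2))
  if (any(abs(nrm - 1) > 1e-6))
    stopf("light directions must be unit vectors (worst deviation %.3g)",
          max(abs(nrm - 1)))
  L <- L / nrm
  if (!is.null(flat_fields) && length(flat_fields) != nrow(L))
    stopf("need one flat-field reference per light source")
  structure(list(directions = L, flat_fields = flat_fields), class = "light_rig")
}

# rank of the light matrix; < 3 means normals are unrecoverable
light_rank <- function(L) qr(L)$rank

#' Flat-field correction of an illumination-dependent image stack
#'
#' Divides each frame by its flat-field reference (a constant-albedo plane
#' captured under the same source), cancelling the inverse-square illumination
#' falloff: `corrected = frame / max(reference, eps)`.  A frame equal to its
#' reference maps to the unit image.  Reference pixels at (or near) zero are
#' masked; if at least 1% of reference pixels are zero a warning is emitted.
#'
#' @param frames list of 2-D matrices (one per light source).
#' @param rig a [light_rig()] carrying `flat_fields`.
#' @param eps floor applied to the reference before division.
#' @return list with `frames` (corrected stack) and `valid` (logical matrix,
#'   FALSE where any reference was degenerate).
#' @export
flat_field_correct <- function(frames, rig, eps = 1e-8) {
  stopifnot(inherits(rig, "light_rig"))
  refs <- rig$flat_fields
  if (is.null(refs)) stopf("light rig carries no flat-field references")
  if (length(frames) != length(refs))
    stopf("need one reference per frame (%d frames, %d references)",
          length(frames), length(refs))
  valid <- matrix(TRUE, nrow(frames[[1]]), ncol(frames[[1]]))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    if (!all(dim(frames[[k]]) == dim(refs[[k]])))
      stopf("frame %d and its reference differ in shape", k)
    zero_frac <- mean(refs[[k]] <= 0)
    if (zero_frac >= 0.01)
      warnf("flat-field reference %d has %.1f%% non-positive pixels; masking them",
            k, 100 * zero_frac)
    valid <- valid & (refs[[k]] > eps)
    out[[k]] <- frames[[k]] / pmax(refs[[k]], eps)
  }
  list(frames = out, valid = valid)
}

#' Least-squares photometric stereo
#'
#' Solves the Lambertian image formation model `I = L %*% G` per pixel, where
#' `I` stacks the observed intensities under each source and `L` stacks the
#' unit light directions.  The least-squares solution
#' `G = pinv(L) %*% I` factors into albedo `||G||` and unit normal `G/||G||`.
#' Pixels whose intensity falls below `shadow_frac` of the stack's 99th
#' percentile in any frame, or whose recovered albedo falls below
#' `albedo_min`, are masked invalid (self/cast shadows break the model).
#'
#' @param frames list of >= 3 flat-field-corrected 2-D matrices.
#' @param rig a [light_rig()]; its direction matrix must have rank 3.
#' @param shadow_frac shadow mask fraction of the 99th-percentile intensity
#'   (default 0.02).
#' @param albedo_min minimum albedo for a pixel to count as valid.
#' @param valid optional logical matrix of a priori valid pixels.
#' @return Object of class `photometric_result`: `normal_map` (h x w x 3,
#'   unit vectors on valid pixels), `albedo_map`, `residual_map` (per-pixel
#'   least-squares residual norm) and `valid`.
#' @export
solve_normals <- function(frames, rig, shadow_frac = 0.02, albedo_min = 1e-6,
                          valid = NULL) {
  stopifnot(inherits(rig, "light_rig"))
  L <- rig$directions
  k <- length(frames)
  if (k < 3) stopf("need at least 3 frames, got %d", k)
  if (nrow(L) != k) stopf("rig has %d directions for %d frames", nrow(L), k)
  if (light_rank(L) < 3) {
    stopf("light directions are rank-deficient (rank %d): %s",
          light_rank(L),
          paste(apply(round(L, 3), 1, paste, collapse = ","), collapse = "; "))
  }
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  I <- do.call(rbind, lapply(frames, as.vector))   # k x npix
  pinvL <- solve(crossprod(L), t(L))               # 3 x k
  G <- pinvL %*% I                                 # 3 x npix
  albedo <- sqrt(colSums(G^2))
  N <- sweep(G, 2, pmax(albedo, 1e-300), "/")
  resid <- sqrt(colSums((L %*% G - I)^2))
  p99 <- quantile(I, 0.99, names = FALSE)
  shadowed <- colSums(I < shadow_frac * p99) > 0
  ok <- !shadowed & albedo >= albedo_min
  if (!is.null(valid)) ok <- ok & as.vector(valid)
  nm <- array(t(N), dim = c(h, w, 3))
  structure(list(
    normal_map = nm,
    albedo_map = matrix(albedo, h, w),
    residual_map = matrix(resid, h, w),
    valid = matrix(ok, h, w)
  ), class = "photometric_result")
}

#' @export
print.photometric_result <- function(x, ...) {
  cat(sprintf("photometric_result: %d x %d, %.1f%% valid, median albedo %.3g\n",
              nrow(x$albedo_map), ncol(x$albedo_map), 100 * mean(x$valid),
              median(x$albedo_map[x$valid])))
  invisible(x)
}

#' Angular error between two normal maps (degrees)
#'
#' @param normals,reference h x w x 3 arrays of unit normals.
#' @param valid logical matrix restricting the comparison.
#' @return numeric vector of per-pixel angular errors in degrees.
#' @export
normal_angular_error <- function(normals, reference, valid = NULL) {
  dotp <- rowSums(matrix(normals, ncol = 3) * matrix(reference, ncol = 3))
  err <- acos(pmin(1, pmax(-1, dotp))) * 180 / pi
  if (!is.null(valid)) err <- err[as.vector(valid)]
  err
}

#' Depth from a normal map by frequency-domain integration
#'
#' Frankot-Chellappa integration of the gradient field implied by the normal
#' map (p = -nx/nz, q = -ny/nz).  Provided as an optional utility; the depth
#' scale is relative.
#'
#' @param normal_map h x w x 3 unit-normal array.
#' @param valid logical matrix; invalid pixels get zero gradient.
#' @return numeric matrix of relative depths (zero mean).
#' @export
integrate_normals <- function(normal_map, valid = NULL) {
  nz <- pmax(normal_map[, , 3], 1e-3)
  p <- -normal_map[, , 1] / nz
  q <- -normal_map[, , 2] / nz
  if (!is.null(valid)) { p[!valid] <- 0; q[!valid] <- 0 }
  h <- nrow(p); w <- ncol(p)
  wy <- 2 * pi * (((seq_len(h) - 1 + h %/% 2) %% h) - h %/% 2) / h
  wx <- 2 * pi * (((seq_len(w) - 1 + w %/% 2) %% w) - w %/% 2) / w
  WX <- matrix(wx, h, w, byrow = TRUE)
  WY <- matrix(wy, h, w)
  denom <- WX^2 + WY^2
  denom[1, 1] <- 1
  # q is the derivative along rows (y), p along columns (x)
  Fz <- (-1i * WX * fft(p) - 1i * WY * fft(q)) / denom
  Fz[1, 1] <- 0
  z <- Re(fft(Fz, inverse = TRUE)) / (h * w)
  z - mean(z)
}

#' Export a normal map as 3-channel 32-bit float TIFF
#' @param normal_map h x w x 3 array with components in [-1, 1].
#' @param path output path.
#' @export
write_normal_map <- function(normal_map, path) {
  tiff::writeTIFF((normal_map + 1) / 2, path, bits.per.sample = 32)
  invisible(path)
}
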