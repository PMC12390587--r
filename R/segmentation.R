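#' Single-finger image with mask and provenance
#'
#' @param image 2-D numeric crop.
#' @param mask logical matrix, same shape, non-empty.
#' @param finger_label one of `"index"`, `"middle"`, `"ring"`, `"little"`,
#'   `"unknown"`.
#' @param rotation_deg normalization rotation already applied (|.| <= 45).
#' @param centroid_xy `c(x, y)` centre of gravity of the mask in source-image
#'   coordinates.
#' @param origin_rc `c(row, col)` of the crop's top-left pixel in the source.
#' @return Object of class `finger_image`.
#' @export
finger_image <- function(image, mask, finger_label = "unknown",
                         rotation_deg = 0, centroid_xy = c(NA, NA),
                         origin_rc = c(1, 1)) {
  mask <- mask > 0
  if (!all(dim(image) == dim(mask))) stopf("image and mask shapes differ")
  if (!any(mask)) stopf("finger mask is empty")
  if (abs(rotation_deg) > 45)
    stopf("rejected as non-finger: |rotation| = %.1f deg exceeds 45 deg", abs(rotation_deg))
  if (!finger_label %in% c("index", "middle", "ring", "little", "unknown"))
    stopf("unknown finger label '%s'", finger_label)
  structure(list(image = image, mask = mask, finger_label = finger_label,
                 rotation_deg = rotation_deg, centroid_xy = centroid_xy,
                 origin_rc = origin_rc),
            class = "finger_image")
}

#' @export
print.finger_image <- function(x, ...) {
  cat(sprintf("finger_image [%s]: %d x %d crop, %d mask px, rotation %.2f deg\n",
              x$finger_label, nrow(x$image), ncol(x$image), sum(x$mask),
              x$rotation_deg))
  invisible(x)
}

#' Foreground (hand) mask by Otsu thresholding and morphological opening
#'
#' Global Otsu threshold on the intensity histogram isolates the bright hand
#' from the dark background; opening with a disk structuring element removes
#' small speckle components.
#'
#' @param image 2-D numeric matrix in \[0, 1\].
#' @param opening_radius disk radius in pixels (default 5).
#' @return logical matrix.
#' @export
foreground_mask <- function(image, opening_radius = 5) {
  if (diff(range(image)) == 0)
    stopf("empty-mask error: constant image has no foreground")
  rng <- range(image)
  thr <- EBImage::otsu(EBImage::Image(image), range = rng)
  mask <- image > thr
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  if (!any(mask)) stopf("empty-mask error: no foreground after opening")
  mask
}

# Runs of TRUE in a logical vector -> matrix of (start, end).
true_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Extract individual fingers from a hand image
#'
#' Iteratively segments up to four fingers: the topmost foreground row gives
#' the tip of the tallest remaining finger; the finger is traced row-by-row
#' downward, following the foreground run connected to the previous row, and
#' the trace stops when the run width exceeds `width_stop_factor` times the
#' running median width (the palm) or when the run ends.  Each traced region
#' is erased from the working mask and returned as a [finger_image()] crop.
#'
#' @param image 2-D numeric matrix.
#' @param mask optional precomputed foreground mask (defaults to
#'   [foreground_mask()] of `image`).
#' @param width_stop_factor stop when the run width exceeds this multiple of
#'   the running median width (default 1.8).
#' @param min_rows rows to trace before the width-stop rule applies
#'   (tolerates the widening rounded tip; default 10).
#' @param pad crop margin in pixels (default 5).
#' @param max_fingers at most this many regions are traced (default 4;
#'   a possible fifth region, e.g. a thumb, is never traced).
#' @return Object of class `segmentation_result`: list of `fingers`
#'   (unlabeled, in tip-height order), `complete` (TRUE iff exactly 4),
#'   `residual_mask` (palm and anything untraced).
#' @export
extract_fingers <- function(image, mask = NULL, width_stop_factor = 1.8,
                            min_rows = 10, pad = 5, max_fingers = 4) {
  if (is.null(mask)) mask <- foreground_mask(image)
  if (!any(mask)) stopf("foreground mask is empty")
  work <- mask
  h <- nrow(mask); w <- ncol(mask)
  fingers <- list()
  for (k in seq_len(max_fingers)) {
    rows_any <- which(rowSums(work) > 0)
    if (length(rows_any) == 0) break
    tip_row <- rows_any[1]
    runs <- true_runs(work[tip_row, ])
    run <- runs[1, , drop = FALSE]          # leftmost run of the topmost row
    trace <- matrix(FALSE, h, w)
    widths <- numeric(0)
    prev <- c(run[1, "start"], run[1, "end"])
    r <- tip_row
    while (r <= h) {
      runs <- true_runs(work[r, ])
      if (nrow(runs) == 0) break
      # 8-connected continuation: runs overlapping [prev - 1, prev + 1]
      ov <- pmin(runs[, "end"], prev[2] + 1) - pmax(runs[, "start"], prev[1] - 1)
      cand <- which(ov >= 0)
      if (length(cand) == 0) break
      j <- cand[which.max(ov[cand])]
      width <- runs[j, "end"] - runs[j, "start"] + 1
      if (length(widths) >= min_rows &&
          width > width_stop_factor * median(widths)) break
      trace[r, runs[j, "start"]:runs[j, "end"]] <- TRUE
      widths <- c(widths, width)
      prev <- c(runs[j, "start"], runs[j, "end"])
      r <- r + 1
    }
    if (!any(trace)) break
    work <- work & !trace
    rr <- range(which(rowSums(trace) > 0))
    cc <- range(which(colSums(trace) > 0))
    r1 <- max(1, rr[1] - pad); r2 <- min(h, rr[2] + pad)
    c1 <- max(1, cc[1] - pad); c2 <- min(w, cc[2] + pad)
    cm <- trace[r1:r2, c1:c2, drop = FALSE]
    ci <- image[r1:r2, c1:c2, drop = FALSE]
    idx <- which(trace, arr.ind = TRUE)
    fingers[[length(fingers) + 1]] <- finger_image(
      ci, cm, centroid_xy = c(mean(idx[, 2]), mean(idx[, 1])),
      origin_rc = c(r1, c1))
  }
  structure(list(fingers = fingers, complete = length(fingers) == 4,
                 residual_mask = work),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d finger(s), complete=%s [%s]\n",
              length(x$fingers), x$complete,
              paste(vapply(x$fingers, `[[`, character(1), "finger_label"),
                    collapse = ", ")))
  invisible(x)
}

#' Reorder segmented fingers anatomically
#'
#' Sorts the four fingers by the x-coordinate of their centre of gravity and
#' assigns labels index..little.  With the default palm-down presentation the
#' right hand reads index-to-little from left to right and the left hand the
#' reverse.
#'
#' @param result a complete [extract_fingers()] result (exactly 4 fingers).
#' @param hand `"LH"` or `"RH"`.
#' @param palm_down logical; flip the label orientation for palm-up
#'   presentations.
#' @return The result with fingers ordered index, middle, ring, little and
#'   labeled accordingly.
#' @export
reorder_fingers <- function(result, hand, palm_down = TRUE) {
  stopifnot(inherits(result, "segmentation_result"))
  if (length(result$fingers) != 4)
    stopf(paste("ordering error: %d fingers; cannot tell whether these are",
                "index, middle and ring fingers, or middle, ring and little"),
          length(result$fingers))
  if (!hand %in% c("LH", "RH")) stopf("hand must be LH or RH")
  xs <- vapply(result$fingers, function(f) f$centroid_xy[1], numeric(1))
  ord <- order(xs)
  left_to_right_is_index_first <- (hand == "RH") == palm_down
  if (!left_to_right_is_index_first) ord <- rev(ord)
  labels <- c("index", "middle", "ring", "little")
  fingers <- result$fingers[ord]
  for (i in 1:4) fingers[[i]]$finger_label <- labels[i]
  result$fingers <- fingers
  result
}

#' Rotation-normalize a finger image
#'
#' Estimates the longitudinal axis as the least-squares line through the
#' per-row midpoints of the mask, then rotates image and mask about the mask
#' centroid so the axis becomes vertical.  The applied angle is recorded in
#' `rotation_deg`.
#'
#' @param finger a [finger_image()].
#' @param max_angle reject crops whose axis deviates more than this many
#'   degrees from vertical (default 45): not a finger.
#' @param min_angle dead-band in degrees: axis estimates below it are within
#'   the resampling quantization noise, so the crop is left untouched
#'   (default 0.15).  This makes normalization idempotent.
#' @return The normalized [finger_image()].
#' @export
normalize_finger <- function(finger, max_angle = 45, min_angle = 0.15) {
  stopifnot(inherits(finger, "finger_image"))
  m <- finger$mask
  # a soft (float) mask preserves sub-pixel geometry across resampling; a
  # freshly traced finger starts from its binary mask
  msoft <- if (is.null(finger$mask_soft)) m * 1 else finger$mask_soft
  rows <- which(rowSums(m) > 0)
  if (length(rows) < 20) stopf("mask spans fewer than 20 rows; cannot normalize")
  # trim the extremal rows: the rounded tip and the (possibly slanted) base
  # cut bias the per-row midpoints
  trim <- max(1, round(0.08 * length(rows)))
  rows <- rows[(trim + 1):(length(rows) - trim)]
  # sub-pixel midpoints: weighted column centroid of the softened mask
  w <- gblur_safe(msoft, 1)
  cols <- seq_len(ncol(m))
  mid <- vapply(rows, function(r) sum(cols * w[r, ]) / sum(w[r, ]), numeric(1))
  fit <- lm(mid ~ rows)
  slope <- coef(fit)[2]                      # d(col)/d(row)
  angle <- atan(slope) * 180 / pi            # axis deviation from vertical
  if (abs(angle) > max_angle)
    stopf("rejected as non-finger: axis angle %.1f deg exceeds %.0f deg",
          angle, max_angle)
  if (abs(angle) < min_angle) return(finger)
  # pad so the rotated mask cannot clip at the crop border
  margin <- ceiling(abs(sin(angle * pi / 180)) * max(dim(m)) / 2) + 2
  pad_mat <- function(x, fill = 0) {
    out <- matrix(fill, nrow(x) + 2 * margin, ncol(x) + 2 * margin)
    out[margin + seq_len(nrow(x)), margin + seq_len(ncol(x))] <- x
    out
  }
  pimg <- pad_mat(finger$image)
  pmsk <- pad_mat(msoft)
  idx <- which(pmsk > 0.5, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  # rotate by the negative of the axis angle so the axis becomes vertical
  img <- rotate_about(pimg, -angle, centroid, nearest = FALSE, fill = 0)
  msk_soft <- rotate_about(pmsk, -angle, centroid, nearest = FALSE, fill = 0)
  msk <- msk_soft > 0.5
  finger$image <- img
  finger$mask <- msk
  finger$mask_soft <- msk_soft
  finger$origin_rc <- finger$origin_rc - margin
  finger$rotation_deg <- finger$rotation_deg + (-angle)
  finger
}
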