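#' Binary vein template
#'
#' The maximum-curvature feature map extracted from a finger-vein image is
#' the biometric template used for matching.
#'
#' @param feature_map logical matrix; between 1 pixel and 30% of all pixels
#'   must be active.
#' @param finger_label source finger label.
#' @param provenance list recording the enhancement method and the
#'   extraction parameters.
#' @return Object of class `vein_template`.
#' @export
vein_template <- function(feature_map, finger_label = "unknown",
                          provenance = list()) {
  fm <- feature_map > 0
  n_active <- sum(fm)
  if (n_active < 1) stopf("empty-template error: no active feature pixels")
  if (n_active > 0.3 * length(fm))
    stopf("degenerate template: %.0f%% of pixels active (max 30%%)",
          100 * n_active / length(fm))
  structure(list(feature_map = fm, finger_label = finger_label,
                 shape = dim(fm), provenance = provenance),
            class = "vein_template")
}

#' @export
print.vein_template <- function(x, ...) {
  cat(sprintf("vein_template [%s]: %d x %d, %d active px (%.1f%%)\n",
              x$finger_label, x$shape[1], x$shape[2], sum(x$feature_map),
              100 * mean(x$feature_map)))
  invisible(x)
}

#' @export
plot.vein_template <- function(x, ...) {
  graphics::image(t(x$feature_map)[, rev(seq_len(x$shape[1]))],
                  col = c("white", "black"), axes = FALSE, asp = x$shape[1] / x$shape[2], ...)
  invisible(x)
}

# registry of enhancement methods
enhancer_registry <- function() {
  list(
    none = function(finger, params) finger,
    baseline = function(finger, params) enhance_baseline(finger, params)
  )
}

# Classical enhancement: the smooth illumination field is multiplicative, so
# the large-kernel background estimate is divided out (homomorphic
# correction); local contrast normalization follows, masked to the finger,
# rescaled to [0, 1].
enhance_baseline <- function(finger, params = list()) {
  bg_sigma <- params$bg_sigma %||% 15
  lcn_sigma <- params$lcn_sigma %||% 8
  eps <- 1e-8
  img <- finger$image
  m <- finger$mask * 1
  blur_m <- gblur_safe(m, bg_sigma)
  bg <- gblur_safe(img * m, bg_sigma) / pmax(blur_m, eps)
  detail <- (img / pmax(bg, eps) - 1) * m
  blur_m2 <- gblur_safe(m, lcn_sigma)
  local_var <- gblur_safe(detail^2, lcn_sigma) / pmax(blur_m2, eps)
  # variance floor at half the global detail scale: keeps near-flat regions
  # from being amplified into hallucinated structure
  sdg <- sd(detail[finger$mask])
  out <- detail / (sqrt(pmax(local_var, (0.5 * sdg)^2)) + 1e-4)
  vals <- out[finger$mask]
  rng <- range(vals)
  if (diff(rng) < eps) {
    out[] <- 0
  } else {
    out <- (out - rng[1]) / diff(rng)
    out[!finger$mask] <- 0
  }
  finger$image <- out
  finger
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enhance vascular structures in a normalized finger image
#'
#' Pluggable enhancement interface.  The `"baseline"` method divides out the
#' smooth background illumination (large-kernel Gaussian estimate of the
#' multiplicative field) and applies local contrast normalization within the
#' finger mask; `"none"` returns the input unchanged.  Learned enhancers can be registered by name
#' through `extra_methods`.
#'
#' @param finger a [finger_image()].
#' @param method enhancer id (default `"baseline"`).
#' @param params optional list of method parameters (`bg_sigma`,
#'   `lcn_sigma`).
#' @param extra_methods named list of additional `function(finger, params)`
#'   enhancers.
#' @return the enhanced [finger_image()].
#' @export
enhance_veins <- function(finger, method = "baseline", params = list(),
                          extra_methods = list()) {
  stopifnot(inherits(finger, "finger_image"))
  reg <- c(enhancer_registry(), extra_methods)
  if (!method %in% names(reg))
    stopf("configuration error: unknown enhancer '%s' (available: %s)",
          method, paste(names(reg), collapse = ", "))
  reg[[method]](finger, params)
}

mc_direction_steps <- function(directions) {
  all_steps <- list(transverse = c(0, 1), longitudinal = c(1, 0),
                    diagonal = c(1, 1), antidiagonal = c(1, -1))
  unknown <- setdiff(directions, names(all_steps))
  if (length(unknown))
    stopf("unknown scan direction(s): %s", paste(unknown, collapse = ", "))
  all_steps[directions]
}

# Deposit curvature scores for one scan direction.  kappa is the profile
# curvature matrix; allowed marks pixels where deposits may land.  Returns a
# score plane.
mc_scan_direction <- function(kappa, allowed, step) {
  h <- nrow(kappa); w <- ncol(kappa)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  line_id <- if (all(step == c(0, 1))) g$r
  else if (all(step == c(1, 0))) g$c
  else if (all(step == c(1, 1))) g$c - g$r
  else g$c + g$r
  pos <- if (step[2] != 0) g$c else g$r
  ord <- order(line_id, pos)
  kv <- as.vector(kappa)[ord]
  concave <- kv > 0
  lid <- line_id[ord]
  # group id increments at every line change or concavity toggle
  brk <- c(TRUE, lid[-1] != lid[-length(lid)] | concave[-1] != concave[-length(concave)])
  grp <- cumsum(brk)
  score <- numeric(h * w)
  starts <- which(brk)
  ends <- c(starts[-1] - 1, length(kv))
  keep <- concave[starts]
  for (i in which(keep)) {
    s <- starts[i]; e <- ends[i]
    W <- e - s + 1
    kmax <- max(kv[s:e])
    mid <- s + (W - 1L) %/% 2L
    # deposit over the central three profile positions: the region centre at
    # full weight, its scan-line neighbours at half, absorbing the sub-pixel
    # uncertainty of the centre estimate
    score[ord[mid]] <- score[ord[mid]] + kmax * W
    if (mid > s) score[ord[mid - 1]] <- score[ord[mid - 1]] + 0.5 * kmax * W
    if (mid < e) score[ord[mid + 1]] <- score[ord[mid + 1]] + 0.5 * kmax * W
  }
  sm <- matrix(score, h, w)
  sm[!allowed] <- 0
  sm
}

# Connectivity reinforcement: each pixel's accumulated score is supported by
# the stronger of its two neighbours on each side along the scan direction,
# taking the weaker side (an isolated peak gets no support).
mc_connect <- function(V, step) {
  f1 <- shift_matrix(V, step[1], step[2])
  f2 <- shift_matrix(V, 2 * step[1], 2 * step[2])
  b1 <- shift_matrix(V, -step[1], -step[2])
  b2 <- shift_matrix(V, -2 * step[1], -2 * step[2])
  pmin(pmax(f1, f2), pmax(b1, b2))
}

#' Maximum-curvature vein template extraction
#'
#' Scans the finger image along the configured directions and evaluates the
#' curvature \eqn{\kappa = P'' / (1 + P'^2)^{3/2}} of each smoothed
#' cross-sectional profile.  Veins are intensity valleys, i.e. concave-up
#' dents of the profile where \eqn{\kappa > 0}; within every such concave
#' region a score proportional to the peak curvature times the region width
#' is deposited at the region centre.  Score planes are summed over directions, reinforced by aligned
#' neighbours along each scan direction, and binarized at the median of the
#' strictly positive scores.
#'
#' The input is affinely renormalized to \[0, 1\] over the mask first, making
#' the template invariant to gain/offset changes of the input.
#'
#' @param finger an enhanced, rotation-normalized [finger_image()].
#' @param sigma Gaussian profile smoothing scale in pixels (default 3).
#' @param directions subset of `"transverse"`, `"longitudinal"`,
#'   `"diagonal"`, `"antidiagonal"`.  The default uses all four; transverse
#'   alone reproduces the single-scan reading.
#' @param erode_margin disk radius by which the mask is shrunk before
#'   deposits are allowed (suppresses boundary curvature; default 3).
#' @return a [vein_template()].
#' @export
extract_mc <- function(finger, sigma = 3,
                       directions = c("transverse", "longitudinal",
                                      "diagonal", "antidiagonal"),
                       erode_margin = 3) {
  stopifnot(inherits(finger, "finger_image"))
  if (!any(finger$mask)) stopf("empty mask")
  steps <- mc_direction_steps(directions)
  img <- finger$image
  vals <- img[finger$mask]
  rng <- range(vals)
  if (diff(rng) <= 0) stopf("empty-template error: flat profile inside mask")
  v <- (img - rng[1]) / diff(rng)
  v[!finger$mask] <- mean(v[finger$mask])  # neutral fill limits edge response
  P <- gblur_safe(v, sigma)   # valleys are concave-up: kappa > 0 at veins
  allowed <- finger$mask
  if (erode_margin > 0) {
    brush <- EBImage::makeBrush(2 * erode_margin + 1, shape = "disc")
    allowed <- EBImage::erode(finger$mask * 1, brush) > 0.5
  }
  V <- matrix(0, nrow(img), ncol(img))
  for (step in steps) {
    d1 <- (shift_matrix(P, -step[1], -step[2]) - shift_matrix(P, step[1], step[2])) / 2
    d2 <- shift_matrix(P, -step[1], -step[2]) - 2 * P + shift_matrix(P, step[1], step[2])
    kappa <- d2 / (1 + d1^2)^1.5
    kappa[kappa < 1e-6] <- 0   # numerical ripple is not curvature
    V <- V + mc_scan_direction(kappa, allowed, step)
  }
  total <- V
  for (step in steps) total <- total + mc_connect(V, step)
  pos <- total[total > 0]
  if (length(pos) == 0) stopf("empty-template error: no curvature maxima found")
  thr <- median(pos)
  fm <- total > thr
  if (!any(fm)) fm <- total >= thr  # all positive scores tied at the median
  vein_template(fm, finger$finger_label,
                provenance = list(enhancer = finger$enhancer %||% NA,
                                  sigma = sigma, directions = directions,
                                  erode_margin = erode_margin))
}
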