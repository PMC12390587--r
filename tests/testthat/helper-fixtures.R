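# Shared fixtures built in code.

# Vertical bar mask/image: a bright bar on dark background.
bar_image <- function(h = 120, w = 60, x0 = 25, x1 = 35, y0 = 10, y1 = h - 10,
                      fg = 0.8, bg = 0.1) {
  img <- matrix(bg, h, w)
  img[y0:min(y1, h), x0:min(x1, w)] <- fg
  img
}

# Finger-like crop with a single vertical dark ridge at a given column.
ridge_finger <- function(h = 100, w = 80, center = 40, sigma = 3,
                         depth = 0.4, bg = 0.8) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- bg * (1 - depth * exp(-(xs - center)^2 / (2 * sigma^2)))
  finger_image(img, matrix(TRUE, h, w))
}

# Random binary template of given density.
random_template <- function(h, w, density, seed) {
  m <- with_seed_test(seed, matrix(runif(h * w) < density, h, w))
  vein_template(m)
}

# seed-scoped RNG for helpers (tests must not disturb the global stream)
with_seed_test <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Brute-force spatial-domain template matcher (oracle): exhaustive overlap
# search over all offsets within max_shift.
brute_force_match <- function(A, B, max_shift) {
  A <- A * 1; B <- B * 1
  best <- -1; best_off <- c(0, 0)
  for (dy in -max_shift[1]:max_shift[1]) {
    for (dx in -max_shift[2]:max_shift[2]) {
      ov <- 0
      ys <- intersect(seq_len(nrow(A)), seq_len(nrow(B)) + dy)
      xs <- intersect(seq_len(ncol(A)), seq_len(ncol(B)) + dx)
      if (length(ys) && length(xs))
        ov <- sum(A[ys, xs] * B[ys - dy, xs - dx, drop = FALSE])
      if (ov > best) { best <- ov; best_off <- c(dy, dx) }
    }
  }
  list(overlap = best, offset = best_off,
       score = best / min(sum(A), sum(B)))
}

# Project a 3-D point (left-camera frame) through a pinhole + Brown
# distortion camera; independent of the package's internals.
oracle_project <- function(X, K, dist, R = diag(3), T = c(0, 0, 0)) {
  Xc <- as.numeric(R %*% X + T)
  x <- Xc[1] / Xc[3]; y <- Xc[2] / Xc[3]
  r2 <- x^2 + y^2
  rad <- 1 + dist[1] * r2 + dist[2] * r2^2 + dist[5] * r2^3
  xd <- x * rad + 2 * dist[3] * x * y + dist[4] * (r2 + 2 * x^2)
  yd <- y * rad + dist[3] * (r2 + 2 * y^2) + 2 * dist[4] * x * y
  c(K[1, 1] * xd + K[1, 3], K[2, 2] * yd + K[2, 3])
}

# small rotation matrix from axis-angle (degrees)
rot3 <- function(axis, deg) {
  th <- deg * pi / 180
  a <- axis / sqrt(sum(axis^2))
  Kx <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
}

# Render + segment + normalize one finger of a synthetic hand.
synth_finger <- function(idseed, sseed, hand = "RH", slot = 2,
                         params = render_params()) {
  id <- make_identity(idseed)
  r <- render_hand(id, params, sseed, hand)
  seg <- reorder_fingers(extract_fingers(r$image), hand)
  list(finger = normalize_finger(seg$fingers[[slot]]), truth = r$truth,
       seg = seg)
}
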