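#' Rendering parameters for the synthetic hand generator
#'
#' Per-sample acquisition jitter and photometric settings.  The defaults are
#' the study conditions used throughout the package's benchmarks.
#'
#' @param rotation_jitter_deg per-finger tilt jitter, uniform in +- this value
#'   (default 3).
#' @param translation_jitter_px global hand translation jitter (default 8).
#' @param gain_jitter intensity gain jitter as a fraction (default 0.1).
#' @param illumination_gradient maximum relative strength of the
#'   multiplicative linear illumination field (default 0.15).
#' @param noise_sd additive Gaussian noise standard deviation on the \[0, 1\]
#'   intensity scale (default 0.02).
#' @param vein_contrast vein valley depth as a fraction of the tissue
#'   intensity (default 0.25).
#' @param visibility_jitter per-finger vein-visibility loss: each rendered
#'   finger multiplies its vein contrast by a uniform draw from
#'   `[1 - visibility_jitter, 1]`, emulating contact-pressure and perfusion
#'   variation between presentations (default 0.45).
#' @return list of class `render_params`.
#' @export
render_params <- function(rotation_jitter_deg = 3, translation_jitter_px = 8,
                          gain_jitter = 0.1, illumination_gradient = 0.15,
                          noise_sd = 0.02, vein_contrast = 0.25,
                          visibility_jitter = 0.45) {
  stopifnot(rotation_jitter_deg >= 0, translation_jitter_px >= 0,
            gain_jitter >= 0, illumination_gradient >= 0, noise_sd >= 0,
            vein_contrast > 0, vein_contrast < 1,
            visibility_jitter >= 0, visibility_jitter < 1)
  structure(list(rotation_jitter_deg = rotation_jitter_deg,
                 translation_jitter_px = translation_jitter_px,
                 gain_jitter = gain_jitter,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, vein_contrast = vein_contrast,
                 visibility_jitter = visibility_jitter),
            class = "render_params")
}

#' Graded difficulty presets for the synthetic benchmark
#' @param level `"easy"`, `"default"` or `"hard"`.
#' @return a [render_params()] object.
#' @export
render_difficulty <- function(level = c("default", "easy", "hard")) {
  switch(match.arg(level),
         easy = render_params(rotation_jitter_deg = 1, translation_jitter_px = 4,
                              gain_jitter = 0.05, illumination_gradient = 0.08,
                              noise_sd = 0.005, vein_contrast = 0.35,
                              visibility_jitter = 0.2),
         default = render_params(),
         hard = render_params(rotation_jitter_deg = 5, translation_jitter_px = 12,
                               gain_jitter = 0.15, illumination_gradient = 0.25,
                               noise_sd = 0.04, vein_contrast = 0.15,
                               visibility_jitter = 0.6))
}

# canonical finger slots (RH, left-to-right): anatomical length fractions
FINGER_SLOTS <- data.frame(
  label = c("index", "middle", "ring", "little"),
  length_frac = c(0.88, 1.00, 0.94, 0.72),
  stringsAsFactors = FALSE)

# one random vein polyline in canonical finger coordinates
# (u along the axis in [0,1], v across the width in [-1,1], w relative width)
random_vein_branch <- function(u0, v0, u1, wobble, width, drift = 0, bow = 0) {
  us <- seq(u0, u1, by = 0.05)
  if (length(us) < 2) us <- c(u0, u1)
  vs <- numeric(length(us))
  vs[1] <- v0
  for (i in 2:length(us)) {
    vs[i] <- vs[i - 1] + drift * 0.05 + rnorm(1, 0, wobble)
    vs[i] <- max(-0.7, min(0.7, vs[i]))
  }
  # smooth lateral bow: vessel curvature that a vertical shift cannot align
  vs <- pmax(-0.7, pmin(0.7, vs + bow * sin(pi * (us - u0) / max(u1 - u0, 1e-9))))
  cbind(u = us, v = vs, w = width * (1 - 0.4 * us))
}

#' Create a synthetic identity
#'
#' Deterministically derives, from the seed, the per-finger geometry (length,
#' width) and a per-finger curvilinear vein network: two trunks emulating the
#' paired digital veins plus 3--6 side branches (5--8 branches in total),
#' generated as biased random walks with distally tapering widths, confined
#' to the finger silhouette.
#'
#' @param seed integer identity seed.
#' @return Object of class `synthetic_identity`.
#' @export
make_identity <- function(seed) {
  with_seed(child_seed(seed, 1), {
    fingers <- lapply(seq_len(4), function(f) {
      len <- 160 * FINGER_SLOTS$length_frac[f] * runif(1, 0.94, 1.06)
      hw <- runif(1, 12.5, 15.5)
      # paired digital veins: one trunk on each side of the finger midline
      trunks <- lapply(c(-1, 1), function(side)
        random_vein_branch(0.03, side * runif(1, 0.10, 0.55), 0.95,
                           wobble = 0.10, width = runif(1, 0.8, 1),
                           drift = runif(1, -0.6, 0.6),
                           bow = runif(1, -0.35, 0.35)))
      n_side <- sample(3:6, 1)
      branches <- lapply(seq_len(n_side), function(b) {
        trunk <- trunks[[sample(1:2, 1)]]
        at <- sample(seq_len(nrow(trunk) - 4), 1)
        side <- sample(c(-1, 1), 1)
        len_u <- runif(1, 0.15, 0.4)
        random_vein_branch(trunk[at, "u"], trunk[at, "v"],
                           min(0.97, trunk[at, "u"] + len_u),
                           wobble = 0.09, width = 0.6,
                           drift = side * runif(1, 0.8, 2.2))
      })
      list(length_px = len, half_width_px = hw, veins = c(trunks, branches))
    })
    names(fingers) <- FINGER_SLOTS$label
    structure(list(seed = seed, fingers = fingers), class = "synthetic_identity")
  })
}

# distance from points (py, px) to segment (a, b) given as c(row, col)
point_segment_dist <- function(py, px, a, b) {
  vy <- b[1] - a[1]; vx <- b[2] - a[2]
  L2 <- vy^2 + vx^2
  if (L2 == 0) return(sqrt((py - a[1])^2 + (px - a[2])^2))
  t <- ((py - a[1]) * vy + (px - a[2]) * vx) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((py - (a[1] + t * vy))^2 + (px - (a[2] + t * vx))^2)
}

#' Render one synthetic NIR hand sample
#'
#' Draws a bright four-finger hand (plus palm) on a dark background:
#' capsule-shaped fingers with per-sample tilt jitter, per-identity vein
#' networks rendered as Gaussian-profile intensity valleys, a multiplicative
#' linear illumination field, gain jitter and additive Gaussian noise.
#' Ground truth (silhouette, per-finger masks and labels, vein centerlines,
#' applied tilts) is returned alongside the image.  A jitter draw that would
#' push a fingertip out of frame is redrawn with a warning (bounded retries).
#'
#' @param identity a [make_identity()] identity.
#' @param params a [render_params()] object.
#' @param sample_seed per-sample seed.
#' @param hand `"RH"` (index leftmost, palm-down) or `"LH"` (mirrored).
#' @param size canvas `c(rows, cols)` (default `c(340, 300)`).
#' @return list with `image` and a `truth` list (`silhouette`,
#'   `finger_masks`, `finger_labels`, `vein_centerlines`, `rotations_deg`,
#'   `palm_top_row`).
#' @export
render_hand <- function(identity, params = render_params(), sample_seed = 0,
                        hand = "RH", size = c(340, 300)) {
  stopifnot(inherits(identity, "synthetic_identity"),
            inherits(params, "render_params"))
  h <- size[1]; w <- size[2]
  y_palm <- round(h * 0.64)
  pitch <- 44
  slots_x <- round(w / 2 + pitch * (seq_len(4) - 2.5))
  order_lr <- if (hand == "RH") 1:4 else 4:1   # anatomical label per slot
  with_seed(child_seed(sample_seed, 7), {
    for (attempt in 1:4) {
      dy <- runif(1, -params$translation_jitter_px, params$translation_jitter_px)
      dx <- runif(1, -params$translation_jitter_px, params$translation_jitter_px)
      phis <- runif(4, -params$rotation_jitter_deg, params$rotation_jitter_deg)
      visib <- runif(4, 1 - params$visibility_jitter, 1)
      tips_ok <- TRUE
      for (s in 1:4) {
        fin <- identity$fingers[[order_lr[s]]]
        phi <- phis[s] * pi / 180
        tip_y <- y_palm + dy - fin$length_px * cos(phi)
        tip_x <- slots_x[s] + dx - fin$length_px * sin(phi) / 2
        if (tip_y < 8 || tip_x < 8 || tip_x > w - 8) tips_ok <- FALSE
      }
      if (tips_ok) break
      warnf("jitter pushed a fingertip out of frame; redrawing (attempt %d)", attempt)
    }
    gain <- 1 + runif(1, -params$gain_jitter, params$gain_jitter)
    gx <- runif(1, -params$illumination_gradient, params$illumination_gradient)
    gy <- runif(1, -params$illumination_gradient, params$illumination_gradient)
    noise <- matrix(rnorm(h * w, 0, params$noise_sd), h, w)

    tissue <- 0.55 * gain
    img <- matrix(0.08, h, w)
    silhouette <- matrix(FALSE, h, w)
    finger_masks <- vector("list", 4)
    centerlines <- vector("list", 4)
    labels <- character(4)
    attn <- matrix(0, h, w)

    for (s in 1:4) {
      fin <- identity$fingers[[order_lr[s]]]
      labels[s] <- FINGER_SLOTS$label[order_lr[s]]
      phi <- phis[s] * pi / 180
      # tilt about the finger's mid-axis so neighbouring tips don't collide
      base <- c(y_palm + dy, slots_x[s] + dx + fin$length_px * sin(phi) / 2)
      axis <- c(-cos(phi), -sin(phi))          # unit vector base -> tip
      nrm <- c(-axis[2], axis[1])              # unit normal
      L <- fin$length_px; hw <- fin$half_width_px
      tip <- base + L * axis
      # finger silhouette: tapered capsule, cut at the palm top row
      r1 <- max(1, floor(min(base[1], tip[1]) - hw - 2))
      r2 <- min(h, ceiling(y_palm) - 1)
      c1 <- max(1, floor(min(base[2], tip[2]) - hw - 2))
      c2 <- min(w, ceiling(max(base[2], tip[2]) + hw + 2))
      g <- expand.grid(y = r1:r2, x = c1:c2)
      t <- ((g$y - base[1]) * axis[1] + (g$x - base[2]) * axis[2]) / L
      tc <- pmin(1, pmax(0, t))
      d <- sqrt((g$y - (base[1] + tc * L * axis[1]))^2 +
                (g$x - (base[2] + tc * L * axis[2]))^2)
      inside <- d <= hw * (1 - 0.12 * tc)
      m <- matrix(FALSE, h, w)
      m[cbind(g$y[inside], g$x[inside])] <- TRUE
      finger_masks[[s]] <- m
      silhouette <- silhouette | m
      # veins: Gaussian-profile valleys along the identity's polylines
      cl <- list()
      for (vn in fin$veins) {
        pts <- cbind(base[1] + vn[, "u"] * L * axis[1] + vn[, "v"] * hw * nrm[1],
                     base[2] + vn[, "u"] * L * axis[2] + vn[, "v"] * hw * nrm[2])
        sigma_v <- 1.1 * vn[1, "w"] + 0.7
        depth <- (0.55 + 0.45 * vn[1, "w"]) * visib[s]
        for (k in seq_len(nrow(pts) - 1)) {
          a <- pts[k, ]; b <- pts[k + 1, ]
          rr1 <- max(1, floor(min(a[1], b[1]) - 3 * sigma_v))
          rr2 <- min(h, ceiling(max(a[1], b[1]) + 3 * sigma_v))
          cc1 <- max(1, floor(min(a[2], b[2]) - 3 * sigma_v))
          cc2 <- min(w, ceiling(max(a[2], b[2]) + 3 * sigma_v))
          if (rr1 > rr2 || cc1 > cc2) next
          gg <- expand.grid(y = rr1:rr2, x = cc1:cc2)
          dd <- point_segment_dist(gg$y, gg$x, a, b)
          val <- depth * exp(-dd^2 / (2 * sigma_v^2))
          idx <- cbind(gg$y, gg$x)
          attn[idx] <- pmax(attn[idx], val)
        }
        cl[[length(cl) + 1]] <- pts
      }
      centerlines[[s]] <- cl
    }
    # palm block below the finger bases
    pc1 <- max(1, min(slots_x) - 24 + round(dx))
    pc2 <- min(w, max(slots_x) + 24 + round(dx))
    pr2 <- min(h, y_palm + 95 + round(dy))
    palm <- matrix(FALSE, h, w)
    palm[ceiling(y_palm):pr2, pc1:pc2] <- TRUE
    silhouette <- silhouette | palm

    img[silhouette] <- tissue
    img <- img * (1 - params$vein_contrast * attn * silhouette)
    field <- 1 + gx * (matrix(seq_len(w), h, w, byrow = TRUE) / w - 0.5) +
      gy * (matrix(seq_len(h), h, w) / h - 0.5)
    img <- img * field + noise
    img <- matrix(pmin(1, pmax(0, img)), h, w)

    list(image = img,
         truth = list(silhouette = silhouette, finger_masks = finger_masks,
                      finger_labels = labels,
                      vein_centerlines = centerlines,
                      rotations_deg = phis, palm_top_row = y_palm))
  })
}

#' Render a synthetic stereo pair with known disparity
#'
#' A dot-textured left view plus a right view resampled from it by a
#' per-pixel disparity field (`d = x_left - x_right`, affine in the image
#' coordinates, as produced by a planar surface).  The exact left-frame
#' disparity map is returned.
#'
#' @param disparity_plane `c(d0, gx, gy)`: disparity at pixel (x, y) is
#'   `d0 + gx * x + gy * y` (constant depth: `gx = gy = 0`).
#' @param dot_density fraction of pixels seeded as dots (default 0.08).
#' @param baseline_mm,focal_px stereo geometry used to report the matching
#'   depth map.
#' @param size image `c(rows, cols)`.
#' @param seed RNG seed for the dot texture.
#' @return list with `left`, `right`, `disparity_true`, `depth_true`,
#'   `baseline_mm`, `focal_px`.
#' @export
render_stereo_pair <- function(disparity_plane = c(20, 0, 0), dot_density = 0.08,
                               baseline_mm = 50, focal_px = 1176.5,
                               size = c(160, 220), seed = 0) {
  h <- size[1]; w <- size[2]
  d0 <- disparity_plane[1]; gx <- disparity_plane[2]; gy <- disparity_plane[3]
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  d_true <- d0 + gx * xs + gy * ys
  if (any(d_true <= 0)) stopf("parameter error: disparity must stay positive")
  if (max(d_true) >= w) stopf("parameter error: disparity exceeds image width")
  if (abs(gx) >= 1) stopf("parameter error: |gx| must be < 1")
  left <- with_seed(child_seed(seed, 11), {
    dots <- matrix(runif(h * w) < dot_density, h, w) * 1
    l <- EBImage::gblur(dots, sigma = 1.2)
    l / max(l)
  })
  # x_left corresponding to right pixel x_r solves x_l = x_r + d(x_l, y)
  xl <- (xs + d0 + gy * ys) / (1 - gx)
  right <- matrix(bilinear_sample(left, as.vector(ys), as.vector(xl), fill = 0), h, w)
  list(left = left, right = right, disparity_true = d_true,
       depth_true = disparity_to_depth(d_true, baseline_mm, focal_px),
       baseline_mm = baseline_mm, focal_px = focal_px)
}

#' Render a Lambertian photometric-stereo quadruple
#'
#' Four frames of a surface (fronto-parallel plane or outward-bulging
#' sphere cap) under directional corner lights, with inverse-square
#' illumination falloff baked into both the frames and the per-source
#' flat-field references, so that flat-field correction cancels it.
#' Analytic ground-truth normals are returned.
#'
#' @param surface `"plane"` or `"sphere"`.
#' @param lights k x 3 matrix of unit light directions (default: four
#'   symmetric corner sources at 40 degrees elevation).
#' @param albedo scalar or matrix surface albedo (default 0.8).
#' @param noise_sd additive Gaussian noise (default 0).
#' @param size image `c(rows, cols)`.
#' @param sphere_radius_frac sphere-cap radius as a fraction of the smaller
#'   image half-side (default 0.9).
#' @param seed RNG seed for the noise.
#' @return list with `frames`, `rig` (a [light_rig()] carrying flat-field
#'   references), `normals_true` (h x w x 3), `on_surface` (logical),
#'   `lit` (logical: positive shading under every source).
#' @export
render_ps_quad <- function(surface = c("sphere", "plane"), lights = NULL,
                           albedo = 0.8, noise_sd = 0, size = c(120, 120),
                           sphere_radius_frac = 0.9, seed = 0) {
  surface <- match.arg(surface)
  h <- size[1]; w <- size[2]
  if (is.null(lights)) {
    el <- 40 * pi / 180
    az <- c(45, 135, 225, 315) * pi / 180
    lights <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  }
  L <- light_rig(lights)$directions
  if (light_rank(L) < 3) stopf("light set must have rank 3")
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  if (surface == "plane") {
    N <- array(0, dim = c(h, w, 3)); N[, , 3] <- 1
    on_surface <- matrix(TRUE, h, w)
  } else {
    R <- sphere_radius_frac * min(cx - 1, cy - 1)
    ux <- (xs - cx) / R; uy <- (ys - cy) / R
    r2 <- ux^2 + uy^2
    on_surface <- r2 < 1
    nz <- sqrt(pmax(0, 1 - r2))
    N <- array(0, dim = c(h, w, 3))
    N[, , 1] <- ifelse(on_surface, ux, 0)
    N[, , 2] <- ifelse(on_surface, uy, 0)
    N[, , 3] <- ifelse(on_surface, nz, 1)   # background is a plane
  }
  if (length(albedo) == 1) albedo <- matrix(albedo, h, w)
  # inverse-square falloff from a near-field source above each corner
  src_xy <- rbind(c(1, 1), c(1, w), c(h, 1), c(h, w))
  height <- 1.5 * max(h, w)
  frames <- vector("list", nrow(L))
  refs <- vector("list", nrow(L))
  Nmat <- matrix(N, ncol = 3)
  noise <- with_seed(child_seed(seed, 13), {
    lapply(seq_len(nrow(L)), function(k)
      matrix(rnorm(h * w, 0, noise_sd), h, w))
  })
  lit <- matrix(TRUE, h, w)
  for (k in seq_len(nrow(L))) {
    shading <- matrix(pmax(0, Nmat %*% L[k, ]), h, w)
    lit <- lit & shading > 0
    fall <- height^2 / ((ys - src_xy[k, 1])^2 + (xs - src_xy[k, 2])^2 + height^2)
    frames[[k]] <- matrix(pmax(albedo * shading * fall + noise[[k]], 0), h, w)
    refs[[k]] <- 0.9 * L[k, 3] * fall       # constant-albedo plane reference
  }
  if (mean(!lit & on_surface) > 0.5)
    warnf("geometry warning: more than half of the surface is in shadow")
  list(frames = frames, rig = light_rig(L, flat_fields = refs),
       normals_true = N, on_surface = on_surface, lit = lit)
}

#' Generate the default synthetic recognition benchmark samples
#'
#' Renders `n_samples` presentations for each hand of each synthetic subject.
#' Identity (vein network, finger geometry) is fixed per subject; only pose
#' and photometric jitter vary between samples, mirroring the
#' genuine/impostor structure the evaluation assumes.
#'
#' @param n_subjects number of identities (default 20).
#' @param hands character vector of hands to render (default both).
#' @param n_samples samples per hand (default 5; sample seeds are
#'   `0:(n_samples-1)` combined with the subject and hand).
#' @param params a [render_params()] object.
#' @param seed master seed; subject identities derive from it.
#' @param size canvas size.
#' @return list of sample records (`subject_id`, `hand`, `sample_index`,
#'   `image`, `truth`).
#' @export
simulate_benchmark <- function(n_subjects = 20, hands = c("LH", "RH"),
                               n_samples = 5, params = render_params(),
                               seed = 0, size = c(340, 300)) {
  out <- list()
  for (s in seq_len(n_subjects)) {
    id <- make_identity(child_seed(seed, 1000 + s))
    for (hd in hands) {
      for (k in seq_len(n_samples) - 1L) {
        smp_seed <- child_seed(seed, s * 101 + match(hd, c("LH", "RH")) * 13 + k * 997)
        r <- render_hand(id, params, sample_seed = smp_seed, hand = hd, size = size)
        out[[length(out) + 1]] <- list(
          subject_id = sprintf("S%03d", s), hand = hd, sample_index = k,
          image = r$image, truth = r$truth)
      }
    }
  }
  out
}
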