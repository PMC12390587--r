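SCHEMA_VERSION <- 1L

#' Multi-channel hand-capture sample
#'
#' One presentation of a hand: an ordered stack of frames (grayscale NIR,
#' color, laser) with one metadata record per frame.  Grayscale frames are
#' integer matrices in the declared bit depth (10-bit sensor data stored in
#' 16-bit integers without rescaling); color frames are `h x w x 3` integer
#' arrays.
#'
#' @param frames list of 2-D integer matrices or 3-D (h, w, 3) arrays.
#' @param frame_meta data frame with one row per frame and columns `camera`
#'   (one of `"left"`, `"right"`, `"rgb"`), `wavelength` (one of `"850"`,
#'   `"950"`, `"white"`, `"laser"`) and `illumination_state` (integer bitmask
#'   of active LED banks).
#' @param subject_id character scalar.
#' @param hand `"LH"` or `"RH"`.
#' @param sample_index integer >= 0.
#' @param bit_depth declared sensor bit depth (default 10).
#' @return Object of class `hand_sample`.
#' @export
hand_sample <- function(frames, frame_meta, subject_id, hand, sample_index,
                        bit_depth = 10) {
  s <- structure(list(frames = frames, frame_meta = frame_meta,
                      subject_id = as.character(subject_id), hand = hand,
                      sample_index = as.integer(sample_index),
                      bit_depth = as.integer(bit_depth)),
                 class = "hand_sample")
  validate_hand_sample(s)
  s
}

validate_hand_sample <- function(s) {
  if (!is.list(s$frames) || length(s$frames) == 0)
    stopf("validation error: sample must contain at least one frame")
  if (!is.data.frame(s$frame_meta) || nrow(s$frame_meta) != length(s$frames))
    stopf("validation error: frame_meta must have exactly one row per frame (%d frames, %d rows)",
          length(s$frames), if (is.data.frame(s$frame_meta)) nrow(s$frame_meta) else 0L)
  need <- c("camera", "wavelength", "illumination_state")
  if (!all(need %in% names(s$frame_meta)))
    stopf("validation error: frame_meta needs columns %s", paste(need, collapse = ", "))
  if (!all(s$frame_meta$camera %in% c("left", "right", "rgb")))
    stopf("validation error: camera must be left/right/rgb")
  if (!all(as.character(s$frame_meta$wavelength) %in% c("850", "950", "white", "laser")))
    stopf("validation error: wavelength must be 850/950/white/laser")
  if (!s$hand %in% c("LH", "RH")) stopf("validation error: hand must be LH or RH")
  if (s$sample_index < 0) stopf("validation error: sample_index must be >= 0")
  maxval <- 2^s$bit_depth - 1
  for (cam in unique(s$frame_meta$camera)) {
    idx <- which(s$frame_meta$camera == cam)
    dims <- lapply(s$frames[idx], function(f) dim(f)[1:2])
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1)
      stopf("validation error: all frames from camera '%s' must share dimensions", cam)
  }
  for (i in seq_along(s$frames)) {
    f <- s$frames[[i]]
    if (!(is.matrix(f) || (is.array(f) && length(dim(f)) == 3 && dim(f)[3] == 3)))
      stopf("validation error: frame %d is neither a matrix nor an h x w x 3 array", i)
    if (min(f) < 0 || max(f) > maxval)
      stopf("validation error: frame %d exceeds declared %d-bit range", i, s$bit_depth)
  }
  invisible(s)
}

#' @export
print.hand_sample <- function(x, ...) {
  cat(sprintf("hand_sample: subject %s %s sample %d, %d frame(s), %d-bit\n",
              x$subject_id, x$hand, x$sample_index, length(x$frames), x$bit_depth))
  print(table(camera = x$frame_meta$camera, wavelength = x$frame_meta$wavelength))
  invisible(x)
}

#' Write a hand sample to an on-disk container
#'
#' The container is a directory holding a JSON manifest (`sample.json`) and
#' one raw little-endian 16-bit payload per frame, grouped per camera
#' (mirroring the per-camera acquisition streams).  The round trip through
#' [read_sample()] is bit-exact.
#'
#' @param sample a valid [hand_sample()].
#' @param container_path directory to create (must not be an existing file).
#' @return `container_path`, invisibly.
#' @export
write_sample <- function(sample, container_path) {
  validate_hand_sample(sample)
  if (file.exists(container_path) && !dir.exists(container_path))
    stopf("container path exists and is not a directory: %s", container_path)
  dir.create(container_path, showWarnings = FALSE, recursive = TRUE)
  framedir <- file.path(container_path, "frames")
  dir.create(framedir, showWarnings = FALSE)
  per_cam_counter <- integer(0)
  frame_files <- character(length(sample$frames))
  shapes <- vector("list", length(sample$frames))
  for (i in seq_along(sample$frames)) {
    cam <- sample$frame_meta$camera[i]
    k <- if (is.na(per_cam_counter[cam])) 0L else per_cam_counter[cam]
    per_cam_counter[cam] <- k + 1L
    fn <- sprintf("%s_%03d.u16", cam, k)
    f <- sample$frames[[i]]
    shapes[[i]] <- dim(f)
    # row-major over (row, col[, channel]) for a stable byte layout
    v <- if (length(dim(f)) == 3) as.integer(aperm(f, c(3, 2, 1))) else as.integer(t(f))
    con <- file(file.path(framedir, fn), "wb")
    writeBin(v, con, size = 2, endian = "little")
    close(con)
    frame_files[i] <- fn
  }
  meta <- list(
    schema_version = SCHEMA_VERSION,
    subject_id = sample$subject_id, hand = sample$hand,
    sample_index = sample$sample_index, bit_depth = sample$bit_depth,
    frames = lapply(seq_along(sample$frames), function(i) list(
      file = frame_files[i],
      shape = as.integer(shapes[[i]]),
      camera = sample$frame_meta$camera[i],
      wavelength = as.character(sample$frame_meta$wavelength[i]),
      illumination_state = as.integer(sample$frame_meta$illumination_state[i])
    ))
  )
  jsonlite::write_json(meta, file.path(container_path, "sample.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(container_path)
}

#' Read a hand sample from an on-disk container
#'
#' Inverse of [write_sample()].
#'
#' @param container_path container directory written by [write_sample()].
#' @return A [hand_sample()].
#' @export
read_sample <- function(container_path) {
  mf <- file.path(container_path, "sample.json")
  if (!file.exists(mf)) stopf("I/O error: no sample manifest at %s", container_path)
  meta <- jsonlite::read_json(mf, simplifyVector = FALSE)
  if (is.null(meta$schema_version) || meta$schema_version != SCHEMA_VERSION)
    stopf("unsupported container schema version: %s (reader supports %d)",
          format(meta$schema_version), SCHEMA_VERSION)
  frames <- vector("list", length(meta$frames))
  fm <- data.frame(camera = character(0), wavelength = character(0),
                   illumination_state = integer(0))
  for (i in seq_along(meta$frames)) {
    fr <- meta$frames[[i]]
    shape <- as.integer(unlist(fr$shape))
    path <- file.path(container_path, "frames", fr$file)
    if (!file.exists(path)) stopf("I/O error: missing frame payload %s", fr$file)
    nvals <- prod(shape)
    if (file.info(path)$size != 2 * nvals)
      stopf("I/O error: truncated frame payload %s (%d bytes, expected %d)",
            fr$file, file.info(path)$size, 2 * nvals)
    con <- file(path, "rb")
    v <- readBin(con, "integer", n = nvals, size = 2, endian = "little",
                 signed = FALSE)
    close(con)
    frames[[i]] <- if (length(shape) == 3)
      aperm(array(v, dim = rev(shape)), c(3, 2, 1))
    else t(matrix(v, nrow = shape[2], ncol = shape[1]))
    fm <- rbind(fm, data.frame(camera = fr$camera,
                               wavelength = as.character(fr$wavelength),
                               illumination_state = as.integer(fr$illumination_state)))
  }
  hand_sample(frames, fm, meta$subject_id, meta$hand, meta$sample_index,
              bit_depth = meta$bit_depth)
}

#' Score table constructor
#'
#' A long table of template comparisons: one row per
#' (probe, enrolled, finger, protocol) with a finite score and a
#' genuine/impostor label.
#'
#' @param probe_id,enrolled_id character vectors.
#' @param finger_label finger label per row.
#' @param protocol_id protocol identifier per row.
#' @param score numeric, finite.
#' @param is_genuine logical.
#' @return data frame of class `score_table`.
#' @export
score_table <- function(probe_id, enrolled_id, finger_label, protocol_id,
                        score, is_genuine) {
  d <- data.frame(probe_id = as.character(probe_id),
                  enrolled_id = as.character(enrolled_id),
                  finger_label = as.character(finger_label),
                  protocol_id = as.character(protocol_id),
                  score = as.numeric(score),
                  is_genuine = as.logical(is_genuine),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$score))) stopf("validation error: scores must be finite")
  key <- paste(d$probe_id, d$enrolled_id, d$finger_label, d$protocol_id, sep = "\r")
  if (anyDuplicated(key)) stopf("validation error: duplicate comparison rows")
  class(d) <- c("score_table", "data.frame")
  d
}

#' Write a score table to CSV (full precision)
#' @param scores a [score_table()].
#' @param path output CSV path.
#' @export
write_score_table <- function(scores, path) {
  d <- as.data.frame(scores)
  d$score <- sprintf("%.17g", d$score)
  write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a score table from CSV
#' @param path CSV written by [write_score_table()].
#' @return a [score_table()].
#' @export
read_score_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  score_table(d$probe_id, d$enrolled_id, d$finger_label, d$protocol_id,
              as.numeric(d$score), d$is_genuine)
}

#' Export a single grayscale image as 16-bit PNG
#' @param img integer matrix within the given bit depth.
#' @param path output path.
#' @param bit_depth source bit depth (values scaled to the full 16-bit range).
#' @export
write_image_png <- function(img, path, bit_depth = 10) {
  png::writePNG(img / (2^bit_depth - 1), path)
  invisible(path)
}
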