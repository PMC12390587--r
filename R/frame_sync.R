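#' Clap pattern definition
#'
#' A clap is a short binary illumination pattern recorded at both ends of a
#' capture sequence.  Matching the two occurrences in the recorded frame
#' brightness recovers the frame alignment even when the sensor misses a
#' non-deterministic number of trigger pulses at the head of the capture.
#'
#' @param code binary vector of length 10; must contain at least one rising
#'   and one falling transition (i.e. be non-constant).
#' @param preamble_blank_frames number of blank frames preceding the first
#'   clap (default 10).
#' @return Object of class `clap_pattern`.
#' @export
clap_pattern <- function(code = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 1),
                         preamble_blank_frames = 10) {
  code <- as.integer(code)
  if (length(code) != 10 || !all(code %in% 0:1))
    stopf("clap code must be a binary vector of length 10")
  if (length(unique(code)) < 2)
    stopf("clap code must be non-constant (needs both transitions)")
  if (preamble_blank_frames < 0) stopf("preamble_blank_frames must be >= 0")
  structure(list(code = code, preamble_blank_frames = as.integer(preamble_blank_frames)),
            class = "clap_pattern")
}

#' Build the illumination schedule for a clap-bracketed capture
#'
#' The schedule is `blanks | code | payload slots (off) | code`, so its length
#' is `preamble + 10 + payload_length + 10`.
#'
#' @param payload_length number of payload frames (> 0).
#' @param pattern a [clap_pattern()].
#' @return Integer 0/1 vector, the illumination state per frame.
#' @export
encode_claps <- function(payload_length, pattern = clap_pattern()) {
  stopifnot(inherits(pattern, "clap_pattern"))
  if (payload_length < 1) stopf("payload_length must be >= 1")
  c(rep(0L, pattern$preamble_blank_frames), pattern$code,
    rep(0L, payload_length), pattern$code)
}

# Two-cluster 1-D split: Lloyd iterations initialised at the extremes.
# Returns the midpoint of the two cluster means.
binarize_threshold <- function(x) {
  c1 <- min(x); c2 <- max(x)
  if (c1 == c2) return(c1)
  for (i in 1:50) {
    mid <- (c1 + c2) / 2
    n1 <- mean(x[x <= mid]); n2 <- mean(x[x > mid])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

#' Recover frame alignment from recorded frame brightness
#'
#' Binarizes the per-frame brightness (threshold halfway between the two
#' brightness cluster means, so detection is invariant to affine brightness
#' scaling), locates the two exact occurrences of the clap code, and verifies
#' that the distance between them equals `10 + expected_payload` so that no
#' payload frame was dropped.
#'
#' @param frame_brightness numeric vector, one mean brightness per recorded
#'   frame (see [frame_brightness()]).
#' @param pattern a [clap_pattern()].
#' @param expected_payload expected number of payload frames between claps.
#' @return Object of class `sync_result` with `start_index` / `end_index`
#'   (1-based inclusive range of the payload in the recorded sequence),
#'   `frames_dropped_head` and `complete`.
#' @export
detect_claps <- function(frame_brightness, pattern = clap_pattern(),
                         expected_payload = NULL) {
  stopifnot(inherits(pattern, "clap_pattern"))
  x <- as.numeric(frame_brightness)
  if (is.null(expected_payload)) stopf("expected_payload is required")
  code <- pattern$code
  nfull <- pattern$preamble_blank_frames + 10 + expected_payload + 10
  if (length(x) < nfull - 3)
    stopf("brightness sequence too short: %d frames, expected at least %d",
          length(x), nfull - 3)
  thr <- binarize_threshold(x)
  b <- as.integer(x > thr)
  # exact binary correlation: positions where the 10-frame window equals code
  nw <- length(b) - 10 + 1
  if (nw < 2) stopf("sequence too short to contain two claps")
  hits <- which(vapply(seq_len(nw), function(i)
    all(b[i:(i + 9)] == code), logical(1)))
  if (length(hits) == 0) stopf("sync error: clap code not found")
  if (length(hits) > 2) stopf("sync error: clap code matched %d times", length(hits))
  if (length(hits) == 1) stopf("sync error: only one clap found")
  gap <- hits[2] - (hits[1] + 10)
  complete <- gap == expected_payload
  if (!complete)
    stopf("dropped-frame error: %d frames between claps, expected %d",
          gap, expected_payload)
  dropped <- (pattern$preamble_blank_frames + 1) - hits[1]
  structure(list(
    start_index = hits[1] + 10L,
    end_index = hits[2] - 1L,
    frames_dropped_head = as.integer(dropped),
    complete = complete
  ), class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("sync: payload frames %d..%d (%d frames), %d head frame(s) dropped, complete=%s\n",
              x$start_index, x$end_index, x$end_index - x$start_index + 1,
              x$frames_dropped_head, x$complete))
  invisible(x)
}

#' Per-frame brightness statistic for clap detection
#'
#' Mean intensity over the central 50% crop of each frame, robust to edge
#' vignetting.
#'
#' @param frames list of 2-D numeric matrices.
#' @return numeric vector of per-frame brightness values.
#' @export
frame_brightness <- function(frames) {
  vapply(frames, function(f) {
    n <- nrow(f); p <- ncol(f)
    ys <- max(1, round(n / 4)):min(n, round(3 * n / 4))
    xs <- max(1, round(p / 4)):min(p, round(3 * p / 4))
    mean(f[ys, xs])
  }, numeric(1))
}
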