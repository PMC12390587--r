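#' Match two vein templates by translation-searched cross-correlation
#'
#' Cross-correlates the two binary feature maps in the frequency domain,
#' restricts the search to offsets `|dy| <= max_shift[1]`,
#' `|dx| <= max_shift[2]`, and normalizes the peak overlap count by the
#' smaller of the two active-pixel counts, bounding the score to \[0, 1\]
#' (an identical pair scores 1).  Overlap counts are rounded to the nearest
#' integer to remove floating-point drift, so the result equals an
#' exhaustive spatial-domain search.  The score is symmetric in its
#' arguments.
#'
#' @param enrolled,probe [vein_template()] objects; each dimension of one may
#'   be at most twice the other's.
#' @param max_shift `c(max_dy, max_dx)`; default 20% of the larger template's
#'   rows/cols.
#' @param normalization `"min"` (default), `"union"` or `"geometric"` active
#'   count normalization.
#' @return Object of class `match_score`: `score` in \[0, 1\] and
#'   `best_offset` (dy, dx) of the probe relative to the enrolled template.
#' @export
match_templates <- function(enrolled, probe, max_shift = NULL,
                            normalization = c("min", "union", "geometric")) {
  stopifnot(inherits(enrolled, "vein_template"), inherits(probe, "vein_template"))
  normalization <- match.arg(normalization)
  A <- enrolled$feature_map * 1
  B <- probe$feature_map * 1
  nA <- sum(A); nB <- sum(B)
  if (nA == 0 || nB == 0) stopf("match error: empty template")
  if (any(dim(A) > 2 * dim(B)) || any(dim(B) > 2 * dim(A)))
    stopf("incompatible-template error: shapes %dx%d vs %dx%d differ by more than 2x",
          nrow(A), ncol(A), nrow(B), ncol(B))
  if (is.null(max_shift))
    max_shift <- round(0.2 * c(max(nrow(A), nrow(B)), max(ncol(A), ncol(B))))
  ms <- as.integer(pmax(0, max_shift))
  N1 <- nrow(A) + nrow(B) - 1
  N2 <- ncol(A) + ncol(B) - 1
  Ap <- matrix(0, N1, N2); Ap[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  Bp <- matrix(0, N1, N2); Bp[seq_len(nrow(B)), seq_len(ncol(B))] <- B
  # overlap(dy, dx) = sum_yx A(y, x) * B(y - dy, x - dx)
  C <- Re(fft(fft(Ap) * Conj(fft(Bp)), inverse = TRUE)) / (N1 * N2)
  C <- round(C)
  dys <- (-ms[1]):ms[1]
  dxs <- (-ms[2]):ms[2]
  dys <- dys[dys > -nrow(B) & dys < nrow(A)]
  dxs <- dxs[dxs > -ncol(B) & dxs < ncol(A)]
  iy <- (dys %% N1) + 1
  ix <- (dxs %% N2) + 1
  W <- C[iy, ix, drop = FALSE]
  peak <- max(W)
  hit <- which(W == peak, arr.ind = TRUE)
  # deterministic tie-break: smallest |dy| + |dx|, then dy, then dx
  od <- order(abs(dys[hit[, 1]]) + abs(dxs[hit[, 2]]), dys[hit[, 1]], dxs[hit[, 2]])
  best <- hit[od[1], ]
  denom <- switch(normalization,
                  min = min(nA, nB),
                  union = nA + nB - peak,
                  geometric = sqrt(nA * nB))
  structure(list(score = peak / denom,
                 best_offset = c(dy = -dys[best[1]], dx = -dxs[best[2]]),
                 overlap = as.integer(peak), n_enrolled = nA, n_probe = nB),
            class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("match_score: %.4f (overlap %d at offset dy=%d dx=%d)\n",
              x$score, x$overlap, x$best_offset[1], x$best_offset[2]))
  invisible(x)
}
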