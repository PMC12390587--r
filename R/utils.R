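#' @importFrom stats fft median sd quantile coef lm predict runif rnorm setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' Evaluate an expression under a fixed RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state.
#' All stochastic code in the package goes through this, so every generator
#' is a pure function of its seeds.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; keeps all seeds
# within the 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.double(seed) * 2654435 + as.double(stream) * 97003) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Shift a matrix by (dy, dx): positive dy moves content down, positive dx
# moves it right.  Vacated cells get `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  ys <- seq_len(n) - dy
  xs <- seq_len(p) - dx
  ok_y <- ys >= 1 & ys <= n
  ok_x <- xs >= 1 & xs <= p
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

# Bilinear sampling of `img` at fractional (row, col) positions.  Positions
# outside the image return `fill`.
bilinear_sample <- function(img, y, x, fill = 0) {
  n <- nrow(img); p <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0;  fx <- x - x0
  inside <- y0 >= 1 & x0 >= 1 & (y0 + 1) <= n & (x0 + 1) <= p
  out <- rep(fill, length(y))
  if (any(inside)) {
    yi <- y0[inside]; xi <- x0[inside]
    fyi <- fy[inside]; fxi <- fx[inside]
    i00 <- img[cbind(yi,     xi)]
    i01 <- img[cbind(yi,     xi + 1)]
    i10 <- img[cbind(yi + 1, xi)]
    i11 <- img[cbind(yi + 1, xi + 1)]
    out[inside] <- i00 * (1 - fyi) * (1 - fxi) + i01 * (1 - fyi) * fxi +
      i10 * fyi * (1 - fxi) + i11 * fyi * fxi
  }
  out
}

# Rotate an image about `center = c(row, col)` by `angle_deg`.  Angles are
# measured from the vertical (column) axis: content whose long axis makes an
# angle phi with the vertical makes phi + angle_deg after the call.
# Inverse-mapped so the output grid is dense; `nearest` for binary masks.
rotate_about <- function(img, angle_deg, center, nearest = FALSE, fill = 0) {
  th <- -angle_deg * pi / 180
  n <- nrow(img); p <- ncol(img)
  g <- expand.grid(y = seq_len(n), x = seq_len(p))
  dy <- g$y - center[1]; dx <- g$x - center[2]
  # inverse rotation of the output grid back into the source image
  sy <- center[1] + cos(th) * dy - sin(th) * dx
  sx <- center[2] + sin(th) * dy + cos(th) * dx
  if (nearest) {
    sy <- round(sy); sx <- round(sx)
    ok <- sy >= 1 & sy <= n & sx >= 1 & sx <= p
    v <- rep(fill, length(sy))
    v[ok] <- img[cbind(sy[ok], sx[ok])]
  } else {
    v <- bilinear_sample(img, sy, sx, fill = fill)
  }
  matrix(v, n, p)
}

# Fast moving-sum box filter (window w x w, zero-padded) via integral image.
box_sum <- function(m, w) {
  n <- nrow(m); p <- ncol(m)
  r <- w %/% 2
  ii <- matrix(0, n + 1, p + 1)
  cs <- apply(m, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  ii[2:(n + 1), 2:(p + 1)] <- cs
  y1 <- pmax(seq_len(n) - r, 1);  y2 <- pmin(seq_len(n) + r, n)
  x1 <- pmax(seq_len(p) - r, 1);  x2 <- pmin(seq_len(p) + r, p)
  ii[y2 + 1, x2 + 1, drop = FALSE] - ii[y1, x2 + 1, drop = FALSE] -
    ii[y2 + 1, x1, drop = FALSE] + ii[y1, x1, drop = FALSE]
}

# Separable Gaussian blur with replicate borders, computed by direct spatial
# convolution: bit-reproducible and exactly translation-covariant regardless
# of the image size (frequency-domain blurs are not, which would break the
# template translation property).
gblur_safe <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x); p <- ncol(x)
  pad_rows <- function(m) m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
  conv_rows <- function(m) {
    mp <- pad_rows(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(x))))
}

# Smallest double strictly greater than x (for strict thresholding).
next_up <- function(x) x + max(abs(x), .Machine$double.xmin) * .Machine$double.eps * 2

is_binary_matrix <- function(m) is.matrix(m) && all(m %in% c(0, 1, TRUE, FALSE))
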