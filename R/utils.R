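# Internal numeric helpers shared across modules. All lengths are micrometres
# unless a name says otherwise; image matrices are indexed [row = y, col = x].

mm_to_um <- function(x) x * 1000
um_to_mm <- function(x) x / 1000

.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(errorCondition(sprintf("`%s` must be a positive finite number", name),
                        class = c("clf_invalid_parameter", "error", "condition")))
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(errorCondition(sprintf("`%s` must be a non-negative finite number", name),
                        class = c("clf_invalid_parameter", "error", "condition")))
  }
  invisible(x)
}

.clf_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "clf_error", "error", "condition")))
}

#' Bilinear sampling of an image at fractional pixel coordinates
#'
#' Coordinates outside the image sample as zero.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param xq,yq numeric vectors of query coordinates (1-based pixel units).
#' @return numeric vector of sampled values.
#' @keywords internal
sample_bilinear <- function(img, xq, yq) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  gv <- function(xi, yi) {
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    v <- numeric(length(xi))
    if (any(ok)) v[ok] <- img[cbind(yi[ok], xi[ok])]
    v
  }
  gv(x0, y0) * (1 - fx) * (1 - fy) +
    gv(x0 + 1, y0) * fx * (1 - fy) +
    gv(x0, y0 + 1) * (1 - fx) * fy +
    gv(x0 + 1, y0 + 1) * fx * fy
}

# Translate an image by (dx, dy) pixels with bilinear interpolation
# (out(x, y) = img(x - dx, y - dy)); optionally evaluate only inside `roi`,
# a list(x = c(x1, x2), y = c(y1, y2)) of integer pixel bounds.
.shift_image <- function(img, dx, dy, roi = NULL) {
  H <- nrow(img); W <- ncol(img)
  if (is.null(roi)) {
    xs <- seq_len(W); ys <- seq_len(H)
  } else {
    xs <- roi$x[1]:roi$x[2]; ys <- roi$y[1]:roi$y[2]
  }
  xq <- rep(xs - dx, each = length(ys))
  yq <- rep(ys - dy, times = length(xs))
  matrix(sample_bilinear(img, xq, yq), length(ys), length(xs))
}

# 3x3 Laplacian (4-neighbour), zero-padded borders trimmed by one pixel.
.laplacian <- function(img) {
  H <- nrow(img); W <- ncol(img)
  if (H < 3 || W < 3) return(matrix(0, 0, 0))
  c0 <- img[2:(H - 1), 2:(W - 1)]
  img[1:(H - 2), 2:(W - 1)] + img[3:H, 2:(W - 1)] +
    img[2:(H - 1), 1:(W - 2)] + img[2:(H - 1), 3:W] - 4 * c0
}

#' Variance-of-Laplacian focus score
#'
#' The default degree-of-focus measure used for autofocus depth estimation and
#' extended-depth-of-focus quantification: the sample variance of the 3x3
#' Laplacian of the image, optionally restricted to a rectangular region.
#'
#' @param img numeric matrix.
#' @param roi optional list(x = c(x1, x2), y = c(y1, y2)) pixel bounds.
#' @return scalar focus score (>= 0).
#' @export
focus_score <- function(img, roi = NULL) {
  if (!is.null(roi)) img <- img[roi$y[1]:roi$y[2], roi$x[1]:roi$x[2], drop = FALSE]
  L <- .laplacian(img)
  if (length(L) < 2) return(0)
  stats::var(as.vector(L))
}

# Parabolic (3-point) interpolation of a peak position. x must be uniform.
# Ties and flat tops resolve toward smaller x.
.parabolic_peak <- function(x, y) {
  i <- which(y == max(y))[1]
  if (i == 1 || i == length(y)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  x[i] + delta * (x[i + 1] - x[i])
}

# Interpolated length of the contiguous interval around the global maximum
# where y >= threshold. Returns 0 if never reached.
.half_max_interval <- function(x, y, threshold) {
  i <- which(y == max(y))[1]
  if (max(y) < threshold) return(c(NA_real_, NA_real_))
  lo <- x[1]; hi <- x[length(x)]
  j <- i
  while (j > 1 && y[j - 1] >= threshold) j <- j - 1
  if (j > 1) {
    lo <- x[j] + (x[j - 1] - x[j]) * (y[j] - threshold) / (y[j] - y[j - 1])
  }
  j <- i
  while (j < length(y) && y[j + 1] >= threshold) j <- j + 1
  if (j < length(y)) {
    hi <- x[j] + (x[j + 1] - x[j]) * (y[j] - threshold) / (y[j] - y[j + 1])
  }
  c(lo, hi)
}

# Sum 2D fine grid into `f`-fold coarser pixels (dims must be multiples of f).
.bin_sum <- function(m, f) {
  H <- nrow(m); W <- ncol(m)
  stopifnot(H %% f == 0, W %% f == 0)
  m <- array(m, c(f, H %/% f, W))
  m <- colSums(m)                      # (H/f) x W
  m <- array(t(m), c(f, W %/% f, H %/% f))
  t(colSums(m))                        # (H/f) x (W/f)
}
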