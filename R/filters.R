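# Edge-enhancement filters for the feature bank. All rasters are matrices
# indexed [y + 1, x + 1] (x rightward, y downward). Boundaries are handled
# by reflection for the convolution filters and by one-sided differences for
# the derivatives.

# Internal: 2D correlation with reflective padding (kernel not flipped;
# all kernels used here are symmetric or handled explicitly)
conv2_reflect <- function(map, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  n <- nrow(map); m <- ncol(map)
  ri <- c(rev(seq_len(kr) + 1L), seq_len(n), n - seq_len(kr))
  ci <- c(rev(seq_len(kc) + 1L), seq_len(m), m - seq_len(kc))
  pad <- map[ri, ci, drop = FALSE]
  out <- matrix(0, n, m)
  for (dy in seq_len(nrow(kernel))) for (dx in seq_len(ncol(kernel))) {
    w <- kernel[dy, dx]
    if (w != 0)
      out <- out + w * pad[(dy - 1L) + seq_len(n), (dx - 1L) + seq_len(m)]
  }
  out
}

#' Directional pixel derivatives
#'
#' Central differences in the interior, one-sided differences at the
#' borders. `derivative_x` differentiates rightward (along columns),
#' `derivative_y` downward (along rows).
#'
#' @param map numeric matrix, at least 3 x 3.
#' @return matrix of the same dimensions.
#' @export
derivative_x <- function(map) {
  stopifnot(nrow(map) >= 3, ncol(map) >= 3)
  m <- ncol(map)
  out <- map
  out[, 2:(m - 1)] <- (map[, 3:m] - map[, 1:(m - 2)]) / 2
  out[, 1] <- map[, 2] - map[, 1]
  out[, m] <- map[, m] - map[, m - 1]
  out
}

#' @rdname derivative_x
#' @export
derivative_y <- function(map) t(derivative_x(t(map)))

#' Laplacian-of-Gaussian filter
#'
#' Correlation with the analytic LoG kernel
#' `(r^2 - 2 sigma^2) / sigma^4 * exp(-r^2 / (2 sigma^2))`, sum-corrected to
#' zero response on constants, reflective boundary.
#'
#' @param map numeric matrix.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return filtered matrix of the same dimensions.
#' @export
log_filter <- function(map, sigma = 2) {
  if (sigma <= 0) stop("sigma must be > 0")
  k <- log_kernel(sigma)
  conv2_reflect(map, k)
}

# Internal: discrete LoG kernel, zero-sum
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  g <- expand.grid(x = -r:r, y = -r:r)
  r2 <- g$x^2 + g$y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k <- matrix(k, 2 * r + 1, 2 * r + 1)
  k - mean(k)
}

#' Sobel gradient-magnitude filter
#'
#' `sqrt(Gx^2 + Gy^2)` of the classic (unnormalized) 3 x 3 Sobel kernels,
#' reflective boundary.
#'
#' @param map numeric matrix, at least 3 x 3.
#' @return filtered matrix of the same dimensions.
#' @export
sobel_filter <- function(map) {
  stopifnot(nrow(map) >= 3, ncol(map) >= 3)
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gx <- conv2_reflect(map, kx)
  gy <- conv2_reflect(map, t(kx))
  sqrt(gx^2 + gy^2)
}
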