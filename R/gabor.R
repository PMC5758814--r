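# Gabor wavelet bank and jets.
#
# Kernel family (classic bunch-graph parameterization): for scale s and
# orientation o, wave vector k = k_max / f^s (log-spaced), angle o * pi / m,
#   psi(x) = (|k|^2 / sigma^2) exp(-|k|^2 |x|^2 / (2 sigma^2))
#            * (exp(i k . x) - exp(-sigma^2 / 2))
# The subtracted term (plus an exact discrete mean correction) makes the
# kernels DC-free, so responses ignore absolute intensity. A "jet" is the
# vector of complex responses of all kernels at one pixel of one channel;
# template matching compares jets through the normalized inner product of
# their magnitude vectors.

#' Build a Gabor wavelet bank
#'
#' @param n_scales number of log-spaced frequency levels.
#' @param n_orientations number of evenly spaced orientations in `[0, pi)`.
#' @param k_max largest center frequency (radians/px).
#' @param f frequency spacing factor (wavelength ratio between levels).
#' @param sigma Gaussian envelope width ratio (envelope SD = `sigma / |k|`).
#' @return list of class `gabor_bank`: `kernels` (list of complex matrices,
#'   odd side, origin at center; order scale-major), `scale`, `orientation`,
#'   `k`, `phi` per kernel, and the construction parameters.
#' @export
build_gabor_bank <- function(n_scales = 5, n_orientations = 8,
                             k_max = pi / 2, f = sqrt(2), sigma = 2 * pi) {
  if (n_scales < 1 || n_orientations < 1) stop("counts must be >= 1")
  kernels <- list()
  scale <- orientation <- kk <- phi <- numeric(0)
  id <- 0L
  for (s in seq_len(n_scales) - 1L) {
    k <- k_max / f^s
    r <- ceiling(2.5 * sigma / k)     # support: 2.5 envelope SDs
    g <- expand.grid(y = -r:r, x = -r:r)       # y = rows (downward)
    r2 <- g$x^2 + g$y^2
    env <- (k^2 / sigma^2) * exp(-k^2 * r2 / (2 * sigma^2))
    for (o in seq_len(n_orientations) - 1L) {
      a <- o * pi / n_orientations
      arg <- k * (cos(a) * g$x + sin(a) * g$y)
      ker <- env * (exp(1i * arg) - exp(-sigma^2 / 2))
      ker <- ker - mean(ker)                   # exact discrete DC removal
      id <- id + 1L
      kernels[[id]] <- matrix(ker, 2 * r + 1, 2 * r + 1)
      scale[id] <- s; orientation[id] <- o; kk[id] <- k; phi[id] <- a
    }
  }
  structure(list(kernels = kernels, scale = scale, orientation = orientation,
                 k = kk, phi = phi, n_scales = n_scales,
                 n_orientations = n_orientations, k_max = k_max, f = f,
                 sigma = sigma, cache = new.env(parent = emptyenv())),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank: %d scales x %d orientations = %d kernels, k_max %.3f, sigma %.2f>\n",
              x$n_scales, x$n_orientations, length(x$kernels), x$k_max, x$sigma))
  invisible(x)
}

# Internal: padded FFTs of all kernels for image-size-n convolution, cached
# on the bank by reference. With zero padding, P >= n + r suffices for all
# n x n output pixels to be wrap-free. Conjugate kernel spectra are stored
# as separate real/imaginary parts: the elementwise complex product is much
# faster in real arithmetic.
bank_ffts <- function(bank, n) {
  rmax <- (max(vapply(bank$kernels, nrow, integer(1))) - 1L) %/% 2L
  P <- fft_good_size(n + rmax)
  key <- paste0("P", P)
  if (!is.null(bank$cache[[key]])) return(bank$cache[[key]])
  kf_cx <- lapply(bank$kernels, function(ker) {
    r <- (nrow(ker) - 1L) %/% 2L
    pad <- matrix(0 + 0i, P, P)
    ix <- ((-r:r) %% P) + 1L
    pad[ix, ix] <- ker
    Conj(fft(pad))
  })
  kf <- lapply(kf_cx, function(K) list(re = Re(K), im = Im(K)))
  res <- list(P = P, kf = kf, kf_cx = kf_cx)
  bank$cache[[key]] <- res
  res
}

# Internal: next FFT-friendly size (factors 2, 3, 5, 7)
fft_good_size <- function(n) {
  repeat {
    m <- n
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    if (m == 1) return(as.integer(n))
    n <- n + 1
  }
}

# Internal: full-image cross-correlation of one channel with every kernel.
# Returns list(re, im): n_px x n_kernels real matrices, rows = the requested
# pixels (linear indices of the [y+1, x+1] raster; all pixels when
# `pixels = NULL`). Image treated as zero outside its bounds (matching
# extract_jet). Real/imaginary parts are kept separate: R's vectorized real
# arithmetic is far faster than its complex arithmetic.
channel_responses <- function(channel, bank, pixels = NULL,
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n <- nrow(channel)
  bf <- bank_ffts(bank, n)
  P <- bf$P
  if (is.null(pixels)) pixels <- seq_len(n * n)
  iy <- (pixels - 1L) %% n; ix <- (pixels - 1L) %/% n
  if (engine == "cpp")
    return(gabor_conv_cpp(channel, bf$kf_cx, iy, ix, P))
  pad <- matrix(0 + 0i, P, P)
  pad[1:n, 1:n] <- channel
  If <- fft(pad)
  a <- Re(If); b <- Im(If)
  sub <- iy + 1L + ix * P     # linear indices into the P x P transform
  out_re <- matrix(0, length(pixels), length(bf$kf))
  out_im <- matrix(0, length(pixels), length(bf$kf))
  for (j in seq_along(bf$kf)) {
    cd <- bf$kf[[j]]
    prod <- complex(real = a * cd$re - b * cd$im,
                    imaginary = a * cd$im + b * cd$re)
    dim(prod) <- c(P, P)
    cc <- fft(prod, inverse = TRUE)
    out_re[, j] <- Re(cc)[sub] / (P * P)
    out_im[, j] <- Im(cc)[sub] / (P * P)
  }
  list(re = out_re, im = out_im)
}

#' Precompute Gabor response maps of a feature stack
#'
#' Convolves every channel with every kernel of the bank (FFT-based), giving
#' the per-pixel jets needed by the template searches. Also accumulates the
#' componentwise complex sum of the 15 channel jets used by the
#' summed-response landmarker.
#'
#' @param stack a [build_feature_stack()] result.
#' @param bank a [build_gabor_bank()].
#' @param pixels optional sorted vector of linear pixel indices
#'   (`iy + 1 + ix * n`) to evaluate; default all pixels. Restricting to
#'   the pixels a search will visit (see the search-window helpers) cuts
#'   memory and time substantially.
#' @return list of class `jet_maps`: `mag` (per channel, an
#'   `n_px x n_kernels` magnitude matrix), `agg_mag` (magnitudes of the
#'   channel-sum jets), `n` (image side), `rowmap` (linear pixel index ->
#'   row, or NULL when all pixels are stored).
#' @export
gabor_responses <- function(stack, bank, pixels = NULL) {
  stopifnot(inherits(stack, "feature_stack"))
  chn <- names(stack$channels)
  n <- nrow(stack$channels[[1]])
  rowmap <- NULL
  if (!is.null(pixels)) {
    pixels <- sort(unique(as.integer(pixels)))
    rowmap <- rep(NA_integer_, n * n)
    rowmap[pixels] <- seq_along(pixels)
  }
  agg_re <- agg_im <- NULL
  mag <- vector("list", length(chn))
  names(mag) <- chn
  for (ch in chn) {
    resp <- channel_responses(stack$channels[[ch]], bank, pixels)
    if (is.null(agg_re)) {
      agg_re <- resp$re; agg_im <- resp$im
    } else {
      agg_re <- agg_re + resp$re; agg_im <- agg_im + resp$im
    }
    mag[[ch]] <- sqrt(resp$re^2 + resp$im^2)
  }
  structure(list(mag = mag, agg_mag = sqrt(agg_re^2 + agg_im^2), n = n,
                 rowmap = rowmap),
            class = "jet_maps")
}

# Internal: rows of a jet_maps matrix for given linear pixel indices
jm_rows <- function(maps, lin) {
  if (is.null(maps$rowmap)) return(lin)
  r <- maps$rowmap[lin]
  if (anyNA(r)) stop("pixel not covered by the precomputed response maps")
  r
}

#' Extract a Gabor jet at one pixel
#'
#' Direct (spatial-domain) evaluation of all kernel responses centered on an
#' integer pixel; pixels outside the image contribute zero. Matches the
#' corresponding pixel of the full-image convolution.
#'
#' @param channel numeric raster (matrix indexed `[y + 1, x + 1]`).
#' @param bank a [build_gabor_bank()].
#' @param point numeric `(x, y)` pixel position, 0-based (rounded to the
#'   nearest pixel center).
#' @return complex vector of length `n_kernels`, class `gabor_jet`.
#' @export
extract_jet <- function(channel, bank, point) {
  n <- nrow(channel); m <- ncol(channel)
  ix <- as.integer(clamp(round(point[1] - 0.5), 0, m - 1))
  iy <- as.integer(clamp(round(point[2] - 0.5), 0, n - 1))
  if (point[1] < 0 || point[1] >= m || point[2] < 0 || point[2] >= n)
    stop("point outside raster")
  res <- complex(length(bank$kernels))
  for (j in seq_along(bank$kernels)) {
    ker <- bank$kernels[[j]]
    r <- (nrow(ker) - 1L) %/% 2L
    ys <- max(1L, iy + 1L - r):min(n, iy + 1L + r)
    xs <- max(1L, ix + 1L - r):min(m, ix + 1L + r)
    kys <- ys - (iy + 1L) + r + 1L
    kxs <- xs - (ix + 1L) + r + 1L
    res[j] <- sum(channel[ys, xs] * Conj(ker[kys, kxs]))
  }
  structure(res, class = "gabor_jet")
}

#' Similarity between two jets
#'
#' Normalized inner product of the magnitude vectors (phase-insensitive,
#' the default) or the real part of the normalized complex inner product
#' (`phase = TRUE`). Returns 0 if either norm is zero.
#'
#' @param j1,j2 jets (complex or magnitude vectors of equal length).
#' @param phase use phase-sensitive similarity.
#' @return similarity in `[0, 1]` (phase-insensitive case).
#' @export
jet_similarity <- function(j1, j2, phase = FALSE) {
  if (length(j1) != length(j2)) stop("jet length mismatch")
  if (phase) {
    n1 <- sqrt(sum(Mod(j1)^2)); n2 <- sqrt(sum(Mod(j2)^2))
    if (n1 == 0 || n2 == 0) return(0)
    return(Re(sum(j1 * Conj(j2))) / (n1 * n2))
  }
  a <- Mod(j1); b <- Mod(j2)
  n1 <- sqrt(sum(a^2)); n2 <- sqrt(sum(b^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(a * b) / (n1 * n2)
}
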