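#' Canonical feature-channel names
#'
#' The fixed channel order of the 15-channel feature bank:
#' `[tex, hgt, crv]` (texture, heightmap, curvature) crossed with
#' `[ori, dx, dy, log, sob]` (unfiltered, x/y derivative,
#' Laplacian-of-Gaussian, Sobel magnitude), main feature varying slowest.
#'
#' @return character vector of length 15 ("tex.ori" ... "crv.sob").
#' @export
feature_channel_names <- function() {
  as.vector(t(outer(c("tex", "hgt", "crv"),
                    c("ori", "dx", "dy", "log", "sob"), paste, sep = ".")))
}

#' Build the 15-channel feature stack of a projected face
#'
#' Applies the four edge enhancements to each of the three main maps and
#' z-score standardizes every channel (constant channels are left at 0) so
#' responses are comparable across channels. Pixel correspondence is
#' preserved: a landmark's pixel coordinates index the same anatomical
#' point in every channel.
#'
#' @param face a `projected_face` with curvature filled
#'   (see [compute_curvature()]).
#' @param log_sigma Gaussian scale (px) of the LoG filter.
#' @return list of class `feature_stack`: `channels` (named list of 15
#'   matrices in canonical order), `face` (the source projection, kept for
#'   the pixel-to-3D back-map), `log_sigma`.
#' @export
build_feature_stack <- function(face, log_sigma = 2) {
  stopifnot(inherits(face, "projected_face"))
  if (is.null(face$curvature))
    stop("face has no curvature raster; run compute_curvature() first")
  mains <- list(tex = face$texture, hgt = face$heightmap, crv = face$curvature)
  channels <- list()
  for (mn in names(mains)) {
    m <- mains[[mn]]
    if (anyNA(m)) stop("main map '", mn, "' contains NA")
    channels[[paste0(mn, ".ori")]] <- m
    channels[[paste0(mn, ".dx")]] <- derivative_x(m)
    channels[[paste0(mn, ".dy")]] <- derivative_y(m)
    channels[[paste0(mn, ".log")]] <- log_filter(m, log_sigma)
    channels[[paste0(mn, ".sob")]] <- sobel_filter(m)
  }
  channels <- channels[feature_channel_names()]
  channels <- lapply(channels, function(ch) {
    s <- stats::sd(ch)
    if (!is.finite(s) || s < 1e-12) matrix(0, nrow(ch), ncol(ch))
    else (ch - mean(ch)) / s
  })
  structure(list(channels = channels, face = face, log_sigma = log_sigma),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<feature_stack: %d channels, %dx%d px>\n",
              length(x$channels), d[1], d[2]))
  invisible(x)
}
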