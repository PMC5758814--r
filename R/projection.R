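# Mercator flattening of a facial mesh over a fitted ellipsoid.
#
# Parameterization: points are mapped to the ellipsoid's normalized sphere
# (ellipsoid_normalize); a pole/meridian frame is built there from the world
# "up" and "front" directions so the frontal face sits in the low-distortion
# band; longitude/latitude follow, then the standard Mercator forward map
# X = lon, Y = asinh(tan(lat)). Pixels are 0-based, x rightward, y downward,
# pixel (i, j) centered at (i + 0.5, j + 0.5).

# Internal: orthonormal (front, left, pole) frame in normalized-sphere space
projection_frame <- function(ell, up = c(0, 1, 0), front = c(0, 0, 1)) {
  tfm <- function(d) {
    w <- (d %*% ell$orientation) / ell$semi_axes
    w / sqrt(sum(w^2))
  }
  pole <- as.numeric(tfm(rbind(up)))
  fr <- as.numeric(tfm(rbind(front)))
  fr <- fr - sum(fr * pole) * pole
  if (sqrt(sum(fr^2)) < 1e-12) stop("up and front directions are parallel")
  fr <- fr / sqrt(sum(fr^2))
  left <- c(pole[2] * fr[3] - pole[3] * fr[2],
            pole[3] * fr[1] - pole[1] * fr[3],
            pole[1] * fr[2] - pole[2] * fr[1])
  rbind(front = fr, left = left, pole = pole)
}

# Internal: (lon, lat, t) of world points; t = |w| is the radial parameter
# (1 on the ellipsoid surface)
lonlat_of <- function(ell, frame, pts) {
  w <- ellipsoid_normalize(ell, pts)
  t <- sqrt(rowSums(w^2))
  wh <- w / t
  lat <- asin(clamp(wh %*% frame["pole", ], -1, 1))
  lon <- atan2(wh %*% frame["left", ], wh %*% frame["front", ])
  cbind(lon = as.numeric(lon), lat = as.numeric(lat), t = t)
}

mercator_fwd <- function(lonlat) cbind(X = lonlat[, 1], Y = asinh(tan(lonlat[, 2])))
mercator_inv <- function(XY) cbind(lon = XY[, 1], lat = atan(sinh(XY[, 2])))

#' Region-of-interest configuration for the Mercator projection
#'
#' @param side ROI side length in Mercator (radian) units. The default 1.6
#'   keeps the frontal face inside the low-distortion band.
#' @param center optional `(X, Y)` Mercator center; default: forward
#'   projection of the mesh vertex centroid direction.
#' @param up,front world directions of the ellipsoid "north pole" (superior)
#'   and of the facial front (longitude zero).
#' @return list of class `roi_config`.
#' @export
roi_config <- function(side = 1.6, center = NULL,
                       up = c(0, 1, 0), front = c(0, 0, 1)) {
  stopifnot(side > 0)
  structure(list(side = side, center = center, up = up, front = front),
            class = "roi_config")
}

#' Project a facial mesh to aligned 2D rasters
#'
#' Flattens the mesh over `ell` with a Mercator projection, rasterizing
#' texture (per-vertex color, or shaded height when absent) and heightmap
#' (signed radial mm distance from the surface to the ellipsoid) on an
#' `n x n` pixel grid over a square ROI, and retaining a per-pixel 3D
#' back-map so that the 2D-3D correspondence is one-to-one. Where several
#' surface sheets cross a pixel's ray the outermost (visible) one is kept.
#' ROI pixels not covered by the mesh are flagged in `hole_mask` and filled
#' by nearest-neighbour inpainting.
#'
#' @param mesh a [surface_mesh()].
#' @param ell an `ellipsoid` from [fit_ellipsoid()].
#' @param roi a [roi_config()].
#' @param image_size raster side in pixels.
#' @return list of class `projected_face`: `texture`, `heightmap` (matrices
#'   indexed `[y + 1, x + 1]`), `curvature` (`NULL` until
#'   [compute_curvature()]), `backmap` (`n x n x 3` array, mm), `tri_id`,
#'   `bary` (per-pixel triangle and barycentric coordinates), `hole_mask`,
#'   `n_holes`, `roi` (resolved ROI: `X0/Y0/side/px_size`), `frame`, `ell`,
#'   and `mm_per_px` (median ground resolution).
#' @export
project_mercator <- function(mesh, ell, roi = roi_config(), image_size = 200L) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(ell, "face_ellipsoid"))
  n <- as.integer(image_size)
  frame <- projection_frame(ell, roi$up, roi$front)
  ll <- lonlat_of(ell, frame, mesh$vertices)
  XY <- mercator_fwd(ll)
  if (is.null(roi$center)) {
    cdir <- colMeans(mesh$vertices)
    cll <- lonlat_of(ell, frame, rbind(cdir))
    roi$center <- as.numeric(mercator_fwd(cll))
  }
  px_size <- roi$side / n
  X0 <- roi$center[1] - roi$side / 2
  Y0 <- roi$center[2] + roi$side / 2
  # continuous pixel coordinates of the vertices
  vx <- (XY[, "X"] - X0) / px_size
  vy <- (Y0 - XY[, "Y"]) / px_size
  # signed height: distance from surface point to its ellipsoid foot point
  wh <- ellipsoid_normalize(ell, mesh$vertices)
  tt <- ll[, "t"]
  foot <- ellipsoid_denormalize(ell, wh / tt)
  h <- sign(tt - 1) * sqrt(rowSums((mesh$vertices - foot)^2))
  tex <- if (is.null(mesh$color)) {
    hr <- range(h); 0.2 + 0.6 * (h - hr[1]) / max(hr[2] - hr[1], 1e-12)
  } else mesh$color

  buf_t <- matrix(-Inf, n, n)       # [y, x]; keep outermost sheet
  buf_h <- matrix(NA_real_, n, n)
  buf_tex <- matrix(NA_real_, n, n)
  buf_tri <- matrix(NA_integer_, n, n)
  buf_b1 <- matrix(NA_real_, n, n); buf_b2 <- matrix(NA_real_, n, n)
  bm <- array(NA_real_, c(n, n, 3))

  tri <- mesh$triangles
  for (k in seq_len(nrow(tri))) {
    v <- tri[k, ]
    x <- vx[v]; y <- vy[v]
    if (anyNA(x) || anyNA(y)) next
    if (max(x) - min(x) > n / 2) next          # spans the lon wrap: skip
    ix0 <- max(1L, floor(min(x) + 0.5) + 1L)   # pixel centers in bbox
    ix1 <- min(n, ceiling(max(x) - 0.5) + 1L)
    iy0 <- max(1L, floor(min(y) + 0.5) + 1L)
    iy1 <- min(n, ceiling(max(y) - 0.5) + 1L)
    if (ix0 > ix1 || iy0 > iy1) next
    px <- rep(ix0:ix1 - 0.5, each = iy1 - iy0 + 1L)
    py <- rep(iy0:iy1 - 0.5, times = ix1 - ix0 + 1L)
    d <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
    if (abs(d) < 1e-12) next
    l1 <- ((y[2] - y[3]) * (px - x[3]) + (x[3] - x[2]) * (py - y[3])) / d
    l2 <- ((y[3] - y[1]) * (px - x[3]) + (x[1] - x[3]) * (py - y[3])) / d
    l3 <- 1 - l1 - l2
    eps <- -1e-9
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (!any(inside)) next
    pxi <- as.integer(px[inside] + 0.5); pyi <- as.integer(py[inside] + 0.5)
    lin <- pyi + (pxi - 1L) * n
    t_int <- l1[inside] * tt[v[1]] + l2[inside] * tt[v[2]] + l3[inside] * tt[v[3]]
    upd <- t_int > buf_t[lin]
    if (!any(upd)) next
    lin <- lin[upd]
    w1 <- l1[inside][upd]; w2 <- l2[inside][upd]; w3 <- 1 - w1 - w2
    buf_t[lin] <- t_int[upd]
    buf_h[lin] <- w1 * h[v[1]] + w2 * h[v[2]] + w3 * h[v[3]]
    buf_tex[lin] <- w1 * tex[v[1]] + w2 * tex[v[2]] + w3 * tex[v[3]]
    buf_tri[lin] <- k
    buf_b1[lin] <- w1; buf_b2[lin] <- w2
    p <- mesh$vertices
    for (dim in 1:3)
      bm[lin + (dim - 1L) * n * n] <-
        w1 * p[v[1], dim] + w2 * p[v[2], dim] + w3 * p[v[3], dim]
  }

  hole_mask <- is.na(buf_h)
  n_holes <- sum(hole_mask)
  if (n_holes > 0 && n_holes < n * n) {
    filled <- inpaint_nn(list(buf_h, buf_tex,
                              bm[, , 1], bm[, , 2], bm[, , 3]), hole_mask)
    buf_h <- filled[[1]]; buf_tex <- filled[[2]]
    bm[, , 1] <- filled[[3]]; bm[, , 2] <- filled[[4]]; bm[, , 3] <- filled[[5]]
  }
  # ground resolution from backmap spacing
  d1 <- sqrt(rowSums((matrix(bm[, -1, ], ncol = 3) -
                      matrix(bm[, -n, ], ncol = 3))^2, na.rm = FALSE))
  mm_per_px <- stats::median(d1, na.rm = TRUE)

  structure(list(texture = buf_tex, heightmap = buf_h, curvature = NULL,
                 backmap = bm, tri_id = buf_tri,
                 bary = array(c(buf_b1, buf_b2, 1 - buf_b1 - buf_b2), c(n, n, 3)),
                 hole_mask = hole_mask, n_holes = n_holes,
                 roi = list(X0 = X0, Y0 = Y0, side = roi$side, px_size = px_size),
                 frame = frame, ell = ell, image_size = n,
                 mm_per_px = mm_per_px),
            class = "projected_face")
}

#' @export
print.projected_face <- function(x, ...) {
  cat(sprintf("<projected_face: %dx%d px, %.2f mm/px, %d hole px%s>\n",
              x$image_size, x$image_size, x$mm_per_px, x$n_holes,
              if (is.null(x$curvature)) "" else ", curvature filled"))
  invisible(x)
}

# Internal: nearest-neighbour-ish inpainting by iterative 4-neighbour mean fill
inpaint_nn <- function(mats, mask) {
  n <- nrow(mats[[1]])
  while (any(mask)) {
    shift <- function(m, dy, dx) {
      out <- matrix(NA_real_, n, n)
      ys <- max(1, 1 + dy):min(n, n + dy); xs <- max(1, 1 + dx):min(n, n + dx)
      out[ys, xs] <- m[ys - dy, xs - dx]
      out
    }
    prev_left <- sum(mask)
    for (i in seq_along(mats)) {
      m <- mats[[i]]
      acc <- matrix(0, n, n); cnt <- matrix(0L, n, n)
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        s <- shift(m, d[1], d[2])
        good <- !is.na(s)
        acc[good] <- acc[good] + s[good]
        cnt <- cnt + good
      }
      fill <- mask & cnt > 0
      m[fill] <- acc[fill] / cnt[fill]
      mats[[i]] <- m
    }
    mask <- is.na(mats[[1]])
    if (sum(mask) == prev_left) break   # isolated unreachable region
  }
  mats
}

#' Project 3D landmarks into pixel coordinates (and back)
#'
#' `project_landmarks` applies the face's forward Mercator map;
#' `backproject_landmarks` reads the per-pixel 3D back-map with bilinear
#' interpolation. Forward-then-backward is identity to within one pixel's
#' ground resolution for landmarks on the projected surface. Landmarks
#' falling outside the ROI are flagged (`ok = FALSE`), never clamped.
#'
#' @param lm3d a [landmarks3d()].
#' @param face a `projected_face`.
#' @return `project_landmarks`: a [landmarks2d()] with `ok` flags;
#'   `backproject_landmarks`: a [landmarks3d()].
#' @export
project_landmarks <- function(lm3d, face) {
  xyz <- lm_coords(lm3d)
  ll <- lonlat_of(face$ell, face$frame, xyz)
  XY <- mercator_fwd(ll)
  x <- (XY[, "X"] - face$roi$X0) / face$roi$px_size
  y <- (face$roi$Y0 - XY[, "Y"]) / face$roi$px_size
  n <- face$image_size
  ok <- x >= 0 & x < n & y >= 0 & y < n
  ids <- sort(lm3d$landmark_id)
  landmarks2d(ids, cbind(x, y),
              names = lm3d$name[order(lm3d$landmark_id)], ok = ok)
}

#' @rdname project_landmarks
#' @param lm2d a [landmarks2d()].
#' @export
backproject_landmarks <- function(lm2d, face) {
  xy <- lm_coords(lm2d)
  xyz <- t(apply(xy, 1, function(p) bilinear_backmap(face, p[1], p[2])))
  ids <- sort(lm2d$landmark_id)
  landmarks3d(ids, xyz, names = lm2d$name[order(lm2d$landmark_id)])
}

# Internal: bilinear interpolation of the backmap at continuous pixel (x, y);
# sample points are pixel centers (i + 0.5, j + 0.5)
bilinear_backmap <- function(face, x, y) {
  n <- face$image_size
  if (is.na(x) || is.na(y) || x < 0 || x >= n || y < 0 || y >= n)
    return(c(NA_real_, NA_real_, NA_real_))
  fx <- clamp(x - 0.5, 0, n - 1); fy <- clamp(y - 0.5, 0, n - 1)
  x0 <- floor(fx); y0 <- floor(fy)
  x1 <- min(x0 + 1, n - 1); y1 <- min(y0 + 1, n - 1)
  ax <- fx - x0; ay <- fy - y0
  v <- function(iy, ix) face$backmap[iy + 1, ix + 1, ]
  (1 - ax) * (1 - ay) * v(y0, x0) + ax * (1 - ay) * v(y0, x1) +
    (1 - ax) * ay * v(y1, x0) + ax * ay * v(y1, x1)
}
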