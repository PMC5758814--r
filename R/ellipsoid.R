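#' Fit an ellipsoid to a point cloud
#'
#' Ellipsoid-specific algebraic least-squares fit: the quadric coefficient
#' vector minimizes the algebraic residual subject to the ellipsoidicity
#' constraint `4J - I^2 = 1` on its quadratic part (the Li-Griffiths
#' constraint, the 3D analogue of Fitzgibbon's direct ellipse fit), solved
#' as a reduced 6 x 6 generalized eigenproblem after centering and scaling
#' for conditioning. Unlike an unconstrained quadric fit this remains an
#' ellipsoid on partial surface coverage such as a frontal face patch.
#'
#' @param mesh a [surface_mesh()] or an n x 3 matrix of points (mm).
#' @return list of class `ellipsoid` with `center` (mm), `semi_axes`
#'   (ascending, mm), `orientation` (3 x 3 rotation, columns = axis
#'   directions matching `semi_axes`) and `residual` (RMS algebraic residual
#'   of the normalized quadric over the input points).
#' @export
fit_ellipsoid <- function(mesh) {
  pts <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as.matrix(mesh)
  stopifnot(ncol(pts) == 3)
  if (nrow(pts) < 9) stop("need at least 9 points to fit an ellipsoid")
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  if (qr(pc)$rank < 3) stop("degenerate point cloud: rank < 3")
  scl <- mean(sqrt(rowSums(pc^2)))
  x <- pc[, 1] / scl; y <- pc[, 2] / scl; z <- pc[, 3] / scl
  D <- cbind(x^2, y^2, z^2, 2 * x * y, 2 * x * z, 2 * y * z,
             2 * x, 2 * y, 2 * z, 1)
  S <- crossprod(D)
  # constraint 4J - I^2 as a quadratic form on (x^2, y^2, z^2) and the
  # (2xy, 2xz, 2yz) coefficients; zero on the linear/constant part
  C1 <- rbind(c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1))
  C1 <- rbind(cbind(C1, matrix(0, 3, 3)),
              cbind(matrix(0, 3, 3), diag(-4, 3)))
  S11 <- S[1:6, 1:6]; S12 <- S[1:6, 7:10]; S22 <- S[7:10, 7:10]
  S22i <- tryCatch(solve(S22), error = function(e)
    stop("degenerate quadric fit (singular design)"))
  M <- S11 - S12 %*% S22i %*% t(S12)
  eg0 <- eigen(solve(C1, M))
  lam <- eg0$values
  real_ok <- abs(Im(lam)) < 1e-6 * (abs(Re(lam)) + 1)
  # admissible eigenvectors can be normalized to v' C1 v = 1; among them the
  # one with the smallest (non-negative, up to rounding) residual wins
  obj <- rep(Inf, length(lam))
  for (i in which(real_ok)) {
    vi <- Re(eg0$vectors[, i])
    cv <- as.numeric(t(vi) %*% C1 %*% vi)
    if (cv > 1e-12 * sum(vi^2))
      obj[i] <- as.numeric(t(vi) %*% M %*% vi) / cv
  }
  if (!any(is.finite(obj))) stop("no ellipsoid solution (degenerate input)")
  v1 <- Re(eg0$vectors[, which.min(obj)])
  v <- c(v1, as.numeric(-S22i %*% t(S12) %*% v1))
  A <- matrix(c(v[1], v[4], v[5],
                v[4], v[2], v[6],
                v[5], v[6], v[3]), 3, 3)
  b <- v[7:9]
  cc <- v[10]
  m <- solve(A, -b)
  k <- -(cc + sum(b * m))
  eg <- eigen(A, symmetric = TRUE)
  if (any(k / eg$values <= 0))
    stop("fitted quadric is not an ellipsoid (point cloud too flat or noisy)")
  semi <- sqrt(k / eg$values)            # in scaled coords
  ord <- order(semi)
  semi <- semi[ord]
  R <- eg$vectors[, ord, drop = FALSE]
  # fix handedness and sign convention (largest component positive)
  for (i in 1:3) if (R[which.max(abs(R[, i])), i] < 0) R[, i] <- -R[, i]
  if (det(R) < 0) R[, 3] <- -R[, 3]
  resid <- sqrt(mean((D %*% v)^2)) / sqrt(abs(k))
  structure(list(center = ctr + m * scl, semi_axes = semi * scl,
                 orientation = R, residual = resid),
            class = "face_ellipsoid")
}

#' @export
print.face_ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid: center (%.1f, %.1f, %.1f) mm, semi-axes (%.1f, %.1f, %.1f) mm>\n",
              x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

# Internal: normalized "unit sphere" coordinates of world points w.r.t. an
# ellipsoid: w = diag(1/a) R^T (p - c). |w| = 1 on the ellipsoid surface.
ellipsoid_normalize <- function(ell, pts) {
  q <- sweep(as.matrix(pts), 2, ell$center) %*% ell$orientation
  sweep(q, 2, ell$semi_axes, `/`)
}

# Internal: world point from normalized coordinates
ellipsoid_denormalize <- function(ell, w) {
  q <- sweep(as.matrix(w), 2, ell$semi_axes, `*`)
  sweep(q %*% t(ell$orientation), 2, ell$center, `+`)
}
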