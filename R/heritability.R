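# Twin-based heritability of geometric facial features: generalized
# Procrustes alignment of landmark configurations, geometric feature
# extraction (coordinates, all pairwise distances, triangle areas/angles on
# a triangulation of the symmetrized mean shape), an additive (narrow-sense)
# twin mixed model, and importance maps summarizing per-feature
# heritabilities over the image.

#' Generalized Procrustes alignment
#'
#' Iterative alignment of 2D landmark configurations: each configuration is
#' centered, scaled to unit centroid size (optional), and rotated to the
#' evolving consensus until the consensus change is below `tol`. Rotations
#' only (no reflections).
#'
#' @param configs list of k x 2 coordinate matrices (or [landmarks2d()]).
#' @param scale include the scaling step.
#' @param tol convergence tolerance on the consensus.
#' @param max_iter iteration cap.
#' @return list of class `gpa_result`: `aligned` (list of k x 2 matrices),
#'   `mean` (consensus shape, unit centroid size if `scale`), `iterations`.
#' @export
procrustes_align <- function(configs, scale = TRUE, tol = 1e-8,
                             max_iter = 200L) {
  if (length(configs) < 2) stop("need at least 2 configurations")
  mats <- lapply(configs, function(cf)
    if (inherits(cf, "data.frame")) lm_coords(cf) else as.matrix(cf))
  mats <- lapply(mats, function(m) {
    m <- sweep(m, 2, colMeans(m))
    s <- sqrt(sum(m^2))
    if (s < 1e-12) stop("degenerate configuration: all points coincident")
    if (scale) m / s else m
  })
  rotate_to <- function(m, target) {
    s <- svd(crossprod(target, m))
    R <- s$v %*% t(s$u)
    if (det(R) < 0) {              # rotation only
      s$v[, 2] <- -s$v[, 2]
      R <- s$v %*% t(s$u)
    }
    m %*% R
  }
  first <- mats[[1]]
  consensus <- first
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, rotate_to, target = consensus)
    new_c <- Reduce(`+`, mats) / length(mats)
    if (scale) new_c <- new_c / sqrt(sum(new_c^2))
    delta <- sqrt(sum((new_c - consensus)^2))
    consensus <- new_c
    if (delta < tol) break
  }
  mats <- lapply(mats, rotate_to, target = consensus)  # final polish
  # canonical global orientation: rotate the whole solution so the
  # consensus best matches the first input configuration; this fixes the
  # rotation GPA leaves free and makes re-alignment of an aligned set a
  # no-op (idempotence)
  s <- svd(crossprod(first, consensus))
  Q <- s$v %*% t(s$u)
  if (det(Q) < 0) {
    s$v[, 2] <- -s$v[, 2]
    Q <- s$v %*% t(s$u)
  }
  mats <- lapply(mats, function(m) m %*% Q)
  consensus <- consensus %*% Q
  structure(list(aligned = mats, mean = consensus, iterations = it),
            class = "gpa_result")
}

# Internal: brute-force Delaunay triangulation (empty circumcircle test),
# suitable for the ~21-point mean shapes used here. Triangles returned with
# vertex indices ascending, rows sorted lexicographically.
delaunay_triangles <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  tris <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next                    # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (pts[others, 1] - ux)^2 + (pts[others, 2] - uy)^2
    if (all(d2 > r2 * (1 - 1e-9)))
      tris[[length(tris) + 1L]] <- c(i, j, k)
  }
  if (length(tris) == 0) stop("degenerate point set: no Delaunay triangle")
  tri <- do.call(rbind, tris)
  tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
}

#' Triangulation of the symmetrized mean shape
#'
#' The consensus is averaged with its left/right mirrored, relabeled copy
#' (midline landmarks self-paired), and the symmetrized mean is Delaunay
#' triangulated. Triangle vertex order is canonicalized (ids ascending).
#'
#' @param mean_shape k x 2 consensus coordinates (rows in landmark-id order).
#' @param pairs integer vector: `pairs[i]` = mirror partner of landmark `i`
#'   (see [face_symmetry_pairs()]).
#' @return list: `triangles` (t x 3 matrix of landmark indices),
#'   `symmetrized` (k x 2 symmetrized mean).
#' @export
symmetrized_mean_triangulation <- function(mean_shape,
                                           pairs = face_symmetry_pairs()) {
  m <- as.matrix(mean_shape)
  stopifnot(nrow(m) == length(pairs))
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  mirrored <- mc
  mirrored[, 1] <- -mirrored[, 1]
  mirrored <- mirrored[pairs, , drop = FALSE]   # relabel to partner ids
  sym <- sweep((mc + mirrored) / 2, 2, ctr, `+`)
  list(triangles = delaunay_triangles(sym), symmetrized = sym)
}

#' Geometric features of aligned configurations
#'
#' Per subject: the aligned coordinates (`c_<id>_<x|y>`), all pairwise
#' distances (`d_<i>_<j>`, i < j), and per triangle the area
#' (`ar_<i>_<j>_<k>`) and the three interior angles
#' (`an_<i>_<j>_<k>_<a|b|c>`, a/b/c = angle at the first/second/third
#' listed landmark).
#'
#' @param aligned list of k x 2 aligned configurations (or a `gpa_result`).
#' @param triangles t x 3 triangle matrix (landmark indices), e.g. from
#'   [symmetrized_mean_triangulation()].
#' @param landmark_ids landmark ids labelling the rows (default 1..k).
#' @return data.frame, one row per subject, one column per feature.
#' @export
extract_features <- function(aligned, triangles,
                             landmark_ids = NULL) {
  if (inherits(aligned, "gpa_result")) aligned <- aligned$aligned
  k <- nrow(aligned[[1]])
  ids <- if (is.null(landmark_ids)) seq_len(k) else landmark_ids
  pair_idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  coord_names <- paste0("c_", rep(ids, each = 2), "_", c("x", "y"))
  dist_names <- paste0("d_", ids[pair_idx[, 1]], "_", ids[pair_idx[, 2]])
  tri_names <- as.vector(apply(triangles, 1, function(t3) {
    nm <- paste(ids[t3], collapse = "_")
    c(paste0("ar_", nm), paste0("an_", nm, "_", c("a", "b", "c")))
  }))
  feats <- lapply(aligned, function(m) {
    co <- as.vector(t(m))
    dv <- sqrt((m[pair_idx[, 1], 1] - m[pair_idx[, 2], 1])^2 +
                 (m[pair_idx[, 1], 2] - m[pair_idx[, 2], 2])^2)
    tf <- as.vector(apply(triangles, 1, function(t3) {
      p <- m[t3, , drop = FALSE]
      ar <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                  (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
      ang <- vapply(1:3, function(v) {
        o <- p[v, ]; a <- p[if (v == 3) 1 else v + 1, ]
        b <- p[if (v == 1) 3 else v - 1, ]
        u <- a - o; w <- b - o
        acos(clamp(sum(u * w) / sqrt(sum(u^2) * sum(w^2)), -1, 1))
      }, numeric(1))
      c(ar, ang)
    }))
    setNames(c(co, dv, tf), c(coord_names, dist_names, tri_names))
  })
  as.data.frame(do.call(rbind, feats))
}

#' Narrow-sense heritability from paired SD components
#'
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`, the additive-genetic share
#' of trait variance. Vectorized.
#'
#' @param sigma_e residual SD(s), >= 0.
#' @param sigma_g genetic SD(s), >= 0.
#' @return h2 value(s) in \[0, 1\].
#' @export
h2_from_sds <- function(sigma_e, sigma_g) {
  if (any(sigma_e < 0) || any(sigma_g < 0)) stop("SDs must be >= 0")
  if (any(sigma_e == 0 & sigma_g == 0)) stop("sigma_e and sigma_g both zero")
  sigma_g^2 / (sigma_g^2 + sigma_e^2)
}

#' Fit the additive twin mixed model to one trait
#'
#' Model: `y = beta0 + beta_age * age + g + e`, with within-pair covariance
#' of `g` equal to `sigma_g^2` for MZ and `0.5 sigma_g^2` for DZ pairs
#' (additive kinship), independent residuals. Fixed effects are profiled by
#' generalized least squares; `(sigma_g, sigma_e)` maximize the REML
#' likelihood over the 2 x 2 pair blocks by bounded quasi-Newton search on
#' the log-variance scale.
#'
#' @param values numeric trait vector (one per individual, in dataset
#'   order), or a column name of `dataset`.
#' @param dataset a `twin_dataset` (see [generate_twin_cohort()]).
#' @param feature optional feature name recorded in the output.
#' @return list of class `heritability_estimate`: `feature`, `beta0`,
#'   `beta_age`, `sigma_e`, `sigma_g`, `h2`, `converged`, `logLik` (REML).
#' @export
fit_twin_model <- function(values, dataset, feature = NA_character_) {
  if (is.character(values) && length(values) == 1) {
    feature <- values
    values <- dataset[[values]]
  }
  stopifnot(length(values) == nrow(dataset))
  pairs <- split(seq_len(nrow(dataset)), dataset$pair_id)
  if (length(pairs) < 10) stop("need at least 10 pairs")
  y <- values
  X <- cbind(1, dataset$age)
  rho <- ifelse(dataset$zygosity == "MZ", 1, 0.5)
  p2 <- pairs[lengths(pairs) == 2]
  p1 <- unlist(pairs[lengths(pairs) == 1])
  i1 <- vapply(p2, `[`, integer(1), 1)
  i2 <- vapply(p2, `[`, integer(1), 2)
  rho2 <- rho[i1]
  tot_var <- stats::var(y)

  # REML log-likelihood with GLS-profiled fixed effects
  reml <- function(par) {
    sg2 <- exp(par[1]); se2 <- exp(par[2])
    v <- sg2 + se2
    cv <- rho2 * sg2
    det2 <- v^2 - cv^2
    if (any(det2 <= 0)) return(-1e10)
    # accumulate X'V^-1X, X'V^-1y, y'V^-1y, log|V|
    XtVX <- matrix(0, 2, 2); XtVy <- numeric(2); yVy <- 0; ldet <- 0
    a <- v / det2; b <- -cv / det2          # 2x2 inverse entries
    x1 <- X[i1, , drop = FALSE]; x2 <- X[i2, , drop = FALSE]
    y1 <- y[i1]; y2 <- y[i2]
    XtVX <- t(x1 * a) %*% x1 + t(x2 * a) %*% x2 +
      t(x1 * b) %*% x2 + t(x2 * b) %*% x1
    XtVy <- colSums(x1 * (a * y1 + b * y2)) + colSums(x2 * (a * y2 + b * y1))
    yVy <- sum(y1 * (a * y1 + b * y2)) + sum(y2 * (a * y2 + b * y1))
    ldet <- sum(log(det2))
    if (length(p1) > 0) {
      xs <- X[p1, , drop = FALSE]; ys <- y[p1]
      XtVX <- XtVX + t(xs / v) %*% xs
      XtVy <- XtVy + colSums(xs * ys) / v
      yVy <- yVy + sum(ys^2) / v
      ldet <- ldet + length(p1) * log(v)
    }
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    rss <- yVy - sum(XtVy * beta)
    -0.5 * (ldet + 2 * sum(log(diag(ch))) + rss)
  }
  init <- log(pmax(c(0.4, 0.6) * tot_var, 1e-8))
  opt <- stats::optim(init, function(p) -reml(p), method = "L-BFGS-B",
                      lower = log(tot_var) - 25, upper = log(tot_var) + 5)
  sg2 <- exp(opt$par[1]); se2 <- exp(opt$par[2])
  # recover GLS betas at the optimum
  beta <- {
    v <- sg2 + se2; cv <- rho2 * sg2; det2 <- v^2 - cv^2
    a <- v / det2; b <- -cv / det2
    x1 <- X[i1, , drop = FALSE]; x2 <- X[i2, , drop = FALSE]
    XtVX <- t(x1 * a) %*% x1 + t(x2 * a) %*% x2 +
      t(x1 * b) %*% x2 + t(x2 * b) %*% x1
    XtVy <- colSums(x1 * (a * y[i1] + b * y[i2])) +
      colSums(x2 * (a * y[i2] + b * y[i1]))
    if (length(p1) > 0) {
      xs <- X[p1, , drop = FALSE]
      XtVX <- XtVX + t(xs / v) %*% xs
      XtVy <- XtVy + colSums(xs * y[p1]) / v
    }
    solve(XtVX, XtVy)
  }
  structure(list(feature = feature, beta0 = beta[1], beta_age = beta[2],
                 sigma_e = sqrt(se2), sigma_g = sqrt(sg2),
                 h2 = sg2 / (sg2 + se2), converged = opt$convergence == 0,
                 logLik = -opt$value),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("<h2 = %.3f (sigma_g %.3g, sigma_e %.3g)%s%s>\n", x$h2,
              x$sigma_g, x$sigma_e,
              if (is.na(x$feature)) "" else paste0(" for ", x$feature),
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Heritability table over a feature set
#'
#' Fits [fit_twin_model()] to every feature column and returns a table with
#' the fixed effects, SD components and h2 per feature.
#'
#' @param features data.frame of per-individual feature values (rows in
#'   `dataset` order).
#' @param dataset a `twin_dataset`.
#' @return data.frame: `feature`, `beta0`, `beta_age`, `sigma_e`, `sigma_g`,
#'   `h2`, `converged`.
#' @export
heritability_table <- function(features, dataset) {
  rows <- lapply(names(features), function(fn) {
    est <- fit_twin_model(features[[fn]], dataset, feature = fn)
    data.frame(feature = fn, beta0 = est$beta0, beta_age = est$beta_age,
               sigma_e = est$sigma_e, sigma_g = est$sigma_g, h2 = est$h2,
               converged = est$converged)
  })
  do.call(rbind, rows)
}

#' Importance map of per-feature heritabilities
#'
#' For each pixel `p`, the weighted average `sum(w_i h_i) / sum(w_i)` with
#' `w_i = h_i / (eps + d(p, c_i))`: weights linear in the heritability and
#' in the inverse distance to the feature center. With `rescale = TRUE` the
#' raster is linearly rescaled to `[0, max(h)]` for display.
#'
#' @param centers n x 2 matrix of feature centers (pixel coordinates:
#'   landmark position, distance midpoint, or triangle centroid/vertex).
#' @param h2_values per-feature heritabilities.
#' @param image_size raster side (px).
#' @param eps distance softening (px).
#' @param rescale rescale the raster to `[0, max(h2)]`.
#' @return `image_size x image_size` matrix.
#' @export
importance_map <- function(centers, h2_values, image_size = 200L, eps = 1,
                           rescale = FALSE) {
  centers <- as.matrix(centers)
  if (nrow(centers) == 0) stop("empty feature list")
  stopifnot(nrow(centers) == length(h2_values))
  n <- as.integer(image_size)
  px <- rep(seq_len(n) - 0.5, each = n)
  py <- rep(seq_len(n) - 0.5, times = n)
  num <- numeric(n * n); den <- numeric(n * n)
  for (i in seq_len(nrow(centers))) {
    w <- h2_values[i] / (eps + sqrt((px - centers[i, 1])^2 +
                                      (py - centers[i, 2])^2))
    num <- num + w * h2_values[i]
    den <- den + w
  }
  val <- ifelse(den > 0, num / den, 0)
  m <- matrix(val, n, n)
  if (rescale) {
    rng <- range(m)
    if (diff(rng) > 0)
      m <- (m - rng[1]) / diff(rng) * max(h2_values)
  }
  m
}

#' Centers of geometric features in pixel coordinates
#'
#' Maps feature names (as produced by [extract_features()]) to 2D centers:
#' landmark position for coordinates, segment midpoint for distances,
#' triangle centroid for areas, and the angle's vertex for angles.
#'
#' @param feature_names character vector of feature names.
#' @param shape k x 2 reference coordinates (rows in landmark-id order).
#' @param landmark_ids ids labelling the rows of `shape`.
#' @return data.frame: `feature`, `cx`, `cy`.
#' @export
feature_centers <- function(feature_names, shape,
                            landmark_ids = seq_len(nrow(shape))) {
  shape <- as.matrix(shape)
  pos <- function(id) shape[match(as.integer(id), landmark_ids), ]
  cen <- t(vapply(feature_names, function(fn) {
    p <- strsplit(fn, "_")[[1]]
    switch(p[1],
      c = pos(p[2]),
      d = (pos(p[2]) + pos(p[3])) / 2,
      ar = (pos(p[2]) + pos(p[3]) + pos(p[4])) / 3,
      an = pos(p[1 + match(p[5], c("a", "b", "c"))]),
      stop("unknown feature name: ", fn))
  }, numeric(2)))
  data.frame(feature = feature_names, cx = cen[, 1], cy = cen[, 2])
}
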