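# Discrete curvature on triangle meshes and its projection to the raster.
#
# Per edge (i, j), the normal curvature along the edge is estimated from the
# vertex normals of the attached triangular patches as
#   kappa_e = (n_j - n_i) . (p_j - p_i) / |p_j - p_i|^2
# (finite-difference shape operator along the edge), with vertex normals the
# area-weighted average of incident triangle normals, oriented away from the
# mesh centroid. kappa_e equals the normal curvature k1 cos^2 a + k2 sin^2 a
# in the edge direction; averaged over a patch's edge directions this
# approximates the mean curvature H = (k1 + k2) / 2: exactly 1/r on a
# sphere, 1/(2r) on a cylinder with a balanced edge-direction mix. Within
# each triangle the three edge values are interpolated linearly
# (edge-midpoint / Crouzeix-Raviart basis), then carried to pixels through
# the projection's triangle/barycentric buffers.

# Internal: per-edge curvature estimates.
# Returns list(edges = e x 2 vertex ids, kappa, tri_edges = m x 3 edge ids
# where column i is the edge opposite local vertex i, boundary = logical).
mesh_edge_curvature <- function(mesh) {
  tri <- mesh$triangles
  v <- mesh$vertices
  m <- nrow(tri)
  # area-weighted face normals, oriented away from the centroid
  # (star-shaped meshes); cross product length = 2 * area
  e1 <- v[tri[, 2], ] - v[tri[, 1], ]
  e2 <- v[tri[, 3], ] - v[tri[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cen <- (v[tri[, 1], ] + v[tri[, 2], ] + v[tri[, 3], ]) / 3
  out_dir <- cen - matrix(colMeans(v), m, 3, byrow = TRUE)
  flip <- rowSums(fn * out_dir) < 0
  fn[flip, ] <- -fn[flip, ]
  vn <- matrix(0, nrow(v), 3)
  for (loc in 1:3) for (dim in 1:3) {
    acc <- tapply(fn[, dim], tri[, loc], sum)
    ids <- as.integer(names(acc))
    vn[ids, dim] <- vn[ids, dim] + acc
  }
  vn <- vn / pmax(sqrt(rowSums(vn^2)), 1e-300)

  # edge table: edge i of a triangle is opposite local vertex i
  ea <- rbind(tri[, c(2, 3)], tri[, c(3, 1)], tri[, c(1, 2)])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  eid <- match(key, unique(key))
  n_edges <- max(eid)
  dup <- duplicated(eid)
  boundary <- rep(TRUE, n_edges)
  boundary[eid[dup]] <- FALSE
  ev <- ea[!duplicated(eid), , drop = FALSE][order(eid[!duplicated(eid)]), , drop = FALSE]

  dp <- v[ev[, 2], , drop = FALSE] - v[ev[, 1], , drop = FALSE]
  dn <- vn[ev[, 2], , drop = FALSE] - vn[ev[, 1], , drop = FALSE]
  kappa <- rowSums(dn * dp) / pmax(rowSums(dp^2), 1e-300)

  list(edges_kappa = kappa, tri_edges = matrix(eid, m, 3),
       n_boundary = sum(boundary))
}

#' Fill the curvature raster of a projected face
#'
#' Estimates per-edge mean curvature on the 3D mesh (see source notes),
#' interpolates it linearly inside each triangle from the three edge values,
#' and transfers it to the raster through the projection's per-pixel
#' triangle/barycentric correspondence (the same one-to-one map as texture
#' and heightmap). Units: 1/mm.
#'
#' @param mesh the [surface_mesh()] that was projected.
#' @param face the `projected_face` from [project_mercator()].
#' @return `face` with `$curvature` filled (hole pixels inpainted as for the
#'   other maps) and `$n_boundary_edges` recorded.
#' @export
compute_curvature <- function(mesh, face) {
  stopifnot(inherits(face, "projected_face"))
  ec <- mesh_edge_curvature(mesh)
  n <- face$image_size
  tri_id <- face$tri_id
  good <- !is.na(tri_id)
  k1 <- ec$edges_kappa[ec$tri_edges[tri_id[good], 1]]
  k2 <- ec$edges_kappa[ec$tri_edges[tri_id[good], 2]]
  k3 <- ec$edges_kappa[ec$tri_edges[tri_id[good], 3]]
  b1 <- face$bary[, , 1][good]; b2 <- face$bary[, , 2][good]
  b3 <- face$bary[, , 3][good]
  # edge-midpoint linear interpolation: value kappa_i at midpoint of the
  # edge opposite vertex i
  crv <- matrix(NA_real_, n, n)
  crv[good] <- k1 * (1 - 2 * b1) + k2 * (1 - 2 * b2) + k3 * (1 - 2 * b3)
  if (any(!good) && any(good))
    crv <- inpaint_nn(list(crv), !good)[[1]]
  face$curvature <- crv
  face$n_boundary_edges <- ec$n_boundary
  face
}
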