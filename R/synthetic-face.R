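#' Standard 21-landmark facial template
#'
#' The package's landmark scheme: 21 named points covering brows/eyes,
#' forehead, nose, mouth and chin, with ids 1-21. Midline landmarks are
#' self-paired under left/right symmetry.
#'
#' @return data.frame with columns `landmark_id`, `name`, `lon`, `lat`
#'   (template position in face-ellipsoid longitude/latitude, radians;
#'   positive longitude = subject's left) and `mirror_id` (id of the
#'   left/right symmetric partner; equals `landmark_id` on the midline).
#' @export
face_template_landmarks <- function() {
  df <- data.frame(
    landmark_id = 1:21,
    name = c("exocanthion_r", "endocanthion_r", "endocanthion_l",
             "exocanthion_l", "glabella", "forehead", "pronasale", "nasion",
             "subnasale", "nose_side_r", "nose_side_l", "nose_outer_r",
             "nose_corner_r", "columella", "nose_corner_l", "nose_outer_l",
             "mouth_corner_r", "mouth_corner_l", "labiale_superius",
             "labiale_inferius", "pogonion"),
    lon = c(-0.40, -0.16, 0.16, 0.40, 0, 0, 0, 0, 0,
            -0.10, 0.10, -0.13, -0.10, 0, 0.10, 0.13,
            -0.24, 0.24, 0, 0, 0),
    lat = c(0.10, 0.10, 0.10, 0.10, 0.28, 0.50, -0.12, 0.12, -0.26,
            -0.10, -0.10, -0.20, -0.25, -0.19, -0.25, -0.20,
            -0.42, -0.42, -0.37, -0.48, -0.62),
    mirror_id = c(4L, 3L, 2L, 1L, 5L, 6L, 7L, 8L, 9L,
                  11L, 10L, 16L, 15L, 14L, 13L, 12L,
                  18L, 17L, 19L, 20L, 21L))
  df
}

#' Left/right landmark symmetry pairing
#'
#' @return integer vector `m` of length 21 with `m[i]` the mirror partner of
#'   landmark `i` (`m[i] == i` on the midline).
#' @export
face_symmetry_pairs <- function() face_template_landmarks()$mirror_id

#' Default landmark sub-graphs for the PC-guided search
#'
#' Five anatomy-based groups of 4-6 landmarks each, fitted in order; groups
#' declare which of their landmarks overlap earlier-fitted groups.
#'
#' @return list of class `subgraph_spec`; each element has `ids` (landmark
#'   ids) and `overlap` (ids shared with earlier groups).
#' @export
face_subgraphs <- function() {
  groups <- list(
    eye_right  = c(1L, 2L, 5L, 6L),
    eye_left   = c(3L, 4L, 5L, 6L),
    nose_upper = c(7L, 8L, 10L, 11L, 14L),
    nose_lower = c(7L, 9L, 12L, 13L, 15L, 16L),
    mouth_chin = c(9L, 17L, 18L, 19L, 20L, 21L))
  seen <- integer(0)
  spec <- lapply(groups, function(ids) {
    ov <- intersect(ids, seen)
    seen <<- union(seen, ids)
    list(ids = ids, overlap = ov)
  })
  # recompute 'seen' sequentially (lapply + <<- already did)
  structure(spec, class = "subgraph_spec")
}

# Relief bumps defining facial structure on the base ellipsoid.
# Columns: lon/lat center (rad), sd_lon/sd_lat (rad), amplitude (mm).
face_relief_bumps <- function() {
  rbind(
    c(0.00, -0.05, 0.10, 0.22, 14),   # nose ridge
    c(0.00, -0.12, 0.09, 0.07,  6),   # nose tip
    c(-0.28, 0.24, 0.13, 0.05,  4),   # brow ridge right
    c(0.28,  0.24, 0.13, 0.05,  4),   # brow ridge left
    c(-0.45, -0.05, 0.14, 0.12, 5),   # cheekbone right
    c(0.45, -0.05, 0.14, 0.12,  5),   # cheekbone left
    c(0.00, -0.42, 0.28, 0.06,  3.5), # lips
    c(0.00, -0.62, 0.14, 0.10,  5),   # chin boss
    c(-0.28, 0.10, 0.10, 0.06, -4),   # eye socket right
    c(0.28,  0.10, 0.10, 0.06, -4))   # eye socket left
}

# Sum of anisotropic Gaussian bumps, evaluated at (lon, lat) vectors -> mm
relief_height <- function(lon, lat, bumps = face_relief_bumps()) {
  h <- numeric(length(lon))
  for (i in seq_len(nrow(bumps))) {
    b <- bumps[i, ]
    h <- h + b[5] * exp(-0.5 * ((lon - b[1]) / b[3])^2 -
                         0.5 * ((lat - b[2]) / b[4])^2)
  }
  h
}

# Grayscale texture of the template face at (lon, lat), before noise.
# Smooth shading of the relief plus dark patches at eyes, brows, mouth and
# nostrils so texture channels carry signal independent of the heightmap.
face_texture <- function(lon, lat, height) {
  dark <- function(cl, cm, sl, sm, a)
    a * exp(-0.5 * ((lon - cl) / sl)^2 - 0.5 * ((lat - cm) / sm)^2)
  t <- 0.75 + 0.015 * height
  t <- t + dark(-0.28, 0.10, 0.09, 0.045, -0.45) + dark(0.28, 0.10, 0.09, 0.045, -0.45)
  t <- t + dark(-0.28, 0.245, 0.12, 0.025, -0.25) + dark(0.28, 0.245, 0.12, 0.025, -0.25)
  t <- t + dark(0, -0.42, 0.26, 0.045, -0.35)
  t <- t + dark(-0.10, -0.24, 0.035, 0.025, -0.3) + dark(0.10, -0.24, 0.035, 0.025, -0.3)
  clamp(t, 0, 1)
}

# Low-rank deformation basis: per mode a smooth 3D displacement field over
# (lon, lat), returned as an n x 3 matrix for unit score. Landmark and vertex
# positions are affine in the mode scores by construction. The default six
# modes mix symmetric global stretches, a nose-prominence mode, and
# asymmetric/local modes so that every landmark coordinate carries genuine
# population variance (as in real cohorts).
mode_field <- function(mode, lon, lat, radial_dir) {
  n <- length(lon)
  blob <- function(cl, cm, s) exp(-(((lon - cl)^2 + (lat - cm)^2) / (2 * s^2)))
  switch(as.character(mode),
    "1" = cbind(sin(lon) / sin(1), numeric(n), numeric(n)),          # width
    "2" = cbind(numeric(n), sin(lat) / sin(1), numeric(n)),          # height
    "3" = radial_dir * blob(0, -0.15, 0.18),                         # nose out
    "4" = cbind(blob(0, -0.2, 0.35), numeric(n), numeric(n)),        # midface lateral shift
    "5" = cbind(sin(lon) / sin(1) * exp(-0.5 * ((lat + 0.42) / 0.18)^2),
                numeric(n), numeric(n)),                             # mouth width
    "6" = cbind(numeric(n), blob(0, -0.1, 0.30), numeric(n)),        # midface vertical shift
    { # further modes: localized radial blobs at cycling centers
      ctr <- rbind(c(-0.3, -0.3), c(0.3, -0.3), c(0, 0.35), c(-0.3, 0.2),
                   c(0.3, 0.2), c(0, -0.55))
      k <- ((mode - 7) %% nrow(ctr)) + 1
      radial_dir * blob(ctr[k, 1], ctr[k, 2], 0.15)
    })
}

#' Synthetic face generator specification
#'
#' Defines the population of face-like meshes used for testing and
#' benchmarking: an ellipsoid base with fixed Gaussian relief (nose, brows,
#' lips, chin, eye sockets), low-rank shape variation, and a deterministic
#' texture with additive noise.
#'
#' @param seed integer RNG seed; all generator output is deterministic in it.
#' @param n_landmarks number of landmarks (only the standard 21 supported).
#' @param shape_modes number of low-rank deformation modes.
#' @param mode_sds per-mode score SD in mm (recycled to `shape_modes`).
#' @param pixel_noise_sd SD of additive per-vertex texture noise
#'   (intensity units, texture range is \[0, 1\]).
#' @param image_size projected raster side in pixels.
#' @param semi_axes base ellipsoid semi-axes (mm), x lateral / y vertical /
#'   z anterior.
#' @param grid_n vertices per parametric direction of the mesh grid.
#' @return list of class `face_spec`.
#' @export
face_spec <- function(seed = 1L, n_landmarks = 21L, shape_modes = 6L,
                      mode_sds = c(2, 1.5, 1.2, 1, 0.8, 0.8),
                      pixel_noise_sd = 0.02,
                      image_size = 200L, semi_axes = c(90, 115, 95),
                      grid_n = 96L) {
  stopifnot(n_landmarks >= 4, all(mode_sds >= 0), shape_modes >= 0,
            pixel_noise_sd >= 0, image_size >= 16, grid_n >= 8)
  if (n_landmarks != 21L)
    stop("only the standard 21-landmark template is supported")
  structure(list(seed = as.integer(seed), n_landmarks = 21L,
                 shape_modes = as.integer(shape_modes),
                 mode_sds = rep_len(mode_sds, shape_modes),
                 pixel_noise_sd = pixel_noise_sd,
                 image_size = as.integer(image_size),
                 semi_axes = semi_axes, grid_n = as.integer(grid_n),
                 lon_range = c(-0.95, 0.95), lat_range = c(-0.85, 0.75)),
            class = "face_spec")
}

# Evaluate the synthetic surface at (lon, lat) given mode scores:
# ellipsoid point + relief along the radial direction + score-weighted
# deformation fields. Returns list(points = n x 3, color = n).
synth_surface_at <- function(spec, lon, lat, scores) {
  u <- cbind(cos(lat) * sin(lon), sin(lat), cos(lat) * cos(lon))
  pe <- sweep(u, 2, spec$semi_axes, `*`)      # point on base ellipsoid
  rdir <- pe / sqrt(rowSums(pe^2))
  h <- relief_height(lon, lat)
  p <- pe + h * rdir
  if (spec$shape_modes > 0) {
    for (m in seq_len(spec$shape_modes)) {
      if (scores[m] != 0)
        p <- p + scores[m] * mode_field(m, lon, lat, rdir)
    }
  }
  list(points = p, color = face_texture(lon, lat, h), height = h)
}

#' Generate one synthetic face
#'
#' Builds the template mesh deformed by the given mode scores, together with
#' ground-truth 3D landmark positions. Output is a deterministic function of
#' `(spec, scores, noise_id)`.
#'
#' @param spec a [face_spec()].
#' @param scores numeric vector of mode scores (mm), length `spec$shape_modes`.
#' @param noise_id integer stream id for the per-vertex texture noise
#'   (subjects in a population get distinct ids).
#' @return list with elements `mesh` ([surface_mesh()]) and
#'   `landmarks` ([landmarks3d()]).
#' @export
generate_face <- function(spec, scores = numeric(spec$shape_modes),
                          noise_id = 0L) {
  stopifnot(inherits(spec, "face_spec"))
  if (length(scores) != spec$shape_modes || any(!is.finite(scores)))
    stop("scores must be ", spec$shape_modes, " finite numbers")
  n <- spec$grid_n
  lon <- seq(spec$lon_range[1], spec$lon_range[2], length.out = n)
  lat <- seq(spec$lat_range[1], spec$lat_range[2], length.out = n)
  g <- expand.grid(lon = lon, lat = lat)       # lon fastest
  s <- synth_surface_at(spec, g$lon, g$lat, scores)
  col <- s$color
  if (spec$pixel_noise_sd > 0) {
    noise <- with_seed(spec$seed * 1000003 + noise_id,
                       rnorm(nrow(g), 0, spec$pixel_noise_sd))
    col <- clamp(col + noise, 0, 1)
  }
  # grid triangulation: cell (i, j) -> two triangles, with diagonals giving
  # a mix of edge directions (important for curvature estimates)
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(1:(n - 1L), n - 1L)
  j <- rep(1:(n - 1L), each = n - 1L)
  tri <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  mesh <- surface_mesh(s$points, tri, col)
  tl <- face_template_landmarks()
  lm <- synth_surface_at(spec, tl$lon, tl$lat, scores)
  list(mesh = mesh, landmarks = landmarks3d(tl$landmark_id, lm$points, tl$name))
}

#' Generate a population of synthetic faces
#'
#' Mode scores are drawn independently per subject from zero-mean normals
#' with SDs `spec$mode_sds`; texture noise gets a distinct stream per subject.
#'
#' @param spec a [face_spec()].
#' @param n number of subjects (>= 1).
#' @return list of length `n`; each element as returned by [generate_face()],
#'   plus `scores` (the drawn mode scores) and `subject_id`.
#' @export
generate_population <- function(spec, n) {
  stopifnot(inherits(spec, "face_spec"), n >= 1)
  score_mat <- with_seed(spec$seed,
    matrix(rnorm(n * spec$shape_modes, 0, rep(spec$mode_sds, each = n)),
           nrow = n))
  lapply(seq_len(n), function(i) {
    f <- generate_face(spec, score_mat[i, ], noise_id = i)
    f$scores <- score_mat[i, ]
    f$subject_id <- sprintf("s%03d", i)
    f
  })
}
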