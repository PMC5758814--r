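#' Triangle surface mesh
#'
#' Lightweight container for a triangulated surface with optional per-vertex
#' grayscale color. Coordinates are in mm.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param color optional numeric vector of length n in \[0, 1\] (grayscale).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, color = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            all(is.finite(vertices)),
            min(triangles) >= 1L, max(triangles) <= nrow(vertices))
  if (!is.null(color)) {
    stopifnot(length(color) == nrow(vertices))
    color <- as.numeric(color)
  }
  structure(list(vertices = vertices, triangles = triangles, color = color),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d triangles%s>\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$color)) "" else ", per-vertex color"))
  invisible(x)
}

#' Named 3D landmark set
#'
#' @param ids integer landmark ids (1..21 in the standard face template).
#' @param xyz numeric length(ids) x 3 matrix of positions in mm.
#' @param names optional character landmark names.
#' @return data.frame of class `landmarks3d` with columns
#'   `landmark_id`, `name`, `x`, `y`, `z`.
#' @export
landmarks3d <- function(ids, xyz, names = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(length(ids) == nrow(xyz), ncol(xyz) == 3)
  df <- data.frame(landmark_id = as.integer(ids),
                   name = if (is.null(names)) paste0("lm", ids) else names,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  class(df) <- c("landmarks3d", "data.frame")
  df
}

#' Named 2D (pixel) landmark set
#'
#' Pixel coordinates are 0-based, x rightward, y downward; the center of
#' pixel `(i, j)` is at continuous coordinate `(i + 0.5, j + 0.5)`.
#'
#' @param ids integer landmark ids.
#' @param xy numeric matrix of pixel coordinates.
#' @param names optional character names.
#' @param ok logical per-landmark validity flag (FALSE when e.g. outside ROI).
#' @return data.frame of class `landmarks2d`.
#' @export
landmarks2d <- function(ids, xy, names = NULL, ok = TRUE) {
  xy <- as.matrix(xy)
  stopifnot(length(ids) == nrow(xy), ncol(xy) == 2)
  df <- data.frame(landmark_id = as.integer(ids),
                   name = if (is.null(names)) paste0("lm", ids) else names,
                   x = xy[, 1], y = xy[, 2],
                   ok = rep_len(ok, length(ids)))
  class(df) <- c("landmarks2d", "data.frame")
  df
}

# Internal: n x 2 / n x 3 coordinate matrix from a landmark set, ordered by id
lm_coords <- function(lms) {
  lms <- lms[order(lms$landmark_id), , drop = FALSE]
  cols <- intersect(c("x", "y", "z"), names(lms))
  as.matrix(lms[, cols, drop = FALSE])
}

#' Write / read a mesh as Wavefront OBJ
#'
#' Vertices are written as `v x y z [gray gray gray]` (per-vertex color as an
#' RGB triplet, a widely understood OBJ extension) and faces as `f i j k`.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `write_obj` returns `path` invisibly; `read_obj` a `surface_mesh`.
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices
  vlines <- if (is.null(mesh$color)) {
    sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3])
  } else {
    sprintf("v %.6f %.6f %.6f %.6f %.6f %.6f",
            v[, 1], v[, 2], v[, 3], mesh$color, mesh$color, mesh$color)
  }
  f <- mesh$triangles
  flines <- sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(vlines, flines), path)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0 || length(fl) == 0) stop("not a triangle-mesh OBJ: ", path)
  vparts <- strsplit(trimws(sub("^v ", "", vl)), "[ \t]+")
  nv <- lengths(vparts)
  vm <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  color <- if (all(nv >= 6)) vapply(vparts, function(p) as.numeric(p[4]), numeric(1)) else NULL
  fparts <- strsplit(trimws(sub("^f ", "", fl)), "[ \t]+")
  fm <- t(vapply(fparts, function(p) as.integer(sub("/.*", "", p[1:3])), integer(3)))
  surface_mesh(vm, fm, color)
}

#' Write / read landmark tables as TSV
#'
#' 3D tables have columns `subject_id, landmark_id, x, y, z` (mm); 2D tables
#' `subject_id, landmark_id, x, y` (pixels, 0-based).
#'
#' @param lms a `landmarks3d` / `landmarks2d` object, or a named list of them
#'   (names become `subject_id`).
#' @param path file path.
#' @param subject_id subject identifier used when `lms` is a single set.
#' @return `write_landmarks` returns `path` invisibly. `read_landmarks`
#'   returns a named list of landmark sets.
#' @export
write_landmarks <- function(lms, path, subject_id = "s1") {
  if (inherits(lms, "data.frame")) lms <- setNames(list(lms), subject_id)
  rows <- do.call(rbind, lapply(names(lms), function(id) {
    x <- as.data.frame(lms[[id]])
    cols <- intersect(c("landmark_id", "x", "y", "z"), names(x))
    cbind(subject_id = id, x[, cols, drop = FALSE])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "landmark_id", "x", "y") %in% names(df)))
  is3d <- "z" %in% names(df)
  out <- lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$landmark_id), ]
    if (is3d) landmarks3d(d$landmark_id, as.matrix(d[, c("x", "y", "z")]))
    else landmarks2d(d$landmark_id, as.matrix(d[, c("x", "y")]))
  })
  out[unique(df$subject_id)]
}
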