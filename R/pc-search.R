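# PC-guided global landmark search (base landmarker 18).
#
# Per sub-graph (4-6 correlated landmarks), PCA of the stacked training
# coordinates gives a low-dimensional configuration space; a grid search
# over the first two PC scores looks for the maximal combined bunch-graph
# similarity summed over the group's landmarks and all 15 channels, with
# candidate configurations restricted to each landmark's mean +/- 1 SD
# training rectangle and a distance penalty tying landmarks shared with
# previously fitted groups to their earlier fit.

#' Fit the per-sub-graph PC model
#'
#' @param landmarks list of training [landmarks2d()] (same subjects as the
#'   bunch graph).
#' @param subgraphs a [face_subgraphs()]-style specification.
#' @return list of class `pc_model`; per group: `ids`, `overlap`, `mean`
#'   (2k vector, x/y interleaved per landmark), `loadings` (2k x 2,
#'   orthonormal), `score_sd` (2), `lm_sd` (k x 2 per-landmark coordinate
#'   SDs), `degenerate` flag.
#' @export
fit_pc_model <- function(landmarks, subgraphs = face_subgraphs()) {
  if (length(landmarks) < 2) stop("need at least 2 training subjects")
  coords <- lapply(landmarks, lm_coords)
  ids_all <- sort(landmarks[[1]]$landmark_id)
  groups <- lapply(subgraphs, function(g) {
    idx <- match(g$ids, ids_all)
    X <- t(vapply(coords, function(cm) as.vector(t(cm[idx, , drop = FALSE])),
                  numeric(2 * length(idx))))       # rows: subjects; x1 y1 x2 y2 ...
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    tot_var <- sum(Xc^2)
    lm_sd <- matrix(apply(X, 2, stats::sd), ncol = 2, byrow = TRUE)
    if (tot_var < 1e-12) {
      return(list(ids = g$ids, overlap = g$overlap, mean = mu,
                  loadings = NULL, score_sd = c(0, 0), lm_sd = lm_sd,
                  degenerate = TRUE))
    }
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    nc <- min(2L, ncol(pc$rotation))
    V <- pc$rotation[, seq_len(nc), drop = FALSE]
    if (nc < 2) {
      # complete to an orthonormal pair; the second score SD is 0 so the
      # search never actually moves along the completed direction
      comp <- qr.Q(qr(cbind(V, diag(nrow(V))[, 1:2])))[, 2, drop = FALSE]
      V <- cbind(V, comp)
    }
    sdev2 <- ifelse(pc$sdev > 1e-10, pc$sdev, 0)
    list(ids = g$ids, overlap = g$overlap, mean = mu, loadings = V,
         score_sd = c(sdev2[1], if (length(sdev2) > 1) sdev2[2] else 0),
         lm_sd = lm_sd, degenerate = FALSE)
  })
  structure(groups, class = "pc_model")
}

#' Reconstruct a group configuration from PC scores
#'
#' Linear reconstruction `mean + s1 * v1 + s2 * v2`.
#'
#' @param model a [fit_pc_model()] result.
#' @param group group index or name.
#' @param s1,s2 scores on the first two PCs.
#' @return k x 2 matrix of (x, y) coordinates, rows in group id order.
#' @export
reconstruct <- function(model, group, s1, s2) {
  g <- model[[group]]
  if (g$degenerate) stop("degenerate group: loadings undefined")
  v <- g$mean + g$loadings[, 1] * s1 + g$loadings[, 2] * s2
  matrix(v, ncol = 2, byrow = TRUE,
         dimnames = list(g$ids, c("x", "y")))
}

#' Grid search over the first two PC scores of one sub-graph
#'
#' Evaluates, over an `r x r` grid of score pairs spanning
#' `+/- score_range_sd` PC-score SDs, the objective
#' `sum over group landmarks, channels of bunch similarity at the
#' reconstructed pixel - lambda * sum over overlap landmarks of the pixel
#' distance to the prior fit`. Only configurations with every landmark
#' inside its mean +/- 1 SD training rectangle (and inside the image) are
#' admissible. Ties: smaller `|(s1, s2)|`, then lexicographic. If no grid
#' point is admissible, falls back to `(0, 0)` with a warning.
#'
#' @param stack test subject's feature stack.
#' @param graph the [train_bunch_graph()] result.
#' @param model a [fit_pc_model()] result.
#' @param group group index or name.
#' @param prior_fits data.frame (`landmark_id`, `x`, `y`) of already-fitted
#'   landmarks, or NULL.
#' @param maps optional precomputed [gabor_responses()].
#' @param grid_r grid resolution per PC.
#' @param score_range_sd half-range of the grid in PC-score SDs.
#' @param lambda overlap penalty weight per pixel of distance.
#' @param subset optional training-subject subset (bagging).
#' @return list: `coords` (k x 2), `s` (chosen scores), `objective`,
#'   `admissible` (count of admissible grid points).
#' @export
pc_grid_search <- function(stack, graph, model, group, prior_fits = NULL,
                           maps = NULL, grid_r = 21, score_range_sd = 2,
                           lambda = 0.01, subset = NULL) {
  g <- model[[group]]
  n <- nrow(stack$channels[[1]])
  if (g$degenerate)
    return(list(coords = matrix(g$mean, ncol = 2, byrow = TRUE,
                                dimnames = list(g$ids, c("x", "y"))),
                s = c(0, 0), objective = NA_real_, admissible = 0L))
  if (is.null(maps)) maps <- gabor_responses(stack, graph$bank)
  s1g <- seq(-score_range_sd * g$score_sd[1], score_range_sd * g$score_sd[1],
             length.out = grid_r)
  s2g <- if (g$score_sd[2] > 0)
    seq(-score_range_sd * g$score_sd[2], score_range_sd * g$score_sd[2],
        length.out = grid_r) else 0
  gr <- expand.grid(s1 = s1g, s2 = s2g)
  k <- length(g$ids)
  # reconstructed coordinates for all grid points: n_grid x k per axis
  rx <- outer(gr$s1, g$loadings[seq(1, 2 * k, 2), 1]) +
    outer(gr$s2, g$loadings[seq(1, 2 * k, 2), 2])
  rx <- sweep(rx, 2, g$mean[seq(1, 2 * k, 2)], `+`)
  ry <- outer(gr$s1, g$loadings[seq(2, 2 * k, 2), 1]) +
    outer(gr$s2, g$loadings[seq(2, 2 * k, 2), 2])
  ry <- sweep(ry, 2, g$mean[seq(2, 2 * k, 2)], `+`)
  mx <- g$mean[seq(1, 2 * k, 2)]; my <- g$mean[seq(2, 2 * k, 2)]
  adm <- rep(TRUE, nrow(gr))
  for (j in seq_len(k)) {
    adm <- adm &
      abs(rx[, j] - mx[j]) <= g$lm_sd[j, 1] + 1e-9 &
      abs(ry[, j] - my[j]) <= g$lm_sd[j, 2] + 1e-9 &
      rx[, j] >= 0 & rx[, j] < n & ry[, j] >= 0 & ry[, j] < n
  }
  if (!any(adm)) {
    warning("no admissible grid point for group; falling back to (0, 0)")
    return(list(coords = matrix(g$mean, ncol = 2, byrow = TRUE,
                                dimnames = list(g$ids, c("x", "y"))),
                s = c(0, 0), objective = NA_real_, admissible = 0L))
  }
  ga <- which(adm)
  obj <- numeric(length(ga))
  for (j in seq_len(k)) {
    ix <- clamp(as.integer(round(rx[ga, j] - 0.5)), 0L, n - 1L)
    iy <- clamp(as.integer(round(ry[ga, j] - 0.5)), 0L, n - 1L)
    rows <- jm_rows(maps, iy + 1L + ix * n)
    li <- match(g$ids[j], graph$landmark_ids)
    for (ch in graph$channel_names) {
      train <- Mod(graph$jets[[ch]][[li]])
      if (!is.null(subset)) train <- train[subset, , drop = FALSE]
      W <- maps$mag[[ch]][rows, , drop = FALSE]
      obj <- obj + bunch_scores(W, train)
    }
    if (!is.null(prior_fits) && g$ids[j] %in% g$overlap &&
        g$ids[j] %in% prior_fits$landmark_id) {
      pf <- prior_fits[match(g$ids[j], prior_fits$landmark_id), ]
      obj <- obj - lambda * sqrt((rx[ga, j] - pf$x)^2 + (ry[ga, j] - pf$y)^2)
    }
  }
  best <- max(obj)
  cand <- which(obj >= best - 1e-12)
  if (length(cand) > 1) {
    nrm <- gr$s1[ga[cand]]^2 + gr$s2[ga[cand]]^2
    cand <- cand[nrm <= min(nrm) + 1e-12]
    if (length(cand) > 1)
      cand <- cand[order(gr$s1[ga[cand]], gr$s2[ga[cand]])]
  }
  pick <- ga[cand[1]]
  coords <- cbind(x = rx[pick, ], y = ry[pick, ])
  rownames(coords) <- g$ids
  list(coords = coords, s = c(gr$s1[pick], gr$s2[pick]),
       objective = best, admissible = length(ga))
}

#' PC-guided landmarker over all sub-graphs (base landmarker 18)
#'
#' Fits groups in their declared order; later groups see earlier fits
#' through the overlap penalty. Landmarks belonging to several groups take
#' their coordinates from the earliest-fitted group.
#'
#' @inheritParams pc_grid_search
#' @return data.frame with `landmark_id`, `x`, `y` for all 21 landmarks.
#' @export
run_pc_landmarker <- function(stack, graph, model, maps = NULL,
                              grid_r = 21, score_range_sd = 2, lambda = 0.01,
                              subset = NULL) {
  if (is.null(maps)) maps <- gabor_responses(stack, graph$bank)
  prior <- NULL
  for (gi in seq_along(model)) {
    r <- pc_grid_search(stack, graph, model, gi, prior_fits = prior,
                        maps = maps, grid_r = grid_r,
                        score_range_sd = score_range_sd, lambda = lambda,
                        subset = subset)
    new <- data.frame(landmark_id = model[[gi]]$ids,
                      x = r$coords[, 1], y = r$coords[, 2])
    new <- new[!new$landmark_id %in% prior$landmark_id, , drop = FALSE]
    prior <- rbind(prior, new)
  }
  prior[order(prior$landmark_id), ]
}
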