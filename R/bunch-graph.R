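# Bunch-graph training and the template-search base landmarkers.
#
# The bunch graph stores, per landmark and per feature channel, the Gabor
# jets extracted at the manually placed training landmarks of all training
# subjects, plus the population mean position and per-axis coordinate SDs.
# At search time a landmark's score at a pixel is the maximum over the
# training jets ("bunch") of the jet similarity with the test jet there;
# the pixel maximizing the score inside a window around the population mean
# is the prediction.

#' Train a bunch graph
#'
#' @param stacks list of [build_feature_stack()] results (training subjects).
#' @param landmarks list of matching [landmarks2d()] manual annotations.
#' @param bank a [build_gabor_bank()].
#' @return list of class `bunch_graph`: `jets[[channel]][[lm]]` (complex
#'   `n_train x n_kernels` matrices), `agg_jets[[lm]]` (channel-sum jets),
#'   `mean_xy` (21 x 2), `sd_xy` (21 x 2), `train_xy` (`n_train` x 2 x 21),
#'   `channel_names`, `landmark_ids`, `n_train`.
#' @export
train_bunch_graph <- function(stacks, landmarks, bank) {
  n_train <- length(stacks)
  if (n_train < 2) stop("need at least 2 training subjects")
  if (length(landmarks) != n_train) stop("stacks/landmarks length mismatch")
  chn <- names(stacks[[1]]$channels)
  coords <- lapply(landmarks, lm_coords)
  ids <- sort(landmarks[[1]]$landmark_id)
  n_lm <- length(ids)
  for (l in landmarks)
    if (nrow(l) != n_lm || anyNA(lm_coords(l)) || !all(l$ok))
      stop("missing or invalid landmark in a training subject")
  nk <- length(bank$kernels)
  jets <- lapply(chn, function(ch) lapply(seq_len(n_lm), function(i)
    matrix(0 + 0i, n_train, nk)))
  names(jets) <- chn
  for (s in seq_len(n_train)) {
    for (ch in chn) {
      channel <- stacks[[s]]$channels[[ch]]
      for (i in seq_len(n_lm)) {
        jets[[ch]][[i]][s, ] <-
          extract_jet(channel, bank, coords[[s]][i, ])
      }
    }
  }
  agg <- lapply(seq_len(n_lm), function(i)
    Reduce(`+`, lapply(chn, function(ch) jets[[ch]][[i]])))
  xy <- array(unlist(coords), c(n_lm, 2, n_train))
  mean_xy <- apply(xy, c(1, 2), mean)
  sd_xy <- apply(xy, c(1, 2), stats::sd)
  structure(list(jets = jets, agg_jets = agg, mean_xy = mean_xy,
                 sd_xy = sd_xy, train_xy = xy, channel_names = chn,
                 landmark_ids = ids, n_train = n_train, bank = bank),
            class = "bunch_graph")
}

#' @export
print.bunch_graph <- function(x, ...) {
  cat(sprintf("<bunch_graph: %d landmarks x %d channels, %d training jets each>\n",
              length(x$landmark_ids), length(x$channel_names), x$n_train))
  invisible(x)
}

# Internal: search-window pixels around the population mean:
# mean +/- max(min_halfwidth, sd_factor * training SD) per axis, clipped.
# Returns list(ix, iy (0-based pixel vectors), lin (column-major indices))
search_window <- function(graph, lm_index, n, min_halfwidth = 10,
                          sd_factor = 2) {
  mu <- graph$mean_xy[lm_index, ]
  hw <- pmax(min_halfwidth, sd_factor * graph$sd_xy[lm_index, ])
  cx <- as.integer(round(mu[1] - 0.5)); cy <- as.integer(round(mu[2] - 0.5))
  xs <- max(0L, cx - ceiling(hw[1])):min(n - 1L, cx + ceiling(hw[1]))
  ys <- max(0L, cy - ceiling(hw[2])):min(n - 1L, cy + ceiling(hw[2]))
  if (length(xs) == 0 || length(ys) == 0) stop("search window outside image")
  ix <- rep(xs, each = length(ys))
  iy <- rep(ys, times = length(xs))
  list(ix = ix, iy = iy, lin = iy + 1L + ix * n, mu = mu,
       nx = length(xs), ny = length(ys))
}

# Internal: union of all landmarks' search-window pixels (padded), the
# pixel set a full base-landmarker pass will visit. Used to restrict
# gabor_responses() to the pixels that matter.
needed_pixels <- function(graph, n, min_halfwidth = 10, sd_factor = 2,
                          pad = 2L) {
  lin <- integer(0)
  for (i in seq_along(graph$landmark_ids)) {
    mu <- graph$mean_xy[i, ]
    hw <- pmax(min_halfwidth, sd_factor * graph$sd_xy[i, ]) + pad
    cx <- as.integer(round(mu[1] - 0.5)); cy <- as.integer(round(mu[2] - 0.5))
    xs <- max(0L, cx - ceiling(hw[1])):min(n - 1L, cx + ceiling(hw[1]))
    ys <- max(0L, cy - ceiling(hw[2])):min(n - 1L, cy + ceiling(hw[2]))
    lin <- c(lin, as.vector(outer(ys + 1L, xs * n, `+`)))
  }
  sort(unique(lin))
}

# Internal: row-normalize a magnitude matrix (zero rows stay zero)
row_unit <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / ifelse(nrm > 0, nrm, 1)
}

# Internal: bunch score for a set of pixels: max over training jets of the
# magnitude cosine. W: n_px x nk magnitudes; train: n_train x nk magnitudes.
bunch_scores <- function(W, train) {
  S <- row_unit(W) %*% t(row_unit(train))
  do.call(pmax, c(as.data.frame(S), list(0)))
}

# Internal: argmax with deterministic tie-breaking: highest score, then
# smallest distance to the population mean, then row-major (y, then x)
# order. The integer argmax is refined to sub-pixel precision by a 1D
# parabolic fit through the score and its two axis neighbours (offset
# clamped to half a pixel; skipped at window borders and at ties) -- the
# standard refinement for quantized template matching.
pick_best <- function(score, win, tol = 1e-12) {
  best <- max(score)
  cand <- which(score >= best - tol)
  tied <- length(cand) > 1
  if (tied) {
    d2 <- (win$ix[cand] + 0.5 - win$mu[1])^2 + (win$iy[cand] + 0.5 - win$mu[2])^2
    cand <- cand[d2 <= min(d2) + 1e-12]
    if (length(cand) > 1) {
      ord <- order(win$iy[cand], win$ix[cand])
      cand <- cand[ord]
    }
  }
  i <- cand[1]
  xy <- c(win$ix[i] + 0.5, win$iy[i] + 0.5)
  if (!tied && !is.null(win$nx) && win$nx * win$ny == length(score)) {
    sm <- matrix(score, win$ny, win$nx)        # iy fastest
    ri <- (i - 1L) %% win$ny + 1L
    ci <- (i - 1L) %/% win$ny + 1L
    para <- function(sm1, s0, sp1) {
      den <- sm1 - 2 * s0 + sp1
      if (den >= -1e-12) return(0)             # not a proper peak
      clamp(0.5 * (sm1 - sp1) / den, -0.5, 0.5)
    }
    if (ci > 1 && ci < win$nx)
      xy[1] <- xy[1] + para(sm[ri, ci - 1], sm[ri, ci], sm[ri, ci + 1])
    if (ri > 1 && ri < win$ny)
      xy[2] <- xy[2] + para(sm[ri - 1, ci], sm[ri, ci], sm[ri + 1, ci])
  }
  list(xy = xy, score = best)
}

#' Locate one landmark on one channel (base landmarkers 1-15)
#'
#' Exhaustive scan of the search window centered at the population mean;
#' the score of a pixel is the maximum over the bunch of the jet similarity
#' between the pixel's jet and a training jet. Ties broken by distance to
#' the population mean, then row-major order.
#'
#' @param stack a [build_feature_stack()] result (test subject).
#' @param channel_id channel name ("tex.ori", ...).
#' @param graph a [train_bunch_graph()] result.
#' @param landmark_id landmark id (1-21).
#' @param maps optional precomputed [gabor_responses()] for `stack`.
#' @param window optional window override as returned by the internal
#'   window builder; default mean +/- max(10 px, 2 x training SD).
#' @param subset optional integer vector: use only these training subjects'
#'   jets (bagging support).
#' @return list with `xy` (predicted pixel-center coordinate, 0-based
#'   continuous) and `score`.
#' @export
locate_landmark <- function(stack, channel_id, graph, landmark_id,
                            maps = NULL, window = NULL, subset = NULL) {
  if (!channel_id %in% graph$channel_names) stop("unknown channel ", channel_id)
  n <- nrow(stack$channels[[1]])
  i <- match(landmark_id, graph$landmark_ids)
  win <- if (is.null(window)) search_window(graph, i, n) else window
  W <- if (!is.null(maps)) {
    maps$mag[[channel_id]][jm_rows(maps, win$lin), , drop = FALSE]
  } else {
    resp <- channel_responses(stack$channels[[channel_id]], graph$bank)
    sqrt(resp$re^2 + resp$im^2)[win$lin, , drop = FALSE]
  }
  train <- Mod(graph$jets[[channel_id]][[i]])
  if (!is.null(subset)) train <- train[subset, , drop = FALSE]
  pick_best(bunch_scores(W, train), win)
}

#' Summed-response landmarker (base landmarker 16)
#'
#' Like [locate_landmark()] but jets are first summed componentwise
#' (complex) across the 15 channels, both for the test pixel and for each
#' training subject, and the search runs on the aggregate jets.
#'
#' @inheritParams locate_landmark
#' @return list with `xy` and `score`.
#' @export
landmarker_sum_responses <- function(stack, graph, landmark_id, maps = NULL,
                                     window = NULL, subset = NULL) {
  n <- nrow(stack$channels[[1]])
  i <- match(landmark_id, graph$landmark_ids)
  win <- if (is.null(window)) search_window(graph, i, n) else window
  if (is.null(maps)) maps <- gabor_responses(stack, graph$bank)
  W <- maps$agg_mag[jm_rows(maps, win$lin), , drop = FALSE]
  train <- Mod(graph$agg_jets[[i]])
  if (!is.null(subset)) train <- train[subset, , drop = FALSE]
  pick_best(bunch_scores(W, train), win)
}

#' Coordinate-mean landmarker (base landmarker 17)
#'
#' Unweighted arithmetic mean of the final coordinates of the 15
#' per-channel base landmarkers.
#'
#' @param base a `base_predictions` data.frame from [run_base_landmarkers()]
#'   (or any subset containing landmarkers 1-15).
#' @return data.frame with `landmark_id`, `x`, `y`.
#' @export
landmarker_mean_coords <- function(base) {
  b <- base[base$landmarker_id %in% 1:15, ]
  if (!all(1:15 %in% b$landmarker_id)) stop("predictions 1-15 required")
  out <- aggregate(cbind(x, y) ~ landmark_id, data = b, FUN = mean)
  out[order(out$landmark_id), ]
}

#' Run the 18 base landmarkers on one subject
#'
#' Landmarkers 1-15: per-channel bunch-graph search in canonical channel
#' order; 16: summed wavelet responses; 17: mean of the final coordinates of
#' 1-15; 18: the PC-guided search (when `pc_model` is given).
#'
#' @param stack test subject's feature stack.
#' @param graph a [train_bunch_graph()] result.
#' @param pc_model optional [fit_pc_model()] result (enables landmarker 18).
#' @param maps optional precomputed [gabor_responses()].
#' @param subset optional training-subject subset (bagging).
#' @return data.frame of class `base_predictions` with columns
#'   `landmarker_id` (1-18), `landmark_id`, `x`, `y`, `score`.
#' @export
run_base_landmarkers <- function(stack, graph, pc_model = NULL, maps = NULL,
                                 subset = NULL) {
  if (is.null(maps))
    maps <- gabor_responses(stack, graph$bank,
                            needed_pixels(graph, nrow(stack$channels[[1]])))
  ids <- graph$landmark_ids
  rows <- list()
  for (ci in seq_along(graph$channel_names)) {
    ch <- graph$channel_names[ci]
    for (lm in ids) {
      r <- locate_landmark(stack, ch, graph, lm, maps = maps, subset = subset)
      rows[[length(rows) + 1L]] <- data.frame(
        landmarker_id = ci, landmark_id = lm,
        x = r$xy[1], y = r$xy[2], score = r$score)
    }
  }
  for (lm in ids) {
    r <- landmarker_sum_responses(stack, graph, lm, maps = maps,
                                  subset = subset)
    rows[[length(rows) + 1L]] <- data.frame(
      landmarker_id = 16L, landmark_id = lm, x = r$xy[1], y = r$xy[2],
      score = r$score)
  }
  out <- do.call(rbind, rows)
  m17 <- landmarker_mean_coords(out)
  out <- rbind(out, data.frame(landmarker_id = 17L,
                               landmark_id = m17$landmark_id,
                               x = m17$x, y = m17$y, score = NA_real_))
  if (!is.null(pc_model)) {
    p18 <- run_pc_landmarker(stack, graph, pc_model, maps = maps,
                             subset = subset)
    out <- rbind(out, data.frame(landmarker_id = 18L,
                                 landmark_id = p18$landmark_id,
                                 x = p18$x, y = p18$y, score = NA_real_))
  }
  class(out) <- c("base_predictions", "data.frame")
  out
}
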