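# Ensemble combination of the 18 base landmarkers: bootstrap aggregation
# (bagging) over resampled training sets, and stacked generalization: a
# least-squares combiner fitted on out-of-fold base predictions, sparsified
# to the 3 best base landmarkers per landmark with normalized weights.

#' Draw bootstrap bags from a training set
#'
#' Bags are multisets drawn i.i.d. uniformly with replacement; bags with
#' fewer than 2 unique subjects are redrawn.
#'
#' @param training_ids vector of training subject indices or ids.
#' @param n_bags number of bags.
#' @param bag_size size of each bag (default: the training size).
#' @param seed RNG seed.
#' @return list of length `n_bags` of multisets (same type as
#'   `training_ids`); attribute `n_redrawn` counts redraws.
#' @export
make_bags <- function(training_ids, n_bags, bag_size = length(training_ids),
                      seed = 1L) {
  if (length(training_ids) == 0) stop("empty training set")
  stopifnot(n_bags >= 1, bag_size >= 1)
  redrawn <- 0L
  bags <- with_seed(seed, lapply(seq_len(n_bags), function(b) {
    repeat {
      bag <- sample(training_ids, bag_size, replace = TRUE)
      if (length(unique(bag)) >= 2 || length(unique(training_ids)) < 2)
        return(bag)
      redrawn <<- redrawn + 1L
    }
  }))
  attr(bags, "n_redrawn") <- redrawn
  bags
}

# Internal: bunch graph restricted to a (multi)set of training subjects;
# equivalent to retraining on that multiset (jets are per-subject)
subset_bunch_graph <- function(graph, idx) {
  g <- graph
  g$jets <- lapply(graph$jets, function(per_lm)
    lapply(per_lm, function(m) m[idx, , drop = FALSE]))
  g$agg_jets <- lapply(graph$agg_jets, function(m) m[idx, , drop = FALSE])
  xy <- graph$train_xy[, , idx, drop = FALSE]
  g$train_xy <- xy
  g$mean_xy <- apply(xy, c(1, 2), mean)
  g$sd_xy <- apply(xy, c(1, 2), stats::sd)
  g$n_train <- length(idx)
  g
}

# Internal: PC model from a landmark coordinate array (n_lm x 2 x n_subj)
pc_model_from_xy <- function(train_xy, landmark_ids,
                             subgraphs = face_subgraphs()) {
  lms <- lapply(seq_len(dim(train_xy)[3]), function(s)
    landmarks2d(landmark_ids, train_xy[, , s]))
  fit_pc_model(lms, subgraphs)
}

#' Bagged landmark prediction
#'
#' Each bag's model is the bunch graph (and PC model, for landmarker 18)
#' restricted to the bag's training multiset; the final coordinate is the
#' unweighted mean of the per-bag predictions.
#'
#' @param stack test subject's feature stack.
#' @param graph full-training [train_bunch_graph()] result.
#' @param bags a [make_bags()] result (training indices `1..n_train`).
#' @param landmarker_id which base landmarker to bag (1-16 or 18).
#' @param subgraphs sub-graph spec (landmarker 18 only).
#' @param maps optional precomputed [gabor_responses()].
#' @return data.frame with `landmark_id`, `x`, `y`.
#' @export
bagging_predict <- function(stack, graph, bags, landmarker_id = 16L,
                            subgraphs = face_subgraphs(), maps = NULL) {
  n <- nrow(stack$channels[[1]])
  if (is.null(maps)) {
    # union of bag-specific search windows (positions only, no jet copying)
    pix <- sort(unique(unlist(lapply(bags, function(bag) {
      xy <- graph$train_xy[, , bag, drop = FALSE]
      needed_pixels(list(landmark_ids = graph$landmark_ids,
                         mean_xy = apply(xy, c(1, 2), mean),
                         sd_xy = apply(xy, c(1, 2), stats::sd)), n)
    }))))
    maps <- gabor_responses(stack, graph$bank, pix)
  }
  acc <- NULL
  for (bag in bags) {
    gb <- subset_bunch_graph(graph, bag)
    pred <- predict_single_landmarker(stack, gb, landmarker_id, maps,
                                      subgraphs)
    acc <- if (is.null(acc)) pred else {
      acc$x <- acc$x + pred$x; acc$y <- acc$y + pred$y; acc
    }
  }
  acc$x <- acc$x / length(bags)
  acc$y <- acc$y / length(bags)
  acc
}

# Internal: coordinates of one base landmarker on one subject
predict_single_landmarker <- function(stack, graph, landmarker_id, maps,
                                      subgraphs = face_subgraphs()) {
  ids <- graph$landmark_ids
  if (landmarker_id %in% seq_along(graph$channel_names)) {
    ch <- graph$channel_names[landmarker_id]
    xy <- t(vapply(ids, function(lm)
      locate_landmark(stack, ch, graph, lm, maps = maps)$xy, numeric(2)))
  } else if (landmarker_id == 16L) {
    xy <- t(vapply(ids, function(lm)
      landmarker_sum_responses(stack, graph, lm, maps = maps)$xy, numeric(2)))
  } else if (landmarker_id == 18L) {
    pm <- pc_model_from_xy(graph$train_xy, ids, subgraphs)
    p <- run_pc_landmarker(stack, graph, pm, maps = maps)
    return(p)
  } else stop("landmarker_id must be 1-16 or 18")
  data.frame(landmark_id = ids, x = xy[, 1], y = xy[, 2])
}

#' Out-of-fold base predictions for stacking
#'
#' Leave-one-out over the training set: each subject is predicted by all 18
#' base landmarkers using models trained on the remaining subjects only (no
#' leakage: the held-out subject's jets and coordinates enter neither the
#' bunch nor the PC model of its fold).
#'
#' @param stacks,landmarks training feature stacks and manual annotations.
#' @param graph optional pre-trained full bunch graph (trained on exactly
#'   these subjects); computed if NULL.
#' @param bank Gabor bank (used when `graph` is NULL).
#' @param subgraphs sub-graph spec for landmarker 18.
#' @param maps_list optional list of precomputed per-subject
#'   [gabor_responses()].
#' @param progress print fold progress.
#' @return data.frame of class `stacking_design`: columns `subject`,
#'   `landmark_id`, `axis` ("x"/"y"), `truth`, `p1` ... `p18`.
#' @export
collect_out_of_fold <- function(stacks, landmarks, graph = NULL,
                                bank = build_gabor_bank(),
                                subgraphs = face_subgraphs(),
                                maps_list = NULL, progress = FALSE) {
  n <- length(stacks)
  if (n < 3) stop("need at least 3 training subjects")
  if (is.null(graph)) graph <- train_bunch_graph(stacks, landmarks, bank)
  rows <- list()
  for (i in seq_len(n)) {
    if (progress) message("fold ", i, "/", n)
    fold_graph <- subset_bunch_graph(graph, setdiff(seq_len(n), i))
    pm <- pc_model_from_xy(fold_graph$train_xy, fold_graph$landmark_ids,
                           subgraphs)
    maps <- if (!is.null(maps_list)) maps_list[[i]] else
      gabor_responses(stacks[[i]], graph$bank,
                      needed_pixels(fold_graph, nrow(stacks[[i]]$channels[[1]])))
    base <- run_base_landmarkers(stacks[[i]], fold_graph, pc_model = pm,
                                 maps = maps)
    truth <- lm_coords(landmarks[[i]])
    ids <- fold_graph$landmark_ids
    for (ax in c("x", "y")) {
      pm18 <- vapply(1:18, function(l) {
        b <- base[base$landmarker_id == l, ]
        b[[ax]][match(ids, b$landmark_id)]
      }, numeric(length(ids)))
      colnames(pm18) <- paste0("p", 1:18)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, landmark_id = ids, axis = ax,
        truth = truth[, ax], pm18)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stacking_design", "data.frame")
  out
}

# Internal: OLS through the origin with a ridge fallback for ill-conditioned
# designs. The 18-predictor design is structurally rank-deficient (the
# coordinate-mean landmarker is an exact linear combination of the 15
# per-channel ones) and several good landmarkers are near-duplicates of each
# other, so plain OLS coefficients can explode with opposite signs; when the
# smallest eigenvalue of X'X falls below cond_tol of the mean diagonal, a
# ridge penalty of penalty_frac x mean diagonal stabilizes them.
ols_or_ridge <- function(X, y, penalty_frac = 0.01, cond_tol = 0.01) {
  XtX <- crossprod(X)
  dm <- mean(diag(XtX))
  if (!is.finite(dm) || dm <= 0)
    return(list(coef = rep(0, ncol(X)), ridge = FALSE))
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > cond_tol * dm) {
    list(coef = as.numeric(solve(XtX, crossprod(X, y))), ridge = FALSE)
  } else {
    list(coef = as.numeric(solve(XtX + diag(penalty_frac * dm, ncol(X)),
                                 crossprod(X, y))), ridge = TRUE)
  }
}

#' Fit the stacking combiner
#'
#' Per landmark: predictions and truth are centered per axis and pooled
#' across axes; one no-intercept least-squares regression of truth on the 18
#' base predictions is fitted (ridge fallback on collinearity); landmarkers
#' are ranked by the absolute coefficients of the SD-standardized predictor
#' columns; the top 3 are refitted by least squares under the constraint
#' that the coefficients sum to 1, giving the relative weights of the final
#' predictor directly (the constrained fit replaces post-hoc normalization,
#' which is unstable when the unconstrained coefficients nearly cancel).
#'
#' @param design a [collect_out_of_fold()] result.
#' @param n_select number of base landmarkers kept per landmark.
#' @param ridge_penalty fallback ridge penalty as a fraction of the mean
#'   diagonal of the (centered) predictor cross-product; applied when the
#'   design is ill-conditioned (see source notes).
#' @return list of class `stacking_model`; per landmark: `ids` (selected
#'   landmarker ids), `weights` (sum 1), `coef_full` (18 standardized
#'   coefficients), `resid_sd`, `used_ridge`.
#' @export
fit_stacking <- function(design, n_select = 3L, ridge_penalty = 0.01) {
  pcols <- paste0("p", 1:18)
  stopifnot(all(pcols %in% names(design)))
  out <- lapply(split(design, design$landmark_id), function(d) {
    if (nrow(d) < 19) stop("need > 18 rows per landmark to fit the combiner")
    X <- as.matrix(d[, pcols]); y <- d$truth
    for (ax in unique(d$axis)) {            # per-axis centering
      r <- d$axis == ax
      X[r, ] <- sweep(X[r, , drop = FALSE], 2, colMeans(X[r, , drop = FALSE]))
      y[r] <- y[r] - mean(y[r])
    }
    sds <- apply(X, 2, stats::sd)
    Xs <- sweep(X, 2, ifelse(sds > 1e-12, sds, 1), `/`)
    Xs[, sds <= 1e-12] <- 0
    f1 <- ols_or_ridge(Xs, y, ridge_penalty)
    coefs <- ifelse(is.na(f1$coef), 0, f1$coef)
    sel <- order(abs(coefs), decreasing = TRUE)[seq_len(n_select)]
    sel <- sort(sel)
    f2 <- constrained_ls(X[, sel, drop = FALSE], y, ridge_penalty)
    w <- f2$coef
    resid <- y - X[, sel, drop = FALSE] %*% w
    list(ids = sel, weights = as.numeric(w), coef_full = coefs,
         resid_sd = stats::sd(resid), used_ridge = f1$ridge || f2$ridge)
  })
  structure(out, class = "stacking_model")
}

# Internal: least squares with the coefficients constrained to sum to 1
# (relative weights). Same conditioning safeguard as ols_or_ridge.
constrained_ls <- function(X, y, penalty_frac = 0.01, cond_tol = 0.01) {
  k <- ncol(X)
  XtX <- crossprod(X)
  dm <- mean(diag(XtX))
  ridge <- FALSE
  if (!is.finite(dm) || dm <= 0)
    return(list(coef = rep(1 / k, k), ridge = FALSE))
  ev <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= cond_tol * dm) {
    XtX <- XtX + diag(penalty_frac * dm, k)
    ridge <- TRUE
  }
  A <- solve(XtX)
  w0 <- A %*% crossprod(X, y)
  u <- A %*% rep(1, k)
  w <- w0 + as.numeric((1 - sum(w0)) / sum(u)) * u
  list(coef = as.numeric(w), ridge = ridge)
}

#' Predict with a fitted stacking model
#'
#' Per landmark, the final coordinate is the weighted sum of the selected
#' base landmarkers' predictions. If a selected prediction is missing, the
#' landmark falls back to landmarker 17 (mean of 1-15) with a warning.
#'
#' @param base a [run_base_landmarkers()] result for the test subject.
#' @param model a [fit_stacking()] result.
#' @return data.frame with `landmark_id`, `x`, `y`.
#' @export
stacking_predict <- function(base, model) {
  lm_ids <- sort(unique(base$landmark_id))
  res <- lapply(lm_ids, function(lm) {
    m <- model[[as.character(lm)]]
    b <- base[base$landmark_id == lm, ]
    sel <- match(m$ids, b$landmarker_id)
    if (anyNA(sel) || anyNA(b$x[sel])) {
      warning("missing selected prediction for landmark ", lm,
              "; falling back to landmarker 17")
      i17 <- match(17L, b$landmarker_id)
      return(data.frame(landmark_id = lm, x = b$x[i17], y = b$y[i17]))
    }
    data.frame(landmark_id = lm,
               x = sum(m$weights * b$x[sel]),
               y = sum(m$weights * b$y[sel]))
  })
  do.call(rbind, res)
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("<stacking_model: %d landmarks, 3 base landmarkers each>\n",
              length(x)))
  for (lm in names(x))
    cat(sprintf("  lm %s: ids (%s), weights (%s)\n", lm,
                paste(x[[lm]]$ids, collapse = ", "),
                paste(sprintf("%.2f", x[[lm]]$weights), collapse = ", ")))
  invisible(x)
}

#' Serialize / load a stacking model as JSON
#'
#' @param model a [fit_stacking()] result.
#' @param path file path.
#' @return `write_stacking_model` returns `path` invisibly;
#'   `read_stacking_model` a `stacking_model`.
#' @export
write_stacking_model <- function(model, path) {
  jsonlite::write_json(lapply(model, function(m)
    list(ids = m$ids, weights = m$weights, coef_full = m$coef_full,
         resid_sd = m$resid_sd, used_ridge = m$used_ridge)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_stacking_model
#' @export
read_stacking_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(raw, function(m)
    list(ids = as.integer(m$ids), weights = as.numeric(m$weights),
         coef_full = as.numeric(m$coef_full), resid_sd = m$resid_sd,
         used_ridge = isTRUE(m$used_ridge))),
    class = "stacking_model")
}
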