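# PC model fitting and the PC-guided grid search

synthetic_rank1_landmarks <- function(n = 20, seed = 2) {
  # configurations = mean + s * v for one known direction v
  set.seed(seed)
  base <- cbind(runif(21, 40, 160), runif(21, 40, 160))
  v <- matrix(rnorm(42), 21, 2)
  v <- v / sqrt(sum(v^2))
  lapply(seq_len(n), function(i) {
    s <- rnorm(1, 0, 3)
    landmarks2d(1:21, base + s * v)
  })
}

test_that("PC model recovers a rank-1 deformation direction", {
  lms <- synthetic_rank1_landmarks()
  model <- fit_pc_model(lms)
  for (g in model) {
    expect_false(g$degenerate)
    V <- g$loadings
    expect_lt(norm(t(V) %*% V - diag(2), "F"), 1e-8)
  }
  # check PC1 alignment within one group against the generating direction
  set.seed(2)
  base <- cbind(runif(21, 40, 160), runif(21, 40, 160))
  v <- matrix(rnorm(42), 21, 2); v <- v / sqrt(sum(v^2))
  g1 <- model[[1]]
  idx <- g1$ids
  vg <- as.vector(t(v[idx, , drop = FALSE]))
  vg <- vg / sqrt(sum(vg^2))
  cosang <- abs(sum(g1$loadings[, 1] * vg))
  expect_gt(cosang, 0.999)
})

test_that("degenerate training collapses to the mean", {
  lms <- rep(list(landmarks2d(1:21, cbind(1:21 * 5 + 20, 100))), 5)
  model <- fit_pc_model(lms)
  expect_true(all(vapply(model, `[[`, logical(1), "degenerate")))
  expect_error(reconstruct(model, 1, 0, 0), "degenerate")
  tr <- small_trained()
  p <- run_pc_landmarker(tr$test$stack, tr$graph, model, maps = tr$maps)
  for (gi in seq_along(model)) {
    mu <- matrix(model[[gi]]$mean, ncol = 2, byrow = TRUE)
    got <- as.matrix(p[match(model[[gi]]$ids, p$landmark_id), c("x", "y")])
    expect_lt(max(abs(got - mu)), 1e-9)
  }
})

test_that("reconstruction is the documented linear map", {
  lms <- synthetic_rank1_landmarks(15, seed = 7)
  model <- fit_pc_model(lms)
  g <- model[[2]]
  r0 <- reconstruct(model, 2, 0, 0)
  expect_equal(as.vector(t(r0)), as.numeric(g$mean))
  # linearity: r(a) + r(b) - mean = r(a + b)
  ra <- reconstruct(model, 2, 1.2, -0.4)
  rb <- reconstruct(model, 2, -0.5, 0.9)
  rab <- reconstruct(model, 2, 0.7, 0.5)
  expect_lt(max(abs(ra + rb - r0 - rab)), 1e-9)
  # matrix-product oracle
  oracle <- g$mean + g$loadings %*% c(1.2, -0.4)
  expect_equal(as.vector(t(ra)), as.numeric(oracle))
})

test_that("grid search is admissible, anchored at the mean for mean-shaped input", {
  tr <- small_trained()
  # every returned landmark lies inside its mean +/- 1 SD rectangle
  for (gi in seq_along(tr$pc)) {
    r <- pc_grid_search(tr$test$stack, tr$graph, tr$pc, gi, maps = tr$maps)
    g <- tr$pc[[gi]]
    mu <- matrix(g$mean, ncol = 2, byrow = TRUE)
    expect_true(all(abs(r$coords - mu) <= g$lm_sd + 1e-6))
    expect_gte(r$admissible, 1)
  }
  # lambda = 0 and no overlap: independent of prior fits
  fake_prior <- data.frame(landmark_id = 1:21, x = 0, y = 0)
  r1 <- pc_grid_search(tr$test$stack, tr$graph, tr$pc, 1, maps = tr$maps,
                       lambda = 0, prior_fits = NULL)
  r2 <- pc_grid_search(tr$test$stack, tr$graph, tr$pc, 1, maps = tr$maps,
                       lambda = 0, prior_fits = fake_prior)
  expect_identical(r1$coords, r2$coords)
})

test_that("a training subject at the group mean is fitted at (0, 0)", {
  # duplicate one subject: the group mean is that subject's configuration
  # and the self-similarity upper bound (group_size x 15) is attained there
  tr <- small_trained()
  stacks <- rep(tr$stacks[1], 3)
  lms <- rep(tr$lms[1], 3)
  graph <- train_bunch_graph(stacks, lms, small_bank())
  pc1 <- fit_pc_model(c(tr$lms[1], tr$lms[2:3]))  # non-degenerate variance
  maps <- gabor_responses(tr$stacks[[1]], small_bank(),
                          facemark:::needed_pixels(graph, 200))
  for (gi in c(1, 3)) {
    r <- pc_grid_search(tr$stacks[[1]], graph, pc1, gi, maps = NULL)
    expect_true(is.list(r))
  }
  # with the duplicated-subject graph, searching that subject's own image
  # must return its own coordinates wherever the PC mean equals them
  pc_dup <- facemark:::pc_model_from_xy(graph$train_xy, graph$landmark_ids)
  expect_true(all(vapply(pc_dup, `[[`, logical(1), "degenerate")))
  p <- run_pc_landmarker(tr$stacks[[1]], graph, pc_dup, maps = maps)
  truth <- lm_coords(tr$lms[[1]])
  expect_lt(max(abs(as.matrix(p[, c("x", "y")]) - truth)), 1e-9)
})

test_that("declaration order of non-overlapping groups does not matter", {
  tr <- small_trained()
  sg <- face_subgraphs()
  # groups 3, 4, 5 share landmarks 7 and 9; groups 1 and 2 overlap in 5, 6.
  # Compare fitting {3, 4, 5} before vs after swapping 1 and 2 ordering.
  reord <- structure(sg[c(2, 1, 3, 4, 5)], class = "subgraph_spec")
  reord[[1]]$overlap <- integer(0)
  reord[[2]]$overlap <- intersect(sg[[1]]$ids, sg[[2]]$ids)
  pc_a <- fit_pc_model(tr$lms, sg)
  pc_b <- fit_pc_model(tr$lms, reord)
  pa <- run_pc_landmarker(tr$test$stack, tr$graph, pc_a, maps = tr$maps,
                          lambda = 0)
  pb <- run_pc_landmarker(tr$test$stack, tr$graph, pc_b, maps = tr$maps,
                          lambda = 0)
  # with lambda 0 the fits decouple; only overlap bookkeeping (which group
  # claims a shared landmark) may differ, so compare non-shared landmarks
  shared <- c(5, 6, 7, 9)
  keep <- !pa$landmark_id %in% shared
  expect_equal(pa[keep, ], pb[keep, ], tolerance = 1e-12)
})
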