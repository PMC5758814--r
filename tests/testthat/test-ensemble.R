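# Bagging and stacking

test_that("bags are reproducible bootstrap multisets", {
  b1 <- make_bags(1:30, n_bags = 5, seed = 9)
  b2 <- make_bags(1:30, n_bags = 5, seed = 9)
  expect_identical(b1[], b2[])
  expect_true(all(lengths(b1) == 30))
  expect_true(any(vapply(b1, anyDuplicated, integer(1)) > 0))
  # expected unique fraction ~ 1 - (1 - 1/n)^n over many bags
  bags <- make_bags(1:30, n_bags = 1000, seed = 10)
  uf <- mean(vapply(bags, function(b) length(unique(b)) / 30, numeric(1)))
  expect_lt(abs(uf - (1 - (1 - 1 / 30)^30)), 0.05)
  expect_error(make_bags(integer(0), 3), "empty")
})

test_that("bagging averages per-bag predictions", {
  tr <- small_trained()
  # two explicit bags -> mean of the two per-bag predictions (oracle)
  bags <- list(c(1L, 2L, 3L, 1L, 2L), c(3L, 4L, 5L, 4L, 5L))
  pred <- bagging_predict(tr$test$stack, tr$graph, bags, landmarker_id = 16L)
  full_maps <- gabor_responses(tr$test$stack, small_bank())
  p1 <- facemark:::predict_single_landmarker(
    tr$test$stack, facemark:::subset_bunch_graph(tr$graph, bags[[1]]), 16L,
    full_maps)
  p2 <- facemark:::predict_single_landmarker(
    tr$test$stack, facemark:::subset_bunch_graph(tr$graph, bags[[2]]), 16L,
    full_maps)
  expect_equal(pred$x, (p1$x + p2$x) / 2)
  expect_equal(pred$y, (p1$y + p2$y) / 2)
  # all-identical bags reduce bagging to the single full model
  full <- list(1:5, 1:5)
  pf <- bagging_predict(tr$test$stack, tr$graph, full, landmarker_id = 16L)
  ps <- facemark:::predict_single_landmarker(tr$test$stack, tr$graph, 16L,
                                             full_maps)
  expect_equal(pf$x, ps$x)
  expect_equal(pf$y, ps$y)
})

test_that("out-of-fold collection has the right shape and no leakage", {
  tr <- small_trained()
  stacks <- tr$stacks[1:3]; lms <- tr$lms[1:3]
  d <- collect_out_of_fold(stacks, lms, bank = small_bank())
  # n = 3 -> 3 folds, each fold's models trained on the other 2 subjects
  expect_s3_class(d, "stacking_design")
  expect_identical(nrow(d), 3L * 21L * 2L)
  expect_true(all(paste0("p", 1:18) %in% names(d)))
  # leakage guard: corrupting the held-out subject's landmarks leaves its
  # fold predictions unchanged (its annotations never enter the fold model)
  lms_bad <- lms
  lms_bad[[2]]$x <- lms_bad[[2]]$x + 5
  graph_ok <- train_bunch_graph(stacks, lms, small_bank())
  fold_ok <- facemark:::subset_bunch_graph(graph_ok, c(1, 3))
  graph_bad <- train_bunch_graph(stacks, lms_bad, small_bank())
  fold_bad <- facemark:::subset_bunch_graph(graph_bad, c(1, 3))
  expect_equal(fold_ok$jets, fold_bad$jets)
  expect_equal(fold_ok$mean_xy, fold_bad$mean_xy)
})

test_that("stacking selects a truth-equal base landmarker with weight > 0.9", {
  set.seed(21)
  n_sub <- 25
  rows <- list()
  for (lm in 1:21) for (ax in c("x", "y")) {
    truth <- rnorm(n_sub, 100, 4)
    P <- matrix(rnorm(n_sub * 18, 100, 4), n_sub, 18)
    P[, 5] <- truth                         # landmarker 5 is exact
    rows[[length(rows) + 1L]] <- data.frame(
      subject = seq_len(n_sub), landmark_id = lm, axis = ax, truth = truth,
      setNames(as.data.frame(P), paste0("p", 1:18)))
  }
  design <- do.call(rbind, rows)
  model <- fit_stacking(design)
  for (m in model) {
    expect_length(m$ids, 3)
    expect_equal(sum(m$weights), 1, tolerance = 1e-9)
    expect_true(5 %in% m$ids)
    expect_gt(m$weights[match(5, m$ids)], 0.9)
  }
})

test_that("stacking OLS matches the normal-equations oracle", {
  set.seed(22)
  n_sub <- 30
  truth <- rnorm(2 * n_sub, 80, 3)
  P <- matrix(rnorm(2 * n_sub * 18, 80, 3), ncol = 18)
  P[, 3] <- truth + rnorm(2 * n_sub, 0, 0.5)
  d <- data.frame(subject = rep(seq_len(n_sub), 2), landmark_id = 1,
                  axis = rep(c("x", "y"), each = n_sub), truth = truth,
                  setNames(as.data.frame(P), paste0("p", 1:18)))
  model <- fit_stacking(d)
  # oracle: center per axis, standardize columns, solve X'X b = X'y
  X <- P; y <- truth
  for (ax in 1:2) {
    r <- seq_len(n_sub) + (ax - 1) * n_sub
    X[r, ] <- sweep(X[r, ], 2, colMeans(X[r, ]))
    y[r] <- y[r] - mean(y[r])
  }
  Xs <- sweep(X, 2, apply(X, 2, sd), `/`)
  b_oracle <- solve(crossprod(Xs), crossprod(Xs, y))
  expect_lt(max(abs(model[["1"]]$coef_full - as.numeric(b_oracle))), 1e-8)
  # refit weights match the sum-to-one constrained normal-equations oracle
  sel <- model[["1"]]$ids
  A <- solve(crossprod(X[, sel]))
  w0 <- A %*% crossprod(X[, sel], y)
  u <- A %*% rep(1, 3)
  w_oracle <- w0 + as.numeric((1 - sum(w0)) / sum(u)) * u
  expect_lt(max(abs(model[["1"]]$weights - as.numeric(w_oracle))), 1e-8)
  expect_equal(sum(model[["1"]]$weights), 1, tolerance = 1e-9)
})

test_that("a duplicated truth-equal landmarker is handled by the ridge fallback", {
  set.seed(23)
  n_sub <- 25
  truth <- rnorm(2 * n_sub, 80, 3)
  P <- matrix(rnorm(2 * n_sub * 18, 80, 3), ncol = 18)
  P[, 4] <- truth
  P[, 9] <- truth                        # exact duplicate -> collinear
  d <- data.frame(subject = rep(seq_len(n_sub), 2), landmark_id = 2,
                  axis = rep(c("x", "y"), each = n_sub), truth = truth,
                  setNames(as.data.frame(P), paste0("p", 1:18)))
  model <- fit_stacking(d)
  m <- model[["2"]]
  expect_true(m$used_ridge)
  expect_true(all(c(4, 9) %in% m$ids) || any(c(4, 9) %in% m$ids))
  sel_truth <- m$ids %in% c(4, 9)
  expect_gt(sum(m$weights[sel_truth]), 0.9)
})

test_that("stacking prediction is the documented weighted sum", {
  model <- structure(list("1" = list(ids = c(2L, 5L, 7L),
                                     weights = c(0.5, 0.3, 0.2))),
                     class = "stacking_model")
  base <- data.frame(landmarker_id = 1:18, landmark_id = 1,
                     x = seq(10, 180, by = 10), y = seq(5, 90, by = 5),
                     score = NA)
  p <- stacking_predict(base, model)
  expect_equal(p$x, 0.5 * 20 + 0.3 * 50 + 0.2 * 70)
  expect_equal(p$y, 0.5 * 10 + 0.3 * 25 + 0.2 * 35)
  # weights (1, 0, 0) reproduce the first selected landmarker
  model2 <- structure(list("1" = list(ids = c(3L, 4L, 5L),
                                      weights = c(1, 0, 0))),
                      class = "stacking_model")
  p2 <- stacking_predict(base, model2)
  expect_equal(c(p2$x, p2$y), c(30, 15))
  # missing selected prediction falls back to landmarker 17
  base3 <- base[base$landmarker_id != 3, ]
  expect_warning(p3 <- stacking_predict(base3, model2), "landmark 1")
  expect_equal(c(p3$x, p3$y), c(170, 85))
})

test_that("stacking model JSON round-trips", {
  m <- structure(list("1" = list(ids = c(1L, 2L, 3L), weights = c(0.2, 0.3, 0.5),
                                 coef_full = rnorm(18), resid_sd = 0.7,
                                 used_ridge = FALSE)),
                 class = "stacking_model")
  path <- tempfile(fileext = ".json")
  write_stacking_model(m, path)
  m2 <- read_stacking_model(path)
  expect_equal(m2[["1"]]$weights, m[["1"]]$weights)
  expect_identical(m2[["1"]]$ids, m[["1"]]$ids)
  expect_equal(m2[["1"]]$coef_full, m[["1"]]$coef_full)
})
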