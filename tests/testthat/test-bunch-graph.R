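# Bunch-graph training and the template-search landmarkers

test_that("training stores one jet per subject and definitional statistics", {
  tr <- small_trained()
  g <- tr$graph
  expect_identical(g$n_train, 5L)
  expect_true(all(vapply(g$jets, function(per_lm)
    all(vapply(per_lm, nrow, integer(1)) == 5L), logical(1))))
  # mean position is the arithmetic mean of the training coordinates
  xy1 <- t(vapply(tr$lms, function(l) unlist(l[l$landmark_id == 1, c("x", "y")]),
                  numeric(2)))
  expect_equal(as.numeric(g$mean_xy[1, ]), as.numeric(colMeans(xy1)))
  # identical training positions give zero SDs and the shared position
  lms_same <- rep(tr$lms[1], 3)
  stacks_same <- rep(tr$stacks[1], 3)
  g2 <- train_bunch_graph(stacks_same, lms_same, small_bank())
  expect_true(all(g2$sd_xy == 0))
  expect_error(train_bunch_graph(tr$stacks[1], tr$lms[1], small_bank()),
               "at least 2")
})

test_that("self-match: a training image scores 1.0 at its own landmark", {
  tr <- small_trained()
  for (ch in c("tex.ori", "hgt.ori", "crv.sob")) {
    r <- locate_landmark(tr$stacks[[1]], ch, tr$graph, 7, maps = tr$train_maps)
    expect_equal(r$score, 1.0, tolerance = 1e-9)
  }
})

test_that("locate_landmark respects the window and breaks ties deterministically", {
  tr <- small_trained()
  n <- 200
  win1 <- list(ix = 55L, iy = 60L, lin = 61L + 55L * n, mu = c(55.5, 60.5))
  r <- locate_landmark(tr$test$stack, "hgt.ori", tr$graph, 7,
                       maps = NULL, window = win1)
  expect_equal(r$xy, c(55.5, 60.5))
  # default window: result lies inside its extent (sub-pixel refined)
  win <- facemark:::search_window(tr$graph, 7, n)
  r2 <- locate_landmark(tr$test$stack, "hgt.ori", tr$graph, 7, maps = tr$maps)
  expect_gte(r2$xy[1], min(win$ix)); expect_lte(r2$xy[1], max(win$ix) + 1)
  expect_gte(r2$xy[2], min(win$iy)); expect_lte(r2$xy[2], max(win$iy) + 1)
  # tie-breaking: constant channel gives score 0 everywhere -> nearest to mean
  stack0 <- tr$test$stack
  stack0$channels[["hgt.ori"]][] <- 0
  r3 <- locate_landmark(stack0, "hgt.ori", tr$graph, 7)
  mu <- tr$graph$mean_xy[match(7, tr$graph$landmark_ids), ]
  expect_lt(sqrt(sum((r3$xy - mu)^2)), 1)
})

test_that("score never decreases when the bunch grows", {
  tr <- small_trained()
  win <- facemark:::search_window(tr$graph, 12, 200)
  W <- tr$maps$mag[["crv.ori"]][facemark:::jm_rows(tr$maps, win$lin), ]
  train <- Mod(tr$graph$jets[["crv.ori"]][[12]])
  s_small <- facemark:::bunch_scores(W, train[1:2, , drop = FALSE])
  s_big <- facemark:::bunch_scores(W, train)
  expect_true(all(s_big >= s_small - 1e-12))
})

test_that("summed-response landmarker aggregates channel jets componentwise", {
  tr <- small_trained()
  g <- tr$graph
  # aggregate training jets = componentwise complex sum over channels (oracle)
  lm_i <- 3
  oracle <- Reduce(`+`, lapply(g$channel_names,
                               function(ch) g$jets[[ch]][[lm_i]]))
  expect_equal(g$agg_jets[[lm_i]], oracle)
  r <- landmarker_sum_responses(tr$test$stack, g, 7, maps = tr$maps)
  win <- facemark:::search_window(g, 7, 200)
  expect_true(r$xy[1] >= min(win$ix) && r$xy[1] <= max(win$ix) + 1 &&
                r$xy[2] >= min(win$iy) && r$xy[2] <= max(win$iy) + 1)
})

test_that("mean-coordinate landmarker averages landmarkers 1-15", {
  base <- expand.grid(landmarker_id = 1:15, landmark_id = c(2, 9))
  set.seed(3)
  base$x <- rnorm(30, 100); base$y <- rnorm(30, 80); base$score <- 0.5
  m <- landmarker_mean_coords(base)
  for (lm in c(2, 9)) {
    expect_equal(m$x[m$landmark_id == lm],
                 mean(base$x[base$landmark_id == lm]))
    expect_equal(m$y[m$landmark_id == lm],
                 mean(base$y[base$landmark_id == lm]))
  }
  ident <- base; ident$x <- 50; ident$y <- 60
  mi <- landmarker_mean_coords(ident)
  expect_true(all(mi$x == 50 & mi$y == 60))
  expect_error(landmarker_mean_coords(base[base$landmarker_id < 15, ]),
               "1-15")
})
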