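# Procrustes alignment, geometric features, and the twin mixed model

random_config <- function(k = 21, seed = 1) {
  set.seed(seed)
  cbind(runif(k, 0, 100), runif(k, 0, 100))
}

test_that("GPA is invariant to similarity transforms and idempotent", {
  base <- random_config(seed = 31)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  copy <- sweep(1.8 * base %*% t(R), 2, c(12, -30), `+`)
  g <- procrustes_align(list(base, copy))
  d <- g$aligned[[1]] - g$aligned[[2]]
  expect_lt(sqrt(sum(d^2)), 1e-8)

  g2 <- procrustes_align(list(base, base))
  expect_lt(sqrt(sum((g2$mean - g2$aligned[[1]])^2)), 1e-12)

  configs <- lapply(1:10, function(i) random_config(seed = 40 + i))
  ga <- procrustes_align(configs)
  gb <- procrustes_align(ga$aligned)
  for (i in 1:10)
    expect_lt(sqrt(sum((ga$aligned[[i]] - gb$aligned[[i]])^2)), 1e-8)

  expect_error(procrustes_align(list(matrix(1, 5, 2), matrix(1, 5, 2))),
               "degenerate")
})

test_that("two-config alignment agrees with the vegan Procrustes oracle", {
  skip_if_not_installed("vegan")
  # rotated copy plus noise, so the optimal map is a proper rotation for
  # both implementations (ours never reflects)
  a <- random_config(seed = 51)
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  set.seed(53)
  b <- a %*% t(R) * 1.3 + matrix(rnorm(42, 0, 2), 21, 2)
  g <- procrustes_align(list(a, b), scale = TRUE)
  # our aligned pair is unit-centroid-size; the mutual best-rotation inner
  # product s relates to vegan's symmetric statistic ss = 1 - s^2, and our
  # squared distance is 2 - 2 s
  ours <- sum((g$aligned[[1]] - g$aligned[[2]])^2)
  v <- vegan::procrustes(a, b, symmetric = TRUE)
  s <- sqrt(1 - v$ss)
  expect_equal(ours, 2 - 2 * s, tolerance = 1e-6)
})

test_that("Delaunay triangle count obeys 2n - 2 - h and symmetrization works", {
  for (seed in 1:5) {
    pts <- random_config(15, seed = 60 + seed)
    tri <- facemark:::delaunay_triangles(pts)
    h <- nrow(pts[chull(pts), , drop = FALSE])
    expect_identical(nrow(tri), 2L * 15L - 2L - h)
    expect_true(all(tri[, 1] < tri[, 2] & tri[, 2] < tri[, 3]))
  }
  # a symmetric shape is unchanged by symmetrization
  tl <- face_template_landmarks()
  shape <- cbind(tl$lon * 100 + 100, -tl$lat * 100 + 100)
  st <- symmetrized_mean_triangulation(shape, face_symmetry_pairs())
  expect_lt(max(abs(st$symmetrized - shape)), 1e-9)
  # mirroring the input yields the same triangle list
  mir <- shape; mir[, 1] <- 200 - mir[, 1]
  mir <- mir[face_symmetry_pairs(), ]
  st2 <- symmetrized_mean_triangulation(mir, face_symmetry_pairs())
  expect_identical(st$triangles, st2$triangles)
})

test_that("geometric features: counts, analytic triangles, angle sums", {
  tri <- rbind(c(1L, 2L, 3L))
  m <- rbind(c(0, 0), c(1, 0), c(0, 1))
  f <- extract_features(list(m), tri)
  expect_equal(f[["ar_1_2_3"]], 0.5)
  expect_equal(f[["an_1_2_3_a"]], pi / 2)
  expect_equal(f[["an_1_2_3_b"]], pi / 4)
  expect_equal(f[["an_1_2_3_c"]], pi / 4)
  expect_equal(f[["d_1_2"]], 1)
  expect_equal(f[["d_2_3"]], sqrt(2))

  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  fe <- extract_features(list(eq), tri)
  expect_equal(unlist(fe[paste0("an_1_2_3_", c("a", "b", "c"))]),
               setNames(rep(pi / 3, 3), paste0("an_1_2_3_", c("a", "b", "c"))))

  # full 21-landmark case: C(21, 2) = 210 distances, angle sums = pi
  cfgs <- lapply(1:4, function(i) random_config(seed = 70 + i))
  ga <- procrustes_align(cfgs)
  tris <- facemark:::delaunay_triangles(ga$mean)
  ff <- extract_features(ga, tris)
  expect_identical(sum(startsWith(names(ff), "d_")), 210L)
  expect_false(any(grepl("^d_([0-9]+)_\\1$", names(ff))))
  for (t in seq_len(nrow(tris))) {
    nm <- paste(tris[t, ], collapse = "_")
    sums <- rowSums(ff[paste0("an_", nm, "_", c("a", "b", "c"))])
    expect_lt(max(abs(sums - pi)), 1e-9)
    expect_true(all(ff[[paste0("ar_", nm)]] >= 0))
  }
})

test_that("h2 identity reproduces printed SD-component pairs", {
  expect_equal(round(h2_from_sds(0.76, 1.01), 2), 0.64)
  expect_equal(round(h2_from_sds(38.39, 100.00), 2), 0.87)
  expect_equal(h2_from_sds(3.7, 0), 0)
  expect_equal(h2_from_sds(0, 2.2), 1)
  expect_error(h2_from_sds(0, 0), "both zero")
  expect_error(h2_from_sds(-1, 1), ">= 0")
})

test_that("twin model recovers simulated variance components", {
  spec <- twin_spec(n_mz = 500, n_dz = 500, h2_true = 0.6, total_sd = 2,
                    beta0 = 5, beta_age = 0.09, seed = 77)
  cohort <- generate_twin_cohort(spec)
  est <- fit_twin_model(cohort$value, cohort)
  expect_true(est$converged)
  expect_lt(abs(est$h2 - 0.6), 0.08)
  expect_lt(abs(est$beta_age - 0.09), 0.02)
  expect_lt(abs(est$beta0 - 5), 1)
  expect_equal(est$h2, est$sigma_g^2 / (est$sigma_g^2 + est$sigma_e^2),
               tolerance = 1e-9)

  # null recovery
  c0 <- generate_twin_cohort(twin_spec(n_mz = 500, n_dz = 500, h2_true = 0,
                                       seed = 78))
  expect_lt(fit_twin_model(c0$value, c0)$h2, 0.1)

  # affine invariance of the heritability estimate
  est2 <- fit_twin_model(3.5 * cohort$value - 40, cohort)
  expect_lt(abs(est2$h2 - est$h2), 1e-6)

  expect_error(fit_twin_model(rnorm(10),
                              generate_twin_cohort(twin_spec(2, 2, seed = 1))[1:10, ]),
               "10 pairs")
})

test_that("MZ-only cohort matches the lme4 random-intercept oracle", {
  skip_if_not_installed("lme4")
  cohort <- generate_twin_cohort(twin_spec(n_mz = 300, n_dz = 0,
                                           h2_true = 0.45, beta_age = 0.05,
                                           seed = 80))
  est <- fit_twin_model(cohort$value, cohort)
  # for MZ pairs the additive model is exactly a random pair intercept
  lf <- lme4::lmer(value ~ age + (1 | pair_id), data = cohort, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(est$sigma_g, vc$sdcor[1], tolerance = 1e-3)
  expect_equal(est$sigma_e, vc$sdcor[2], tolerance = 1e-3)
  expect_equal(est$beta_age, lme4::fixef(lf)[["age"]], tolerance = 1e-4)
})

test_that("importance maps behave like inverse-distance weighted averages", {
  m1 <- importance_map(cbind(10, 12), 0.7, image_size = 32)
  expect_lt(max(abs(m1 - 0.7)), 1e-12)
  m2 <- importance_map(rbind(c(5, 5), c(25, 25)), c(0.5, 0.5), image_size = 32)
  expect_lt(max(abs(m2 - 0.5)), 1e-12)
  m3 <- importance_map(rbind(c(8, 8), c(24, 24)), c(0.2, 0.9),
                       image_size = 32)
  expect_true(all(m3 >= 0.2 - 1e-12 & m3 <= 0.9 + 1e-12))
  # near a feature center the map approaches that feature's h2
  expect_lt(abs(m3[25, 25] - 0.9), 0.05)
  expect_error(importance_map(matrix(0, 0, 2), numeric(0)), "empty")
  # display rescaling maps to [0, max h2]
  m4 <- importance_map(rbind(c(8, 8), c(24, 24)), c(0.2, 0.9),
                       image_size = 32, rescale = TRUE)
  expect_equal(range(m4), c(0, 0.9))
})

test_that("feature centers follow the documented conventions", {
  shape <- rbind(c(0, 0), c(10, 0), c(0, 10))
  cen <- feature_centers(c("c_1_x", "d_1_2", "ar_1_2_3", "an_1_2_3_b"),
                         shape, landmark_ids = 1:3)
  expect_equal(unlist(cen[1, c("cx", "cy")]), c(cx = 0, cy = 0))
  expect_equal(unlist(cen[2, c("cx", "cy")]), c(cx = 5, cy = 0))
  expect_equal(unlist(cen[3, c("cx", "cy")]),
               c(cx = 10 / 3, cy = 10 / 3))
  expect_equal(unlist(cen[4, c("cx", "cy")]), c(cx = 10, cy = 0))
})
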