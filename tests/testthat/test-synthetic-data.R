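# Synthetic face and twin-cohort generators

test_that("face generation is deterministic and affine in mode scores", {
  spec <- face_spec(seed = 3, grid_n = 16)
  f0 <- generate_face(spec)
  f0b <- generate_face(spec)
  expect_identical(f0$mesh$vertices, f0b$mesh$vertices)
  expect_identical(f0$mesh$color, f0b$mesh$color)

  # zero scores give the template; +1/-1 SD displacements are antisymmetric
  nm <- spec$shape_modes
  sc <- numeric(nm); sc[1] <- spec$mode_sds[1]
  fp <- generate_face(spec, sc)
  fm <- generate_face(spec, -sc)
  d_plus <- lm_coords(fp$landmarks) - lm_coords(f0$landmarks)
  d_minus <- lm_coords(fm$landmarks) - lm_coords(f0$landmarks)
  expect_lt(max(abs(d_plus + d_minus)), 1e-9)
  expect_gt(max(abs(d_plus)), 0.1)   # the mode actually moves landmarks

  # finite-difference linearity across all modes
  s <- seq(-1, 1, length.out = nm) + 0.2
  f1 <- generate_face(spec, s)
  pred <- lm_coords(f0$landmarks)
  for (m in seq_len(nm)) {
    e <- numeric(nm); e[m] <- 1
    fe <- generate_face(spec, e)
    pred <- pred + s[m] * (lm_coords(fe$landmarks) - lm_coords(f0$landmarks))
  }
  expect_lt(max(abs(pred - lm_coords(f1$landmarks))), 1e-9)

  expect_error(generate_face(spec, c(1, NA, numeric(nm - 2))), "finite")
  expect_error(generate_population(spec, 0))
})

test_that("population landmark SDs match the mode-projected closed form", {
  spec <- face_spec(seed = 9, grid_n = 16, pixel_noise_sd = 0)
  pop <- generate_population(spec, 500)
  lm_arr <- vapply(pop, function(s) lm_coords(s$landmarks),
                   matrix(0, 21, 3))
  emp_sd <- apply(lm_arr, c(1, 2), sd)
  # closed form: landmark positions are mean + sum_m s_m * d_m with
  # s_m ~ N(0, mode_sds[m]^2), so SD = sqrt(sum_m (sd_m * d_m)^2) per axis
  f0 <- generate_face(spec)
  pred_var <- matrix(0, 21, 3)
  for (m in seq_len(spec$shape_modes)) {
    e <- numeric(spec$shape_modes); e[m] <- 1
    fe <- generate_face(spec, e)
    d <- lm_coords(fe$landmarks) - lm_coords(f0$landmarks)
    pred_var <- pred_var + (spec$mode_sds[m] * d)^2
  }
  pred_sd <- sqrt(pred_var)
  big <- pred_sd > 0.2          # compare where there is real displacement
  expect_true(any(big))
  expect_lt(max(abs(emp_sd[big] - pred_sd[big]) / pred_sd[big]), 0.10)

  # reproducibility of the population under a fixed seed
  pop2 <- generate_population(spec, 3)
  pop3 <- generate_population(spec, 3)
  expect_identical(lapply(pop2, `[[`, "scores"), lapply(pop3, `[[`, "scores"))
})

test_that("twin construction yields the theoretical MZ/DZ correlations", {
  # no genetic signal
  c0 <- generate_twin_cohort(twin_spec(n_mz = 200, n_dz = 200, h2_true = 0,
                                       seed = 4))
  expect_lt(abs(facemark:::intra_pair_cor(c0, "MZ")), 0.15)
  expect_lt(abs(facemark:::intra_pair_cor(c0, "DZ")), 0.15)

  # full heritability: MZ co-twins identical up to fixed effects
  c1 <- generate_twin_cohort(twin_spec(n_mz = 50, n_dz = 10, h2_true = 1,
                                       beta_age = 0, seed = 5))
  mz <- c1[c1$zygosity == "MZ", ]
  v <- do.call(rbind, split(mz$value, mz$pair_id))
  expect_lt(max(abs(v[, 1] - v[, 2])), 1e-9)

  # h2 = 0.6: correlations approach 0.6 (MZ) and 0.3 (DZ)
  c2 <- generate_twin_cohort(twin_spec(n_mz = 500, n_dz = 500, h2_true = 0.6,
                                       beta_age = 0.05, seed = 6))
  expect_lt(abs(facemark:::intra_pair_cor(
    within(c2, value <- value - 0.05 * age), "MZ") - 0.6), 0.07)
  expect_lt(abs(facemark:::intra_pair_cor(
    within(c2, value <- value - 0.05 * age), "DZ") - 0.3), 0.07)

  expect_error(twin_spec(h2_true = 1.2), "0, 1")
})
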