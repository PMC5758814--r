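# End-to-end synthetic benchmark: generate a face population, project and
# build feature stacks, train the bunch graph and PC model, fit the stacking
# combiner on out-of-fold predictions over the training set, and evaluate
# all base landmarkers plus the stacked predictor on held-out test subjects.
# This is the package's standard experiment harness for tests and for
# reproducing the method comparison at desk scale.

#' Project a synthetic subject and build its feature stack
#'
#' Convenience wrapper: ellipsoid fit, Mercator projection, curvature, and
#' feature bank for one `generate_face()` subject; also projects its
#' ground-truth landmarks to pixels.
#'
#' @param subject list with `mesh` and `landmarks` (from [generate_face()]).
#' @param image_size raster side in pixels.
#' @param roi a [roi_config()].
#' @return list: `stack` (feature_stack), `landmarks` (landmarks2d truth),
#'   `face` (projected_face).
#' @export
prepare_subject <- function(subject, image_size = 200L, roi = roi_config()) {
  ell <- fit_ellipsoid(subject$mesh)
  face <- project_mercator(subject$mesh, ell, roi, image_size)
  face <- compute_curvature(subject$mesh, face)
  stack <- build_feature_stack(face)
  lm2 <- project_landmarks(subject$landmarks, face)
  if (!all(lm2$ok)) stop("ground-truth landmark outside ROI")
  list(stack = stack, landmarks = lm2, face = face)
}

#' Best template-based landmarker on the training set
#'
#' Selects, from the out-of-fold design table, the template-search
#' landmarker (ids 1-16) with the smallest pooled RMS coordinate error over
#' the training subjects. This is the single model one would deploy without
#' the ensemble, and the natural target of the bagging experiment (bags
#' re-extract its templates).
#'
#' @param design a [collect_out_of_fold()] result.
#' @return integer landmarker id.
#' @export
best_template_landmarker <- function(design) {
  rms <- vapply(1:16, function(l)
    sqrt(mean((design[[paste0("p", l)]] - design$truth)^2)), numeric(1))
  which.min(rms)
}

#' Run the synthetic landmarking benchmark
#'
#' Generates `n_train + n_test` synthetic faces, trains the full pipeline on
#' the training subjects (bunch graph, PC model, stacking combiner via
#' leave-one-out out-of-fold collection), and evaluates all 18 base
#' landmarkers and the stacked predictor on the test subjects, in mm.
#'
#' @param spec a [face_spec()]; its seed drives the whole experiment.
#' @param n_train,n_test training and test subjects.
#' @param bank a [build_gabor_bank()].
#' @param subgraphs a [face_subgraphs()] spec.
#' @param progress print progress messages.
#' @return list of class `benchmark_result`: `test_errors` (long data.frame:
#'   method, subject, landmark_id, error_mm; methods "base1" ... "base18",
#'   "stacked"), `report` (cv_report over test errors), `stacking_model`,
#'   `design` (out-of-fold table), `graph`, `pc_model`, `prepared_test`,
#'   `base_test` (per-subject base predictions).
#' @export
run_benchmark <- function(spec = face_spec(), n_train = 30L, n_test = 10L,
                          bank = build_gabor_bank(),
                          subgraphs = face_subgraphs(), progress = FALSE) {
  pop <- generate_population(spec, n_train + n_test)
  say <- function(...) if (progress) message(...)
  say("projecting ", length(pop), " subjects")
  prep <- lapply(pop, prepare_subject, image_size = spec$image_size)
  tr <- seq_len(n_train)
  te <- n_train + seq_len(n_test)
  stacks_tr <- lapply(prep[tr], `[[`, "stack")
  lms_tr <- lapply(prep[tr], `[[`, "landmarks")
  say("training bunch graph")
  graph <- train_bunch_graph(stacks_tr, lms_tr, bank)
  pc <- fit_pc_model(lms_tr, subgraphs)
  say("collecting out-of-fold predictions")
  design <- collect_out_of_fold(stacks_tr, lms_tr, graph = graph,
                                subgraphs = subgraphs, progress = progress)
  smodel <- fit_stacking(design)
  say("evaluating test subjects")
  rows <- list()
  base_test <- list()
  for (j in seq_along(te)) {
    p <- prep[[te[j]]]
    maps <- gabor_responses(p$stack, bank,
                            needed_pixels(graph, spec$image_size))
    base <- run_base_landmarkers(p$stack, graph, pc_model = pc, maps = maps)
    base_test[[j]] <- base
    stacked <- stacking_predict(base, smodel)
    for (l in 1:18) {
      b <- base[base$landmarker_id == l, ]
      err <- landmark_error_mm(b, p$landmarks, p$stack$face)
      rows[[length(rows) + 1L]] <- data.frame(
        method = paste0("base", l), subject = te[j],
        landmark_id = as.integer(names(err)), error_mm = as.numeric(err))
    }
    err <- landmark_error_mm(stacked, p$landmarks, p$stack$face)
    rows[[length(rows) + 1L]] <- data.frame(
      method = "stacked", subject = te[j],
      landmark_id = as.integer(names(err)), error_mm = as.numeric(err))
  }
  test_errors <- do.call(rbind, rows)
  structure(list(test_errors = test_errors, report = cv_report(test_errors),
                 stacking_model = smodel, design = design, graph = graph,
                 pc_model = pc, prepared_test = prep[te],
                 base_test = base_test),
            class = "benchmark_result")
}
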