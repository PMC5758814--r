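# Leave-one-out accuracy evaluation. Errors are reported as 3D Euclidean
# distances in mm: predicted and manual pixel coordinates are both carried
# back to 3D through the projection's back-map, so in-plane pixel errors are
# converted at the local ground resolution.

#' Per-landmark error in mm
#'
#' Backprojects predicted and reference pixel coordinates to 3D via the
#' face's back-map (bilinear) and returns their Euclidean distances.
#'
#' @param pred,truth [landmarks2d()] (or data.frames with `landmark_id`,
#'   `x`, `y`) over the same landmark ids.
#' @param face the subject's `projected_face`.
#' @return named numeric vector of mm errors, names = landmark ids.
#' @export
landmark_error_mm <- function(pred, truth, face) {
  ids <- sort(truth$landmark_id)
  stopifnot(identical(sort(pred$landmark_id), ids))
  p3 <- t(vapply(seq_along(ids), function(i) {
    r <- pred[match(ids[i], pred$landmark_id), ]
    bilinear_backmap(face, r$x, r$y)
  }, numeric(3)))
  t3 <- t(vapply(seq_along(ids), function(i) {
    r <- truth[match(ids[i], truth$landmark_id), ]
    bilinear_backmap(face, r$x, r$y)
  }, numeric(3)))
  if (anyNA(p3) || anyNA(t3)) stop("landmark outside ROI in error computation")
  setNames(sqrt(rowSums((p3 - t3)^2)), ids)
}

#' Leave-one-out cross-validation harness
#'
#' For each fold, every method is trained on the remaining subjects and
#' predicts the held-out subject; per-landmark mm errors are recorded.
#' A method is a function `f(train_stacks, train_landmarks, test_stack)`
#' returning a data.frame with `landmark_id`, `x`, `y`.
#'
#' @param dataset list of subjects, each `list(stack = feature_stack,
#'   landmarks = landmarks2d)`.
#' @param methods named list of method functions.
#' @param seed RNG seed (fixed for methods that use randomness).
#' @return list of class `cv_report`: `errors` (long data.frame: method,
#'   subject, landmark_id, error_mm), `summary` (per method x landmark mean,
#'   sd, n), `grand` (per method grand mean/sd = equal-weight mean over
#'   per-landmark means).
#' @export
run_loo <- function(dataset, methods, seed = 1L) {
  n <- length(dataset)
  if (n < 3) stop("need at least 3 subjects")
  stopifnot(length(names(methods)) == length(methods))
  rows <- list()
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    train_stacks <- lapply(dataset[tr], `[[`, "stack")
    train_lms <- lapply(dataset[tr], `[[`, "landmarks")
    test <- dataset[[i]]
    for (mname in names(methods)) {
      pred <- tryCatch(
        with_seed(seed, methods[[mname]](train_stacks, train_lms, test$stack)),
        error = function(e) {
          message("method ", mname, " failed on fold ", i, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(pred)) next
      err <- landmark_error_mm(pred, test$landmarks, test$stack$face)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mname, subject = i,
        landmark_id = as.integer(names(err)), error_mm = as.numeric(err))
    }
  }
  cv_report(do.call(rbind, rows))
}

#' Assemble a CV report from long-format errors
#'
#' @param errors data.frame with `method`, `subject`, `landmark_id`,
#'   `error_mm`.
#' @return a `cv_report` (see [run_loo()]).
#' @export
cv_report <- function(errors) {
  stopifnot(all(errors$error_mm >= 0))
  summary <- aggregate(error_mm ~ method + landmark_id, data = errors,
                       FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                           n = length(v)))
  summary <- data.frame(method = summary$method,
                        landmark_id = summary$landmark_id,
                        mean_mm = summary$error_mm[, "mean"],
                        sd_mm = summary$error_mm[, "sd"],
                        n = summary$error_mm[, "n"])
  grand <- aggregate(mean_mm ~ method, data = summary,
                     FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  grand <- data.frame(method = grand$method,
                      grand_mean_mm = grand$mean_mm[, "mean"],
                      grand_sd_mm = grand$mean_mm[, "sd"])
  structure(list(errors = errors, summary = summary, grand = grand),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n")
  print(x$grand, row.names = FALSE)
  invisible(x)
}

#' Write a CV report to files
#'
#' Writes `report.tsv` (per-landmark table with quality flags: "good" for
#' mean error < 2 mm, "poor" for > 4 mm) plus `report.md` (human-readable)
#' and `raw_errors.tsv`.
#'
#' @param report a `cv_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the per-landmark table with flags.
#' @export
format_report <- function(report, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$summary
  tab$flag <- ifelse(tab$mean_mm < 2, "good",
                     ifelse(tab$mean_mm > 4, "poor", ""))
  write.table(tab, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$errors, file.path(dir, "raw_errors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  md <- c("# Landmarking accuracy (leave-one-out)", "",
          "| method | landmark | mean mm | sd mm | flag |",
          "|---|---|---|---|---|",
          sprintf("| %s | %d | %s | %.2f | %s |",
                  tab$method, tab$landmark_id,
                  ifelse(tab$flag == "good", sprintf("__%.2f__", tab$mean_mm),
                         ifelse(tab$flag == "poor", sprintf("*%.2f*", tab$mean_mm),
                                sprintf("%.2f", tab$mean_mm))),
                  tab$sd_mm, tab$flag),
          "", "| method | grand mean mm | grand sd |", "|---|---|---|",
          sprintf("| %s | %.2f | %.2f |", report$grand$method,
                  report$grand$grand_mean_mm, report$grand$grand_sd_mm))
  writeLines(md, file.path(dir, "report.md"))
  invisible(tab)
}
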