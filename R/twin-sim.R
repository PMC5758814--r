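#' Twin cohort simulation specification
#'
#' Simulates a trait under the additive (narrow-sense) twin model:
#' `value = beta0 + beta_age * age + g + e`, with the genetic effect `g`
#' shared exactly within monozygotic (MZ) pairs and correlated 0.5 within
#' dizygotic (DZ) pairs, so that `cov(MZ) = sigma_g^2` and
#' `cov(DZ) = 0.5 * sigma_g^2` by construction.
#'
#' @param n_mz,n_dz numbers of MZ / DZ pairs (`n_mz + n_dz >= 1`).
#' @param h2_true additive-genetic share of trait variance, in \[0, 1\].
#' @param total_sd total trait SD `sqrt(sigma_g^2 + sigma_e^2)` (trait units).
#' @param beta0,beta_age fixed-effect intercept and age slope.
#' @param age_range years; ages drawn uniformly per pair (co-twins share age).
#' @param seed integer RNG seed.
#' @return list of class `twin_spec`.
#' @export
twin_spec <- function(n_mz = 37L, n_dz = 163L, h2_true = 0.5, total_sd = 1,
                      beta0 = 0, beta_age = 0, age_range = c(18, 75),
                      seed = 1L) {
  if (h2_true < 0 || h2_true > 1) stop("h2_true must be in [0, 1]")
  stopifnot(n_mz + n_dz >= 1, total_sd > 0, length(age_range) == 2)
  structure(list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 h2_true = h2_true, total_sd = total_sd, beta0 = beta0,
                 beta_age = beta_age, age_range = age_range,
                 seed = as.integer(seed)),
            class = "twin_spec")
}

#' Simulate a twin cohort
#'
#' For DZ pairs the genetic effects of the co-twins are drawn from a
#' bivariate normal with correlation 0.5 (additive model); MZ co-twins share
#' `g` exactly. Residuals are independent.
#'
#' @param spec a [twin_spec()].
#' @return data.frame of class `twin_dataset` with columns `individual_id`,
#'   `pair_id`, `zygosity` ("MZ"/"DZ"), `age` (years) and `value`.
#' @export
generate_twin_cohort <- function(spec) {
  stopifnot(inherits(spec, "twin_spec"))
  sg <- spec$total_sd * sqrt(spec$h2_true)
  se <- spec$total_sd * sqrt(1 - spec$h2_true)
  n_pairs <- spec$n_mz + spec$n_dz
  with_seed(spec$seed, {
    zyg <- rep(c("MZ", "DZ"), c(spec$n_mz, spec$n_dz))
    age <- runif(n_pairs, spec$age_range[1], spec$age_range[2])
    # genetic effects: g2 = g1 for MZ; corr 0.5 for DZ via g2 = 0.5 g1 + sqrt(.75) u
    g1 <- rnorm(n_pairs, 0, sg)
    u <- rnorm(n_pairs, 0, sg)
    g2 <- ifelse(zyg == "MZ", g1, 0.5 * g1 + sqrt(0.75) * u)
    e <- matrix(rnorm(2 * n_pairs, 0, se), n_pairs, 2)
    fixed <- spec$beta0 + spec$beta_age * age
    v1 <- fixed + g1 + e[, 1]
    v2 <- fixed + g2 + e[, 2]
    df <- data.frame(
      individual_id = sprintf("t%04d_%d", rep(seq_len(n_pairs), each = 2), 1:2),
      pair_id = sprintf("p%04d", rep(seq_len(n_pairs), each = 2)),
      zygosity = rep(zyg, each = 2),
      age = rep(age, each = 2),
      value = as.vector(rbind(v1, v2)))
    class(df) <- c("twin_dataset", "data.frame")
    df
  })
}

#' Write / read a twin cohort as TSV
#'
#' @param cohort a `twin_dataset` (or compatible data.frame).
#' @param path file path.
#' @return `write_twin_cohort` returns `path` invisibly; `read_twin_cohort`
#'   a `twin_dataset`.
#' @export
write_twin_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_twin_cohort
#' @export
read_twin_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual_id", "pair_id", "zygosity", "age") %in% names(df)))
  class(df) <- c("twin_dataset", "data.frame")
  df
}

# Internal: empirical intra-pair correlation by zygosity
intra_pair_cor <- function(cohort, zygosity, column = "value") {
  d <- cohort[cohort$zygosity == zygosity, ]
  sp <- split(d[[column]], d$pair_id)
  sp <- sp[lengths(sp) == 2]
  m <- do.call(rbind, sp)
  # double-entered correlation (symmetric in co-twin order)
  stats::cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
}
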