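#' Region membership probabilities for the benchmark designs
#'
#' The three benchmark designs partition the unit square of covariates
#' `(Z1, Z2)` into 1, 2 or 3 regions:
#' * `D1` — a single region A (no effect modification);
#' * `D2` — region B where `Z1, Z2 > 0.5`, region A elsewhere
#'   (either covariate `<= 0.5`);
#' * `D3` — region A where `Z1 < 0.5`, region B where `Z1, Z2 > 0.5`,
#'   region C where `Z1 > 0.5, Z2 < 0.5`.
#'
#' With `smoothing_width = 0` membership is crisp. Otherwise each
#' half-space indicator `1{u > 0.5}` is replaced by the logistic ramp
#' `1 / (1 + exp(-(u - 0.5) / w))`, producing a gradual transition band of
#' width ~`w` around the boundaries; region probabilities are the
#' corresponding products and complements and always sum to 1.
#'
#' @param design `"D1"`, `"D2"` or `"D3"`.
#' @param z Numeric matrix (rows = points, 2 columns) or length-2 vector
#'   in the unit square.
#' @param smoothing_width Logistic boundary width `w >= 0` (covariate
#'   units; default 0.05).
#' @return Matrix of probabilities, one row per point, columns named after
#'   the design's regions.
#' @export
region_membership <- function(design, z, smoothing_width = 0.05) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  z <- as.matrix(z)
  stopifnot(ncol(z) == 2L)
  ramp <- function(u) {
    if (smoothing_width == 0) as.numeric(u > 0.5)
    else stats::plogis((u - 0.5) / smoothing_width)
  }
  s1 <- ramp(z[, 1]); s2 <- ramp(z[, 2])
  switch(design,
    D1 = cbind(A = rep(1, nrow(z))),
    D2 = { pb <- s1 * s2; cbind(A = 1 - pb, B = pb) },
    D3 = cbind(A = 1 - s1, B = s1 * s2, C = s1 * (1 - s2)),
    stop("unknown design '", design, "'"))
}

#' Generate a benchmark dataset with known effect-modification structure
#'
#' Simulates a case/control omics study on the unit covariate square:
#' `n_per_class` observations per outcome class, covariates
#' `Z1, Z2 ~ U(0, 1)`, and `M` exposures. Controls (`Y = 0`) always draw
#' every exposure from `N(base_mean, sd^2)`. Cases (`Y = 1`) first draw a
#' region from [region_membership()] at their covariate point (soft
#' assignment near smoothed boundaries); in region A exposures match the
#' control distribution (no association), while in regions B and C the
#' exposures are split into three random equal sets with means
#' `base_mean`, `shifted_means[1]` and `shifted_means[2]` — region C (D3
#' only) uses an independently drawn set partition, so its association
#' pattern differs from B's.
#'
#' @param design `"D1"`, `"D2"` or `"D3"`.
#' @param n_per_class Observations per outcome class (default 100).
#' @param M Number of exposures, divisible by 3 (default 30).
#' @param base_mean,shifted_means,sd Normal-exposure parameters
#'   (defaults 2, c(2.7, 1.3), 0.5).
#' @param smoothing_width Boundary smoothing passed to
#'   [region_membership()] (default 0.05).
#' @param seed Optional integer seed; fixed seed gives a bit-identical
#'   dataset.
#' @return List of class `synthetic_dataset`: `data` (data frame with
#'   `Y`, `X1..XM`, `Z1`, `Z2`), `roles` (a ready [column_roles()]),
#'   `true_region` (sampled region per observation), `sets` (the
#'   variable-set partitions used per shifted region) and the generating
#'   parameters.
#' @export
generate_dataset <- function(design = c("D1", "D2", "D3"),
                             n_per_class = 100, M = 30,
                             base_mean = 2, shifted_means = c(2.7, 1.3),
                             sd = 0.5, smoothing_width = 0.05,
                             seed = NULL) {
  design <- match.arg(design)
  stopifnot(M %% 3 == 0)
  if (!is.null(seed)) set.seed(seed)
  N <- 2L * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  z <- cbind(Z1 = stats::runif(N), Z2 = stats::runif(N))

  draw_sets <- function() {
    perm <- sample.int(M)
    split(perm, rep(1:3, each = M / 3))
  }
  sets <- list(B = draw_sets())
  if (design == "D3") sets$C <- draw_sets()
  means_for <- function(region) {
    mu <- rep(base_mean, M)
    if (region %in% names(sets)) {
      mu[sets[[region]][[2]]] <- shifted_means[1]
      mu[sets[[region]][[3]]] <- shifted_means[2]
    }
    mu
  }

  prob <- region_membership(design, z, smoothing_width)
  regions <- colnames(prob)
  true_region <- vapply(seq_len(N), function(i)
    sample(regions, 1L, prob = prob[i, ]), character(1))

  x <- matrix(NA_real_, N, M, dimnames = list(NULL, paste0("X", 1:M)))
  for (i in seq_len(N)) {
    mu <- if (y[i] == 0L) rep(base_mean, M) else means_for(true_region[i])
    x[i, ] <- stats::rnorm(M, mu, sd)
  }

  roles <- column_roles(outcome = "Y", exposures = colnames(x),
                        covariates = c("Z1", "Z2"),
                        outcome_family = "binary")
  structure(list(data = data.frame(Y = y, x, z), roles = roles,
                 true_region = true_region, sets = sets,
                 design = design, n_per_class = n_per_class, M = M,
                 base_mean = base_mean, shifted_means = shifted_means,
                 sd = sd, smoothing_width = smoothing_width, seed = seed),
            class = "synthetic_dataset")
}

#' Uniform reference matrix over a template's column ranges
#'
#' Draws a matrix of the template's shape with each column independently
#' uniform on that column's observed `[min, max]`; the null model behind
#' the elbow significance test.
#'
#' @param template Numeric matrix.
#' @param seed Optional integer seed.
#' @return Matrix of the same dimensions.
#' @export
generate_reference_matrix <- function(template, seed = NULL) {
  template <- as.matrix(template)
  stopifnot(length(template) > 0)
  if (!is.null(seed)) set.seed(seed)
  lo <- apply(template, 2, min); hi <- apply(template, 2, max)
  u <- matrix(stats::runif(length(template)), nrow(template))
  out <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  dimnames(out) <- dimnames(template)
  out
}

#' Simulate a benchmark dataset to disk
#'
#' Writes the observations as CSV plus a sidecar truth file (per-row
#' sampled region and the shifted variable-set partitions) for validation
#' against ground truth.
#'
#' @inheritParams generate_dataset
#' @param out Path of the CSV to write; the truth sidecar gets the suffix
#'   `_truth.json`.
#' @return The `synthetic_dataset`, invisibly.
#' @export
simulate_esp_data <- function(design, seed, out, ...) {
  ds <- generate_dataset(design, seed = seed, ...)
  utils::write.csv(ds$data, out, row.names = FALSE)
  truth <- list(design = ds$design, seed = seed,
                smoothing_width = ds$smoothing_width,
                true_region = ds$true_region,
                sets = lapply(ds$sets, function(s) lapply(s, as.integer)))
  jsonlite::write_json(truth, sub("\\.csv$", "", out) |>
                         paste0("_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(ds)
}
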