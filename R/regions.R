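#' Summarise ESP clusters as covariate-space regions
#'
#' Maps window clusters back to covariate space: per cluster, the centroid
#' of its member windows' standardized profiles, the dispersion of those
#' member profiles around the centroid, and the window midpoints (centres)
#' with their strata for plotting the regions. Exposures are ranked by the
#' largest between-cluster centroid gap, highlighting which omics variables
#' differ most across regions.
#'
#' @param esp A standardized `esp_matrix` (or bare matrix of standardized
#'   profiles).
#' @param labels Integer cluster labels aligned with the ESP rows.
#' @param cover The [enumerate_windows()] cover the rows come from.
#' @return Object of class `region_summary`: `centroids` (k x M),
#'   `sigma` (k x M member-scatter standard deviations), `sizes`,
#'   `midpoints` (data frame: window, cluster, stratum, centre coords),
#'   `exposure_gap` (named, sorted decreasing), `k`.
#' @export
summarize_regions <- function(esp, labels, cover = NULL) {
  x <- as_feature_matrix(esp)
  stopifnot(length(labels) == nrow(x))
  ks <- sort(unique(labels))
  sizes <- vapply(ks, function(c) sum(labels == c), integer(1))
  stopifnot(all(sizes > 0L))
  centroids <- rowsum(x, labels) / sizes
  sigma <- t(vapply(ks, function(c) {
    xc <- x[labels == c, , drop = FALSE]
    if (nrow(xc) < 2L) rep(0, ncol(x)) else apply(xc, 2, stats::sd)
  }, numeric(ncol(x))))
  dimnames(sigma) <- dimnames(centroids)

  gap <- if (length(ks) > 1L) {
    apply(centroids, 2, function(col) max(stats::dist(col)))
  } else stats::setNames(rep(0, ncol(x)), colnames(x))
  gap <- sort(gap, decreasing = TRUE)

  midpoints <- NULL
  if (!is.null(cover)) {
    midpoints <- data.frame(window = seq_len(cover$n_retained),
                            cluster = labels)
    for (d in cover$discrete) midpoints[[d]] <- cover$strata[[d]]
    for (j in seq_along(cover$continuous))
      midpoints[[cover$continuous[j]]] <- cover$centers[, j]
  }
  structure(list(centroids = centroids, sigma = sigma, sizes = sizes,
                 midpoints = midpoints, exposure_gap = gap,
                 k = length(ks)),
            class = "region_summary")
}

#' Fuzzy cluster membership of a covariate point
#'
#' Hard clustering of overlapping windows induces fuzzy clustering of
#' points: a point's membership in cluster c is the fraction of retained
#' windows containing the point that carry label c. Points contained in no
#' retained window are flagged uncovered.
#'
#' @param cover A [enumerate_windows()] cover.
#' @param labels Window cluster labels.
#' @param z Covariate point (named vector or single-row data frame).
#' @return List: `covered` (logical), `fractions` (named numeric per
#'   cluster, summing to 1; `NULL` when uncovered), `majority` (label with
#'   the largest fraction; ties to the smallest label), `n_windows`.
#' @export
point_membership <- function(cover, labels, z) {
  idx <- point_windows(cover, z)
  if (!length(idx))
    return(list(covered = FALSE, fractions = NULL, majority = NA_integer_,
                n_windows = 0L))
  lab <- labels[idx]
  frac <- table(factor(lab, levels = sort(unique(labels)))) / length(lab)
  frac <- stats::setNames(as.numeric(frac), names(frac))
  list(covered = TRUE, fractions = frac,
       majority = as.integer(names(frac)[which.max(frac)]),
       n_windows = length(idx))
}

#' Fuzzy membership table for many points
#'
#' @param cover,labels As in [point_membership()].
#' @param points Data frame of covariate points (one per row; must contain
#'   every covariate column).
#' @return Data frame: one row per point with `covered`, `majority` and a
#'   `frac_<c>` column per cluster.
#' @export
membership_table <- function(cover, labels, points) {
  ks <- sort(unique(labels))
  rows <- lapply(seq_len(nrow(points)), function(i) {
    m <- point_membership(cover, labels, points[i, , drop = FALSE])
    fr <- if (m$covered) m$fractions else stats::setNames(
      rep(NA_real_, length(ks)), as.character(ks))
    c(list(covered = m$covered, majority = m$majority), as.list(fr))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  names(out) <- c("covered", "majority", paste0("frac_", ks))
  cbind(points, out)
}

#' Two-dimensional principal-component view of the windows
#'
#' Projects the standardized window profiles onto their first two principal
#' components (centred, not re-scaled) for visual inspection of the cluster
#' structure. Sign convention: within each component the loading of largest
#' magnitude is made positive, so the projection is reproducible.
#'
#' @param esp Standardized `esp_matrix` or matrix (M >= 2 columns).
#' @return Nw x 2 matrix of scores (columns `PC1`, `PC2`) with the variance
#'   explained in attribute `"var_explained"`.
#' @export
project_windows_2d <- function(esp) {
  x <- as_feature_matrix(esp)
  stopifnot(ncol(x) >= 2L, nrow(x) >= 2L)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, 1:2, drop = FALSE]
  scores <- p$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (rot[which.max(abs(rot[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- c("PC1", "PC2")
  structure(scores,
            var_explained = (p$sdev^2 / sum(p$sdev^2))[1:2])
}

#' @export
print.region_summary <- function(x, ...) {
  cat("<region_summary> ", x$k, " region(s); window counts: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  top <- utils::head(x$exposure_gap, 5)
  cat("  top exposure gaps: ",
      paste(names(top), signif(top, 3), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write region reports as TSV
#'
#' @param regions A `region_summary`.
#' @param path_regions Per-cluster centroid/sigma table (long format:
#'   cluster, exposure, centroid, sigma).
#' @param path_midpoints Window-midpoint table (window, cluster, stratum,
#'   centre coordinates); skipped when the summary has no cover.
#' @export
write_region_report <- function(regions, path_regions,
                                path_midpoints = NULL) {
  long <- do.call(rbind, lapply(seq_len(regions$k), function(c)
    data.frame(cluster = rownames(regions$centroids)[c],
               exposure = colnames(regions$centroids),
               centroid = regions$centroids[c, ],
               sigma = regions$sigma[c, ], row.names = NULL)))
  utils::write.table(long, path_regions, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(path_midpoints) && !is.null(regions$midpoints))
    utils::write.table(regions$midpoints, path_midpoints, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(regions)
}
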