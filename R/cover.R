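#' Nearest-neighbour box side lengths
#'
#' For every observation, finds the smallest axis-aligned hyperrectangle
#' containing the observation and its `n - 1` nearest neighbours, and
#' returns its side length in each continuous-covariate dimension. The
#' neighbour search uses Euclidean distance on covariates standardized by
#' their sample standard deviation; side lengths are reported in the
#' original units. These per-point box sides drive the data-driven choice
#' of window size and gliding step (see [window_geometry()]).
#'
#' @param z Numeric matrix or data frame, N rows x Jc continuous
#'   covariates, in original units.
#' @param n Neighbourhood size (the observation itself counts), `2 <= n <= N`.
#' @return N x Jc matrix of box side lengths.
#' @export
neighborhood_box_sides <- function(z, n) {
  z <- as.matrix(z)
  N <- nrow(z)
  if (N < 2L) stop("need at least 2 observations")
  if (n > N) stop("neighbourhood size n = ", n, " exceeds N = ", N)
  if (n < 2L) stop("n must be at least 2")
  sdev <- apply(z, 2, stats::sd)
  sdev[sdev == 0] <- 1
  zs <- sweep(z, 2, sdev, "/")
  d <- as.matrix(stats::dist(zs))
  sides <- matrix(0, N, ncol(z), dimnames = list(NULL, colnames(z)))
  for (i in seq_len(N)) {
    nb <- order(d[i, ])[seq_len(n)]   # ties broken by row order; includes i
    box <- z[nb, , drop = FALSE]
    sides[i, ] <- apply(box, 2, max) - apply(box, 2, min)
  }
  sides
}

#' Window size and gliding step from box side lengths
#'
#' The window side in dimension j is the `percentile`-th percentile
#' (linear interpolation between order statistics) of the per-point box
#' sides, so that a window placed at a typical point captures at least the
#' target number of observations; the gliding step is the minimum observed
#' side. A zero minimum (duplicated points) falls back to the smallest
#' positive side.
#'
#' @param sides Matrix from [neighborhood_box_sides()].
#' @param percentile Percentile for the window side (default 95).
#' @param n Target number of observations per window (carried along as
#'   metadata and the default window-occupancy floor).
#' @return An object of class `window_geometry` with elements `L` (sides),
#'   `step` (gliding steps), `n_target` and `percentile`.
#' @export
window_geometry <- function(sides, percentile = 95, n = NULL) {
  sides <- as.matrix(sides)
  if (!nrow(sides)) stop("empty side matrix")
  L <- apply(sides, 2, stats::quantile, probs = percentile / 100,
             names = FALSE)  # type 7: linear interpolation
  step <- apply(sides, 2, function(s) {
    m <- min(s)
    if (m > 0) return(m)
    pos <- s[s > 0]
    if (!length(pos)) stop("degenerate covariate: all box sides are zero")
    min(pos)
  })
  if (any(L <= 0)) stop("degenerate covariate: window side is zero")
  structure(list(L = L, step = pmin(step, L), n_target = n,
                 percentile = percentile),
            class = "window_geometry")
}

#' Enumerate the overlapping window cover of covariate space
#'
#' Candidate window centres form the grid `Zj_min + ij * step_j`,
#' `ij = 0..nj` with `nj = floor((Zj_max - Zj_min) / step_j)` in every
#' continuous dimension, crossed with every observed combination of the
#' discrete covariates (stratification). An observation belongs to a window
#' when each continuous covariate lies in the closed interval
#' `[c_j - L_j/2, c_j + L_j/2]` and its discrete covariates equal the
#' window's stratum. Candidates with fewer than `min_obs` members — and,
#' for a binary outcome, fewer than `min_class_count` members in either
#' class — are discarded.
#'
#' @param obs An [observation_table()].
#' @param geometry A [window_geometry()] whose `L`/`step` are named after
#'   (or aligned with) the continuous covariates.
#' @param min_obs Occupancy floor per window; defaults to the geometry's
#'   `n_target` (or 1 if unset).
#' @param min_class_count For binary outcomes, minimum members per outcome
#'   class in a retained window (default 5); ignored otherwise.
#' @return An object of class `cover_geometry`: `geometry`, `windows`
#'   (list of `stratum`, `center`, `member_idx`), `centers` matrix,
#'   `strata` data frame per window, counts `n_candidate` / `n_retained`,
#'   and the covariate column order used by [point_windows()].
#' @export
enumerate_windows <- function(obs, geometry,
                              min_obs = NULL, min_class_count = 5) {
  stopifnot(inherits(obs, "observation_table"),
            inherits(geometry, "window_geometry"))
  if (is.null(min_obs)) min_obs <- if (is.null(geometry$n_target)) 1L else geometry$n_target
  stopifnot(min_obs >= 1)
  roles <- obs$roles
  ccov <- continuous_covariates(roles)
  dcov <- discrete_covariates(roles)
  zc <- as.matrix(obs$data[ccov])
  L <- rep_len(unname(geometry$L), length(ccov))
  step <- rep_len(unname(geometry$step), length(ccov))

  axes <- lapply(seq_along(ccov), function(j) {
    zmin <- min(zc[, j]); zmax <- max(zc[, j])
    nj <- floor((zmax - zmin) / step[j] + 1e-9)
    zmin + (0:nj) * step[j]
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- ccov

  strata <- if (length(dcov)) {
    unique(obs$data[dcov])
  } else data.frame(row.names = 1)[1, , drop = FALSE]
  n_strata <- nrow(strata)
  n_candidate <- nrow(grid) * n_strata

  binary <- roles$outcome_family == "binary"
  y <- obs$data[[roles$outcome]]

  windows <- list()
  centers <- list()
  strat_rows <- list()
  for (s in seq_len(n_strata)) {
    in_stratum <- if (length(dcov)) {
      Reduce(`&`, lapply(dcov, function(d) obs$data[[d]] == strata[s, d]))
    } else rep(TRUE, obs$n_obs)
    for (g in seq_len(nrow(grid))) {
      ok <- in_stratum
      for (j in seq_along(ccov))
        ok <- ok & abs(zc[, j] - grid[g, j]) <= L[j] / 2
      idx <- which(ok)
      if (length(idx) < min_obs) next
      if (binary) {
        tab <- tabulate(y[idx] + 1L, nbins = 2L)
        if (any(tab < min_class_count)) next
      }
      windows[[length(windows) + 1L]] <- list(
        stratum = if (length(dcov)) as.numeric(strata[s, dcov]) else numeric(0),
        center = grid[g, ], member_idx = idx)
      centers[[length(centers) + 1L]] <- grid[g, ]
      strat_rows[[length(strat_rows) + 1L]] <- s
    }
  }
  if (!length(windows))
    stop("cover is empty; reduce min_obs or increase n")

  center_mat <- do.call(rbind, centers)
  colnames(center_mat) <- ccov
  strata_df <- strata[unlist(strat_rows), , drop = FALSE]
  rownames(strata_df) <- NULL
  structure(list(geometry = geometry, windows = windows,
                 centers = center_mat, strata = strata_df,
                 continuous = ccov, discrete = dcov,
                 min_obs = min_obs,
                 min_class_count = if (binary) min_class_count else NA,
                 n_candidate = n_candidate,
                 n_retained = length(windows)),
            class = "cover_geometry")
}

#' Windows containing a covariate point
#'
#' Because windows overlap, a point typically lies in several; the list of
#' containing windows is what makes cluster membership fuzzy at the point
#' level.
#'
#' @param cover A [enumerate_windows()] result.
#' @param z Named numeric vector (or single-row data frame) giving every
#'   covariate coordinate, continuous and discrete.
#' @return Integer vector of retained-window indices containing `z`
#'   (possibly empty for points in sparse, uncovered regions).
#' @export
point_windows <- function(cover, z) {
  z <- unlist(z)
  keys <- c(cover$continuous, cover$discrete)
  if (is.null(names(z)) || !all(keys %in% names(z))) {
    if (length(z) != length(keys))
      stop("z must supply the coordinates ",
           paste(keys, collapse = ", "))
    names(z) <- keys
  }
  L <- rep_len(unname(cover$geometry$L), length(cover$continuous))
  ok <- rep(TRUE, cover$n_retained)
  for (j in seq_along(cover$continuous)) {
    zj <- z[[cover$continuous[j]]]
    ok <- ok & abs(cover$centers[, j] - zj) <= L[j] / 2
  }
  for (d in cover$discrete)
    ok <- ok & cover$strata[[d]] == z[[d]]
  which(ok)
}

#' @export
print.cover_geometry <- function(x, ...) {
  cat("<cover_geometry> ", x$n_retained, " windows retained of ",
      x$n_candidate, " candidates\n", sep = "")
  cat("  L:    ", paste(signif(x$geometry$L, 4), collapse = ", "), "\n")
  cat("  step: ", paste(signif(x$geometry$step, 4), collapse = ", "), "\n")
  cat("  min_obs: ", x$min_obs, "\n")
  invisible(x)
}

#' Write the cover report as TSV
#'
#' One row per retained window: stratum values, centre coordinates, member
#' count.
#'
#' @param cover A `cover_geometry`.
#' @param path Output file.
#' @export
write_cover_report <- function(cover, path) {
  df <- data.frame(window = seq_len(cover$n_retained))
  for (d in cover$discrete) df[[d]] <- cover$strata[[d]]
  for (j in seq_along(cover$continuous))
    df[[paste0("center_", cover$continuous[j])]] <- cover$centers[, j]
  df$n_members <- vapply(cover$windows, function(w) length(w$member_idx), 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
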