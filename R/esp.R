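#' Effect size of one exposure within one window
#'
#' Fits the working model `f(Y) = b0 + b_m X_m + sum_j a_j Z'_j` on the
#' observations of a single window. For a continuous outcome the model is
#' ordinary least squares and the effect size is the slope `b_m`; for a
#' binary outcome it is maximum-likelihood logistic regression and the
#' effect size is the odds ratio `exp(b_m)`.
#'
#' Small windows make logistic separation routine. On non-convergence or a
#' wild coefficient the fit is repeated with a light L2 ridge on the
#' non-intercept coefficients (`lambda = 1e-4 * n_window`), and any slope
#' still beyond +/-10 on the log-odds scale is clamped there before
#' exponentiating; such fits are flagged.
#'
#' @param y Outcome vector for the window's members.
#' @param x Exposure vector.
#' @param confounders Optional numeric matrix of within-window adjustment
#'   covariates (columns that are collinear or constant inside the window
#'   are dropped automatically).
#' @param family `"continuous"` or `"binary"`.
#' @return List with `raw` (slope or odds ratio), `beta` (coefficient on
#'   the model scale), `ok` (logical: clean fit) and `confounders_dropped`.
#' @export
fit_window_effect <- function(y, x, confounders = NULL,
                              family = c("continuous", "binary")) {
  family <- match.arg(family)
  X <- cbind(`(Intercept)` = 1, x = x)
  dropped <- FALSE
  if (!is.null(confounders) && NCOL(confounders) > 0) {
    Xc <- cbind(X, as.matrix(confounders))
    # keep the confounders only if they leave the design full rank
    if (qr(Xc)$rank == ncol(Xc)) X <- Xc else dropped <- TRUE
  }

  if (family == "continuous") {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients[["x"]]
    return(list(raw = beta, beta = beta,
                ok = is.finite(beta), confounders_dropped = dropped))
  }

  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients[["x"]]
  ok <- fit$converged && is.finite(beta) && abs(beta) <= 10
  if (!ok) {
    beta <- ridge_logistic(X, y, lambda = 1e-4 * nrow(X))[["x"]]
    if (!is.finite(beta)) beta <- 0
    if (abs(beta) > 10) beta <- sign(beta) * 10
  }
  list(raw = exp(beta), beta = beta, ok = ok, confounders_dropped = dropped)
}

# Logistic IRLS with an L2 penalty on all non-intercept coefficients.
# Used only as a separation fallback; lambda is tiny so estimates match
# ML closely whenever the likelihood has an interior maximum.
ridge_logistic <- function(X, y, lambda, max_iter = 50, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  stats::setNames(beta, colnames(X))
}

#' Assemble the raw effect-size-profile matrix
#'
#' Runs [fit_window_effect()] for every retained window and exposure,
#' producing the Nw x M matrix whose row l is the effect-size profile of
#' window l. An exposure that fails cleanly in more than `max_fail_frac`
#' of windows is dropped from the matrix; isolated failures are imputed
#' with the exposure's mean raw effect over its clean windows, keeping the
#' matrix complete for clustering.
#'
#' @param cover A [enumerate_windows()] cover.
#' @param obs The [observation_table()] the cover was built on.
#' @param confounders Character vector of column names adjusted for inside
#'   every window (default none, i.e. univariate effect sizes).
#' @param or_scale For binary outcomes: enter odds ratios `exp(b_m)` into
#'   the feature matrix instead of log odds ratios `b_m`. Default `FALSE`:
#'   the log scale is symmetric around the null and variance-stable, which
#'   small-window fits (where the occasional near-separated window yields
#'   extreme odds ratios) need for a usable clustering geometry.
#' @param max_fail_frac Failure fraction above which an exposure is dropped
#'   (default 0.2).
#' @return Object of class `esp_matrix`: `raw` (Nw x M), `standardized`
#'   (`NULL` until [standardize_esp()]), `window_index`, `dropped_exposures`,
#'   `n_flagged` fit count.
#' @export
build_esp_matrix <- function(cover, obs, confounders = character(),
                             or_scale = FALSE, max_fail_frac = 0.2) {
  stopifnot(inherits(cover, "cover_geometry"),
            inherits(obs, "observation_table"))
  roles <- obs$roles
  fam <- roles$outcome_family
  y_all <- obs$data[[roles$outcome]]
  expo <- roles$exposures
  conf_mat <- if (length(confounders)) as.matrix(obs$data[confounders]) else NULL

  Nw <- cover$n_retained
  raw <- matrix(NA_real_, Nw, length(expo), dimnames = list(NULL, expo))
  ok <- matrix(FALSE, Nw, length(expo))
  for (l in seq_len(Nw)) {
    idx <- cover$windows[[l]]$member_idx
    y <- y_all[idx]
    cf <- if (is.null(conf_mat)) NULL else conf_mat[idx, , drop = FALSE]
    for (m in seq_along(expo)) {
      f <- fit_window_effect(y, obs$data[[expo[m]]][idx], cf, fam)
      raw[l, m] <- if (fam == "binary" && !or_scale) f$beta else f$raw
      ok[l, m] <- f$ok
    }
  }

  fail_frac <- colMeans(!ok)
  drop <- fail_frac > max_fail_frac
  if (all(drop)) stop("every exposure failed to fit in most windows")
  for (m in which(!drop & fail_frac > 0)) {
    clean <- raw[ok[, m], m]
    raw[!ok[, m], m] <- mean(clean)
  }
  structure(list(raw = raw[, !drop, drop = FALSE],
                 standardized = NULL,
                 window_index = seq_len(Nw),
                 dropped_exposures = expo[drop],
                 n_flagged = sum(!ok[, !drop])),
            class = "esp_matrix")
}

#' Standardize the effect-size-profile matrix
#'
#' Centres and scales each exposure's effect sizes across windows (sample
#' standard deviation), yielding the dimensionless profiles that form the
#' clustering feature space. Exposures whose effect size does not vary
#' across windows carry no clustering information and are dropped.
#'
#' @param esp An `esp_matrix` from [build_esp_matrix()] (or a bare numeric
#'   matrix of raw effect sizes).
#' @return The `esp_matrix` with its `standardized` slot filled;
#'   zero-variance exposures appended to `dropped_exposures`.
#' @export
standardize_esp <- function(esp) {
  if (is.matrix(esp)) esp <- structure(
    list(raw = esp, standardized = NULL, window_index = seq_len(nrow(esp)),
         dropped_exposures = character(0), n_flagged = 0L),
    class = "esp_matrix")
  raw <- esp$raw
  if (nrow(raw) < 2L) stop("need at least 2 windows to standardize")
  sdev <- apply(raw, 2, stats::sd)
  keep <- is.finite(sdev) & sdev > 0
  if (!any(keep)) stop("all effect-size columns have zero variance")
  esp$dropped_exposures <- c(esp$dropped_exposures, colnames(raw)[!keep])
  raw <- raw[, keep, drop = FALSE]
  esp$raw <- raw
  esp$standardized <- scale(raw)[, , drop = FALSE]
  attr(esp$standardized, "scaled:center") <- NULL
  attr(esp$standardized, "scaled:scale") <- NULL
  esp
}

#' @export
print.esp_matrix <- function(x, ...) {
  cat("<esp_matrix> ", nrow(x$raw), " windows x ", ncol(x$raw),
      " exposures", if (!is.null(x$standardized)) " (standardized)", "\n",
      sep = "")
  if (length(x$dropped_exposures))
    cat("  dropped: ", paste(x$dropped_exposures, collapse = ", "), "\n")
  invisible(x)
}

#' Write ESP matrices as TSV
#'
#' @param esp An `esp_matrix`.
#' @param path_raw,path_std Output paths (either may be `NULL` to skip).
#' @export
write_esp_matrix <- function(esp, path_raw = NULL, path_std = NULL) {
  dump1 <- function(m, path) {
    df <- data.frame(window = esp$window_index, m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_raw)) dump1(esp$raw, path_raw)
  if (!is.null(path_std) && !is.null(esp$standardized))
    dump1(esp$standardized, path_std)
  invisible(esp)
}
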