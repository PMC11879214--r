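#' Drop exposures and rows with excessive missingness
#'
#' Applies the two-stage missingness filter used for omics matrices:
#' exposure columns missing in more than `column_threshold` of individuals
#' are discarded first, then rows missing more than `row_threshold` of the
#' retained exposures are discarded. Only exposure columns count towards the
#' missing fractions; outcome, covariate and confounder columns are expected
#' complete.
#'
#' @param data Data frame with (possibly incomplete) exposure columns.
#' @param roles A [column_roles()] object; `roles$exposures` restricted to
#'   the surviving columns is returned in the attribute `"roles"`.
#' @param column_threshold,row_threshold Maximum tolerated missing fraction
#'   (defaults 0.2, i.e. the 20% rule).
#' @return The filtered data frame, with attributes `dropped_columns` and
#'   `dropped_rows` recording what was removed and `roles` the updated
#'   role declaration.
#' @export
filter_missingness <- function(data, roles, column_threshold = 0.2,
                               row_threshold = 0.2) {
  stopifnot(column_threshold >= 0, column_threshold <= 1,
            row_threshold >= 0, row_threshold <= 1)
  expo <- intersect(roles$exposures, names(data))
  col_frac <- vapply(data[expo], function(x) mean(is.na(x)), numeric(1))
  keep_cols <- expo[col_frac <= column_threshold]
  if (!length(keep_cols))
    stop("no exposures survive missingness filter")
  dropped_cols <- setdiff(expo, keep_cols)

  row_frac <- rowMeans(is.na(data[keep_cols]))
  keep_rows <- row_frac <= row_threshold
  out <- data[keep_rows, setdiff(names(data), dropped_cols), drop = FALSE]
  rownames(out) <- NULL

  roles$exposures <- keep_cols
  structure(out,
            dropped_columns = dropped_cols,
            dropped_rows = which(!keep_rows),
            roles = roles)
}

#' Impute remaining missing exposures by k nearest neighbours
#'
#' Each missing cell is replaced by the mean of that exposure over the k
#' nearest rows. Distances are mean squared differences over mutually
#' observed exposures, computed on internally standardized values so that
#' no single exposure dominates; imputed values are on the original scale.
#' Only rows where the target exposure is observed qualify as neighbours;
#' rank ties are broken by row order.
#'
#' @param data Data frame (typically the output of [filter_missingness()]).
#' @param roles A [column_roles()] object.
#' @param k Number of neighbours (default 3).
#' @return The completed data frame with attribute `n_imputed`, the number
#'   of cells filled in.
#' @export
impute_knn <- function(data, roles, k = 3) {
  stopifnot(k >= 1)
  expo <- intersect(roles$exposures, names(data))
  x <- as.matrix(data[expo])
  if (!anyNA(x)) return(structure(data, n_imputed = 0L))

  if (any(rowSums(!is.na(x)) == 0L))
    stop("row with all exposures missing; filter it out before imputing")

  mu <- colMeans(x, na.rm = TRUE)
  sdev <- apply(x, 2, stats::sd, na.rm = TRUE)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdev, "/")

  need <- which(rowSums(is.na(x)) > 0L)
  n_imputed <- 0L
  for (i in need) {
    zi <- z[i, ]
    obs_i <- !is.na(zi)
    # mean squared difference over mutually observed exposures
    diff2 <- sweep(z[, obs_i, drop = FALSE], 2, zi[obs_i])^2
    shared <- rowSums(!is.na(diff2))
    d2 <- rowMeans(diff2, na.rm = TRUE)
    d2[shared == 0L] <- Inf
    d2[i] <- Inf
    for (m in which(is.na(x[i, ]))) {
      cand <- which(!is.na(x[, m]) & is.finite(d2))
      if (length(cand) < k)
        stop("fewer than k = ", k, " usable neighbours for row ", i,
             ", exposure '", expo[m], "'")
      nn <- cand[order(d2[cand])[seq_len(k)]]
      x[i, m] <- mean(x[nn, m])
      n_imputed <- n_imputed + 1L
    }
  }
  data[expo] <- as.data.frame(x)
  structure(data, n_imputed = n_imputed)
}

#' Transform and standardize exposures
#'
#' Optionally applies x -> log(1 + x) to every exposure (the usual variance
#' stabilisation for concentration data), then standardizes each exposure to
#' mean 0 and sample standard deviation 1 (denominator N - 1), and returns a
#' validated [observation_table()]. Synthetic benchmark data are used with
#' `log1p = FALSE`.
#'
#' @param data Complete data frame.
#' @param roles A [column_roles()] object.
#' @param log1p Apply the log(1 + x) transform before standardizing?
#' @return An [observation_table()].
#' @export
transform_exposures <- function(data, roles, log1p = TRUE) {
  expo <- roles$exposures
  for (m in expo) {
    v <- data[[m]]
    if (log1p) {
      if (any(v <= -1))
        stop("exposure '", m, "' has values <= -1; log(1+x) undefined")
      v <- log1p(v)
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("exposure '", m, "' has zero variance after transform")
    data[[m]] <- (v - mean(v)) / s
  }
  observation_table(data, roles)
}

#' One-call preprocessing pipeline
#'
#' Runs [filter_missingness()], [impute_knn()] and [transform_exposures()]
#' in sequence and collects a provenance log.
#'
#' @inheritParams filter_missingness
#' @inheritParams impute_knn
#' @inheritParams transform_exposures
#' @return An [observation_table()] with attribute `provenance`: dropped
#'   columns, dropped rows, number of imputed cells.
#' @export
preprocess_observations <- function(data, roles, column_threshold = 0.2,
                                    row_threshold = 0.2, k = 3,
                                    log1p = TRUE) {
  filt <- filter_missingness(data, roles, column_threshold, row_threshold)
  roles2 <- attr(filt, "roles")
  comp <- impute_knn(filt, roles2, k = k)
  obs <- transform_exposures(as.data.frame(comp), roles2, log1p = log1p)
  attr(obs, "provenance") <- list(
    dropped_columns = attr(filt, "dropped_columns"),
    dropped_rows = attr(filt, "dropped_rows"),
    n_imputed = attr(comp, "n_imputed"))
  obs
}

#' Read an observations table from CSV/TSV
#'
#' @param path Path to a delimited file with a header row. The delimiter is
#'   taken from the extension (`.tsv`/`.txt` = tab, otherwise comma).
#' @return A data frame.
#' @export
read_observations <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
}
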