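#' Declare column roles for an observations table
#'
#' Assigns each column of a rectangular dataset to one of the roles used by
#' the pipeline: a single outcome, M omics exposures, J modifier covariates
#' (continuous or discrete) and an optional set of confounders used for
#' within-window adjustment. Confounders may coincide with covariates; all
#' other role sets must be disjoint.
#'
#' @param outcome Name of the outcome column.
#' @param exposures Character vector of exposure (omics) column names.
#' @param covariates Character vector of modifier covariate column names.
#' @param outcome_family `"continuous"` (linear slopes) or `"binary"`
#'   (logistic odds ratios; the column must be coded 0/1).
#' @param covariate_types Character vector, one of `"continuous"` or
#'   `"discrete"` per covariate. Recycled if length 1. Discrete covariates
#'   (e.g. numerically encoded sex) stratify the window cover instead of
#'   being covered by gliding windows.
#' @param confounders Character vector of confounder column names; may
#'   overlap `covariates`, may be empty.
#' @return An object of class `column_roles`.
#' @export
column_roles <- function(outcome, exposures, covariates,
                         outcome_family = c("continuous", "binary"),
                         covariate_types = "continuous",
                         confounders = character()) {
  outcome_family <- match.arg(outcome_family)
  stopifnot(length(outcome) == 1L, length(exposures) >= 1L,
            length(covariates) >= 1L)
  covariate_types <- rep_len(covariate_types, length(covariates))
  if (!all(covariate_types %in% c("continuous", "discrete")))
    stop("covariate_types must be 'continuous' or 'discrete'")
  names(covariate_types) <- covariates

  if (outcome %in% c(exposures, covariates, confounders))
    stop("outcome column '", outcome, "' cannot hold another role")
  if (length(intersect(exposures, covariates)))
    stop("exposures and covariates must be disjoint")
  if (length(setdiff(intersect(confounders, exposures), character(0))))
    stop("confounders may overlap covariates but not exposures")

  structure(
    list(outcome = outcome, outcome_family = outcome_family,
         exposures = exposures, covariates = covariates,
         covariate_types = covariate_types, confounders = confounders),
    class = "column_roles")
}

continuous_covariates <- function(roles)
  roles$covariates[roles$covariate_types[roles$covariates] == "continuous"]

discrete_covariates <- function(roles)
  roles$covariates[roles$covariate_types[roles$covariates] == "discrete"]

#' Assemble a validated observations table
#'
#' Bundles a complete (no missing values) data frame with its declared
#' column roles. Validation enforces the pipeline's entry contract: all role
#' columns present and numeric, no missing values, a 0/1 coding for a binary
#' outcome, and at least two observations.
#'
#' @param data Data frame holding all role columns.
#' @param roles A [column_roles()] object.
#' @return An object of class `observation_table` with elements `data`,
#'   `roles` and `n_obs`.
#' @export
observation_table <- function(data, roles) {
  stopifnot(inherits(roles, "column_roles"), is.data.frame(data))
  used <- unique(c(roles$outcome, roles$exposures, roles$covariates,
                   roles$confounders))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[, used, drop = FALSE]
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("all role columns must be numeric (encode discrete covariates numerically)")
  if (anyNA(data))
    stop("observation_table requires complete data; run the preprocessing ",
         "steps (missingness filter, kNN imputation) first")
  if (nrow(data) < 2L) stop("need at least 2 observations")
  if (roles$outcome_family == "binary") {
    y <- data[[roles$outcome]]
    if (!all(y %in% c(0, 1)) || length(unique(y)) != 2L)
      stop("binary outcome must contain exactly the codes {0, 1}")
  }
  structure(list(data = data, roles = roles, n_obs = nrow(data)),
            class = "observation_table")
}

#' @export
print.observation_table <- function(x, ...) {
  r <- x$roles
  cat("<observation_table> ", x$n_obs, " observations\n", sep = "")
  cat("  outcome:    ", r$outcome, " (", r$outcome_family, ")\n", sep = "")
  cat("  exposures:  ", length(r$exposures), "\n", sep = "")
  cat("  covariates: ", paste0(r$covariates, " [",
                               r$covariate_types[r$covariates], "]",
                               collapse = ", "), "\n", sep = "")
  if (length(r$confounders))
    cat("  confounders:", paste(r$confounders, collapse = ", "), "\n")
  invisible(x)
}
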