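#' End-to-end effect-modifier analysis
#'
#' Runs the full pipeline on a prepared observations table: data-driven
#' window geometry, overlapping-window cover of the covariate space,
#' per-window effect-size profiles, standardization, cluster-number
#' selection with the reference-null elbow test, and region summaries.
#'
#' @param obs An [observation_table()], a `synthetic_dataset` from
#'   [generate_dataset()], or a data frame (then `roles` is required).
#' @param roles A [column_roles()] object when `obs` is a data frame.
#' @param n_target Target observations per window used for the automatic
#'   geometry (default 20).
#' @param percentile Percentile for the window sides (default 95).
#' @param min_obs Window occupancy floor (default `n_target`).
#' @param min_class_count Per-class floor for binary outcomes (default 5).
#' @param L,step Optional manual window sides / gliding steps (named or in
#'   continuous-covariate order), overriding the automatic geometry.
#' @param L_scale,step_scale Scale factors applied to the (automatic or
#'   manual) sides and steps — the knobs used by sensitivity analyses such
#'   as halving the steps or enlarging the windows by 1.5.
#' @param confounders Columns adjusted for inside each window. `NULL`
#'   (default) adjusts for the continuous modifier covariates themselves;
#'   use `character(0)` for unadjusted univariate effect sizes.
#' @param or_scale Cluster binary effect sizes on the odds-ratio scale
#'   instead of the default log-odds-ratio scale (see
#'   [build_esp_matrix()]).
#' @param alpha,nref,kmax,fixed_k,early_stop Passed to
#'   [select_clusters()].
#' @param seed Integer seed for the reference-null draws.
#' @param outdir Optional directory; when given, all reports (config,
#'   cover, ESP matrices, selection JSON, regions, per-observation fuzzy
#'   membership, log) are written there.
#' @return Object of class `esp_fit`: `obs`, `geometry`, `cover`, `esp`,
#'   `selection`, `regions`, `config`.
#' @export
esp_run <- function(obs, roles = NULL,
                    n_target = 20, percentile = 95,
                    min_obs = n_target, min_class_count = 5,
                    L = NULL, step = NULL, L_scale = 1, step_scale = 1,
                    confounders = NULL, or_scale = FALSE,
                    alpha = 1e-3, nref = 2000, kmax = NULL,
                    fixed_k = NULL, early_stop = FALSE,
                    elbow_from = c("kmeans", "agglomerative"),
                    seed = NULL, outdir = NULL) {
  elbow_from <- match.arg(elbow_from)
  if (inherits(obs, "synthetic_dataset"))
    obs <- observation_table(obs$data, obs$roles)
  if (is.data.frame(obs)) {
    if (is.null(roles)) stop("supply `roles` with a data-frame input")
    obs <- observation_table(obs, roles)
  }
  stopifnot(inherits(obs, "observation_table"))
  ccov <- continuous_covariates(obs$roles)
  if (is.null(confounders)) confounders <- ccov

  sides <- neighborhood_box_sides(obs$data[ccov], n_target)
  geom <- window_geometry(sides, percentile = percentile, n = n_target)
  if (!is.null(L)) geom$L[] <- rep_len(unname(L), length(geom$L))
  if (!is.null(step)) geom$step[] <- rep_len(unname(step), length(geom$step))
  geom$L <- geom$L * L_scale
  geom$step <- geom$step * step_scale

  cover <- enumerate_windows(obs, geom, min_obs = min_obs,
                             min_class_count = min_class_count)
  esp <- standardize_esp(
    build_esp_matrix(cover, obs, confounders = confounders,
                     or_scale = or_scale))
  selection <- select_clusters(esp, alpha = alpha, nref = nref,
                               kmax = kmax, seed = seed, fixed_k = fixed_k,
                               early_stop = early_stop,
                               elbow_from = elbow_from)
  regions <- summarize_regions(esp, selection$labels, cover)

  config <- list(n_target = n_target, percentile = percentile,
                 min_obs = min_obs, min_class_count = min_class_count,
                 L = as.list(geom$L), step = as.list(geom$step),
                 L_scale = L_scale, step_scale = step_scale,
                 confounders = confounders, or_scale = or_scale,
                 alpha = alpha, nref = nref,
                 kmax = kmax, fixed_k = fixed_k, early_stop = early_stop,
                 seed = seed)
  fit <- structure(list(obs = obs, geometry = geom, cover = cover,
                        esp = esp, selection = selection,
                        regions = regions, config = config),
                   class = "esp_fit")
  if (!is.null(outdir)) write_fit_artifacts(fit, outdir)
  fit
}

write_fit_artifacts <- function(fit, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  jsonlite::write_json(fit$config, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       na = "null")
  write_cover_report(fit$cover, p("cover.tsv"))
  write_esp_matrix(fit$esp, p("esp_raw.tsv"), p("esp_standardized.tsv"))
  write_selection_json(fit$selection, p("selection.json"))
  write_region_report(fit$regions, p("regions.tsv"), p("midpoints.tsv"))
  covs <- fit$obs$roles$covariates
  memb <- membership_table(fit$cover, fit$selection$labels,
                           fit$obs$data[covs])
  utils::write.table(memb, p("membership.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("observations: %d", fit$obs$n_obs),
    sprintf("windows retained: %d of %d candidates",
            fit$cover$n_retained, fit$cover$n_candidate),
    sprintf("exposures clustered: %d (dropped: %s)", ncol(fit$esp$raw),
            if (length(fit$esp$dropped_exposures))
              paste(fit$esp$dropped_exposures, collapse = ", ") else "none"),
    sprintf("flagged effect-size fits: %d", fit$esp$n_flagged),
    sprintf("k_final: %d (p = %s)", fit$selection$k_final,
            format(fit$selection$p_value))), p("log.txt"))
  invisible(fit)
}

#' @export
print.esp_fit <- function(x, ...) {
  cat("<esp_fit>\n")
  print(x$cover)
  print(x$selection)
  print(x$regions)
  invisible(x)
}

#' Monte-Carlo validation on the benchmark designs
#'
#' Generates `n_datasets` replicates of a benchmark design, runs the full
#' pipeline on each (automatic window geometry at `n_target`, unadjusted
#' univariate logistic effect sizes, automatic cluster-number selection)
#' and tabulates the selected number of clusters — one row of the
#' contingency matrix between true region count and identified cluster
#' count. Sensitivity variants are available through `L_scale` /
#' `step_scale`.
#'
#' Replicate seeds are drawn deterministically from `seed`, so results are
#' reproducible and independent of any parallel execution order.
#'
#' @inheritParams generate_dataset
#' @inheritParams esp_run
#' @param n_datasets Number of replicates.
#' @param seed Master seed.
#' @return Object of class `esp_validation`: `counts` (named table of
#'   `k_final` frequencies), `k_final` per replicate (`NA` on failure),
#'   `n_failed`, `design`, `n_datasets` and the parameters used.
#' @export
esp_validate <- function(design, n_datasets, seed = 1,
                         n_target = 20, alpha = 1e-3,
                         L_scale = 1, step_scale = 1,
                         nref = 2000, kmax = NULL,
                         smoothing_width = 0.05,
                         min_class_count = 5, early_stop = TRUE,
                         elbow_from = c("kmeans", "agglomerative")) {
  elbow_from <- match.arg(elbow_from)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  k_final <- rep(NA_integer_, n_datasets)
  for (i in seq_len(n_datasets)) {
    k_final[i] <- tryCatch({
      ds <- generate_dataset(design, seed = rep_seeds[i],
                             smoothing_width = smoothing_width)
      fit <- esp_run(ds, n_target = n_target, alpha = alpha,
                     L_scale = L_scale, step_scale = step_scale,
                     nref = nref, kmax = kmax,
                     min_class_count = min_class_count,
                     confounders = character(0), elbow_from = elbow_from,
                     early_stop = early_stop, seed = rep_seeds[i])
      fit$selection$k_final
    }, error = function(e) NA_integer_)
  }
  counts <- table(factor(k_final, levels = seq_len(max(5, k_final,
                                                       na.rm = TRUE))))
  structure(list(counts = counts, k_final = k_final,
                 n_failed = sum(is.na(k_final)), design = design,
                 n_datasets = n_datasets, seed = seed,
                 params = list(n_target = n_target, alpha = alpha,
                               L_scale = L_scale, step_scale = step_scale,
                               nref = nref, kmax = kmax,
                               smoothing_width = smoothing_width)),
            class = "esp_validation")
}

#' @export
print.esp_validation <- function(x, ...) {
  cat("<esp_validation> design ", x$design, ", ", x$n_datasets,
      " replicates (", x$n_failed, " failed)\n", sep = "")
  print(x$counts)
  invisible(x)
}
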