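# Small fixture builders used across the test files.

# A complete toy observations table with a continuous outcome.
toy_obs <- function(n = 40, m = 3, seed = 1, family = "continuous") {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("X", 1:m)))
  df <- data.frame(
    Y = if (family == "binary") rep_len(c(0, 1), n) else rnorm(n),
    x, Z1 = runif(n), Z2 = runif(n))
  roles <- column_roles("Y", paste0("X", 1:m), c("Z1", "Z2"),
                        outcome_family = family)
  observation_table(df, roles)
}

# A 1-D cover with hand-set geometry on covariate values spanning [0, 1].
toy_cover_1d <- function(z, L = 0.4, step = 0.16, min_obs = 1) {
  df <- data.frame(Y = rnorm(length(z)), X1 = rnorm(length(z)), Z1 = z)
  roles <- column_roles("Y", "X1", "Z1")
  obs <- observation_table(df, roles)
  geom <- structure(list(L = c(Z1 = L), step = c(Z1 = step),
                         n_target = NULL, percentile = 95),
                    class = "window_geometry")
  list(obs = obs, cover = enumerate_windows(obs, geom, min_obs = min_obs))
}

# Two well-separated Gaussian blobs in feature space.
blob_matrix <- function(n_per = 15, m = 5, sep = 20, seed = 1, k = 2) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(c)
    matrix(rnorm(n_per * m, mean = c * sep), n_per, m)))
}

# Shared Monte-Carlo validation runs (expensive); memoised per session so
# the contingency criteria and the sensitivity ordering reuse them.
.mc_cache <- new.env(parent = emptyenv())
cached_validation <- function(key, design, n_datasets, ...) {
  if (is.null(.mc_cache[[key]]))
    .mc_cache[[key]] <- esp_validate(design, n_datasets, seed = 1, ...)
  .mc_cache[[key]]
}

rate_of <- function(v, k) 100 * mean(!is.na(v$k_final) & v$k_final == k)
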