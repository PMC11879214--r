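test_that("neighbourhood boxes match hand-derived side lengths", {
  # 1-D points {0, 1, 3}, n = 2: nearest neighbour of 0 is 1, of 1 is 0,
  # of 3 is 1 -> box sides (1, 1, 2)
  sides <- neighborhood_box_sides(matrix(c(0, 1, 3)), n = 2)
  expect_equal(as.vector(sides), c(1, 1, 2))

  # n = N: every box is the full per-dimension range
  set.seed(1)
  z <- cbind(runif(15), runif(15, 10, 20))
  sides_all <- neighborhood_box_sides(z, n = 15)
  expect_equal(unname(sides_all[1, ]), unname(apply(z, 2, max) - apply(z, 2, min)))
  expect_true(all(apply(sides_all, 2, function(s) length(unique(s)) == 1L)))

  # duplicated points give a zero box for the duplicated observation
  zd <- matrix(c(0, 0, 5, 9))
  expect_equal(neighborhood_box_sides(zd, 2)[1, ], c(0))

  expect_error(neighborhood_box_sides(matrix(1:3), 4), "exceeds")
  expect_error(neighborhood_box_sides(matrix(1), 1), "at least 2")
})

test_that("window geometry takes the interpolated percentile and the minimum step", {
  g <- window_geometry(matrix(c(0.1, 0.2, 0.4)), percentile = 95)
  expect_equal(unname(g$L), 0.38)   # type-7 interpolation by hand
  expect_equal(unname(g$step), 0.1)

  gc <- window_geometry(matrix(rep(0.3, 6)))
  expect_equal(unname(gc$L), 0.3)
  expect_equal(unname(gc$step), 0.3)

  # zero minimum falls back to the smallest positive side
  gz <- window_geometry(matrix(c(0, 0, 0.2, 0.5)))
  expect_equal(unname(gz$step), 0.2)
  expect_error(window_geometry(matrix(rep(0, 4))), "degenerate")

  # monotonicity: enlarging the neighbourhood never shrinks any side
  set.seed(2)
  z <- cbind(runif(60), runif(60))
  for (n in c(10, 20, 30)) {
    L_small <- window_geometry(neighborhood_box_sides(z, n))$L
    L_big <- window_geometry(neighborhood_box_sides(z, n + 10))$L
    expect_true(all(L_big >= L_small - 1e-12))
  }
})

test_that("candidate grid follows Zmin + i*step and the documented count", {
  # covariates spanning [0,1] exactly, step 0.16 -> nj = 6, 49 candidates
  set.seed(4)
  n <- 60
  df <- data.frame(Y = rnorm(n), X1 = rnorm(n),
                   Z1 = c(0, 1, runif(n - 2)), Z2 = c(0, 1, runif(n - 2)))
  obs <- observation_table(df, column_roles("Y", "X1", c("Z1", "Z2")))
  geom <- structure(list(L = c(Z1 = 0.4, Z2 = 0.4),
                         step = c(Z1 = 0.16, Z2 = 0.16),
                         n_target = NULL, percentile = 95),
                    class = "window_geometry")
  cov <- enumerate_windows(obs, geom, min_obs = 1)
  expect_equal(cov$n_candidate, 49L)
  expect_true(all(cov$centers %in% (0 + (0:6) * 0.16)))

  # with min_obs = 1, every observation lies in at least one retained window
  hits <- vapply(seq_len(n), function(i)
    length(point_windows(cov, df[i, c("Z1", "Z2")])), integer(1))
  expect_true(all(hits >= 1L))

  expect_error(enumerate_windows(obs, geom, min_obs = n + 1), "cover is empty")
})

test_that("window membership equals exhaustive interval checks (oracle)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:30, 1)
    df <- data.frame(Y = rnorm(n), X1 = rnorm(n),
                     Z1 = runif(n), Z2 = runif(n, -2, 5))
    obs <- observation_table(df, column_roles("Y", "X1", c("Z1", "Z2")))
    geom <- window_geometry(neighborhood_box_sides(df[c("Z1", "Z2")],
                                                   max(3, n %/% 3)))
    cov <- enumerate_windows(obs, geom, min_obs = 1)
    for (w in cov$windows) {
      inside <- abs(df$Z1 - w$center[["Z1"]]) <= geom$L[["Z1"]] / 2 &
                abs(df$Z2 - w$center[["Z2"]]) <= geom$L[["Z2"]] / 2
      expect_identical(w$member_idx, which(inside))
    }
  }
})

test_that("occupancy floor and binary class floor are enforced", {
  # every retained window satisfies min_obs = n across seeds
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    df <- data.frame(Y = rnorm(n), X1 = rnorm(n),
                     Z1 = runif(n), Z2 = runif(n))
    obs <- observation_table(df, column_roles("Y", "X1", c("Z1", "Z2")))
    geom <- window_geometry(neighborhood_box_sides(df[c("Z1", "Z2")], 20),
                            n = 20)
    cov <- enumerate_windows(obs, geom)
    sizes <- vapply(cov$windows, function(w) length(w$member_idx), 1L)
    expect_true(all(sizes >= 20))
  }

  # binary outcomes additionally require both classes in every window
  set.seed(9)
  n <- 120
  df <- data.frame(Y = rep(c(0, 1), n / 2), X1 = rnorm(n),
                   Z1 = runif(n), Z2 = runif(n))
  obs <- observation_table(df, column_roles("Y", "X1", c("Z1", "Z2"),
                                            outcome_family = "binary"))
  geom <- window_geometry(neighborhood_box_sides(df[c("Z1", "Z2")], 15))
  cov <- enumerate_windows(obs, geom, min_obs = 15, min_class_count = 5)
  y <- df$Y
  for (w in cov$windows)
    expect_true(min(table(y[w$member_idx])) >= 5)
})

test_that("discrete covariates stratify the cover", {
  set.seed(10)
  n <- 160
  df <- data.frame(Y = rnorm(n), X1 = rnorm(n),
                   Z1 = runif(n), sex = rep(c(0, 1), each = n / 2))
  roles <- column_roles("Y", "X1", c("Z1", "sex"),
                        covariate_types = c("continuous", "discrete"))
  obs <- observation_table(df, roles)
  geom <- window_geometry(neighborhood_box_sides(df["Z1"], 15))
  cov <- enumerate_windows(obs, geom, min_obs = 5)
  # candidate grid duplicated per stratum
  expect_equal(cov$n_candidate %% 2L, 0L)
  expect_setequal(unique(cov$strata$sex), c(0, 1))
  # members never cross strata
  for (i in seq_len(cov$n_retained))
    expect_true(all(df$sex[cov$windows[[i]]$member_idx] ==
                      cov$strata$sex[i]))
  # point lookup respects the stratum
  idx <- point_windows(cov, c(Z1 = 0.5, sex = 0))
  expect_true(all(cov$strata$sex[idx] == 0))
})

test_that("point lookup matches the 1-D hand case and returns empty outside", {
  set.seed(11)
  tc <- toy_cover_1d(c(0, 1, runif(40)))
  hits <- point_windows(tc$cover, c(Z1 = 0.3))
  expect_equal(sort(tc$cover$centers[hits, 1]),
               c(0.16, 0.32, 0.48), tolerance = 1e-12)
  # a window's own centre is always inside it
  expect_true(1L %in% point_windows(tc$cover,
                                    c(Z1 = tc$cover$centers[1, 1])))
  expect_length(point_windows(tc$cover, c(Z1 = 7)), 0)
})
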