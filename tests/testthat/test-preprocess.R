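roles4 <- column_roles("Y", paste0("X", 1:4), "Z1")

test_that("missingness filter drops columns first, then rows", {
  # 10 x 4 exposures: X2 missing 3/10 (> 20% -> dropped); after the drop,
  # row 1 misses 2 of the 3 surviving exposures (> 20% -> dropped)
  df <- data.frame(Y = rnorm(10), Z1 = runif(10),
                   X1 = c(NA, 2:10), X2 = c(1, NA, NA, NA, 5:10),
                   X3 = c(NA, 2:10), X4 = 1:10)
  out <- filter_missingness(df, roles4)
  expect_equal(attr(out, "dropped_columns"), "X2")
  expect_equal(attr(out, "dropped_rows"), 1L)
  expect_equal(dim(out[attr(out, "roles")$exposures]), c(9L, 3L))
  expect_equal(attr(out, "roles")$exposures, c("X1", "X3", "X4"))

  # idempotence: a second pass changes nothing
  out2 <- filter_missingness(as.data.frame(out), attr(out, "roles"))
  expect_equal(as.data.frame(out2), as.data.frame(out),
               ignore_attr = TRUE)

  # a column with exactly 25% missing is dropped at the 20% threshold
  df2 <- data.frame(Y = rnorm(8), Z1 = runif(8),
                    X1 = c(NA, NA, 3:8), X2 = 1:8, X3 = 1:8, X4 = 1:8)
  expect_true("X1" %in% attr(filter_missingness(df2, roles4),
                             "dropped_columns"))

  # fully observed tables pass through untouched
  df3 <- data.frame(Y = rnorm(5), Z1 = runif(5), X1 = 1:5, X2 = 1:5,
                    X3 = 1:5, X4 = 1:5)
  expect_equal(as.data.frame(filter_missingness(df3, roles4)), df3,
               ignore_attr = TRUE)

  expect_error(filter_missingness(
    data.frame(Y = 1:4, Z1 = 1:4, X1 = NA_real_, X2 = NA_real_,
               X3 = NA_real_, X4 = NA_real_), roles4),
    "no exposures survive")
})

test_that("kNN imputation averages the k nearest rows and preserves observed cells", {
  roles2 <- column_roles("Y", c("X1", "X2"), "Z1")
  # 5-row toy; row 1 misses X2. Distances from row 1 on standardized X1
  # rank rows (2,3,4) as the 3 nearest; imputed value = mean of their X2.
  df <- data.frame(Y = rnorm(5), Z1 = runif(5),
                   X1 = c(0, 0.1, -0.1, 0.2, 3),
                   X2 = c(NA, 10, 12, 14, 50))
  out <- impute_knn(df, roles2, k = 3)
  expect_equal(out$X2[1], mean(c(10, 12, 14)))
  expect_equal(attr(out, "n_imputed"), 1L)
  expect_identical(out$X1, df$X1)          # observed cells bit-identical
  expect_identical(out$X2[-1], df$X2[-1])

  # k = 1 takes the single nearest neighbour's value
  out1 <- impute_knn(df, roles2, k = 1)
  expect_equal(out1$X2[1], 10)

  # nothing to impute -> identical table
  full <- data.frame(Y = 1:4, Z1 = 1:4, X1 = c(1, 2, 3, 4),
                     X2 = c(4, 3, 2, 1))
  expect_equal(as.data.frame(impute_knn(full, roles2, k = 3)), full,
               ignore_attr = TRUE)

  # a row with every exposure missing must be filtered before imputing
  bad <- data.frame(Y = 1:3, Z1 = 1:3, X1 = c(NA, 1, 2), X2 = c(NA, 1, 2))
  expect_error(impute_knn(bad, roles2, k = 1), "all exposures missing")
})

test_that("exposure transform standardizes to mean 0 / sample SD 1", {
  roles1 <- column_roles("Y", "X1", "Z1")
  df <- data.frame(Y = rnorm(3), Z1 = runif(3), X1 = c(1, 2, 3))
  obs <- transform_exposures(df, roles1, log1p = FALSE)
  expect_equal(obs$data$X1, c(-1, 0, 1))   # sample SD of (1,2,3) is 1

  # log(1 + x) applied before standardization: exp(1)-1 maps to 1, and a
  # symmetric pre-image gives a symmetric standardized column
  df2 <- data.frame(Y = rnorm(3), Z1 = runif(3),
                    X1 = exp(c(0, 1, 2)) - 1)
  obs2 <- transform_exposures(df2, roles1, log1p = TRUE)
  expect_equal(obs2$data$X1, c(-1, 0, 1))

  expect_error(transform_exposures(
    data.frame(Y = 1:3, Z1 = 1:3, X1 = c(-1.5, 1, 2)), roles1),
    "X1")
  expect_error(transform_exposures(
    data.frame(Y = 1:3, Z1 = 1:3, X1 = rep(0, 3)), roles1),
    "zero variance")

  # mean/SD contract on random matrices
  set.seed(42)
  for (r in 1:5) {
    df3 <- data.frame(Y = rnorm(30), Z1 = runif(30),
                      matrix(rexp(30 * 4), 30,
                             dimnames = list(NULL, paste0("X", 1:4))))
    obs3 <- transform_exposures(df3, roles4, log1p = TRUE)
    x <- as.matrix(obs3$data[paste0("X", 1:4)])
    expect_true(all(abs(colMeans(x)) < 1e-10))
    expect_true(all(abs(apply(x, 2, sd) - 1) < 1e-10))
  }
})

test_that("the one-call pipeline validates its output table", {
  set.seed(3)
  df <- data.frame(Y = rep(c(0, 1), 15), Z1 = runif(30),
                   matrix(rexp(30 * 6), 30,
                          dimnames = list(NULL, paste0("X", 1:6))))
  df$X1[c(2, 5)] <- NA   # 1/6 of a row missing stays under the 20% rule
  roles <- column_roles("Y", paste0("X", 1:6), "Z1",
                        outcome_family = "binary")
  obs <- preprocess_observations(df, roles)
  expect_s3_class(obs, "observation_table")
  expect_false(anyNA(obs$data))
  expect_equal(attr(obs, "provenance")$n_imputed, 2L)
})
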