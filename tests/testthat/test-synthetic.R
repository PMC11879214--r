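test_that("region membership matches the design geometry", {
  # crisp D2: (0.2, 0.8) is region A because Z1 <= 0.5
  expect_equal(region_membership("D2", c(0.2, 0.8), 0)[1, "A"], c(A = 1))
  expect_equal(region_membership("D2", c(0.7, 0.8), 0)[1, "B"], c(B = 1))
  # on the Z1 = 0.5 boundary with a narrow ramp, P(B) ~ 1/2
  expect_equal(region_membership("D2", c(0.5, 0.8), 0.05)[1, "B"],
               c(B = 0.5), tolerance = 5e-3)

  # crisp D3 areas over the unit square: (1/2, 1/4, 1/4)
  g <- seq(0.005, 0.995, by = 0.01)
  grid <- as.matrix(expand.grid(g, g))
  areas <- colMeans(region_membership("D3", grid, 0))
  expect_equal(unname(areas), c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # probabilities always sum to one, smoothed or crisp
  set.seed(41)
  zs <- matrix(runif(400), ncol = 2)
  for (d in c("D1", "D2", "D3")) for (w in c(0, 0.05, 0.2))
    expect_equal(rowSums(region_membership(d, zs, w)),
                 rep(1, 200), tolerance = 1e-12)

  expect_error(region_membership("D9", c(0.5, 0.5)), "unknown design")
})

test_that("generated datasets honour class balance, moments and determinism", {
  ds <- generate_dataset("D1", seed = 1)
  expect_equal(as.integer(table(ds$data$Y)), c(100L, 100L))
  expect_identical(ds$data, generate_dataset("D1", seed = 1)$data)

  # D1: exposures independent of Y and Z, mean ~2, SD ~0.5
  x <- as.matrix(ds$data[paste0("X", 1:30)])
  expect_equal(mean(x), 2, tolerance = 0.02)
  expect_equal(sd(x), 0.5, tolerance = 0.02)

  # per-column SD lands in [0.45, 0.55] almost always
  sds <- unlist(lapply(1:50, function(s) {
    d <- generate_dataset("D1", seed = s)
    apply(as.matrix(d$data[paste0("X", 1:30)]), 2, sd)
  }))
  expect_gte(mean(sds >= 0.45 & sds <= 0.55), 0.95)

  # D2 cases deep in region B: the three variable sets centre at
  # 2, 2.7 and 1.3
  ds2 <- generate_dataset("D2", seed = 2, smoothing_width = 0)
  b <- ds2$data$Y == 1 & ds2$true_region == "B"
  xb <- as.matrix(ds2$data[paste0("X", 1:30)])[b, ]
  sets <- ds2$sets$B
  expect_equal(mean(xb[, sets[[1]]]), 2, tolerance = 0.1)
  expect_equal(mean(xb[, sets[[2]]]), 2.7, tolerance = 0.1)
  expect_equal(mean(xb[, sets[[3]]]), 1.3, tolerance = 0.1)
  # controls keep the null distribution everywhere
  x0 <- as.matrix(ds2$data[paste0("X", 1:30)])[ds2$data$Y == 0, ]
  expect_equal(mean(x0), 2, tolerance = 0.03)

  # D3 uses an independent set partition in region C
  ds3 <- generate_dataset("D3", seed = 3)
  expect_false(identical(ds3$sets$B, ds3$sets$C))
})

test_that("shifted exposures associate with the outcome only inside region B", {
  # mean |log odds ratio| of the shifted variables, region B vs region A
  set.seed(44)
  diffs <- vapply(1:30, function(s) {
    ds <- generate_dataset("D2", seed = s, smoothing_width = 0)
    shifted <- unlist(ds$sets$B[2:3])
    crisp <- ds$data$Z1 > 0.5 & ds$data$Z2 > 0.5
    lnor <- function(rows) mean(vapply(shifted, function(m)
      abs(fit_window_effect(ds$data$Y[rows], ds$data[[paste0("X", m)]][rows],
                            family = "binary")$beta), numeric(1)))
    lnor(which(crisp)) - lnor(which(!crisp))
  }, numeric(1))
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 1e-6)
})

test_that("reference matrices stay inside the template's column ranges", {
  set.seed(45)
  tpl <- cbind(runif(50, -3, -1), runif(50, 10, 20), rep(4, 50))
  ref <- generate_reference_matrix(tpl, seed = 9)
  expect_equal(dim(ref), dim(tpl))
  expect_true(all(ref[, 1] >= min(tpl[, 1]) & ref[, 1] <= max(tpl[, 1])))
  expect_equal(ref[, 3], rep(4, 50))   # degenerate range stays constant

  # uniform mean: column averages over many draws near (min + max) / 2
  means <- rowMeans(replicate(200, colMeans(
    generate_reference_matrix(tpl))))
  mid <- (apply(tpl, 2, min) + apply(tpl, 2, max)) / 2
  expect_equal(unname(means), unname(mid), tolerance = 0.05)
})

test_that("datasets round-trip through the CSV writer with a truth sidecar", {
  tmp <- file.path(tempdir(), "d2_sim.csv")
  ds <- simulate_esp_data("D2", seed = 5, out = tmp)
  back <- read_observations(tmp)
  expect_equal(back, ds$data, tolerance = 1e-12)
  truth_path <- sub("\\.csv$", "_truth.json", tmp)
  expect_true(file.exists(truth_path))
  truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  expect_equal(truth$design, "D2")
  expect_equal(truth$true_region, ds$true_region)
  unlink(c(tmp, truth_path))
})
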