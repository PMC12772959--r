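test_that("projection is an expectation: constants, linearity, hand case", {
  mm <- tiny_mapping()
  one <- project_feature(mm, c(1, 1))
  expect_equal(one$values, matrix(1, 2, 2))
  f1 <- c(3, 7)
  fld <- project_feature(mm, f1)
  expect_equal(as.numeric(fld$values), c(3, 7, 5, 7))
  f2 <- c(-1, 2)
  lin <- project_feature(mm, 2 * f1 + 3 * f2)
  expect_equal(lin$values,
               2 * fld$values + 3 * project_feature(mm, f2)$values,
               tolerance = 1e-9)
  expect_error(project_feature(mm, 1:3), "length")
  expect_error(project_feature(mm, c(1, NA)), "finite")
})

test_that("projected fields stay within the feature's range", {
  tis <- small_tissue(seed = 33)
  imp <- impute_expression(tis$expr)
  sg <- aggregate_reads(tis$reads, tis$grid, tis$panel)
  mm <- map_cells(imp, sg, models = fit_all_landmarks(imp, sg$panel,
                                                      k_range = 2:3, seed = 1))
  f <- imp[, "LM01"]
  fld <- project_feature(mm, f)
  expect_gte(min(fld$values), min(f) - 1e-9)
  expect_lte(max(fld$values), max(f) + 1e-9)
})

test_that("indicator projections are probabilities that sum over a partition", {
  mm <- tiny_mapping()
  labels <- c("podo", "endo")
  fa <- project_indicator(mm, labels, "podo")
  fb <- project_indicator(mm, labels, "endo")
  expect_true(all(fa$values >= 0 & fa$values <= 1))
  expect_equal(fa$values + fb$values, matrix(1, 2, 2), tolerance = 1e-12)
  # all cells in the target: certainty everywhere
  expect_equal(project_indicator(mm, c("x", "x"), "x")$values, matrix(1, 2, 2))
  expect_error(project_indicator(mm, labels, "missing"), "missing")
})

test_that("Gaussian smoothing preserves constants and the kernel shape", {
  mm <- tiny_mapping()
  fld <- project_feature(mm, c(1, 1))
  expect_identical(smooth_field(fld, 0), fld)
  expect_equal(smooth_field(fld, 1)$values, fld$values, tolerance = 1e-9)
  # impulse response: ratio of offsets 1 and 0 follows exp(-1/(2 sigma^2))
  g <- grid_spec(512, 512, 16)
  imp <- structure(list(values = matrix(0, 32, 32), name = "imp", sigma = 0,
                        provenance = "score", grid = g),
                   class = "spatial_field")
  imp$values[16, 16] <- 1
  sm <- smooth_field(imp, sigma = 1.5)
  expect_equal(sm$values[17, 16] / sm$values[16, 16],
               exp(-1 / (2 * 1.5^2)), tolerance = 1e-9)
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)  # mass conserved
  expect_error(smooth_field(imp, -1), "sigma")
})

test_that("percentile thresholds act on non-zero values with >= ties", {
  g <- grid_spec(160, 160, 16)
  fld <- structure(list(values = matrix(0, 10, 10), name = "f", sigma = 0,
                        provenance = "score", grid = g),
                   class = "spatial_field")
  fld$values[] <- 1:100
  tr <- threshold_percentile(fld, 95)
  expect_equal(sum(tr$mask), 5L)  # 96..100 plus the >=-tied threshold value
  expect_equal(sum(threshold_percentile(fld, 0)$mask), 100L)
  expect_equal(sum(threshold_percentile(fld, 100)$mask), 1L)
  fld$values[] <- 0
  expect_error(threshold_percentile(fld, 95), "non-zero")
})

test_that("elbow threshold finds a synthetic hinge and scales affinely", {
  g <- grid_spec(320, 320, 16)
  lo <- seq(0.01, 0.2, length.out = 120)        # shallow background ramp
  hi <- seq(0.25, 6, length.out = 40)           # steep signal ramp
  v <- matrix(0, 20, 20)
  v[seq_along(c(lo, hi))] <- c(lo, hi)
  fld <- structure(list(values = v, name = "f", sigma = 0,
                        provenance = "score", grid = g),
                   class = "spatial_field")
  tr <- auto_threshold(fld, k = 20)
  # the intersection must sit near the hinge between the two ramps
  u <- sort(unique(v[v > 0]))
  hinge_idx <- which.min(abs(u - 0.25))
  thr_idx <- which.min(abs(u - tr$threshold))
  expect_lte(abs(thr_idx - hinge_idx), 15)
  # affine equivariance
  fld10 <- fld; fld10$values <- fld$values * 10
  expect_equal(auto_threshold(fld10, k = 20)$threshold, 10 * tr$threshold,
               tolerance = 1e-9)
  # degenerate input
  flat <- fld; flat$values[] <- 0; flat$values[1:3] <- 1
  expect_error(auto_threshold(flat, k = 20), "unique")
  expect_error(auto_threshold(fld, k = 1), "k must")
})

test_that("composite rendering respects masks and grid agreement", {
  mm <- tiny_mapping()
  fa <- project_feature(mm, c(1, 0))
  fb <- project_feature(mm, c(0, 1))
  img <- composite_render(list(fa, fb), c("red", "green"), point_um = 0)
  expect_equal(dim(img), c(2, 2, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_error(composite_render(list(fa), c("red", "green")), "colour")
})
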