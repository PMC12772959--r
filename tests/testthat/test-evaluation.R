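field_from <- function(v, tile = 16) {
  g <- grid_spec(ncol(v) * tile, nrow(v) * tile, tile)
  structure(list(values = v, name = "f", sigma = 0, provenance = "score",
                 grid = g), class = "spatial_field")
}

test_that("cardinality binarization keeps the top bins with stable ties", {
  v <- matrix(0, 4, 4)
  v[1, 1] <- 5; v[2, 2] <- 4; v[3, 3] <- 3; v[4, 4] <- 2
  d <- binarize_to_cardinality(field_from(v), 3)
  expect_equal(nrow(d$points), 3L)
  expect_setequal(paste(d$points[, 1], d$points[, 2]),
                  c("1 1", "2 2", "3 3"))
  # full-support request keeps exactly the non-zero support
  d4 <- binarize_to_cardinality(field_from(v), 4)
  expect_equal(nrow(d4$points), 4L)
  # 4-way tie at the cut: lexicographically first (row, then col) win
  vt <- matrix(0, 3, 3); vt[1, 1] <- 1; vt[1, 3] <- 1; vt[3, 1] <- 1; vt[2, 2] <- 1
  dt <- binarize_to_cardinality(field_from(vt), 2)
  expect_equal(unname(dt$points), rbind(c(1, 1), c(1, 3)))
  expect_error(binarize_to_cardinality(field_from(v), 0), "n must")
  expect_error(binarize_to_cardinality(field_from(v), 5), "n must")
})

test_that("reconstruction error vanishes for a perfect indicator field", {
  set.seed(50)
  v <- matrix(0, 12, 12)
  on <- sample(144, 20)
  v[on] <- 1
  fld <- field_from(v)
  measured <- binarize_to_cardinality(fld, 20)
  expect_lt(reconstruction_error(measured, fld, blur = 2), 1e-6)
})

test_that("reconstruction error grows as the inferred support drifts away", {
  base <- matrix(0, 40, 40)
  base[10:15, 10:15] <- 1
  measured <- binarize_to_cardinality(field_from(base), 36)
  errs <- vapply(seq(0, 18, by = 2), function(sh) {
    v <- matrix(0, 40, 40)
    v[10:15 + sh, 10:15 + sh] <- 1
    reconstruction_error(measured, field_from(v), blur = 2)
  }, numeric(1))
  expect_true(all(diff(errs) > -1e-6))
  expect_gt(errs[length(errs)], errs[1])
})

test_that("bootstrap tails calibrate extremes correctly", {
  g <- grid_spec(640, 640, 16)
  set.seed(51)
  measured <- spatial_distribution(cbind(sample(10:20, 8), sample(10:20, 8)))
  bt <- bootstrap_tail_probability(measured, 0, g, n_boot = 100, seed = 3)
  expect_equal(bt$tail, 0)
  bt2 <- bootstrap_tail_probability(measured, max(bt$null) + 1, g,
                                    n_boot = 100, seed = 3)
  expect_equal(bt2$tail, 1)
  # monotone in the observed divergence
  qs <- quantile(bt$null, c(.2, .5, .8))
  tails <- vapply(qs, function(q)
    bootstrap_tail_probability(measured, q, g, n_boot = 100, seed = 3)$tail,
    numeric(1))
  expect_true(all(diff(tails) >= 0))
  expect_error(bootstrap_tail_probability(measured, 1, g, n_boot = 50),
               "n_boot")
})

test_that("bootstrap null is reproducible under a fixed seed", {
  g <- grid_spec(320, 320, 16)
  measured <- spatial_distribution(cbind(c(2, 5, 9), c(3, 8, 14)))
  b1 <- bootstrap_tail_probability(measured, 2, g, n_boot = 100, seed = 9)
  b2 <- bootstrap_tail_probability(measured, 2, g, n_boot = 100, seed = 9)
  expect_identical(b1$null, b2$null)
})

test_that("leave-one-out evaluation reports every landmark independently", {
  tis <- small_tissue(seed = 52)
  imp <- impute_expression(tis$expr)
  sg <- aggregate_reads(tis$reads, tis$grid, tis$panel)
  models <- fit_all_landmarks(imp, sg$panel, k_range = 2:3, seed = 1)
  rep <- evaluate_reconstruction(sg, imp, lam = 0.9, blur = 2,
                                 n_boot = 100, seed = 2, models = models)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep), length(models$panel))
  expect_true(all(rep$divergence_full >= 0))
  expect_true(all(rep$divergence_loocv >= 0))
  expect_true(all(rep$tail_prob_full >= 0 & rep$tail_prob_full <= 1))
  # removing a landmark never changes another landmark's measured signal
  red <- spatmap:::drop_landmark(sg, models, models$panel[1])
  for (l in red$models$panel)
    expect_equal(measured_distribution(red$sg, l)$points,
                 measured_distribution(sg, l)$points)
  # training advantage: full-model error no worse than held-out on average
  expect_lte(mean(rep$divergence_full), mean(rep$divergence_loocv) + 1e-6)
})
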