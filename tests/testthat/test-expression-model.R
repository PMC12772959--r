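test_that("zero diffusion steps return the input unchanged", {
  set.seed(1)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("c", 1:10), LETTERS[1:6]))
  expect_identical(impute_expression(x, n_neighbors = 3, t = 0), x)
})

test_that("diffusion operator is row-stochastic and respects duplicates", {
  set.seed(2)
  x <- matrix(rnorm(80), 20, 4)
  M <- spatmap:::diffusion_operator(x, 5)
  expect_equal(unname(rowSums(M)), rep(1, 20), tolerance = 1e-12)
  expect_true(all(M >= 0))
  # two duplicated cells receive identical smoothed profiles
  x2 <- rbind(x, x[1, ], x[1, ])
  out <- impute_expression(x2, n_neighbors = 4, t = 2)
  expect_equal(out[21, ], out[22, ], tolerance = 1e-12)
})

test_that("with only two identical cells diffusion is a fixed point", {
  x <- matrix(rep(c(1, 2, 3), each = 2), 2, 3)
  out <- impute_expression(x, n_neighbors = 1, t = 5)
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("imputation validates its inputs", {
  x <- matrix(rnorm(20), 5, 4)
  expect_error(impute_expression(x, n_neighbors = 10, t = 1), "n_neighbors")
  x[2, 2] <- NA
  expect_error(impute_expression(x, n_neighbors = 2, t = 1), "finite")
  expect_error(impute_expression(matrix(rnorm(20), 5, 4), t = -1), "t must")
})

test_that("imputation smooths towards cluster structure", {
  set.seed(4)
  # two tight groups: after diffusion, within-group variance shrinks
  x <- rbind(matrix(rnorm(100, 0, 1), 20, 5),
             matrix(rnorm(100, 10, 1), 20, 5))
  out <- impute_expression(x, n_neighbors = 5, t = 3)
  expect_lt(mean(apply(out[1:20, ], 2, var)),
            mean(apply(x[1:20, ], 2, var)))
  expect_equal(dim(out), dim(x))
})

test_that("two-population mixtures are recovered within tolerance", {
  set.seed(10)
  x <- c(rnorm(1000, 0, 1), rnorm(1000, 5, 1))
  m <- fit_on_off(x, seed = 2)
  expect_lt(abs(m$mu_on - 5), 0.2)
  expect_lt(abs(m$mu_off - 0), 0.2)
  expect_gte(m$k_selected, 2)
  expect_lte(m$k_selected, 8)
  expect_true(m$mu_on >= m$mu_off)
  expect_true(m$var_on > 0 && m$var_off > 0)
})

test_that("off-population pooling is moment-matched", {
  fit <- list(mean = c(0, 2, 6), var = c(1, 1, 1), weight = c(.5, .3, .2))
  m <- spatmap:::pool_on_off(fit, k_selected = 3, loglik = 0, landmark = "g")
  expect_equal(m$mu_on, 6)
  expect_equal(m$mu_off, (.5 * 0 + .3 * 2) / .8)
  # pooled variance = weighted second moment minus squared pooled mean
  w <- c(.5, .3) / .8
  expect_equal(m$var_off, sum(w * (c(1, 1) + c(0, 2)^2)) - m$mu_off^2)
})

test_that("the on component always has the maximal mean", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(200, sample(1:5, 1), 1) + rbinom(200, 1, .4) * runif(1, 2, 6)
    m <- fit_on_off(x, k_range = 2:4, seed = i)
    expect_gte(m$mu_on, m$mu_off)
  }
})

test_that("selected likelihood is no worse than an mclust fit at the same k", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(12)
  x <- c(rnorm(400, 0, .5), rnorm(300, 3, .8))
  ours <- fit_gmm1d(x, 2, seed = 3)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_gte(ours$loglik, ref$loglik - 1e-3)
  ref_on <- max(ref$parameters$mean)
  expect_equal(max(ours$mean), ref_on, tolerance = 0.1)
})

test_that("degenerate landmark vectors are rejected with the landmark name", {
  expect_error(fit_on_off(rep(1, 50), landmark = "Gene7"), "Gene7")
  expect_error(fit_on_off(rnorm(10), landmark = "g"), "20 cells")
})

test_that("panel fitting drops empty and duplicated landmarks with warnings", {
  set.seed(13)
  expr <- cbind(A = c(rnorm(100, 0, .3), rnorm(100, 4, .3)),
                B = c(rnorm(100, 1, .4), rnorm(100, 6, .4)),
                C = rep(0, 200))
  expect_warning(ms <- fit_all_landmarks(expr, c("A", "B", "C")), "no reads")
  expect_identical(ms$panel, c("A", "B"))
  expect_warning(ms2 <- fit_all_landmarks(expr, c("A", "B", "A")),
                 "duplicated")
  expect_identical(ms2$panel, c("A", "B"))
  expect_error(fit_all_landmarks(expr, character()), "empty")
  expect_error(suppressWarnings(fit_all_landmarks(expr, c("A", "C"))),
               "fewer than 2")
})

test_that("on/off model sets round-trip through TSV", {
  set.seed(14)
  expr <- cbind(A = c(rnorm(60, 0, .3), rnorm(60, 4, .3)),
                B = c(rnorm(60, 1, .4), rnorm(60, 6, .4)))
  ms <- fit_all_landmarks(expr, c("A", "B"), k_range = 2:3)
  f <- tempfile(fileext = ".tsv")
  write_on_off_models(ms, f)
  ms2 <- read_on_off_models(f)
  expect_equal(ms2$table, ms$table, tolerance = 1e-12)
})
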