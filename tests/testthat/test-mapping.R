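make_models <- function(tab) {
  models <- lapply(seq_len(nrow(tab)), function(i)
    structure(as.list(tab[i, ]), class = "on_off_model"))
  names(models) <- tab$landmark
  structure(list(models = models, panel = tab$landmark, table = tab),
            class = "on_off_model_set")
}

two_gene_models <- make_models(data.frame(
  landmark = c("A", "B"), mu_on = c(5, 4), var_on = c(1, 2),
  mu_off = c(0, 1), var_off = c(0.5, 1), k = 2, loglik = 0))

test_that("signature parameters select on/off moments per bit", {
  p <- signature_params(c(1, 0), two_gene_models)
  expect_equal(p$mean, c(5, 1))
  expect_equal(p$var, c(1, 1))
  expect_equal(signature_params(c(0, 0), two_gene_models)$mean, c(0, 1))
  expect_equal(signature_params(c(1, 1), two_gene_models)$mean, c(5, 4))
  expect_error(signature_params(c(1, 0, 1), two_gene_models), "length")
})

test_that("log-density matches the closed-form diagonal normal", {
  # var = 1/(2 pi) makes the normalising constant vanish at the mode
  p <- list(mean = 0, var = 1 / (2 * pi))
  expect_equal(log_density(0, p), 0, tolerance = 1e-12)
  # diagonal covariance: density factorises over dimensions
  p2 <- list(mean = c(1, -1), var = c(2, 3))
  expect_equal(log_density(c(0.5, 0.2), p2),
               dnorm(0.5, 1, sqrt(2), log = TRUE) +
                 dnorm(0.2, -1, sqrt(3), log = TRUE),
               tolerance = 1e-12)
  # the mode maximises the density
  expect_gt(log_density(c(1, -1), p2), log_density(c(1.2, -0.8), p2))
  expect_error(log_density(0, list(mean = 0, var = -1)), "variance")
})

test_that("likelihood matrix equals element-wise log densities", {
  sig_table <- rbind(c(1, 0), c(0, 1), c(0, 0))
  set.seed(20)
  imputed <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("A", "B")))
  ld <- likelihood_matrix(imputed, sig_table, two_gene_models)
  expect_equal(dim(ld), c(4L, 3L))
  for (c_ in 1:4) for (s in 1:3) {
    expect_equal(ld[c_, s],
                 log_density(imputed[c_, ],
                             signature_params(sig_table[s, ], two_gene_models)),
                 tolerance = 1e-9)
  }
  # identical cells give identical rows
  imp2 <- imputed[c(1, 1), ]
  ld2 <- likelihood_matrix(imp2, sig_table, two_gene_models)
  expect_equal(ld2[1, ], ld2[2, ])
})

test_that("mapping columns are distributions broadcast per signature", {
  g <- grid_spec(32, 32, 16)
  reads <- data.frame(gene = c("A", "A", "B"), x = c(1, 17, 17), y = c(1, 1, 17))
  sg <- aggregate_reads(reads, g, c("A", "B"))
  set.seed(21)
  imputed <- cbind(A = c(5.1, 0.2, 0.1), B = c(1.2, 4.1, 0.9))
  rownames(imputed) <- paste0("c", 1:3)
  ld <- likelihood_matrix(imputed, sg$sig_table, two_gene_models)
  mm <- build_mapping(ld, sg, lam = 0.5)
  cs <- Matrix::colSums(mm$P)
  expect_equal(unname(cs), rep(1, 4), tolerance = 1e-9)
  # bins 1 and 3 share the A-only signature -> identical columns
  same <- which(sg$sig_index == sg$sig_index[1])
  expect_gte(length(same), 2)
  expect_equal(mm$P[, same[1]], mm$P[, same[2]])
})

test_that("an overwhelming cell yields a one-hot bin distribution", {
  g <- grid_spec(16, 16, 16)
  sg <- aggregate_reads(data.frame(gene = "A", x = 1, y = 1), g, c("A", "B"))
  models <- two_gene_models
  # cell 1 matches the A-on signature essentially exactly; cell 2 is far off
  imputed <- cbind(A = c(5, -50), B = c(1, 60))
  ld <- likelihood_matrix(imputed, sg$sig_table, models)
  mm <- build_mapping(ld, sg, lam = 0.9)
  col <- as.numeric(mm$P[, 1])
  expect_equal(col, c(1, 0))
})

test_that("whole-pipeline mapping is column-stochastic on synthetic tissue", {
  tis <- small_tissue(seed = 31)
  imp <- impute_expression(tis$expr)
  sg <- aggregate_reads(tis$reads, tis$grid, tis$panel)
  models <- fit_all_landmarks(imp, sg$panel, k_range = 2:4, seed = 1)
  mm <- map_cells(imp, sg, models = models, lam = 0.9)
  cs <- Matrix::colSums(mm$P)
  expect_equal(unname(cs), rep(1, ncol(mm$P)), tolerance = 1e-9)
  expect_lte(length(unique(round(cs, 12))), nrow(sg$sig_table))
  # sparsity: support well below the full cell count on average
  expect_lt(Matrix::nnzero(mm$P) / ncol(mm$P), nrow(mm$P) / 2)
})
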