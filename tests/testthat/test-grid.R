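test_that("bin counts follow ceiling arithmetic, edge tiles retained", {
  g <- grid_spec(16619, 14810, tile = 16)
  expect_identical(c(g$bins_h, g$bins_w), c(926L, 1039L))
  # exact multiples need no partial tile
  expect_identical(grid_spec(32, 48, 16)$bins_w, 2L)
  expect_identical(grid_spec(32, 48, 16)$bins_h, 3L)
  expect_error(grid_spec(0, 10, 16), "width_px")
  expect_error(grid_spec(10, 10, 0), "tile")
})

test_that("reads land in half-open tiles and set single bits", {
  g <- grid_spec(32, 32, 16)
  reads <- data.frame(gene = c("A", "A", "B"),
                      x = c(1, 17, 17), y = c(1, 1, 17))
  sg <- aggregate_reads(reads, g, panel = c("A", "B"))
  bits <- as.matrix(sg$bits)
  set <- which(bits > 0, arr.ind = TRUE)
  # linear bin index is (col-1)*bins_h + row
  expect_setequal(
    paste(set[, 1], colnames(bits)[set[, 2]]),
    c(paste(1, "A"),          # (row 1, col 1) <- (1,1)
      paste(3, "A"),          # (row 1, col 2) <- (17,1)
      paste(4, "B")))         # (row 2, col 2) <- (17,17)
  # duplicated reads of one gene in one tile still one bit
  sg2 <- aggregate_reads(rbind(reads, reads), g, panel = c("A", "B"))
  expect_equal(as.matrix(sg2$bits), bits)
})

test_that("single read at a fractional coordinate sets only its tile", {
  g <- grid_spec(64, 64, 16)
  sg <- aggregate_reads(data.frame(gene = "A", x = 0.5, y = 0.5), g, "A")
  expect_equal(sum(sg$bits), 1)
  expect_equal(as.numeric(sg$bits[1, 1]), 1)
})

test_that("unknown genes and out-of-bounds coordinates are rejected by name", {
  g <- grid_spec(32, 32, 16)
  expect_error(aggregate_reads(data.frame(gene = "Z", x = 1, y = 1), g, "A"),
               "Z")
  expect_error(aggregate_reads(data.frame(gene = "A", x = 32, y = 1), g, "A"),
               "outside")
  expect_error(aggregate_reads(data.frame(gene = "A", x = -0.1, y = 1), g, "A"),
               "outside")
  # the max boundary is half-open: exactly width_px is out of bounds
  expect_error(aggregate_reads(data.frame(gene = "A", x = 1, y = 32), g, "A"),
               "outside")
})

test_that("unique signatures deduplicate with occupancy conservation", {
  g <- grid_spec(32, 32, 16)
  reads <- data.frame(gene = c("A", "A", "B"),
                      x = c(1, 17, 17), y = c(1, 1, 17))
  sg <- aggregate_reads(reads, g, panel = c("A", "B"))
  us <- unique_signatures(sg)
  expect_equal(nrow(us$sig_table), 3L)  # A-only, zero, B-only
  expect_equal(sum(us$sig_count), 4L)
  counts <- us$sig_count[match(
    c("10", "00", "01"),
    apply(us$sig_table, 1, paste, collapse = ""))]
  expect_equal(counts, c(2L, 1L, 1L))
  # empty grid: a single all-zero signature covering every bin
  sg0 <- aggregate_reads(data.frame(gene = character(), x = numeric(),
                                    y = numeric()), g, panel = c("A", "B"))
  expect_equal(nrow(sg0$sig_table), 1L)
  expect_equal(sg0$sig_count, 4L)
})

test_that("sig_index + sig_table round-trips the bit tensor, fuzzed", {
  set.seed(42)
  for (rep in 1:5) {
    g <- grid_spec(sample(40:90, 1), sample(40:90, 1), 16)
    n <- sample(20:80, 1)
    panel <- LETTERS[1:4]
    reads <- data.frame(gene = sample(panel, n, TRUE),
                        x = runif(n, 0, g$width_px - 1e-9),
                        y = runif(n, 0, g$height_px - 1e-9))
    sg <- aggregate_reads(reads, g, panel)
    rebuilt <- sg$sig_table[sg$sig_index, , drop = FALSE]
    expect_equal(unname(as.matrix(sg$bits)), unname(rebuilt))
    expect_equal(sum(sg$sig_count), g$bins_h * g$bins_w)
  }
})

test_that("permuting read order leaves the signature table contents fixed", {
  g <- grid_spec(64, 64, 16)
  set.seed(7)
  reads <- data.frame(gene = sample(c("A", "B", "C"), 30, TRUE),
                      x = runif(30, 0, 63.9), y = runif(30, 0, 63.9))
  sg1 <- aggregate_reads(reads, g, c("A", "B", "C"))
  sg2 <- aggregate_reads(reads[sample(nrow(reads)), ], g, c("A", "B", "C"))
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  expect_equal(key(sg1$sig_table), key(sg2$sig_table))
})

test_that("coarser tiles reduce unique signatures and per-landmark bits", {
  set.seed(9)
  reads <- data.frame(gene = sample(c("A", "B"), 120, TRUE),
                      x = runif(120, 0, 127.9), y = runif(120, 0, 127.9))
  fine <- aggregate_reads(reads, grid_spec(128, 128, 8), c("A", "B"))
  coarse <- aggregate_reads(reads, grid_spec(128, 128, 32), c("A", "B"))
  expect_lte(nrow(coarse$sig_table), nrow(fine$sig_table))
  expect_true(all(Matrix::colSums(coarse$bits) <=
                    Matrix::colSums(fine$bits)))
  expect_gte(nrow(coarse$sig_table), 1L)
})

test_that("spot tables and signature grids round-trip through disk", {
  g <- grid_spec(64, 64, 16)
  reads <- data.frame(gene = c("A", "B"), x = c(3.5, 40.25), y = c(10, 60))
  f <- tempfile(fileext = ".csv")
  write.csv(reads, f, row.names = FALSE, quote = FALSE)
  rt <- read_spot_table(f)
  expect_equal(rt, reads)
  sg <- aggregate_reads(rt, g, c("A", "B"))
  f2 <- tempfile(fileext = ".tsv")
  write_signature_grid(sg, f2)
  expect_true(file.exists(f2))
  tab <- read.table(f2, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), 2L)
})
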