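#' Define the binning geometry of a spatial reference space
#'
#' The reference space is the pixel raster of an in situ sequencing (ISS)
#' experiment; spots are reported in fractional pixel coordinates with the
#' origin at the top-left, x along columns and y along rows. Square tiles of
#' \code{tile} pixels aggregate spots into bins; partial tiles at the right
#' and bottom edges are retained, so the grid has
#' \code{ceiling(height_px / tile)} rows and \code{ceiling(width_px / tile)}
#' columns.
#'
#' @param width_px,height_px Integer extent of the reference space in pixels.
#' @param tile Integer edge length of the square aggregation tile, in pixels.
#' @return A \code{grid_spec} object with elements \code{width_px},
#'   \code{height_px}, \code{tile}, \code{bins_w}, \code{bins_h}.
#' @examples
#' g <- grid_spec(16619, 14810, tile = 16)
#' c(g$bins_h, g$bins_w)  # 926 1039
#' @export
grid_spec <- function(width_px, height_px, tile = 16L) {
  stopifnot(length(width_px) == 1L, length(height_px) == 1L, length(tile) == 1L)
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  tile <- as.integer(tile)
  if (is.na(width_px) || width_px < 1L) stop("grid_spec: width_px must be >= 1")
  if (is.na(height_px) || height_px < 1L) stop("grid_spec: height_px must be >= 1")
  if (is.na(tile) || tile < 1L) stop("grid_spec: tile must be >= 1")
  structure(
    list(width_px = width_px, height_px = height_px, tile = tile,
         bins_w = as.integer(ceiling(width_px / tile)),
         bins_h = as.integer(ceiling(height_px / tile))),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d px, tile %d -> %d x %d bins (rows x cols)\n",
              x$width_px, x$height_px, x$tile, x$bins_h, x$bins_w))
  invisible(x)
}

n_bins <- function(grid) grid$bins_h * grid$bins_w

# Linear bin index (1-based, column-major so matrix(v, bins_h, bins_w)
# reshapes correctly): row r, col c -> (c-1)*bins_h + r.
bin_linear_index <- function(row, col, grid) (col - 1L) * grid$bins_h + row

bin_row_col <- function(idx, grid) {
  idx0 <- idx - 1L
  cbind(row = idx0 %% grid$bins_h + 1L, col = idx0 %/% grid$bins_h + 1L)
}

#' Read an ISS spot table
#'
#' Reads the spot-level export of a targeted ISS platform: one record per
#' decoded transcript with columns \code{gene,x,y} (header required; comma or
#' tab separated). Coordinates are fractional pixels in the reference space.
#'
#' @param path Path to the CSV/TSV spot table.
#' @return A data.frame with columns \code{gene} (character), \code{x},
#'   \code{y} (numeric).
#' @export
read_spot_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("gene", "x", "y")
  if (!all(need %in% names(df)))
    stop("spot table must have columns 'gene', 'x', 'y'; found: ",
         paste(names(df), collapse = ", "))
  df$gene <- as.character(df$gene)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (anyNA(df$x) || anyNA(df$y)) stop("spot table has non-numeric coordinates")
  df[need]
}

#' Read a landmark panel file
#'
#' One gene symbol per line; blank lines and lines starting with '#' ignored.
#'
#' @param path Path to the panel file.
#' @return Character vector of gene symbols.
#' @export
read_panel <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Aggregate ISS reads into a binary landmark-signature grid
#'
#' Each read at fractional pixel \code{(x, y)} falls into the half-open tile
#' \code{[k*tile, (k+1)*tile)} on each axis; a bin's signature is the bit
#' vector over the landmark panel recording which landmarks had at least one
#' read in the tile. Bins sharing the same bit vector share a signature id;
#' the table of unique signatures with occupancy counts is computed alongside.
#'
#' @param reads Data.frame with columns \code{gene}, \code{x}, \code{y}
#'   (see [read_spot_table()]).
#' @param grid A [grid_spec()].
#' @param panel Character vector of landmark gene symbols; every read's gene
#'   must belong to it.
#' @param count_mode If \code{TRUE}, per-bin read counts are retained in the
#'   \code{counts} slot in addition to the binary bits. The core model uses
#'   only the binary representation.
#' @return A \code{signature_grid} object: \code{bits} (sparse logical
#'   \code{n_bins x L} matrix, \pkg{Matrix} class), \code{sig_index} (integer
#'   per bin, indexing \code{sig_table}), \code{sig_table} (0/1 matrix of
#'   unique signatures, one row each), \code{sig_count} (occupancy counts),
#'   \code{panel}, \code{grid}.
#' @export
aggregate_reads <- function(reads, grid, panel, count_mode = FALSE) {
  if (length(panel) == 0L) stop("aggregate_reads: empty landmark panel")
  panel <- unique(panel)
  stopifnot(inherits(grid, "grid_spec"))
  gi <- match(reads$gene, panel)
  if (anyNA(gi)) {
    bad <- unique(reads$gene[is.na(gi)])
    stop("aggregate_reads: reads for gene(s) not in the panel: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  oob <- reads$x < 0 | reads$x >= grid$width_px |
         reads$y < 0 | reads$y >= grid$height_px
  if (any(oob))
    stop(sprintf("aggregate_reads: %d read(s) outside the %d x %d px reference space",
                 sum(oob), grid$width_px, grid$height_px))
  col <- as.integer(floor(reads$x / grid$tile)) + 1L
  row <- as.integer(floor(reads$y / grid$tile)) + 1L
  bin <- bin_linear_index(row, col, grid)
  nb <- n_bins(grid)
  L <- length(panel)
  bits <- Matrix::sparseMatrix(i = bin, j = gi, x = 1,
                               dims = c(nb, L),
                               dimnames = list(NULL, panel))
  counts <- if (count_mode) bits else NULL
  bits <- methods::as(bits > 0, "CsparseMatrix") * 1  # binary dgCMatrix
  sg <- list(bits = bits, counts = counts, panel = panel, grid = grid)
  sg <- c(sg, signature_index(bits))
  structure(sg, class = "signature_grid")
}

# Deduplicate bin signatures. Returns sig_table (unique 0/1 matrix, rows in
# first-appearance order by bin index), sig_count, sig_index (per bin).
signature_index <- function(bits) {
  keys <- bit_keys(bits)
  first <- !duplicated(keys)
  uk <- keys[first]
  sig_index <- match(keys, uk)
  sig_table <- as.matrix(bits[which(first), , drop = FALSE])
  rownames(sig_table) <- NULL
  list(sig_table = sig_table,
       sig_count = as.integer(tabulate(sig_index, nbins = length(uk))),
       sig_index = sig_index)
}

# Compact string key per row of a sparse binary matrix.
bit_keys <- function(bits) {
  m <- methods::as(Matrix::t(bits), "CsparseMatrix")  # columns = bins
  p <- m@p; i <- m@i
  vapply(seq_len(ncol(m)), function(b) {
    if (p[b + 1L] == p[b]) "" else
      paste(i[(p[b] + 1L):p[b + 1L]], collapse = ",")
  }, character(1))
}

#' @export
print.signature_grid <- function(x, ...) {
  cat(sprintf(
    "signature_grid: %d x %d bins, %d landmarks, %d unique signatures (%d occupied bins)\n",
    x$grid$bins_h, x$grid$bins_w, length(x$panel), nrow(x$sig_table),
    sum(Matrix::rowSums(x$bits) > 0)))
  invisible(x)
}

#' Table of unique landmark signatures with occupancy counts
#'
#' @param sg A \code{signature_grid} from [aggregate_reads()].
#' @return List with \code{sig_table} (unique 0/1 matrix, one signature per
#'   row) and \code{sig_count} (number of bins carrying each signature;
#'   counts sum to the number of bins). The all-zero signature is a
#'   legitimate entry.
#' @export
unique_signatures <- function(sg) {
  stopifnot(inherits(sg, "signature_grid"))
  list(sig_table = sg$sig_table, sig_count = sg$sig_count)
}

#' Measured spatial distribution of one landmark
#'
#' The set of bins whose signature has the landmark's bit set, with uniform
#' weights — the binarized measured signal used as the reconstruction target.
#'
#' @param sg A \code{signature_grid}.
#' @param landmark Gene symbol.
#' @return A [spatial_distribution()].
#' @export
measured_distribution <- function(sg, landmark) {
  l <- match(landmark, sg$panel)
  if (is.na(l)) stop("measured_distribution: unknown landmark ", landmark)
  idx <- which(sg$bits[, l] > 0)
  if (length(idx) == 0L)
    stop("measured_distribution: landmark ", landmark, " has no measured bins")
  rc <- bin_row_col(idx, sg$grid)
  spatial_distribution(rc, rep(1, nrow(rc)))
}

#' Write a signature grid as sparse TSV
#'
#' Emits a triplet table (\code{bin}, \code{row}, \code{col}, \code{gene})
#' with one line per set bit, preceded by '#' header lines carrying the grid
#' geometry.
#'
#' @param sg A \code{signature_grid}.
#' @param path Output path.
#' @export
write_signature_grid <- function(sg, path) {
  tb <- Matrix::summary(methods::as(sg$bits, "TsparseMatrix"))
  rc <- bin_row_col(tb$i, sg$grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid %d %d tile %d panel %s",
                     sg$grid$width_px, sg$grid$height_px, sg$grid$tile,
                     paste(sg$panel, collapse = ",")), con)
  utils::write.table(
    data.frame(bin = tb$i, row = rc[, "row"], col = rc[, "col"],
               gene = sg$panel[tb$j]),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
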