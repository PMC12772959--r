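#' Per-signature diagonal-normal parameters
#'
#' A bin's landmark signature selects, for each landmark, either the "on" or
#' the "off" population of its mixture summary: bit 1 takes
#' \code{(mu_on, var_on)}, bit 0 takes the pooled \code{(mu_off, var_off)}.
#' The resulting mean/variance vectors define a diagonal multivariate normal
#' over landmark expression for cells located at bins carrying the signature.
#'
#' @param bits 0/1 vector over the retained landmark panel.
#' @param models An \code{on_off_model_set} (see [fit_all_landmarks()]).
#' @return List with \code{mean} and \code{var} vectors (length = panel).
#' @export
signature_params <- function(bits, models) {
  tab <- models$table
  if (length(bits) != nrow(tab))
    stop("signature_params: signature length ", length(bits),
         " does not match retained panel size ", nrow(tab))
  on <- bits > 0
  list(mean = ifelse(on, tab$mu_on, tab$mu_off),
       var  = ifelse(on, tab$var_on, tab$var_off))
}

#' Log-density of a cell's landmark profile under a signature distribution
#'
#' Diagonal multivariate normal:
#' \eqn{\sum_l [-\tfrac12\log(2\pi v_l) - (x_l - m_l)^2 / (2 v_l)]}.
#'
#' @param cell_expr Numeric vector over the retained panel.
#' @param params List with \code{mean}, \code{var} from [signature_params()].
#' @return Scalar log-density.
#' @export
log_density <- function(cell_expr, params) {
  if (any(params$var <= 0)) stop("log_density: non-positive variance")
  if (!all(is.finite(cell_expr))) stop("log_density: non-finite expression")
  sum(-0.5 * log(2 * pi * params$var) -
        (cell_expr - params$mean)^2 / (2 * params$var))
}

#' Cells-by-signatures log-likelihood matrix
#'
#' Scores every cell against every unique landmark signature under the
#' per-signature diagonal normal. Computed once per unique signature; the
#' caller broadcasts to bins. Implemented as three matrix products so the
#' cost is \code{O(cells x signatures x landmarks)} in BLAS.
#'
#' @param imputed Cells x landmarks matrix of imputed expression; columns
#'   must be the retained panel in model order.
#' @param sig_table Unique-signature 0/1 matrix (signatures x landmarks).
#' @param models An \code{on_off_model_set}.
#' @return Dense cells x signatures matrix of log-densities.
#' @export
likelihood_matrix <- function(imputed, sig_table, models) {
  tab <- models$table
  if (!identical(colnames(imputed), models$panel))
    imputed <- imputed[, models$panel, drop = FALSE]
  S <- nrow(sig_table); L <- ncol(sig_table)
  stopifnot(L == nrow(tab))
  B <- sig_table > 0
  M <- t(ifelse(t(B), tab$mu_on, tab$mu_off))          # S x L means
  V <- t(ifelse(t(B), tab$var_on, tab$var_off))        # S x L variances
  if (any(V <= 0)) stop("likelihood_matrix: non-positive variance")
  # log N(x; m, v) summed over l:
  #   -0.5*sum(log 2 pi v) - 0.5*sum(x^2/v) + sum(x m/v) - 0.5*sum(m^2/v)
  const <- -0.5 * rowSums(log(2 * pi * V)) - 0.5 * rowSums(M^2 / V)  # per sig
  X <- imputed
  out <- -0.5 * (X^2 %*% t(1 / V)) + X %*% t(M / V)
  sweep(out, 2L, const, "+")
}

#' Build the mapping matrix P
#'
#' For each unique signature, the vector of cell log-densities is normalised
#' into a sparse probability distribution over cells with
#' [sparsegen_lin()] (sparsegen takes the same scores softmax would, but
#' yields exact zeros for implausible cells), then broadcast to every bin
#' carrying the signature. Columns of P are therefore proper distributions
#' over cells; bins sharing a signature share a column.
#'
#' @param logdens Cells x unique-signatures log-density matrix
#'   (see [likelihood_matrix()]).
#' @param sg The \code{signature_grid} providing \code{sig_index}.
#' @param lam Sparsity coefficient for [sparsegen_lin()] (default 0.9).
#' @param cell_ids Optional cell identifiers (rownames of \code{logdens}
#'   used when absent).
#' @return A \code{mapping_matrix}: \code{P} (sparse \code{dgCMatrix}, cells
#'   x bins), \code{cell_ids}, \code{grid}, \code{lam}.
#' @export
build_mapping <- function(logdens, sg, lam = 0.9, cell_ids = rownames(logdens)) {
  stopifnot(inherits(sg, "signature_grid"))
  S <- ncol(logdens)
  if (S != nrow(sg$sig_table))
    stop("build_mapping: log-density columns do not match unique signatures")
  nc <- nrow(logdens)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nc))
  # per-signature sparse distribution over cells
  cols <- vector("list", S)
  for (s in seq_len(S)) {
    p <- sparsegen_lin(logdens[, s], lam)
    nz <- which(p > 0)
    cols[[s]] <- list(i = nz, x = p[nz])
  }
  sig_of_bin <- sg$sig_index
  nb <- length(sig_of_bin)
  nnz_per_sig <- vapply(cols, function(cc) length(cc$i), integer(1))
  nnz <- sum(nnz_per_sig[sig_of_bin])
  ii <- integer(nnz); jj <- integer(nnz); xx <- numeric(nnz)
  pos <- 0L
  for (b in seq_len(nb)) {
    cc <- cols[[sig_of_bin[b]]]
    k <- length(cc$i)
    if (k == 0L) next
    idx <- pos + seq_len(k)
    ii[idx] <- cc$i; jj[idx] <- b; xx[idx] <- cc$x
    pos <- pos + k
  }
  P <- Matrix::sparseMatrix(i = ii[seq_len(pos)], j = jj[seq_len(pos)],
                            x = xx[seq_len(pos)], dims = c(nc, nb))
  structure(list(P = P, cell_ids = cell_ids, grid = sg$grid, lam = lam),
            class = "mapping_matrix")
}

#' @export
print.mapping_matrix <- function(x, ...) {
  cat(sprintf("mapping_matrix: %d cells x %d bins, lam = %g, mean support %.1f cells/bin\n",
              nrow(x$P), ncol(x$P), x$lam,
              Matrix::nnzero(x$P) / ncol(x$P)))
  invisible(x)
}

#' Map cells onto a signature grid
#'
#' Convenience wrapper running [fit_all_landmarks()] (unless models are
#' supplied), [likelihood_matrix()] and [build_mapping()].
#'
#' @param imputed Cells x genes imputed expression matrix (named columns).
#' @param sg A \code{signature_grid}.
#' @param models Optional precomputed \code{on_off_model_set}.
#' @param lam Sparsity coefficient.
#' @param seed Seed forwarded to the mixture fits.
#' @return A \code{mapping_matrix}.
#' @export
map_cells <- function(imputed, sg, models = NULL, lam = 0.9, seed = 1L) {
  if (is.null(models)) models <- fit_all_landmarks(imputed, sg$panel, seed = seed)
  # restrict signatures to retained landmarks (some may have been dropped)
  keep <- match(models$panel, sg$panel)
  sig_table <- sg$sig_table[, keep, drop = FALSE]
  if (!identical(models$panel, sg$panel)) {
    # re-deduplicate over the retained columns
    sub <- signature_index(methods::as(Matrix::Matrix(sg$sig_table[sg$sig_index, keep,
                                                                   drop = FALSE],
                                                      sparse = TRUE), "CsparseMatrix"))
    sg$sig_table <- sub$sig_table; sg$sig_index <- sub$sig_index
    sg$sig_count <- sub$sig_count
    sig_table <- sg$sig_table
  }
  ld <- likelihood_matrix(imputed[, models$panel, drop = FALSE], sig_table, models)
  build_mapping(ld, sg, lam = lam, cell_ids = rownames(imputed))
}

#' Write a mapping matrix in MatrixMarket format
#'
#' Writes \code{P} as \code{<prefix>.mtx} plus \code{<prefix>_cells.tsv}
#' (cell ids) and \code{<prefix>_bins.tsv} (bin row/col coordinates).
#'
#' @param mm A \code{mapping_matrix}.
#' @param prefix Output path prefix.
#' @export
write_mapping <- function(mm, prefix) {
  Matrix::writeMM(mm$P, paste0(prefix, ".mtx"))
  utils::write.table(data.frame(cell_id = mm$cell_ids),
                     paste0(prefix, "_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rc <- bin_row_col(seq_len(ncol(mm$P)), mm$grid)
  utils::write.table(as.data.frame(rc), paste0(prefix, "_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
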