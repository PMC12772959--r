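#' Binarize a spatial field to a target cardinality
#'
#' Keeps the \code{n} highest-valued bins with uniform weights, so the
#' inferred signal can be compared with a measured binary signal of the same
#' cardinality. Ties at the cut are broken deterministically by (row, col)
#' lexicographic order.
#'
#' @param field A \code{spatial_field}.
#' @param n Target number of bins (1 <= n <= number of non-zero bins).
#' @param mask Optional logical matrix (same shape); bins outside it are
#'   treated as zero. Used to confine reconstruction assessment to the
#'   assayed tissue region.
#' @return A \code{spatial_distribution} of \code{n} uniformly weighted bins.
#' @export
binarize_to_cardinality <- function(field, n, mask = NULL) {
  stopifnot(inherits(field, "spatial_field"))
  v <- field$values
  if (!is.null(mask)) v <- v * mask
  nz <- which(v > 0)
  if (n < 1L || n > length(nz))
    stop("binarize_to_cardinality: n must be in [1, ", length(nz),
         " (non-zero bins)], got ", n)
  nr <- nrow(v)
  rows <- (nz - 1L) %% nr + 1L
  cols <- (nz - 1L) %/% nr + 1L
  ord <- order(-v[nz], rows, cols)
  keep <- ord[seq_len(n)]
  spatial_distribution(cbind(rows[keep], cols[keep]), rep(1, n))
}

#' Reconstruction error of one landmark
#'
#' Sinkhorn divergence between the measured bin set of a landmark (uniform
#' weights) and the inferred field binarized to the measured cardinality.
#'
#' @param measured \code{spatial_distribution} of measured bins
#'   (see [measured_distribution()]).
#' @param inferred \code{spatial_field} of projected expression.
#' @param blur Sinkhorn length scale in bins.
#' @param mask Optional logical matrix confining the inferred signal to the
#'   assayed region (see [binarize_to_cardinality()]).
#' @return Scalar divergence.
#' @export
reconstruction_error <- function(measured, inferred, blur = 2, mask = NULL) {
  n <- nrow(measured$points)
  v <- inferred$values
  if (!is.null(mask)) v <- v * mask
  inf_d <- binarize_to_cardinality(inferred, min(n, sum(v > 0)), mask = mask)
  sinkhorn_divergence(measured, inf_d, blur = blur)
}

#' Bootstrap tail probability of an observed divergence
#'
#' Null model: the landmark's signal is scattered uniformly over the
#' reference grid. Each bootstrap replicate samples as many bins, uniformly
#' without replacement, as the measured signal has, and records its Sinkhorn
#' divergence from the measured distribution. The tail probability is the
#' fraction of null divergences at or below the observed one — small values
#' mean the reconstruction is far better than chance placement.
#'
#' @param measured \code{spatial_distribution} of the measured signal.
#' @param observed_div Observed divergence to be calibrated.
#' @param grid A [grid_spec()].
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param blur Sinkhorn length scale.
#' @param seed Integer seed.
#' @param pooled Alternative reading in which a single large uniform
#'   reference sample of \code{n_boot} bins is drawn and divergences are
#'   computed on \code{n_boot / 10} disjoint cardinality-matched chunks of
#'   it; default \code{FALSE} (one cardinality-matched sample per replicate).
#' @param support Optional integer vector of candidate bin indices the null
#'   samples from (default: every bin of the grid). Pass the assayed tissue
#'   bins to calibrate against placements inside the section only.
#' @param ... Solver options forwarded to the transport computation.
#' @return List: \code{tail} (fraction <= observed), \code{null}
#'   (divergences), \code{observed}.
#' @export
bootstrap_tail_probability <- function(measured, observed_div, grid,
                                       n_boot = 1000L, blur = 2, seed = 1L,
                                       pooled = FALSE, support = NULL, ...) {
  if (n_boot < 100L) stop("bootstrap_tail_probability: n_boot must be >= 100")
  if (is.null(support)) support <- seq_len(n_bins(grid))
  n <- nrow(measured$points)
  if (length(support) < n)
    stop("bootstrap_tail_probability: support smaller than the measured cardinality")
  set.seed(seed)
  reps <- if (pooled) max(1L, n_boot %/% 10L) else n_boot
  eps <- blur^2
  wb <- measured$weights / sum(measured$weights)
  obb <- ot_self(measured$points, wb, eps)  # shared across replicates
  wa <- rep(1 / n, n)
  null <- vapply(seq_len(reps), function(r) {
    idx <- support[sample.int(length(support), n)]
    pts <- bin_row_col(idx, grid)
    storage.mode(pts) <- "double"
    oab <- ot_eps(cost_matrix(pts, measured$points), wa, wb, eps, ...)
    oaa <- ot_self(pts, wa, eps)
    max(oab - 0.5 * oaa - 0.5 * obb, 0)
  }, numeric(1))
  list(tail = mean(null <= observed_div), null = null, observed = observed_div)
}

#' Full-model and leave-one-out reconstruction evaluation
#'
#' For every retained landmark: (i) full model — cells are mapped with all
#' landmarks and the landmark's imputed expression projected and binarized
#' to the measured cardinality; (ii) LOOCV — the landmark is removed from
#' the signature grid and the model, the mapping is rebuilt from the
#' remaining landmarks, and the held-out landmark's expression is projected
#' through the reduced mapping. Both divergences are calibrated against the
#' uniform-bootstrap null of the measured signal (the null depends only on
#' the measured distribution, so it is shared).
#'
#' On/off mixture fits are computed once; leaving a landmark out does not
#' change the other landmarks' fits, only the signatures and the mapping.
#'
#' @param sg \code{signature_grid} of the measured landmark reads.
#' @param imputed Cells x genes imputed expression matrix (named columns)
#'   containing at least the panel.
#' @param lam Sparsity coefficient for the mapping.
#' @param blur Sinkhorn length scale.
#' @param n_boot Bootstrap replicates per landmark.
#' @param seed Integer seed.
#' @param loocv Set \code{FALSE} to skip the leave-one-out pass.
#' @param models Optional precomputed \code{on_off_model_set}.
#' @return An \code{evaluation_report} data.frame: one row per landmark with
#'   \code{divergence_full}, \code{divergence_loocv}, \code{tail_prob_full},
#'   \code{tail_prob_loocv}, \code{cardinality}.
#' @export
evaluate_reconstruction <- function(sg, imputed, lam = 0.9, blur = 2,
                                    n_boot = 1000L, seed = 1L, loocv = TRUE,
                                    models = NULL) {
  stopifnot(inherits(sg, "signature_grid"))
  if (is.null(models)) models <- fit_all_landmarks(imputed, sg$panel, seed = seed)
  panel <- models$panel
  if (loocv && length(panel) < 3L)
    stop("evaluate_reconstruction: LOOCV needs >= 3 landmarks")
  measured <- lapply(panel, function(l) measured_distribution(sg, l))
  names(measured) <- panel
  # assayed tissue support: bins with at least one read of any landmark.
  # The inferred signal is binarized within it (bins never measured carry no
  # signal to compare against); the bootstrap null remains uniform over the
  # whole reference space.
  assayed <- which(Matrix::rowSums(sg$bits) > 0)
  mask <- matrix(FALSE, sg$grid$bins_h, sg$grid$bins_w)
  mask[assayed] <- TRUE
  mm_full <- map_cells(imputed, sg, models = models, lam = lam)
  rows <- vector("list", length(panel))
  for (i in seq_along(panel)) {
    l <- panel[i]
    card <- nrow(measured[[l]]$points)
    fld_full <- project_feature(mm_full, imputed[, l], name = l)
    div_full <- reconstruction_error(measured[[l]], fld_full, blur = blur,
                                     mask = mask)
    div_loo <- NA_real_
    if (loocv) {
      red <- drop_landmark(sg, models, l)
      mm_red <- map_cells(imputed, red$sg, models = red$models, lam = lam)
      fld_loo <- project_feature(mm_red, imputed[, l], name = l)
      div_loo <- reconstruction_error(measured[[l]], fld_loo, blur = blur,
                                      mask = mask)
    }
    boot <- bootstrap_tail_probability(measured[[l]],
                                       observed_div = div_full, grid = sg$grid,
                                       n_boot = n_boot, blur = blur,
                                       seed = seed + i)
    rows[[i]] <- data.frame(
      landmark = l, cardinality = card,
      divergence_full = div_full, divergence_loocv = div_loo,
      tail_prob_full = mean(boot$null <= div_full),
      tail_prob_loocv = if (loocv) mean(boot$null <= div_loo) else NA_real_)
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("evaluation_report", "data.frame")
  rep
}

# Remove one landmark from a signature grid and a model set.
drop_landmark <- function(sg, models, landmark) {
  keep <- setdiff(models$panel, landmark)
  keep_idx <- match(keep, sg$panel)
  bits <- sg$bits[, keep_idx, drop = FALSE]
  sg2 <- list(bits = bits, counts = NULL, panel = keep, grid = sg$grid)
  sg2 <- c(sg2, signature_index(bits))
  class(sg2) <- "signature_grid"
  models2 <- models
  models2$models <- models$models[keep]
  models2$panel <- keep
  models2$table <- models$table[models$table$landmark %in% keep, , drop = FALSE]
  list(sg = sg2, models = models2)
}

#' @export
print.evaluation_report <- function(x, ...) {
  ok_full <- sum(x$tail_prob_full < 0.05)
  cat(sprintf("evaluation_report: %d landmarks; %d/%d reconstructed (tail < 0.05)",
              nrow(x), ok_full, nrow(x)))
  if (!all(is.na(x$tail_prob_loocv)))
    cat(sprintf("; %d/%d under LOOCV", sum(x$tail_prob_loocv < 0.05), nrow(x)))
  cat("\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
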