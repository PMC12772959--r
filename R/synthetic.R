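#' Specification of a synthetic zoned tissue
#'
#' Describes a circular tissue section organised as concentric zones (the
#' default three annuli mimic a cortex / intermediate / medulla layout), each
#' populated by zone-restricted cell types. Every type switches a subset of
#' landmark genes "on": on-state expression is drawn from a high normal, the
#' off state from a low normal, giving each landmark the bimodal marginal the
#' on/off mixture model assumes. ISS-style reads are emitted per cell and
#' landmark as a Bernoulli detection of the on state at the cell's pixel
#' position; dissociated profiles are the same expression plus independent
#' Gaussian noise, with the rows shuffled so no positional information leaks.
#'
#' @param width_px,height_px,tile Reference-space geometry (defaults
#'   2048 x 2048 px, 16 px tiles: a 128 x 128-bin grid).
#' @param zone_fractions Area fractions of the concentric zones (sum to 1).
#' @param n_types Number of cell types; types are assigned to zones in
#'   round-robin order (\code{zone_of_type}).
#' @param n_cells Total number of cells placed.
#' @param landmarks_per_type Landmarks specific to each type (default 2, so
#'   6 types give the 12-landmark panel).
#' @param p_on_self,p_on_other Probability that a landmark is "on" in a cell
#'   of its own type / any other type.
#' @param mu_on,sd_on,mu_off,sd_off On/off expression normals
#'   (log-expression units).
#' @param detection Per cell-landmark Bernoulli detection probability of an
#'   on-state read in the ISS channel.
#' @param noise_sd SD of the additive Gaussian noise on dissociated
#'   profiles.
#' @param dropout Zero-inflation probability applied to the dissociated
#'   matrix (default 0; exercise the imputation path by raising it).
#' @param extra_genes Optional named list of non-landmark genes, each a list
#'   with \code{types} (type indices expressing it), \code{p_on},
#'   \code{mu_on}, \code{sd_on}, \code{mu_off}, \code{sd_off}; used for
#'   feature-projection and ligand-receptor experiments.
#' @param seed Integer seed making the tissue fully reproducible.
#' @return A \code{tissue_spec} list.
#' @export
tissue_spec <- function(width_px = 2048L, height_px = 2048L, tile = 16L,
                        zone_fractions = c(0.25, 0.35, 0.40),
                        n_types = 6L, n_cells = 1800L,
                        landmarks_per_type = 2L,
                        p_on_self = 0.9, p_on_other = 0.03,
                        mu_on = 4, sd_on = 0.6, mu_off = 0.2, sd_off = 0.2,
                        detection = 0.35, noise_sd = 0.3, dropout = 0,
                        extra_genes = NULL, seed = 1L) {
  if (abs(sum(zone_fractions) - 1) > 1e-8)
    stop("tissue_spec: zone fractions must sum to 1")
  if (any(zone_fractions <= 0)) stop("tissue_spec: zone fractions must be > 0")
  if (detection < 0 || detection > 1 || p_on_self < 0 || p_on_self > 1 ||
      p_on_other < 0 || p_on_other > 1 || dropout < 0 || dropout > 1)
    stop("tissue_spec: probabilities must lie in [0, 1]")
  if (sd_on <= 0 || sd_off <= 0) stop("tissue_spec: SDs must be > 0")
  n_zones <- length(zone_fractions)
  if (n_types < n_zones) stop("tissue_spec: need at least one type per zone")
  structure(
    list(width_px = width_px, height_px = height_px, tile = tile,
         zone_fractions = zone_fractions, n_types = n_types,
         n_cells = n_cells, landmarks_per_type = landmarks_per_type,
         p_on_self = p_on_self, p_on_other = p_on_other,
         mu_on = mu_on, sd_on = sd_on, mu_off = mu_off, sd_off = sd_off,
         detection = detection, noise_sd = noise_sd, dropout = dropout,
         extra_genes = extra_genes, seed = seed,
         zone_of_type = (seq_len(n_types) - 1L) %% n_zones + 1L),
    class = "tissue_spec")
}

#' Simulate a synthetic tissue
#'
#' @param spec A [tissue_spec()].
#' @return A \code{synthetic_tissue}: \code{cells} (data.frame id, x, y,
#'   zone, type in placement order), \code{reads} (ISS spot table),
#'   \code{expr} (dissociated cells x genes matrix, rows shuffled, rownames
#'   = cell ids), \code{panel} (landmark symbols), \code{grid}
#'   ([grid_spec()]), \code{spec}, and \code{zone_of_bin} (integer per bin,
#'   0 outside the tissue disc).
#' @export
simulate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  grid <- grid_spec(spec$width_px, spec$height_px, spec$tile)
  cx <- spec$width_px / 2; cy <- spec$height_px / 2
  R <- min(cx, cy) * 0.98
  # concentric zone radii from cumulative area fractions
  r_out <- R * sqrt(cumsum(spec$zone_fractions))
  r_in <- c(0, r_out[-length(r_out)])
  n_zones <- length(spec$zone_fractions)

  # expected per-zone cell counts proportional to area fractions
  zone <- sample.int(n_zones, spec$n_cells, replace = TRUE,
                     prob = spec$zone_fractions)
  # uniform placement within each annulus
  u <- stats::runif(spec$n_cells)
  rad <- sqrt(r_in[zone]^2 + u * (r_out[zone]^2 - r_in[zone]^2))
  th <- stats::runif(spec$n_cells, 0, 2 * pi)
  x <- pmin(pmax(cx + rad * cos(th), 0), spec$width_px - 1e-6)
  y <- pmin(pmax(cy + rad * sin(th), 0), spec$height_px - 1e-6)
  type_candidates <- split(seq_len(spec$n_types), spec$zone_of_type)
  type <- vapply(zone, function(z) {
    cand <- type_candidates[[z]]
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, integer(1))
  cells <- data.frame(id = sprintf("cell%04d", seq_len(spec$n_cells)),
                      x = x, y = y, zone = zone, type = type,
                      stringsAsFactors = FALSE)

  # landmark panel and on/off states
  L <- spec$n_types * spec$landmarks_per_type
  panel <- sprintf("LM%02d", seq_len(L))
  type_of_landmark <- rep(seq_len(spec$n_types), each = spec$landmarks_per_type)
  p_on <- matrix(spec$p_on_other, spec$n_types, L)
  p_on[cbind(type_of_landmark, seq_len(L))] <- spec$p_on_self
  on_state <- matrix(stats::rbinom(spec$n_cells * L, 1L,
                                   p_on[cells$type, ]) == 1L,
                     spec$n_cells, L)
  expr_lm <- matrix(stats::rnorm(spec$n_cells * L,
                                 ifelse(on_state, spec$mu_on, spec$mu_off),
                                 ifelse(on_state, spec$sd_on, spec$sd_off)),
                    spec$n_cells, L)
  expr_lm <- pmax(expr_lm, 0)
  colnames(expr_lm) <- panel

  # extra (non-landmark) genes
  expr_xg <- NULL
  if (length(spec$extra_genes)) {
    expr_xg <- sapply(spec$extra_genes, function(gdef) {
      p <- ifelse(cells$type %in% gdef$types, gdef$p_on, spec$p_on_other)
      on <- stats::rbinom(spec$n_cells, 1L, p) == 1L
      pmax(stats::rnorm(spec$n_cells,
                        ifelse(on, gdef$mu_on, gdef$mu_off),
                        ifelse(on, gdef$sd_on, gdef$sd_off)), 0)
    })
    colnames(expr_xg) <- names(spec$extra_genes)
  }

  # ISS reads: one Bernoulli(detection) trial per on-state cell-landmark
  det <- on_state & matrix(stats::runif(spec$n_cells * L) < spec$detection,
                           spec$n_cells, L)
  idx <- which(det, arr.ind = TRUE)
  reads <- data.frame(gene = panel[idx[, 2L]],
                      x = cells$x[idx[, 1L]], y = cells$y[idx[, 1L]],
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$gene, reads$x, reads$y), , drop = FALSE]
  rownames(reads) <- NULL

  # dissociated matrix: noise, optional dropout, shuffled rows
  expr <- cbind(expr_lm, expr_xg)
  expr_noisy <- pmax(expr + matrix(stats::rnorm(length(expr), 0, spec$noise_sd),
                                   nrow(expr)), 0)
  if (spec$dropout > 0)
    expr_noisy[matrix(stats::runif(length(expr_noisy)) < spec$dropout,
                      nrow(expr_noisy))] <- 0
  dimnames(expr_noisy) <- list(cells$id, colnames(expr))
  perm <- sample.int(spec$n_cells)
  expr_noisy <- expr_noisy[perm, , drop = FALSE]

  # ground-truth zone of each bin (zone of the tile centre; 0 outside disc)
  rc <- bin_row_col(seq_len(n_bins(grid)), grid)
  bx <- (rc[, "col"] - 0.5) * spec$tile
  by <- (rc[, "row"] - 0.5) * spec$tile
  br <- sqrt((bx - cx)^2 + (by - cy)^2)
  zone_of_bin <- integer(n_bins(grid))
  for (z in rev(seq_len(n_zones))) zone_of_bin[br <= r_out[z]] <- z

  structure(
    list(cells = cells, reads = reads, expr = expr_noisy, panel = panel,
         grid = grid, spec = spec, zone_of_bin = zone_of_bin,
         type_of_landmark = type_of_landmark),
    class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf(
    "synthetic_tissue: %d cells, %d types, %d zones, %d landmarks, %d reads on a %d x %d-bin grid\n",
    nrow(x$cells), x$spec$n_types, length(x$spec$zone_fractions),
    length(x$panel), nrow(x$reads), x$grid$bins_h, x$grid$bins_w))
  invisible(x)
}

#' Mapping accuracy against synthetic ground truth
#'
#' For each cell, the row of P is renormalised into that cell's distribution
#' over bins; the zone mass is the probability assigned to bins of the
#' cell's true zone and the expected distance is the mean bin-distance to
#' the true position. Enrichment is zone mass over the chance level (the
#' zone's share of all bins, which is what a uniform mapping attains).
#'
#' @param mm A \code{mapping_matrix} built on the tissue's grid.
#' @param tissue A \code{synthetic_tissue}.
#' @return List: \code{per_cell} data.frame (\code{id}, \code{zone_mass},
#'   \code{chance}, \code{expected_dist}), \code{mean_zone_mass},
#'   \code{mean_enrichment}.
#' @export
mapping_accuracy <- function(mm, tissue) {
  stopifnot(inherits(mm, "mapping_matrix"), inherits(tissue, "synthetic_tissue"))
  ids <- rownames(tissue$expr)
  if (is.null(mm$cell_ids) || !setequal(mm$cell_ids, ids))
    stop("mapping_accuracy: cell ids of mapping and tissue do not align")
  ord <- match(ids, mm$cell_ids)
  truth <- tissue$cells[match(ids, tissue$cells$id), ]
  grid <- tissue$grid
  rc <- bin_row_col(seq_len(ncol(mm$P)), grid)
  bin_x <- (rc[, "col"] - 0.5) * grid$tile
  bin_y <- (rc[, "row"] - 0.5) * grid$tile
  zb <- tissue$zone_of_bin
  nbin_total <- length(zb)
  chance <- vapply(seq_along(ids), function(i)
    sum(zb == truth$zone[i]) / nbin_total, numeric(1))
  Pt <- methods::as(Matrix::t(mm$P), "CsparseMatrix")  # bins x cells
  pp <- Pt@p; pi <- Pt@i; px <- Pt@x
  zone_mass <- numeric(length(ids)); edist <- numeric(length(ids))
  for (i in seq_along(ids)) {
    j <- ord[i]
    rng <- if (pp[j + 1L] > pp[j]) (pp[j] + 1L):pp[j + 1L] else integer(0)
    if (!length(rng)) { zone_mass[i] <- NA; edist[i] <- NA; next }
    nz <- pi[rng] + 1L
    r <- px[rng] / sum(px[rng])
    zone_mass[i] <- sum(r[zb[nz] == truth$zone[i]])
    edist[i] <- sum(r * sqrt((bin_x[nz] - truth$x[i])^2 +
                               (bin_y[nz] - truth$y[i])^2)) / grid$tile
  }
  per_cell <- data.frame(id = ids, zone_mass = zone_mass, chance = chance,
                         expected_dist = edist)
  list(per_cell = per_cell,
       mean_zone_mass = mean(zone_mass, na.rm = TRUE),
       mean_enrichment = mean(zone_mass / chance, na.rm = TRUE))
}
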