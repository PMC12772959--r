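#' Read a CellPhoneDB-style ligand-receptor complex table
#'
#' Expects the minimal CSV layout used by curated interaction databases:
#' columns \code{id}, \code{ligand} and \code{receptor}, the latter two
#' holding gene symbols with multi-component complexes joined by \code{+}
#' (e.g. \code{"Fzd3+Lrp6"}). Additional columns are carried along as
#' metadata.
#'
#' @param path CSV (or TSV) file path.
#' @return A \code{complex_table}: data.frame with list-columns
#'   \code{ligand_components} and \code{receptor_components}.
#' @export
read_complex_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("id", "ligand", "receptor")
  if (!all(need %in% names(df)))
    stop("complex table must have columns 'id', 'ligand', 'receptor'")
  complex_table(df$id, strsplit(df$ligand, "+", fixed = TRUE),
                strsplit(df$receptor, "+", fixed = TRUE))
}

#' Construct a ligand-receptor complex table in code
#'
#' @param id Interaction identifiers.
#' @param ligand_components,receptor_components Lists of gene-symbol
#'   vectors, one entry per interaction.
#' @return A \code{complex_table}.
#' @export
complex_table <- function(id, ligand_components, receptor_components) {
  if (any(lengths(ligand_components) == 0L) ||
      any(lengths(receptor_components) == 0L))
    stop("complex_table: empty component list")
  d <- data.frame(id = as.character(id), stringsAsFactors = FALSE)
  d$ligand_components <- ligand_components
  d$receptor_components <- receptor_components
  structure(d, class = c("complex_table", "data.frame"))
}

#' Stoichiometric complex expression per cell
#'
#' A multi-subunit complex is only functional where all subunits are
#' present, so its per-cell expression is the minimum across component
#' genes. Gene matching is case-insensitive.
#'
#' @param expr Cells x genes matrix with column names.
#' @param components Character vector of component gene symbols.
#' @return Numeric per-cell vector.
#' @export
complex_expression <- function(expr, components) {
  if (length(components) == 0L) stop("complex_expression: empty component list")
  j <- match(tolower(components), tolower(colnames(expr)))
  if (anyNA(j))
    stop("complex_expression: gene(s) not in expression matrix: ",
         paste(components[is.na(j)], collapse = ", "))
  sub <- expr[, j, drop = FALSE]
  apply(sub, 1L, min)
}

#' Spatial abundance of a per-cell quantity
#'
#' Projects the per-cell vector through the mapping matrix into a per-bin
#' expectation and returns the supported bins as a weighted spatial
#' distribution (bins below \code{floor} dropped).
#'
#' @param mm A \code{mapping_matrix}.
#' @param v Per-cell values (e.g. [complex_expression()]).
#' @param floor Mass floor below which bins are dropped (default 1e-8).
#' @param max_support Upper bound on the number of supported bins; when the
#'   field is broader, only the \code{max_support} highest-mass bins are
#'   kept (they carry the bulk of the expectation; the transport stage cost
#'   grows with the square of the support size). Default 400.
#' @param mask Optional logical bins_h x bins_w matrix; bins outside it are
#'   dropped before the floor and the support cap. Pass the assayed tissue
#'   support so unmeasured background bins (which all share the all-zero
#'   landmark signature) cannot soak up abundance mass.
#' @return A \code{spatial_distribution}.
#' @export
spatial_abundance <- function(mm, v, floor = 1e-8, max_support = 400L,
                              mask = NULL) {
  fld <- project_feature(mm, v, name = "abundance")
  w <- fld$values
  if (!is.null(mask)) w <- w * mask
  idx <- which(w > floor)
  if (length(idx) == 0L)
    stop("spatial_abundance: no bin retains mass above the floor")
  if (length(idx) > max_support)
    idx <- idx[order(-w[idx])[seq_len(max_support)]]
  nr <- nrow(w)
  spatial_distribution(cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L),
                       w[idx])
}

#' Rank ligand-receptor interactions by spatial plausibility
#'
#' For each curated interaction: the ligand and receptor complex expressions
#' (stoichiometric minima) are projected into spatial abundance fields; the
#' debiased Sinkhorn divergence between the two fields measures their
#' spatial separation; reach-limited transport moves ligand mass to receptor
#' bins and yields the mean receptor saturation. The composite score
#' \deqn{score = \bar a_L \, \bar a_R \, e^{-S / reach^2}}
#' (abundance product damped by separation relative to the squared reach) is
#' one documented choice; all raw terms are reported so users can re-rank.
#' Interactions with unresolvable genes are skipped with a warning.
#'
#' @param db A \code{complex_table}.
#' @param expr Cells x genes matrix (imputed expression).
#' @param mm A \code{mapping_matrix} for the same cells.
#' @param reach Transport reach in bins.
#' @param blur Sinkhorn length scale in bins.
#' @param mask Optional logical bins_h x bins_w matrix restricting scoring
#'   to a region (typically the assayed tissue support; see
#'   [spatial_abundance()]).
#' @return A \code{ccc_ranking} data.frame sorted by descending score:
#'   \code{id}, \code{ligand_abundance}, \code{receptor_abundance},
#'   \code{divergence}, \code{mean_saturation}, \code{score}.
#' @export
rank_interactions <- function(db, expr, mm, reach = 10, blur = 2,
                              mask = NULL) {
  stopifnot(inherits(db, "complex_table"))
  rows <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    lg <- db$ligand_components[[i]]; rg <- db$receptor_components[[i]]
    missing <- c(lg, rg)[!tolower(c(lg, rg)) %in% tolower(colnames(expr))]
    if (length(missing)) {
      warning("rank_interactions: skipping ", db$id[i],
              " (missing gene(s): ", paste(missing, collapse = ", "), ")")
      next
    }
    vl <- complex_expression(expr, lg)
    vr <- complex_expression(expr, rg)
    if (all(vl == 0) || all(vr == 0)) {
      rows[[i]] <- data.frame(id = db$id[i], ligand_abundance = mean(vl),
                              receptor_abundance = mean(vr),
                              divergence = NA_real_,
                              mean_saturation = 0, score = 0)
      next
    }
    dl <- spatial_abundance(mm, vl, mask = mask)
    dr <- spatial_abundance(mm, vr, mask = mask)
    S <- sinkhorn_divergence(dl, dr, blur = blur)
    tr <- transport_ligand(dl, dr, reach = reach, blur = blur)
    rows[[i]] <- data.frame(id = db$id[i],
                            ligand_abundance = mean(vl),
                            receptor_abundance = mean(vr),
                            divergence = S,
                            mean_saturation = mean(tr$saturation),
                            score = mean(vl) * mean(vr) * exp(-S / reach^2))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("rank_interactions: no scorable interaction")
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ccc_ranking", "data.frame")
  out
}

mask_distribution <- function(d, mask) {
  keep <- mask[cbind(d$points[, 1L], d$points[, 2L])]
  if (!any(keep)) stop("mask_distribution: no support inside mask")
  spatial_distribution(d$points[keep, , drop = FALSE], d$weights[keep])
}

#' @export
print.ccc_ranking <- function(x, ...) {
  cat(sprintf("ccc_ranking: %d interaction(s)\n", nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}
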