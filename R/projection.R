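#' Project a per-cell feature into a spatial field
#'
#' The expectation of a per-cell feature under each bin's distribution over
#' cells: field value at bin \eqn{i} is \eqn{\sum_c P_{ci} f_c}. Because the
#' columns of P are probability distributions, the field is a convex
#' combination of feature values and inherits the feature's bounds. Works for
#' gene expression, gene-set or regulon scores, or any other numeric
#' annotation.
#'
#' @param mm A \code{mapping_matrix} (see [build_mapping()]).
#' @param f Numeric per-cell feature, length = number of cells.
#' @param name Feature name recorded in the result.
#' @return A \code{spatial_field}: \code{values} (bins_h x bins_w matrix),
#'   \code{name}, \code{sigma} (smoothing applied, 0 here), \code{provenance}.
#' @export
project_feature <- function(mm, f, name = "feature") {
  stopifnot(inherits(mm, "mapping_matrix"))
  if (length(f) != nrow(mm$P))
    stop("project_feature: feature length ", length(f),
         " does not match ", nrow(mm$P), " cells")
  if (!all(is.finite(f))) stop("project_feature: non-finite feature values")
  v <- as.numeric(Matrix::crossprod(mm$P, f))
  structure(list(values = matrix(v, mm$grid$bins_h, mm$grid$bins_w),
                 name = name, sigma = 0, provenance = "score",
                 grid = mm$grid),
            class = "spatial_field")
}

#' Project a categorical annotation as an indicator field
#'
#' Encodes membership of \code{target} as a 0/1 vector and projects it; the
#' field value at a bin is the probability that the bin's cell carries the
#' annotation, in [0, 1]. Indicator fields over a full partition of the cells
#' sum to 1 at every bin.
#'
#' @param mm A \code{mapping_matrix}.
#' @param labels Per-cell category labels.
#' @param target The category to project.
#' @return A \code{spatial_field} with provenance \code{"indicator"}.
#' @export
project_indicator <- function(mm, labels, target) {
  if (!target %in% labels)
    stop("project_indicator: category '", target, "' not present in labels")
  fld <- project_feature(mm, as.numeric(labels == target),
                         name = paste0("indicator:", target))
  fld$provenance <- "indicator"
  fld
}

#' @export
print.spatial_field <- function(x, ...) {
  cat(sprintf("spatial_field '%s': %d x %d bins, range [%.4g, %.4g], sigma = %g\n",
              x$name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values), x$sigma))
  invisible(x)
}

#' Gaussian smoothing of a spatial field
#'
#' Because the bin-wise distributions are inferred independently per unique
#' signature, adjacent bins can jump abruptly; a small Gaussian blur
#' suppresses that high-frequency noise. Separable convolution with a
#' truncated (4 sigma) kernel and reflective boundaries; \code{sigma = 0} is
#' the identity.
#'
#' @param field A \code{spatial_field}.
#' @param sigma Kernel standard deviation in bins.
#' @return A smoothed \code{spatial_field}.
#' @export
smooth_field <- function(field, sigma = 1) {
  stopifnot(inherits(field, "spatial_field"))
  if (sigma < 0) stop("smooth_field: sigma must be >= 0")
  if (sigma == 0) return(field)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  v <- field$values
  v <- apply(v, 2L, conv_reflect, k = k)            # along rows
  v <- t(apply(v, 1L, conv_reflect, k = k))         # along cols
  field$values <- v
  field$sigma <- sqrt(field$sigma^2 + sigma^2)
  field
}

# 1-D convolution with reflective (symmetric, repeatedly folded) padding, so
# kernels wider than the grid still behave.
conv_reflect <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  n <- length(x)
  pos <- (1L - r):(n + r)
  # fold indices into [1, n] by symmetric reflection with period 2n
  m <- (pos - 1L) %% (2L * n)
  m <- ifelse(m >= n, 2L * n - 1L - m, m)
  xp <- x[m + 1L]
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
}

#' Percentile threshold of a spatial field
#'
#' The threshold is the \code{q}-th percentile of the *non-zero* field values
#' (zeros dominate sparse fields and would collapse any percentile); the mask
#' keeps bins with value >= threshold.
#'
#' @param field A \code{spatial_field}.
#' @param q Percentile in [0, 100].
#' @return A \code{threshold_result}: \code{threshold}, \code{mask} (logical
#'   matrix), \code{method}.
#' @export
threshold_percentile <- function(field, q) {
  stopifnot(inherits(field, "spatial_field"))
  if (q < 0 || q > 100) stop("threshold_percentile: q must be in [0, 100]")
  nz <- field$values[field$values > 0]
  if (length(nz) == 0L) stop("threshold_percentile: field has no non-zero values")
  thr <- as.numeric(stats::quantile(nz, q / 100, names = FALSE))
  structure(list(threshold = thr, mask = field$values >= thr,
                 method = sprintf("percentile:%g", q)),
            class = "threshold_result")
}

#' Automatic elbow threshold of a spatial field
#'
#' The sorted unique non-zero expected values of a projected field typically
#' trace an inverted-sigmoid curve: a long shallow tail of background values
#' followed by a steep rise of genuine signal. The elbow is located by
#' fitting one line to \code{k} consecutive sorted values starting at the
#' median index and another to the \code{k} largest values; the threshold is
#' the sorted value nearest the intersection abscissa.
#'
#' @param field A \code{spatial_field}.
#' @param k Window size for each linear fit (default 20).
#' @param anchor \code{"median"} (default) starts the lower window at the
#'   median index of the sorted unique values; \code{"smallest"} starts it at
#'   the first (smallest) value.
#' @return A \code{threshold_result} with diagnostic slopes in
#'   \code{$lines}.
#' @export
auto_threshold <- function(field, k = 20L, anchor = c("median", "smallest")) {
  stopifnot(inherits(field, "spatial_field"))
  anchor <- match.arg(anchor)
  if (k < 2L) stop("auto_threshold: k must be >= 2")
  u <- sort(unique(field$values[field$values > 0]))
  m <- length(u)
  if (m < 2L * k)
    stop("auto_threshold: need at least 2k = ", 2L * k,
         " unique non-zero values, have ", m)
  lo_start <- if (anchor == "median") (m + 1L) %/% 2L else 1L
  lo_start <- min(lo_start, m - k + 1L)  # window must fit
  lo_idx <- lo_start:(lo_start + k - 1L)
  hi_idx <- (m - k + 1L):m
  f1 <- stats::lm.fit(cbind(1, lo_idx), u[lo_idx])$coefficients
  f2 <- stats::lm.fit(cbind(1, hi_idx), u[hi_idx])$coefficients
  if (abs(f1[2] - f2[2]) < 1e-12 * (abs(f1[2]) + abs(f2[2]) + 1e-300))
    stop("auto_threshold: fitted lines are parallel; try a larger k")
  x_star <- (f2[1] - f1[1]) / (f1[2] - f2[2])
  i_star <- min(max(round(x_star), 1L), m)
  thr <- u[i_star]
  structure(list(threshold = thr, mask = field$values >= thr,
                 method = sprintf("auto-elbow:k=%d,anchor=%s", k, anchor),
                 lines = list(lower = f1, upper = f2, x_star = x_star)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result (%s): threshold = %.6g, %d bins retained\n",
              x$method, x$threshold, sum(x$mask)))
  invisible(x)
}

#' Compose thresholded fields into an RGB overlay
#'
#' Purely presentational: each field is thresholded (or taken whole), scaled
#' to [0, 1], tinted with its colour and summed into an RGB raster; the
#' result can be written as PNG with \code{png::writePNG()}. Point rendering
#' at a nominal physical diameter is approximated by dilating each retained
#' bin to a disc of the corresponding radius.
#'
#' @param fields List of \code{spatial_field}s sharing one grid.
#' @param colors Character vector of colours, one per field.
#' @param thresholds Optional list of \code{threshold_result}s (or NULL
#'   entries for no thresholding).
#' @param point_um Nominal point diameter in micrometres (display only).
#' @param um_per_bin Physical bin edge; with 0.2 um pixels and 16 px tiles
#'   the default is 3.2.
#' @return Numeric array \code{bins_h x bins_w x 3} with values in [0, 1].
#' @export
composite_render <- function(fields, colors, thresholds = NULL,
                             point_um = 15, um_per_bin = 3.2) {
  if (length(fields) != length(colors))
    stop("composite_render: need one colour per field")
  dims <- dim(fields[[1]]$values)
  img <- array(0, c(dims, 3L))
  rad <- max(0L, round(point_um / um_per_bin / 2))
  for (i in seq_along(fields)) {
    v <- fields[[i]]$values
    if (!identical(dim(v), dims))
      stop("composite_render: fields must share one grid")
    if (!is.null(thresholds) && !is.null(thresholds[[i]]))
      v <- v * thresholds[[i]]$mask
    if (max(v) > 0) v <- v / max(v)
    if (rad > 0L) v <- dilate_disc(v, rad)
    rgb <- grDevices::col2rgb(colors[i]) / 255
    for (ch in 1:3) img[, , ch] <- img[, , ch] + v * rgb[ch]
  }
  pmin(img, 1)
}

# Max-dilation of a grid by a disc of radius r bins.
dilate_disc <- function(v, r) {
  out <- v
  for (dr in -r:r) for (dc in -r:r) {
    if (dr * dr + dc * dc > r * r || (dr == 0 && dc == 0)) next
    sh <- shift_grid(v, dr, dc)
    out <- pmax(out, sh)
  }
  out
}

shift_grid <- function(v, dr, dc) {
  n <- nrow(v); m <- ncol(v)
  out <- matrix(0, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  out[rs, cs] <- v[rs - dr, cs - dc]
  out
}

#' Write a spatial field as a TSV grid
#' @param field A \code{spatial_field}.
#' @param path Output path.
#' @export
write_field <- function(field, path) {
  utils::write.table(field$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
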