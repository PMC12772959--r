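#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Plain EM with multiple seeded restarts, a log-likelihood convergence
#' tolerance and a variance floor. Used internally by [fit_on_off()]; exposed
#' because it is also a convenient independent building block.
#'
#' @param x Numeric vector of observations.
#' @param k Number of components.
#' @param n_restarts Random restarts; the best achieved log-likelihood wins.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations per restart.
#' @param var_floor Lower bound on component variances.
#' @param seed Integer seed controlling restart initialisation.
#' @return List: \code{mean}, \code{var}, \code{weight} (length \code{k},
#'   unordered), \code{loglik}, \code{converged}.
#' @export
fit_gmm1d <- function(x, k, n_restarts = 5L, tol = 1e-6, max_iter = 200L,
                      var_floor = 1e-6, seed = 1L) {
  n <- length(x)
  stopifnot(k >= 1L, n >= k)
  best <- NULL
  rs <- local({ set.seed(seed); sample.int(.Machine$integer.max, n_restarts) })
  for (r in seq_len(n_restarts)) {
    set.seed(rs[r])
    # initialise means at random data points, equal weights, common variance
    mu <- sort(sample(x, k)) + stats::rnorm(k, 0, stats::sd(x) / 100 + 1e-9)
    v <- rep(max(stats::var(x) / k, var_floor), k)
    w <- rep(1 / k, k)
    fit <- .em_gmm1d_run(x, mu, v, w, tol, max_iter, var_floor)
    if (is.finite(fit$loglik) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop("fit_gmm1d: EM failed to produce a finite-likelihood fit after ",
         n_restarts, " restarts")
  best
}

#' Two-population on/off summary of a landmark's imputed expression
#'
#' Fits Gaussian mixtures with \code{k} components for each \code{k} in
#' \code{k_range} and selects the best-supported component count. The
#' component with the highest mean is the "on" population (cells expressing
#' the landmark); the remaining components are pooled by moment matching
#' into a single "off" normal: the pooled mean is the weight-averaged
#' component mean and the pooled variance is the weighted second moment
#' about the pooled mean.
#'
#' Model selection defaults to BIC. Selecting by raw likelihood always
#' favours the largest \code{k} (the models are nested), and the extra
#' components split the expressing mode, so the "highest-mean = on" rule
#' would summarise only a sliver of it and pool the rest into "off";
#' \code{selection = "loglik"} provides that literal alternative.
#'
#' @param x Numeric vector: imputed expression of one landmark across cells.
#' @param k_range Candidate component counts (default \code{2:8}).
#' @param landmark Name used in error messages and the result.
#' @param seed Integer seed for EM restarts.
#' @param selection \code{"bic"} (default) or \code{"loglik"}.
#' @param ... Passed to [fit_gmm1d()].
#' @return An \code{on_off_model}: \code{landmark}, \code{mu_on},
#'   \code{var_on}, \code{mu_off}, \code{var_off}, \code{k_selected},
#'   \code{loglik}.
#' @export
fit_on_off <- function(x, k_range = 2:8, landmark = "landmark", seed = 1L,
                       selection = c("bic", "loglik"), ...) {
  selection <- match.arg(selection)
  x <- as.numeric(x)
  if (length(x) < 20L)
    stop("fit_on_off: need >= 20 cells for landmark ", landmark)
  if (!all(is.finite(x))) stop("fit_on_off: non-finite expression for ", landmark)
  if (stats::var(x) <= 0)
    stop("fit_on_off: constant expression for landmark ", landmark,
         "; no on/off structure to fit")
  fits <- lapply(k_range, function(k)
    fit_gmm1d(x, k, seed = seed + k, ...))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  crit <- if (selection == "bic")
    2 * ll - (3 * k_range - 1) * log(length(x)) else ll
  best <- fits[[which.max(crit)]]
  pool_on_off(best, k_selected = k_range[which.max(crit)],
              loglik = ll[which.max(crit)], landmark = landmark)
}

# Reduce a fitted mixture to on/off parameters (moment matching for "off").
pool_on_off <- function(fit, k_selected, loglik, landmark) {
  on <- which.max(fit$mean)
  off <- setdiff(seq_along(fit$mean), on)
  w <- fit$weight[off] / sum(fit$weight[off])
  mu_off <- sum(w * fit$mean[off])
  var_off <- sum(w * (fit$var[off] + fit$mean[off]^2)) - mu_off^2
  structure(
    list(landmark = landmark,
         mu_on = fit$mean[on], var_on = max(fit$var[on], 1e-6),
         mu_off = mu_off, var_off = max(var_off, 1e-6),
         k_selected = k_selected, loglik = loglik),
    class = "on_off_model")
}

#' @export
print.on_off_model <- function(x, ...) {
  cat(sprintf("on_off_model %s: on N(%.3f, %.3f), off N(%.3f, %.3f), k=%d, loglik=%.1f\n",
              x$landmark, x$mu_on, x$var_on, x$mu_off, x$var_off,
              x$k_selected, x$loglik))
  invisible(x)
}

#' Fit on/off models for a whole landmark panel
#'
#' Landmarks absent from the expression matrix, duplicated in the panel, or
#' with zero reads across all cells are dropped with a warning (an all-zero
#' landmark carries no information and cannot support a mixture fit).
#'
#' @param expr Cells x genes matrix of imputed normalized log-expression with
#'   column names.
#' @param panel Character vector of landmark symbols.
#' @param k_range,seed,... Passed to [fit_on_off()].
#' @return An \code{on_off_model_set}: list with \code{models} (named list of
#'   \code{on_off_model}), \code{panel} (retained landmark order), and
#'   \code{table} (one row per retained landmark).
#' @export
fit_all_landmarks <- function(expr, panel, k_range = 2:8, seed = 1L, ...) {
  if (length(panel) == 0L) stop("fit_all_landmarks: empty panel")
  if (anyDuplicated(panel)) {
    warning("fit_all_landmarks: duplicated panel entries collapsed")
    panel <- unique(panel)
  }
  missing <- setdiff(panel, colnames(expr))
  if (length(missing)) {
    warning("fit_all_landmarks: landmark(s) absent from expression matrix, excluded: ",
            paste(missing, collapse = ", "))
    panel <- setdiff(panel, missing)
  }
  zero <- panel[vapply(panel, function(g) all(expr[, g] == 0), logical(1))]
  if (length(zero)) {
    warning("fit_all_landmarks: landmark(s) with no reads excluded: ",
            paste(zero, collapse = ", "))
    panel <- setdiff(panel, zero)
  }
  if (length(panel) < 2L)
    stop("fit_all_landmarks: fewer than 2 usable landmarks remain")
  models <- lapply(panel, function(g)
    fit_on_off(expr[, g], k_range = k_range, landmark = g, seed = seed, ...))
  names(models) <- panel
  tab <- do.call(rbind, lapply(models, function(m)
    data.frame(landmark = m$landmark, mu_on = m$mu_on, var_on = m$var_on,
               mu_off = m$mu_off, var_off = m$var_off, k = m$k_selected,
               loglik = m$loglik)))
  rownames(tab) <- NULL
  structure(list(models = models, panel = panel, table = tab),
            class = "on_off_model_set")
}

#' @export
print.on_off_model_set <- function(x, ...) {
  cat(sprintf("on_off_model_set: %d landmarks\n", length(x$panel)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Write an on/off model set as TSV
#' @param models An \code{on_off_model_set}.
#' @param path Output path.
#' @export
write_on_off_models <- function(models, path) {
  utils::write.table(models$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an on/off model set from TSV
#' @param path Path written by [write_on_off_models()].
#' @return An \code{on_off_model_set}.
#' @export
read_on_off_models <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i)
    structure(list(landmark = tab$landmark[i], mu_on = tab$mu_on[i],
                   var_on = tab$var_on[i], mu_off = tab$mu_off[i],
                   var_off = tab$var_off[i], k_selected = tab$k[i],
                   loglik = tab$loglik[i]),
              class = "on_off_model"))
  names(models) <- tab$landmark
  structure(list(models = models, panel = tab$landmark, table = tab),
            class = "on_off_model_set")
}
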