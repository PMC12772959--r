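#' Bayesian probability that clusters are marked by a gene
#'
#' Given the imputed expression of one gene and a cluster assignment for
#' every cell, estimates for each cluster the posterior probability that the
#' cluster is "marked" by the gene — that its mean expression lies above a
#' latent threshold separating expressing from non-expressing clusters, with
#' a sigmoid decision boundary of latent sharpness.
#'
#' Model: \eqn{x_j \sim N(\mu_{c(j)}, \sigma_{c(j)}^2)} with
#' \eqn{\mu_k \sim N(\hat m, \hat s^2)} (hyper-parameters estimated from the
#' reference expression pool) and \eqn{\sigma_k} given a positive-truncated
#' Cauchy prior located and scaled by the pool's median absolute deviation.
#' The threshold \eqn{T} is normally distributed and the decision sharpness
#' \eqn{\alpha} follows a half-Cauchy; neither enters the likelihood (the
#' data cannot refine them), so their posteriors equal their priors. The
#' threshold prior is anchored by the gene's own on/off mixture summary:
#' \eqn{T \sim N((\mu_{on}+\mu_{off})/2, ((\mu_{on}-\mu_{off})/6)^2)}, i.e.
#' essentially all prior mass lies between the two expression modes, and
#' \eqn{\alpha \sim \mathrm{halfCauchy}(0, 10)}. The marking probability of
#' cluster \eqn{k} in one posterior draw is
#' \eqn{\mathrm{logistic}(\alpha(\mu_k - T))}.
#'
#' Sampling: \eqn{\mu_k} by conjugate Gibbs updates, \eqn{\log \sigma_k} by
#' adaptive random-walk Metropolis (step sizes tuned during warm-up),
#' \eqn{T, \alpha} drawn from their (conditional = prior) distributions;
#' 4 chains, 50% warm-up. Split-R-hat on the cluster means must not exceed
#' 1.05.
#'
#' @param x Numeric vector: imputed expression of the gene, one value per
#'   cell.
#' @param clusters Per-cell cluster labels (factor or vector); every cluster
#'   needs >= 5 cells.
#' @param n_samples Total retained posterior draws across chains
#'   (default 2000; the high-fidelity setting is 10000).
#' @param pool Optional numeric vector/matrix of reference expression (all
#'   genes x all cells) used to estimate the hyper-parameters; defaults to
#'   \code{x} itself.
#' @param n_chains Number of chains (default 4).
#' @param seed Integer seed; the sampler is deterministic given it.
#' @return A \code{marking_model}: \code{clusters} (levels), \code{draws}
#'   (n_samples x K matrix of marking probabilities), \code{mu_draws},
#'   \code{T_draws}, \code{alpha_draws}, \code{rhat}, \code{priors}.
#' @export
fit_marking_model <- function(x, clusters, n_samples = 2000L, pool = NULL,
                              n_chains = 4L, seed = 1L) {
  x <- as.numeric(x)
  cl <- factor(clusters)
  if (length(cl) != length(x))
    stop("fit_marking_model: one cluster label per cell required")
  K <- nlevels(cl)
  if (K < 2L) stop("fit_marking_model: need >= 2 clusters")
  nk <- table(cl)
  if (any(nk < 5L))
    stop("fit_marking_model: cluster(s) with < 5 cells: ",
         paste(names(nk)[nk < 5], collapse = ", "))
  pool <- if (is.null(pool)) x else as.numeric(pool)
  m0 <- mean(pool); s0 <- stats::sd(pool)
  smad <- max(stats::mad(pool), 1e-6)
  if (s0 <= 0) stop("fit_marking_model: constant reference pool")
  # threshold prior anchored between the gene's off and on modes
  oo <- fit_on_off(x, landmark = "marking-gene", seed = seed)
  t_mu <- (oo$mu_on + oo$mu_off) / 2
  t_sd <- max((oo$mu_on - oo$mu_off) / 6, 1e-3)
  a_scale <- 10
  idx <- split(seq_along(x), cl)
  sx <- vapply(idx, function(i) sum(x[i]), numeric(1))
  n_per <- lengths(idx)

  per_chain <- ceiling(n_samples / n_chains)
  warm <- per_chain  # 50% warm-up: equal number of discarded draws
  total <- warm + per_chain
  mu_ch <- vector("list", n_chains)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  draws_p <- NULL; draws_mu <- NULL; draws_T <- NULL; draws_a <- NULL
  log_prior_sigma <- function(sig)
    stats::dcauchy(sig, smad, smad, log = TRUE) + log(sig)  # + log-Jacobian
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    mu <- vapply(idx, function(i) mean(x[i]), numeric(1))
    lsig <- log(pmax(vapply(idx, function(i) stats::sd(x[i]), numeric(1)),
                     1e-3))
    step <- rep(0.3, K); acc <- rep(0, K); tune_n <- rep(0, K)
    keep_mu <- matrix(NA_real_, per_chain, K)
    keep_T <- numeric(per_chain); keep_a <- numeric(per_chain)
    for (it in seq_len(total)) {
      sig2 <- exp(2 * lsig)
      # Gibbs for mu_k: conjugate normal
      post_var <- 1 / (n_per / sig2 + 1 / s0^2)
      post_mean <- post_var * (sx / sig2 + m0 / s0^2)
      mu <- stats::rnorm(K, post_mean, sqrt(post_var))
      # adaptive RW-MH for log sigma_k
      for (k in seq_len(K)) {
        prop <- lsig[k] + stats::rnorm(1, 0, step[k])
        xi <- x[idx[[k]]]
        ll_cur <- sum(stats::dnorm(xi, mu[k], exp(lsig[k]), log = TRUE)) +
          log_prior_sigma(exp(lsig[k]))
        ll_prop <- sum(stats::dnorm(xi, mu[k], exp(prop), log = TRUE)) +
          log_prior_sigma(exp(prop))
        if (log(stats::runif(1)) < ll_prop - ll_cur) {
          lsig[k] <- prop
          if (it <= warm) acc[k] <- acc[k] + 1
        }
        if (it <= warm) {
          tune_n[k] <- tune_n[k] + 1
          if (tune_n[k] %% 50 == 0) {  # adapt towards ~44% acceptance
            rate <- acc[k] / 50
            step[k] <- step[k] * ifelse(rate > 0.44, 1.25, 0.8)
            acc[k] <- 0
          }
        }
      }
      # T and alpha: no likelihood term; conditionals are the priors
      Tn <- stats::rnorm(1, t_mu, t_sd)
      an <- abs(stats::rcauchy(1, 0, a_scale))
      if (it > warm) {
        keep_mu[it - warm, ] <- mu
        keep_T[it - warm] <- Tn
        keep_a[it - warm] <- an
      }
    }
    mu_ch[[ch]] <- keep_mu
    draws_mu <- rbind(draws_mu, keep_mu)
    draws_T <- c(draws_T, keep_T)
    draws_a <- c(draws_a, keep_a)
  }
  rhat <- split_rhat(mu_ch)
  if (any(rhat > 1.05))
    stop(sprintf("fit_marking_model: chains not mixed (max split-Rhat %.3f); increase n_samples",
                 max(rhat)))
  p <- stats::plogis(draws_a * (draws_mu - draws_T))
  colnames(p) <- levels(cl)
  colnames(draws_mu) <- levels(cl)
  structure(
    list(clusters = levels(cl), draws = p, mu_draws = draws_mu,
         T_draws = draws_T, alpha_draws = draws_a, rhat = rhat,
         priors = list(mu = c(mean = m0, sd = s0),
                       sigma = c(location = smad, scale = smad),
                       T = c(mean = t_mu, sd = t_sd),
                       alpha = c(scale = a_scale))),
    class = "marking_model")
}

# Split-R-hat across chains for each column of a list of draw matrices.
split_rhat <- function(chains) {
  halves <- do.call(c, lapply(chains, function(m) {
    n <- nrow(m) %/% 2L
    list(m[seq_len(n), , drop = FALSE], m[(n + 1L):(2L * n), , drop = FALSE])
  }))
  vapply(seq_len(ncol(chains[[1]])), function(k) {
    d <- vapply(halves, function(h) c(mean(h[, k]), stats::var(h[, k])),
                numeric(2))
    n <- nrow(halves[[1]])
    B <- n * stats::var(d[1, ])
    W <- mean(d[2, ])
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Marking probability for one posterior draw
#'
#' The sigmoid decision rule \eqn{\mathrm{logistic}(\alpha(\mu_k - T))}:
#' 0.5 exactly at the threshold, approaching a hard step as the sharpness
#' grows.
#'
#' @param mu_k Cluster mean expression in the draw.
#' @param T_draw Threshold in the draw.
#' @param alpha Sharpness in the draw.
#' @return Probability in [0, 1].
#' @export
marking_probability <- function(mu_k, T_draw, alpha) {
  stats::plogis(alpha * (mu_k - T_draw))
}

#' Posterior summary of cluster marking probabilities
#'
#' @param model A \code{marking_model}.
#' @param level Credible level for the equal-tailed interval (default 0.89).
#' @return A \code{marking_summary} data.frame: \code{cluster}, \code{mean},
#'   \code{lo}, \code{hi}.
#' @export
summarize_marking <- function(model, level = 0.89) {
  stopifnot(inherits(model, "marking_model"))
  if (nrow(model$draws) < 100L)
    stop("summarize_marking: need >= 100 posterior draws")
  a <- (1 - level) / 2
  qs <- apply(model$draws, 2L, stats::quantile, probs = c(a, 1 - a),
              names = FALSE)
  out <- data.frame(cluster = model$clusters,
                    mean = colMeans(model$draws),
                    lo = qs[1, ], hi = qs[2, ])
  rownames(out) <- NULL
  class(out) <- c("marking_summary", "data.frame")
  out
}

#' @export
print.marking_model <- function(x, ...) {
  cat(sprintf("marking_model: %d clusters, %d posterior draws (max split-Rhat %.3f)\n",
              length(x$clusters), nrow(x$draws), max(x$rhat)))
  print(summarize_marking(x), digits = 3)
  invisible(x)
}
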