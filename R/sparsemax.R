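#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Projects a real score vector onto the probability simplex
#' \eqn{\{p : p_i \ge 0, \sum_i p_i = 1\}} in the Euclidean metric. Unlike
#' softmax, the projection has sparse support: scores far below the leaders
#' receive exactly zero mass, so each spatial bin's distribution over cells
#' involves only a handful of plausible cells.
#'
#' The closed form follows the standard threshold construction: with
#' \eqn{z_{(1)} \ge z_{(2)} \ge \dots} the sorted scores, the support size is
#' \eqn{k^\* = \max\{k : 1 + k z_{(k)} > \sum_{j \le k} z_{(j)}\}}, the
#' threshold \eqn{\tau = (\sum_{j \le k^\*} z_{(j)} - 1)/k^\*}, and the output
#' is \eqn{\max(z_i - \tau, 0)}.
#'
#' @param z Numeric vector of scores (finite).
#' @return Numeric vector of the same length: non-negative, sums to 1.
#' @seealso [sparsegen_lin()] for the sparsity-controlled generalisation.
#' @examples
#' sparsemax(c(2, 0, 0))        # one-hot
#' sparsemax(c(0.6, 0.4, 0))    # already on the simplex
#' @export
sparsemax <- function(z) {
  if (length(z) == 0L) stop("sparsemax: empty input vector")
  if (!all(is.finite(z))) stop("sparsemax: non-finite scores")
  # shift-invariance of the projection: subtract max for numerical safety
  z <- z - max(z)
  zs <- sort(z, decreasing = TRUE)
  css <- cumsum(zs)
  k <- seq_along(zs)
  supp <- k[1 + k * zs > css]
  kstar <- supp[length(supp)]
  tau <- (css[kstar] - 1) / kstar
  pmax(z - tau, 0)
}

#' Sparsegen-lin: simplex projection with tunable sparsity
#'
#' Generalises [sparsemax()] with a sparsity coefficient \code{lam < 1}: the
#' scores are scaled by \eqn{1/(1-\lambda)} before projection, so larger
#' \code{lam} stretches the score gaps and shrinks the support.
#' \code{lam = 0} recovers sparsemax exactly; \code{lam} close to 1 approaches
#' a one-hot argmax.
#'
#' @param z Numeric vector of scores.
#' @param lam Sparsity coefficient, \code{lam < 1}. Negative values are
#'   allowed and produce denser outputs than sparsemax.
#' @return Probability vector of the same length as \code{z}.
#' @examples
#' sparsegen_lin(c(0.6, 0.4, 0), lam = 0.5)  # (0.7, 0.3, 0)
#' @export
sparsegen_lin <- function(z, lam = 0) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam >= 1)
    stop("sparsegen_lin: 'lam' must be a single finite value < 1")
  sparsemax(z / (1 - lam))
}
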