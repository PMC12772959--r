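# Independent oracles used across tests. Both are brute-force constructions
# that share no code with the implementations they check.

# Euclidean projection onto the probability simplex by exhaustive support
# enumeration: for every candidate support S, tau = (sum(z_S) - 1)/|S|; the
# KKT conditions require z_i > tau on S and z_i <= tau off S. Feasible
# candidates are compared by squared distance. Only usable for short vectors.
simplex_projection_oracle <- function(z) {
  n <- length(z)
  best <- NULL
  best_d <- Inf
  for (mask in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    tau <- (sum(z[S]) - 1) / length(S)
    p <- numeric(n)
    p[S] <- z[S] - tau
    if (any(p[S] <= -1e-12) || any(z[-S] - tau > 1e-12)) next
    d <- sum((p - z)^2)
    if (d < best_d) { best_d <- d; best <- p }
  }
  best
}

# Exact optimal transport cost between two uniform distributions of equal
# cardinality: an assignment problem solved by enumerating permutations
# (n <= 8). Cost entries are halved squared Euclidean distances, matching
# the package's transport cost.
exact_ot_uniform_oracle <- function(a_points, b_points) {
  n <- nrow(a_points)
  stopifnot(n == nrow(b_points), n <= 8L)
  C <- outer(rowSums(a_points^2), rowSums(b_points^2), "+") -
    2 * tcrossprod(a_points, b_points)
  C <- pmax(C, 0) / 2
  perms <- all_permutations(n)
  costs <- apply(perms, 1L, function(p) sum(C[cbind(seq_len(n), p)]))
  min(costs) / n  # uniform weights 1/n per atom
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Small deterministic tissue shared by several tests (kept light: a 32x32
# bin grid with 600 cells).
small_tissue <- function(seed = 5, ...) {
  simulate_tissue(tissue_spec(width_px = 512L, height_px = 512L,
                              n_cells = 600L, seed = seed, ...))
}

# A hand-built 2-cell / 4-bin mapping matrix on a 2x2-bin grid.
tiny_mapping <- function(P = rbind(c(1, 0, 0.5, 0),
                                   c(0, 1, 0.5, 1))) {
  g <- grid_spec(32L, 32L, 16L)
  structure(list(P = Matrix::Matrix(P, sparse = TRUE),
                 cell_ids = paste0("c", seq_len(nrow(P))),
                 grid = g, lam = 0.9),
            class = "mapping_matrix")
}
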