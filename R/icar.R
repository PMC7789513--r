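#' Graph Laplacian of an adjacency structure
#'
#' The ICAR precision is `Q / sigma2` with `Q = diag(m) - W`, where `m` is
#' the vector of neighbour counts.  Q is singular (the constant vector is in
#' its null space); on a connected graph its rank is N - 1 and the prior is
#' identified by the sum-to-zero constraint.
#'
#' @param adj an `adjacency` object.
#' @return N x N numeric matrix.
#' @export
icar_laplacian <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  diag(adj$neighbor_counts) - adj$W
}

#' ICAR full conditional for one area
#'
#' Given the values at all other areas, the conditional law of an
#' ICAR-distributed effect at area i is Gaussian with mean equal to the
#' average of its neighbours' values and variance `sigma2 / m_i`, `m_i` the
#' neighbour count.
#'
#' @param x length-N effect vector.
#' @param i area index (1-based).
#' @param adj an `adjacency` object.
#' @param sigma2 conditional variance scale (> 0).
#' @return list with `mean` and `variance`.
#' @export
icar_full_conditional <- function(x, i, adj, sigma2) {
  stopifnot(inherits(adj, "adjacency"), sigma2 > 0,
            length(x) == length(adj$area_ids))
  m <- adj$neighbor_counts[i]
  if (m == 0L) stop("area ", adj$area_ids[i], " is an island: ICAR full ",
                    "conditional undefined")
  nb <- adj$neighbors[[i]]
  list(mean = sum(x[nb]) / m, variance = sigma2 / m)
}

#' ICAR unnormalized log-density (pairwise-difference form)
#'
#' For a sum-to-zero vector x the intrinsic prior has log-density
#' `-((N-1)/2) log(sigma2) - x' Q x / (2 sigma2)` up to a constant, with
#' the quadratic form equal to `sum_ij w_ij (x_i - x_j)^2 / 2`.  The
#' `(N-1)` exponent reflects the rank of Q on a connected graph and is what
#' makes the variance updates correct.
#'
#' @param x length-N vector (should sum to zero).
#' @param adj an `adjacency` object.
#' @param sigma2 variance scale.
#' @param normalized include the `-((N-1)/2) log(2 pi sigma2)` rank-aware
#'   normalizing term (default TRUE).
#' @return scalar log-density (up to the sigma2-free constant involving the
#'   Laplacian's non-null eigenvalues).
#' @export
icar_log_density <- function(x, adj, sigma2, normalized = TRUE) {
  stopifnot(inherits(adj, "adjacency"), sigma2 > 0)
  Q <- icar_laplacian(adj)
  quad <- as.numeric(t(x) %*% Q %*% x)
  n <- length(x)
  out <- -quad / (2 * sigma2)
  if (normalized) out <- out - ((n - 1) / 2) * log(2 * pi * sigma2)
  out
}

#' Draw from the sum-to-zero ICAR distribution
#'
#' Samples the intrinsic prior restricted to the sum-to-zero subspace by
#' eigendecomposition of the Laplacian `Q = diag(m) - W`: independent
#' Gaussian mass `sigma2 / lambda_k` is placed on each eigenvector with
#' non-null eigenvalue `lambda_k`, and the null (constant) direction gets
#' none, so the output sums to zero by construction.
#'
#' @param adj an `adjacency` object; the graph must be connected.
#' @param sigma2 variance scale.
#' @param n_draws number of independent draws.
#' @return if `n_draws == 1` a length-N vector, else an `n_draws` x N
#'   matrix; each draw sums to zero to within 1e-10.
#' @export
sample_icar <- function(adj, sigma2, n_draws = 1L) {
  stopifnot(inherits(adj, "adjacency"), sigma2 > 0)
  if (max(adj$components) > 1L) {
    stop("graph is disconnected: sample the ICAR per connected component ",
         "with a sum-to-zero constraint in each")
  }
  Q <- icar_laplacian(adj)
  eig <- eigen(Q, symmetric = TRUE)
  n <- nrow(Q)
  lambda <- eig$values[seq_len(n - 1L)]   # non-null eigenvalues (descending)
  V <- eig$vectors[, seq_len(n - 1L), drop = FALSE]
  z <- matrix(stats::rnorm(n_draws * (n - 1L)), n_draws, n - 1L)
  z <- sweep(z, 2L, sqrt(sigma2 / lambda), "*")
  draws <- z %*% t(V)
  draws <- draws - rowMeans(draws)  # guard against fp drift off the subspace
  colnames(draws) <- adj$area_ids
  if (n_draws == 1L) drop(draws) else draws
}
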