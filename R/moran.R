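#' Global Moran's I
#'
#' `I = (N / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with `S0 = sum_ij w_ij`.  Under the null of no spatial
#' association the expectation is `-1/(N-1)`.
#'
#' @param values length-N numeric vector in adjacency area order.
#' @param adj an `adjacency` object.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, adj) {
  stopifnot(inherits(adj, "adjacency"))
  n <- length(adj$area_ids)
  if (length(values) != n) stop("values length must match adjacency")
  if (n < 2L) stop("need at least 2 areas")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("zero variance: values are constant")
  s0 <- sum(adj$W)
  (n / s0) * as.numeric(t(z) %*% adj$W %*% z) / denom
}

# Moran's I for many value vectors sharing one adjacency (columns of Z);
# used by the permutation test.  Edge-list form avoids N^2 work per column.
morans_i_many <- function(Z, adj) {
  n <- nrow(Z)
  idx <- which(adj$W == 1, arr.ind = TRUE)  # both directions present
  s0 <- nrow(idx)
  Zc <- sweep(Z, 2L, colMeans(Z))
  cross <- colSums(Zc[idx[, 1L], , drop = FALSE] *
                   Zc[idx[, 2L], , drop = FALSE])
  (n / s0) * cross / colSums(Zc^2)
}

#' Permutation test for positive spatial autocorrelation
#'
#' One-sided test of Moran's I against the exchangeable null: the observed
#' statistic is compared with `n_permutations` random relabelings of areas
#' and `p = (1 + #[I_perm >= I_obs]) / (n_permutations + 1)`.
#'
#' @inheritParams morans_i
#' @param n_permutations number of permutations (>= 99).
#' @param seed optional integer seed for the permutation generator.
#' @return an object of class `moran_test`: list with `statistic`,
#'   `expected_null` (`-1/(N-1)`), `p_value`, `n_permutations`, `seed`.
#' @export
morans_i_test <- function(values, adj, n_permutations = 999L, seed = NULL) {
  if (n_permutations < 99L) stop("need at least 99 permutations")
  obs <- morans_i(values, adj)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  perms <- replicate(n_permutations, values[sample.int(n)])
  stat_perm <- morans_i_many(perms, adj)
  p <- (1 + sum(stat_perm >= obs)) / (n_permutations + 1)
  structure(list(statistic = obs, expected_null = -1 / (n - 1),
                 p_value = p, n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (null expectation %.4f)\n",
              x$statistic, x$expected_null))
  cat(sprintf("  one-sided permutation p = %.4g (%d permutations)\n",
              x$p_value, x$n_permutations))
  invisible(x)
}

#' Per-year Moran's I table for a panel
#'
#' Runs the permutation test on the observed rates of each year.
#'
#' @param panel a [mortality_panel()].
#' @param adj an `adjacency` object whose ids match the panel's areas.
#' @param n_permutations,seed passed to [morans_i_test()]; per-year seeds
#'   are derived from `seed` so years are independent but reproducible.
#' @return data frame `year, I, expected, p_value`.
#' @export
moran_by_year <- function(panel, adj, n_permutations = 999L, seed = NULL) {
  stopifnot(inherits(panel, "mortality_panel"))
  if (!identical(panel$area_ids, adj$area_ids)) {
    stop("panel and adjacency area ids do not match")
  }
  r <- panel_rates(panel)
  out <- lapply(seq_along(panel$years), function(t) {
    st <- morans_i_test(r[, t], adj, n_permutations,
                        seed = if (is.null(seed)) NULL else seed + t)
    data.frame(year = panel$years[t], I = st$statistic,
               expected = st$expected_null, p_value = st$p_value)
  })
  do.call(rbind, out)
}

#' Mean lag-1 autocorrelation of area rate series
#'
#' For each area, the lag-1 sample autocorrelation of its T yearly rates
#' using the plug-in estimator `sum_{t<T}(x_t - xbar)(x_{t+1} - xbar) /
#' sum_t (x_t - xbar)^2`; areas with a constant series are skipped with a
#' warning, and the unweighted mean over the remaining areas is returned.
#'
#' @param panel a [mortality_panel()] with at least 3 years.
#' @return scalar mean lag-1 autocorrelation.
#' @export
mean_lag1_acf <- function(panel) {
  stopifnot(inherits(panel, "mortality_panel"))
  if (length(panel$years) < 3L) stop("need at least 3 years for lag-1 ACF")
  r <- panel_rates(panel)
  acf1 <- apply(r, 1L, lag1_acf)
  if (all(is.na(acf1))) stop("all area series are constant")
  if (anyNA(acf1)) {
    warning(sum(is.na(acf1)), " constant area series skipped in ACF mean")
  }
  mean(acf1, na.rm = TRUE)
}

lag1_acf <- function(x) {
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  sum(z[-length(z)] * z[-1L]) / denom
}
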