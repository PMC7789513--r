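#' Centered time index
#'
#' The linear-trend terms use a centered index `t* = t - midpoint` so the
#' overall slope is orthogonal to the intercept.  With an odd number of
#' consecutive years the midpoint is the median year and `sum(t*) = 0`
#' exactly; with an even T the mean year is used, which keeps the centering
#' property at half-integer values.
#'
#' @param years integer vector of consecutive calendar years.
#' @return an object of class `time_index`: list with `years` and `t_star`.
#' @export
time_index <- function(years) {
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("years must be consecutive")
  }
  structure(list(years = years, t_star = years - mean(years)),
            class = "time_index")
}

#' Model state for the spatio-temporal BYM model
#'
#' One full set of parameters for the model
#' `logit(mu_it) = alpha + (s_i + u_i) + d0 t* + v_t + d1_i t* + eps_it`:
#' overall level `alpha`, structured (`s`, ICAR) and unstructured (`u`,
#' Gaussian) spatial effects, overall linear slope `d0` and nonlinear trend
#' residual `v`, area-specific differential slopes `d1` (ICAR), a cell-level
#' Gaussian overdispersion term `eps`, and the five variance hyperparameters.
#' `s`, `d1` and `v` carry sum-to-zero identification constraints.
#'
#' @param alpha,d0 scalars.
#' @param s,u,d1 length-N vectors.
#' @param v length-T vector.
#' @param eps N x T matrix.
#' @param sigma2_s,sigma2_u,sigma2_v,sigma2_d,sigma2_eps positive variances.
#' @param check validate the sum-to-zero constraints (default TRUE).
#' @return an object of class `bym_state`.
#' @export
bym_state <- function(alpha, s, u, d0, v, d1, eps,
                      sigma2_s, sigma2_u, sigma2_v, sigma2_d, sigma2_eps,
                      check = TRUE) {
  n <- length(s); t_len <- length(v)
  stopifnot(length(u) == n, length(d1) == n,
            is.matrix(eps), nrow(eps) == n, ncol(eps) == t_len)
  sig <- c(sigma2_s, sigma2_u, sigma2_v, sigma2_d, sigma2_eps)
  if (any(sig <= 0)) stop("all variances must be > 0")
  if (check) {
    for (nm in c("s", "d1", "v")) {
      val <- get(nm)
      if (abs(sum(val)) > 1e-8 * max(1, length(val))) {
        stop(nm, " must sum to zero (got sum ", signif(sum(val), 3), ")")
      }
    }
  }
  structure(list(alpha = alpha, s = s, u = u, d0 = d0, v = v, d1 = d1,
                 eps = eps, sigma2_s = sigma2_s, sigma2_u = sigma2_u,
                 sigma2_v = sigma2_v, sigma2_d = sigma2_d,
                 sigma2_eps = sigma2_eps),
            class = "bym_state")
}

#' Linear predictor and fitted risk
#'
#' @param state a [bym_state()].
#' @param tindex a [time_index()].
#' @return `linear_predictor`: N x T matrix of logits; `logit_risk`: N x T
#'   matrix of probabilities `mu_it` in (0, 1).
#' @export
linear_predictor <- function(state, tindex) {
  stopifnot(inherits(state, "bym_state"), inherits(tindex, "time_index"))
  ts <- tindex$t_star
  n <- length(state$s)
  eta <- state$alpha + (state$s + state$u) +
    outer(rep(1, n), state$d0 * ts + state$v) +
    outer(state$d1, ts) + state$eps
  dimnames(eta) <- dimnames(state$eps)
  eta
}

#' @rdname linear_predictor
#' @export
logit_risk <- function(state, tindex) {
  stats::plogis(linear_predictor(state, tindex))
}

#' Binomial log-likelihood of a panel under a model state
#'
#' `sum_it log dbinom(y_it | n_it, mu_it)` including the binomial
#' coefficient, finite for all risks in (0, 1).
#'
#' @param panel a [mortality_panel()].
#' @param state a [bym_state()] with matching dimensions.
#' @param tindex a [time_index()] for the panel's years.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(panel, state, tindex) {
  stopifnot(inherits(panel, "mortality_panel"))
  if (nrow(panel$births) != length(state$s) ||
      ncol(panel$births) != length(state$v)) {
    stop("panel and state dimensions do not match")
  }
  eta <- linear_predictor(state, tindex)
  # dbinom on the logit scale avoids mu == 1 underflow for extreme eta
  sum(lchoose(panel$births, panel$deaths) +
        panel$deaths * eta -
        panel$births * log1p(exp(pmin(eta, 35))) -
        panel$births * pmax(eta - 35, 0))
}

#' Prior configuration for the variance hyperparameters
#'
#' Two families are supported.  The default places a positive half-Gaussian
#' prior on each random-effect standard deviation, `sigma ~ N+(0, scale2)`
#' with `scale2 = 10` — a weakly informative choice for logit-scale
#' effects.  Alternatively a Gamma prior on each precision
#' `1/sigma2 ~ Gamma(shape, rate)` reproduces the classic WinBUGS-style
#' setup and admits exact conjugate variance updates in the sampler.
#'
#' @param family `"half_gaussian"` (on SDs) or `"gamma"` (on precisions).
#' @param scale2 half-Gaussian variance parameter (on the SD scale).
#' @param shape,rate Gamma hyperparameters (used when `family = "gamma"`).
#' @return an object of class `bym_prior`.
#' @export
bym_prior <- function(family = c("half_gaussian", "gamma"), scale2 = 10,
                      shape = 0.001, rate = 0.001) {
  family <- match.arg(family)
  stopifnot(scale2 > 0, shape > 0, rate > 0)
  structure(list(family = family, scale2 = scale2,
                 shape = shape, rate = rate),
            class = "bym_prior")
}

# log hyperprior density of one variance component, given sigma2
log_sigma_prior <- function(sigma2, prior) {
  if (prior$family == "half_gaussian") {
    # density of sigma = sqrt(sigma2): half-Gaussian N+(0, scale2)
    sigma <- sqrt(sigma2)
    0.5 * log(2 / (pi * prior$scale2)) - sigma^2 / (2 * prior$scale2)
  } else {
    # density of tau = 1/sigma2 ~ Gamma(shape, rate)
    tau <- 1 / sigma2
    stats::dgamma(tau, shape = prior$shape, rate = prior$rate, log = TRUE)
  }
}

#' Joint log-prior of a model state
#'
#' Sum of the ICAR log-densities of `s` and `d1` (pairwise-difference
#' quadratic form with rank-(N-1) normalization), independent Gaussian
#' log-densities of `u`, `v` and `eps`, flat priors on `alpha` and `d0`,
#' and the hyperprior densities of the five variance components.
#'
#' @param state a [bym_state()].
#' @param adj an `adjacency` object.
#' @param prior a [bym_prior()].
#' @return scalar log-prior.
#' @export
log_prior <- function(state, adj, prior = bym_prior()) {
  stopifnot(inherits(state, "bym_state"), inherits(adj, "adjacency"),
            inherits(prior, "bym_prior"))
  n <- length(state$s); t_len <- length(state$v)
  lp <- icar_log_density(state$s, adj, state$sigma2_s) +
    icar_log_density(state$d1, adj, state$sigma2_d) +
    sum(stats::dnorm(state$u, 0, sqrt(state$sigma2_u), log = TRUE)) +
    sum(stats::dnorm(state$v, 0, sqrt(state$sigma2_v), log = TRUE)) +
    sum(stats::dnorm(state$eps, 0, sqrt(state$sigma2_eps), log = TRUE))
  lp + log_sigma_prior(state$sigma2_s, prior) +
    log_sigma_prior(state$sigma2_u, prior) +
    log_sigma_prior(state$sigma2_v, prior) +
    log_sigma_prior(state$sigma2_d, prior) +
    log_sigma_prior(state$sigma2_eps, prior)
}

#' Joint log-posterior (up to the evidence constant)
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return scalar `log_likelihood + log_prior`.
#' @export
log_posterior <- function(panel, state, adj, tindex, prior = bym_prior()) {
  log_likelihood(panel, state, tindex) + log_prior(state, adj, prior)
}
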