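#' Sampler control settings
#'
#' Defaults mirror common practice for this model class: long chains with a
#' substantial burn-in, proposal adaptation restricted to the burn-in so
#' retained draws come from a fixed kernel, and a Gelman-Rubin convergence
#' threshold of 1.04.
#'
#' @param n_iterations total iterations per chain.
#' @param n_burnin iterations discarded (must be `< n_iterations`).
#' @param n_chains number of chains with overdispersed starts.
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param adapt_until proposal scales adapt during iterations
#'   `1..adapt_until` only; must be `<= n_burnin`.  Default: the burn-in.
#' @param rhat_threshold convergence warning threshold on R-hat.
#' @param progress_every print a progress line every so many iterations
#'   (0 = silent).
#' @return an object of class `bym_control`.
#' @export
bym_control <- function(n_iterations = 100000L, n_burnin = 30000L,
                        n_chains = 2L, thin = 1L, adapt_until = NULL,
                        rhat_threshold = 1.04, progress_every = 0L) {
  if (is.null(adapt_until)) adapt_until <- n_burnin
  stopifnot(n_burnin < n_iterations, n_chains >= 1L, thin >= 1L,
            adapt_until <= n_burnin, rhat_threshold > 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 thin = as.integer(thin),
                 adapt_until = as.integer(adapt_until),
                 rhat_threshold = rhat_threshold,
                 progress_every = as.integer(progress_every)),
            class = "bym_control")
}

block_names <- c("alpha", "d0", "s", "u", "d1", "v", "eps",
                 "sigma_s", "sigma_u", "sigma_v", "sigma_d", "sigma_eps",
                 "su_swap")

default_init <- function(panel, chain) {
  n <- length(panel$area_ids); t_len <- length(panel$years)
  p_hat <- sum(panel$deaths) / sum(panel$births)
  # overdispersed starts: chain-indexed offsets on alpha, alternating sigma
  offset <- c(0, -0.5, 0.5, -1, 1)[(chain - 1L) %% 5L + 1L]
  sig <- if (chain %% 2L == 1L) 0.1 else 1
  list(alpha = stats::qlogis(p_hat) + offset,
       d0 = 0,
       s = rep(0, n), u = rep(0, n), d1 = rep(0, n),
       v = rep(0, t_len), eps = matrix(0, n, t_len),
       sigma2 = rep(sig^2, 5),
       prop = c(0.05, 0.02, rep(0.1, 5), rep(0.3, 5), 0.3))
}

#' Fit the Bayesian spatio-temporal BYM model
#'
#' Fits `deaths[i,t] ~ Binomial(births[i,t], mu[i,t])` with
#' `logit(mu_it) = alpha + s_i + u_i + d0 t* + v_t + d1_i t* + eps_it` by
#' Metropolis-within-Gibbs MCMC.  `s` (structured spatial) and `d1`
#' (differential local slopes) carry ICAR priors on the contiguity graph;
#' `u`, `v` and `eps` are independent Gaussians; `alpha` and `d0` get flat
#' priors; variance hyperparameters follow [bym_prior()].  `s` and `d1`
#' are re-centered to sum to zero after every sweep (the mean is
#' transferred into `alpha` / `d0`, leaving the likelihood untouched);
#' `v` is sampled with in-subspace proposals so its sum-to-zero constraint
#' holds exactly throughout.  A likelihood-free balancing move
#' `(s_i, u_i) -> (s_i + c, u_i - c)` keeps the structured/unstructured
#' split well mixed.
#'
#' @param panel a [mortality_panel()].
#' @param adj an `adjacency` object with the panel's areas (same id order).
#' @param prior a [bym_prior()].
#' @param control a [bym_control()].
#' @param seed integer seed; chain c runs under `seed + c - 1`.
#' @param init optional list of per-chain initial states (as produced by
#'   the internal default); mainly for tests.
#' @param update named logical vector switching parameter blocks on/off
#'   (names among alpha, d0, s, u, d1, v, eps, sigma); blocks switched off
#'   stay at their initial values.  Intended for validation studies.
#' @param use_likelihood set `FALSE` to sample from the prior only
#'   (flat-likelihood validation mode).
#' @return an object of class `bym_st`: list with `draws` (list of
#'   chain matrices, retained iterations x parameters), `parameters`
#'   (column names), `rhat` (per-parameter), `acceptance` (per chain x
#'   block), `panel`, `adj`, `tindex`, `prior`, `control`, `seed`.
#' @export
bym_st <- function(panel, adj, prior = bym_prior(), control = bym_control(),
                   seed = 1L, init = NULL, update = NULL,
                   use_likelihood = TRUE) {
  stopifnot(inherits(panel, "mortality_panel"), inherits(adj, "adjacency"),
            inherits(prior, "bym_prior"), inherits(control, "bym_control"))
  if (!identical(panel$area_ids, adj$area_ids)) {
    stop("panel and adjacency area ids do not match")
  }
  n <- length(panel$area_ids); t_len <- length(panel$years)
  if (t_len >= 64L) stop("panels with 64+ periods are not supported")
  tindex <- time_index(panel$years)

  upd <- rep(TRUE, 8L)
  names(upd) <- c("alpha", "d0", "s", "u", "d1", "v", "eps", "sigma")
  if (!is.null(update)) {
    bad <- setdiff(names(update), names(upd))
    if (length(bad) > 0L) stop("unknown update block(s): ",
                               paste(bad, collapse = ", "))
    upd[names(update)] <- update
  }

  nb_num <- adj$neighbor_counts
  nb_adj <- as.integer(unlist(adj$neighbors) - 1L)
  fam <- if (prior$family == "half_gaussian") 0L else 1L
  prior_cpp <- list(family = fam, scale2 = prior$scale2,
                    shape = prior$shape, rate = prior$rate)

  par_names <- c("alpha", "d0",
                 paste0("s[", panel$area_ids, "]"),
                 paste0("u[", panel$area_ids, "]"),
                 paste0("d1[", panel$area_ids, "]"),
                 paste0("v[", panel$years, "]"),
                 "sigma2_s", "sigma2_u", "sigma2_v", "sigma2_d", "sigma2_eps",
                 paste0("eps[", rep(panel$area_ids, t_len), ",",
                        rep(panel$years, each = n), "]"))

  draws <- vector("list", control$n_chains)
  acceptance <- matrix(NA_real_, control$n_chains, length(block_names),
                       dimnames = list(NULL, block_names))
  for (chain in seq_len(control$n_chains)) {
    ini <- if (is.null(init)) default_init(panel, chain) else init[[chain]]
    set.seed(seed + chain - 1L)
    res <- bym_mcmc_cpp(
      y = matrix(as.double(panel$deaths), n, t_len),
      nn = matrix(as.double(panel$births), n, t_len),
      tstar = tindex$t_star,
      nb_num = as.integer(nb_num), nb_adj = nb_adj,
      init = ini, prior = prior_cpp,
      control = list(n_iter = control$n_iterations,
                     burnin = control$n_burnin,
                     thin = control$thin,
                     adapt_until = control$adapt_until,
                     use_likelihood = use_likelihood,
                     update = unname(upd),
                     progress_every = control$progress_every))
    colnames(res$draws) <- par_names
    draws[[chain]] <- res$draws
    acceptance[chain, ] <- res$acceptance
  }

  rhat <- if (control$n_chains >= 2L) {
    vapply(seq_along(par_names), function(j) {
      mat <- vapply(draws, function(d) d[, j], numeric(nrow(draws[[1L]])))
      tryCatch(gelman_rubin(t(mat)), error = function(e) NA_real_)
    }, numeric(1))
  } else rep(NA_real_, length(par_names))
  names(rhat) <- par_names

  fit <- structure(list(draws = draws, parameters = par_names,
                        rhat = rhat, acceptance = acceptance,
                        panel = panel, adj = adj, tindex = tindex,
                        prior = prior, control = control, seed = seed,
                        n_areas = n, n_years = t_len,
                        use_likelihood = use_likelihood),
                   class = "bym_st")
  bad <- which(!is.na(rhat) & rhat > control$rhat_threshold)
  if (length(bad) > 0L) {
    warning(length(bad), " parameter(s) with R-hat above ",
            control$rhat_threshold, "; worst: ",
            paste(utils::head(names(sort(rhat[bad], decreasing = TRUE)), 5L),
                  collapse = ", "))
  }
  fit
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Plain (non-split) R-hat for one scalar parameter:
#' `sqrt(((n-1)/n * W + B/n) / W)` with between-chain variance `B` and
#' mean within-chain variance `W`.  The split-chain variant (each chain
#' halved before the comparison, more sensitive to trends) is available
#' via `split = TRUE`.
#'
#' @param chains matrix with one row per chain, one column per retained
#'   iteration (>= 2 chains, >= 10 iterations).
#' @param split use split chains.
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  chains <- as.matrix(chains)
  if (nrow(chains) < 2L) stop("need at least 2 chains")
  if (ncol(chains) < 10L) stop("need at least 10 iterations per chain")
  if (split) {
    half <- ncol(chains) %/% 2L
    chains <- rbind(chains[, seq_len(half), drop = FALSE],
                    chains[, ncol(chains) - half + seq_len(half),
                           drop = FALSE])
  }
  n <- ncol(chains)
  means <- rowMeans(chains)
  W <- mean(apply(chains, 1L, stats::var))
  if (W == 0) stop("degenerate chains: zero within-chain variance")
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# pooled draws across chains for a subset of parameters
pooled_draws <- function(fit, pattern = NULL) {
  stopifnot(inherits(fit, "bym_st"))
  mat <- do.call(rbind, fit$draws)
  if (!is.null(pattern)) mat <- mat[, grep(pattern, colnames(mat),
                                           fixed = FALSE), drop = FALSE]
  mat
}

#' Posterior summary table
#'
#' Pooled-chain posterior mean, standard deviation and equal-tailed
#' quantiles for every scalar parameter, plus R-hat when available.
#'
#' @param object a [bym_st()] fit.
#' @param probs quantile levels (default 2.5/50/97.5%).
#' @param pars optional regular expression selecting parameters (default:
#'   all non-`eps` parameters).
#' @param ... unused.
#' @return a data frame, one row per parameter.
#' @export
summary.bym_st <- function(object, probs = c(0.025, 0.5, 0.975),
                           pars = "^(?!eps)", ...) {
  keep <- grepl(pars, object$parameters, perl = TRUE)
  mat <- pooled_draws(object)[, keep, drop = FALSE]
  qs <- t(apply(mat, 2L, stats::quantile, probs = probs))
  out <- data.frame(parameter = colnames(mat),
                    mean = colMeans(mat),
                    sd = apply(mat, 2L, stats::sd),
                    qs,
                    rhat = object$rhat[keep],
                    check.names = FALSE, row.names = NULL)
  names(out)[3L + seq_along(probs)] <- paste0("q", probs * 100)
  out
}

#' @export
print.bym_st <- function(x, ...) {
  kept <- nrow(x$draws[[1L]])
  cat(sprintf("Spatio-temporal BYM fit: %d areas x %d years\n",
              x$n_areas, x$n_years))
  cat(sprintf("  %d chain(s), %d retained draws each (of %d iterations, burn-in %d, thin %d)\n",
              x$control$n_chains, kept, x$control$n_iterations,
              x$control$n_burnin, x$control$thin))
  if (!all(is.na(x$rhat))) {
    cat(sprintf("  max R-hat %.3f (threshold %.2f)\n",
                max(x$rhat, na.rm = TRUE), x$control$rhat_threshold))
  }
  core <- summary(x, pars = "^(alpha|d0|sigma2)")
  print(cbind(core[1L], round(core[-1L], 4)))
  invisible(x)
}

#' @export
coef.bym_st <- function(object, ...) {
  mat <- pooled_draws(object)
  colMeans(mat)
}

#' @export
fitted.bym_st <- function(object, ...) {
  rs <- risk_surface(object)
  matrix(rs$cells$risk_mean_per1000, object$n_areas, object$n_years,
         dimnames = dimnames(object$panel$births))
}

#' Pearson residuals at the posterior mean risk
#' @param object a [bym_st()] fit.
#' @param ... unused.
#' @return N x T matrix of `(y - n p) / sqrt(n p (1 - p))`.
#' @export
residuals.bym_st <- function(object, ...) {
  p <- fitted(object) / 1000
  n <- object$panel$births; y <- object$panel$deaths
  (y - n * p) / sqrt(n * p * (1 - p))
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws replicate death-count panels: for each replicate a retained
#' posterior draw is selected at random and deaths are simulated as
#' `Binomial(births, mu_it)` under that draw's risk surface.
#'
#' @param object a [bym_st()] fit.
#' @param nsim number of replicate panels.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` N x T death-count matrices.
#' @export
simulate.bym_st <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mat <- pooled_draws(object)
  n <- object$panel$births
  idx <- sample.int(nrow(mat), nsim, replace = TRUE)
  lapply(idx, function(r) {
    mu <- mu_surface_one(mat[r, ], object)
    out <- matrix(stats::rbinom(length(n), as.vector(n), as.vector(mu)),
                  nrow(n), ncol(n), dimnames = dimnames(n))
    out
  })
}

# N x T risk matrix from one draw (named parameter vector)
mu_surface_one <- function(draw, fit) {
  n <- fit$n_areas; t_len <- fit$n_years
  s <- draw[grep("^s\\[", names(draw))]
  u <- draw[grep("^u\\[", names(draw))]
  d1 <- draw[grep("^d1\\[", names(draw))]
  v <- draw[grep("^v\\[", names(draw))]
  eps <- matrix(draw[grep("^eps\\[", names(draw))], n, t_len)
  ts <- fit$tindex$t_star
  eta <- draw[["alpha"]] + (s + u) +
    outer(rep(1, n), draw[["d0"]] * ts + v) + outer(d1, ts) + eps
  stats::plogis(eta)
}

#' Trace / trend plot for a fitted model
#'
#' `which = "trend"` draws the posterior overall relative-trend curve
#' `exp(d0 t* + v_t)` with its 95% band; `which = "trace"` draws trace
#' plots of alpha, d0 and the variance components.
#'
#' @param x a [bym_st()] fit.
#' @param which `"trend"` or `"trace"`.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.bym_st <- function(x, which = c("trend", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trend") {
    tr <- overall_trend(x)
    ylim <- range(tr$lo, tr$hi)
    plot(tr$year, tr$rel_trend, type = "b", pch = 19, ylim = ylim,
         xlab = "year", ylab = "relative trend", ...)
    graphics::lines(tr$year, tr$lo, lty = 2)
    graphics::lines(tr$year, tr$hi, lty = 2)
    graphics::abline(h = 1, col = "grey60")
  } else {
    pars <- c("alpha", "d0", "sigma2_s", "sigma2_u", "sigma2_v",
              "sigma2_d", "sigma2_eps")
    old <- graphics::par(mfrow = c(4, 2), mar = c(3, 4, 2, 1))
    on.exit(graphics::par(old))
    for (p in pars) {
      j <- match(p, x$parameters)
      graphics::matplot(vapply(x$draws, function(d) d[, j],
                               numeric(nrow(x$draws[[1L]]))),
                        type = "l", lty = 1, ylab = p, xlab = "")
    }
  }
  invisible(x)
}
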