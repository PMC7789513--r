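smoke_fit <- function(seed = 1L, n_chains = 1L, iters = 600L, burn = 200L,
                      ...) {
  sim <- simulate_panel(scenario_config(n_rows = 3L, n_cols = 3L,
                                        n_years = 3L), seed = 2)
  bym_st(sim$panel, sim$adj,
         control = bym_control(n_iterations = iters, n_burnin = burn,
                               n_chains = n_chains, adapt_until = burn),
         seed = seed, ...)
}

test_that("the sampler is deterministic under a fixed seed", {
  f1 <- suppressWarnings(smoke_fit(seed = 5L))
  f2 <- suppressWarnings(smoke_fit(seed = 5L))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(smoke_fit(seed = 6L))
  expect_false(identical(f1$draws[[1L]], f3$draws[[1L]]))
})

test_that("chains differ, bookkeeping holds, and constraints survive", {
  fit <- suppressWarnings(smoke_fit(n_chains = 2L, iters = 800L,
                                    burn = 300L))
  expect_length(fit$draws, 2L)
  expect_false(identical(fit$draws[[1L]], fit$draws[[2L]]))
  expect_equal(nrow(fit$draws[[1L]]), 500L)
  # retained draws satisfy the sum-to-zero constraints
  for (ch in 1:2) {
    d <- fit$draws[[ch]]
    s_cols <- grep("^s\\[", colnames(d))
    d1_cols <- grep("^d1\\[", colnames(d))
    v_cols <- grep("^v\\[", colnames(d))
    expect_lt(max(abs(rowSums(d[, s_cols]))), 1e-8)
    expect_lt(max(abs(rowSums(d[, d1_cols]))), 1e-8)
    expect_lt(max(abs(rowSums(d[, v_cols]))), 1e-8)
  }
  # R-hat reported for every scalar parameter including the variances
  expect_equal(length(fit$rhat), length(fit$parameters))
  expect_true(all(c("sigma2_s", "sigma2_u", "sigma2_v", "sigma2_d",
                    "sigma2_eps") %in% names(fit$rhat)))
})

test_that("thinning keeps the advertised number of draws", {
  fit <- suppressWarnings(smoke_fit(iters = 1000L, burn = 400L))
  expect_equal(nrow(fit$draws[[1L]]), 600L)
  sim <- simulate_panel(scenario_config(n_rows = 3L, n_cols = 3L,
                                        n_years = 3L), seed = 2)
  fit2 <- suppressWarnings(
    bym_st(sim$panel, sim$adj,
           control = bym_control(n_iterations = 1000L, n_burnin = 400L,
                                 n_chains = 1L, thin = 3L,
                                 adapt_until = 400L), seed = 1))
  expect_equal(nrow(fit2$draws[[1L]]), 200L)
})

test_that("acceptance rates land in a healthy band after adaptation", {
  sim <- simulate_panel(study_scenario(), seed = 8)
  fit <- suppressWarnings(
    bym_st(sim$panel, sim$adj,
           control = bym_control(n_iterations = 3000L, n_burnin = 1000L,
                                 n_chains = 1L, adapt_until = 1000L),
           seed = 3))
  acc <- fit$acceptance[1L, ]
  expect_true(all(acc > 0.1 & acc < 0.7),
              info = paste(names(acc), round(acc, 2), collapse = " "))
})

test_that("flat-likelihood mode recovers the prior law of u and v", {
  sim <- simulate_panel(scenario_config(n_rows = 3L, n_cols = 3L,
                                        n_years = 5L), seed = 4)
  s2u <- 0.25; s2v <- 0.49
  init <- list(list(alpha = 0, d0 = 0, s = rep(0, 9L), u = rep(0, 9L),
                    d1 = rep(0, 9L), v = rep(0, 5L),
                    eps = matrix(0, 9L, 5L),
                    sigma2 = c(1, s2u, s2v, 1, 1),
                    prop = c(0.05, 0.02, rep(0.3, 5L), rep(0.3, 5L))))
  fit <- bym_st(sim$panel, sim$adj, seed = 10, init = init,
                use_likelihood = FALSE,
                update = c(alpha = FALSE, d0 = FALSE, s = FALSE, u = TRUE,
                           d1 = FALSE, v = TRUE, eps = FALSE,
                           sigma = FALSE),
                control = bym_control(n_iterations = 30000L,
                                      n_burnin = 5000L, n_chains = 1L,
                                      adapt_until = 5000L))
  d <- fit$draws[[1L]]
  u <- d[, grep("^u\\[", colnames(d))]
  v <- d[, grep("^v\\[", colnames(d))]
  # u sites are iid N(0, s2u)
  expect_lt(abs(mean(u)), 0.05)
  expect_equal(mean(apply(u, 2L, var)), s2u, tolerance = 0.1)
  # v is recentered each sweep: projected Gaussian with per-coordinate
  # variance s2v * (1 - 1/T)
  expect_lt(max(abs(rowSums(v))), 1e-8)
  expect_equal(mean(apply(v, 2L, var)), s2v * (1 - 1 / 5), tolerance = 0.15)
})

test_that("gelman_rubin behaves on iid, shifted, and degenerate chains", {
  set.seed(1)
  iid <- matrix(rnorm(2 * 10000L), 2L, 10000L)
  r <- gelman_rubin(iid)
  expect_gte(r, 0.99)
  expect_lte(r, 1.02)
  shifted <- rbind(rnorm(500L, 0), rnorm(500L, 10))
  expect_gt(gelman_rubin(shifted), 1.04)
  expect_error(gelman_rubin(matrix(1, 2L, 100L)), "degenerate")
  expect_error(gelman_rubin(matrix(rnorm(10), 1L, 10L)), "2 chains")
})

test_that("posterior summaries report pooled means and quantiles", {
  fit <- suppressWarnings(smoke_fit(n_chains = 2L))
  s <- summary(fit)
  expect_true(all(c("alpha", "d0", "sigma2_eps") %in% s$parameter))
  expect_false(any(grepl("^eps", s$parameter)))
  expect_true(all(s$q2.5 <= s$q50 & s$q50 <= s$q97.5))
  # quantile sanity on a known sample
  set.seed(2)
  x <- rnorm(1e5)
  expect_equal(unname(quantile(x, 0.975)), qnorm(0.975), tolerance = 0.03)
})

test_that("a convergence warning lists offending parameters", {
  # two very short chains on a hard posterior: R-hat should trip for some
  # parameter and bym_st should warn rather than fail
  expect_warning(smoke_fit(n_chains = 2L, iters = 300L, burn = 100L),
                 "R-hat")
})

test_that("doubling thin with doubled iterations leaves means stable", {
  sim <- simulate_panel(scenario_config(n_rows = 3L, n_cols = 3L,
                                        n_years = 3L), seed = 2)
  base <- suppressWarnings(
    bym_st(sim$panel, sim$adj, seed = 9,
           control = bym_control(n_iterations = 4000L, n_burnin = 1000L,
                                 n_chains = 1L, adapt_until = 1000L)))
  thinned <- suppressWarnings(
    bym_st(sim$panel, sim$adj, seed = 9,
           control = bym_control(n_iterations = 7000L, n_burnin = 1000L,
                                 n_chains = 1L, thin = 2L,
                                 adapt_until = 1000L)))
  a1 <- mean(base$draws[[1L]][, "alpha"])
  a2 <- mean(thinned$draws[[1L]][, "alpha"])
  mc_se <- sd(base$draws[[1L]][, "alpha"]) / sqrt(200)  # generous ESS guess
  expect_lt(abs(a1 - a2), 5 * mc_se)
})
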