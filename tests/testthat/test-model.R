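# random valid state on a given panel/adjacency
random_state <- function(panel, adj, seed = 1) {
  set.seed(seed)
  n <- length(panel$area_ids); t_len <- length(panel$years)
  zsum <- function(x) x - mean(x)
  bym_state(alpha = rnorm(1, -4, 0.5),
            s = zsum(rnorm(n)), u = rnorm(n, 0, 0.3),
            d0 = rnorm(1, 0, 0.05), v = zsum(rnorm(t_len, 0, 0.1)),
            d1 = zsum(rnorm(n, 0, 0.1)),
            eps = matrix(rnorm(n * t_len, 0, 0.1), n, t_len),
            sigma2_s = runif(1, 0.2, 2), sigma2_u = runif(1, 0.2, 2),
            sigma2_v = runif(1, 0.2, 2), sigma2_d = runif(1, 0.2, 2),
            sigma2_eps = runif(1, 0.2, 2))
}

zero_state <- function(n, t_len, alpha = 0, d0 = 0, ...) {
  args <- list(alpha = alpha, s = rep(0, n), u = rep(0, n), d0 = d0,
               v = rep(0, t_len), d1 = rep(0, n),
               eps = matrix(0, n, t_len),
               sigma2_s = 1, sigma2_u = 1, sigma2_v = 1, sigma2_d = 1,
               sigma2_eps = 1)
  do.call(bym_state, modifyList(args, list(...)))
}

test_that("centered time index sums to zero and centers at the median year", {
  ti <- time_index(2011:2017)
  expect_equal(sum(ti$t_star), 0)
  expect_equal(ti$t_star, -3:3)
  ti2 <- time_index(2011:2014)
  expect_equal(sum(ti2$t_star), 0)
  expect_equal(ti2$t_star, c(-1.5, -0.5, 0.5, 1.5))
  expect_error(time_index(c(2011L, 2013L)), "consecutive")
})

test_that("fitted risk inverts the linear predictor", {
  ti <- time_index(2011:2013)
  st <- zero_state(2L, 3L)
  expect_true(all(logit_risk(st, ti) == 0.5))
  st2 <- zero_state(2L, 3L, alpha = qlogis(0.02))
  expect_equal(unique(as.vector(logit_risk(st2, ti))), 0.02)
  st3 <- zero_state(2L, 3L, d0 = 0.1)
  expect_equal(logit_risk(st3, ti)[1L, 1L], plogis(-0.1))
})

test_that("state constraints are enforced at construction", {
  expect_error(zero_state(3L, 3L, s = c(1, 1, 1)), "sum to zero")
  expect_error(zero_state(3L, 3L, sigma2_u = 0), "variances")
})

test_that("log-likelihood matches closed forms and the brute-force oracle", {
  ti <- time_index(2011L)
  one <- mortality_panel(data.frame(area_id = "a", year = 2011L,
                                    births = 1L, deaths = 1L))
  st <- zero_state(1L, 1L)  # mu = 0.5
  expect_equal(log_likelihood(one, st, ti), log(0.5), tolerance = 1e-12)
  ten <- mortality_panel(data.frame(area_id = "a", year = 2011L,
                                    births = 10L, deaths = 0L))
  st2 <- zero_state(1L, 1L, alpha = qlogis(0.1))
  expect_equal(log_likelihood(ten, st2, ti), 10 * log(0.9),
               tolerance = 1e-12)

  sim <- simulate_panel(scenario_config(n_rows = 2L, n_cols = 2L,
                                        n_years = 3L), seed = 3)
  st3 <- random_state(sim$panel, sim$adj, seed = 4)
  ti3 <- time_index(sim$panel$years)
  eta <- linear_predictor(st3, ti3)
  expect_equal(log_likelihood(sim$panel, st3, ti3),
               loglik_oracle(sim$panel, eta), tolerance = 1e-10)
})

test_that("log-prior matches a dense-matrix oracle on small graphs", {
  for (seed in 1:3) {
    sim <- simulate_panel(scenario_config(n_rows = 2L, n_cols = 2L,
                                          n_years = 3L), seed = seed)
    st <- random_state(sim$panel, sim$adj, seed = seed + 10)
    # oracle: every term written out densely and independently
    Q <- diag(sim$adj$neighbor_counts) - sim$adj$W
    n <- 4L; t_len <- 3L
    icar_term <- function(x, s2) {
      -((n - 1) / 2) * log(2 * pi * s2) -
        as.numeric(t(x) %*% Q %*% x) / (2 * s2)
    }
    gauss <- function(x, s2) sum(-0.5 * log(2 * pi * s2) - x^2 / (2 * s2))
    half_gauss <- function(s2, scale2 = 10) {
      0.5 * log(2 / (pi * scale2)) - s2 / (2 * scale2)
    }
    oracle <- icar_term(st$s, st$sigma2_s) + icar_term(st$d1, st$sigma2_d) +
      gauss(st$u, st$sigma2_u) + gauss(st$v, st$sigma2_v) +
      gauss(st$eps, st$sigma2_eps) +
      half_gauss(st$sigma2_s) + half_gauss(st$sigma2_u) +
      half_gauss(st$sigma2_v) + half_gauss(st$sigma2_d) +
      half_gauss(st$sigma2_eps)
    expect_equal(log_prior(st, sim$adj), oracle, tolerance = 1e-10)
  }
})

test_that("zero spatial vectors contribute only the normalizing term", {
  adj <- path_adj(4L)
  sim_panel <- panel_with_rates(matrix(20, 4L, 3L))
  st <- zero_state(4L, 3L)
  # with all effects zero the quadratic forms vanish: only normalizers and
  # hyperpriors remain
  expected_u <- -(4 / 2) * log(2 * pi)  # sigma2_u = 1
  gauss_terms <- sum(dnorm(st$u, 0, 1, log = TRUE))
  expect_equal(gauss_terms, expected_u)
  expect_true(is.finite(log_prior(st, adj)))
})

test_that("log-posterior is the sum of likelihood and prior, and finite", {
  sim <- simulate_panel(scenario_config(n_rows = 2L, n_cols = 3L,
                                        n_years = 3L), seed = 6)
  ti <- time_index(sim$panel$years)
  st <- random_state(sim$panel, sim$adj, seed = 7)
  expect_equal(log_posterior(sim$panel, st, sim$adj, ti),
               log_likelihood(sim$panel, st, ti) + log_prior(st, sim$adj),
               tolerance = 1e-12)
  for (s2 in c(1e-6, 1, 1e6)) {
    st2 <- zero_state(6L, 3L, sigma2_eps = s2)
    expect_true(is.finite(log_posterior(sim$panel, st2, sim$adj, ti)))
  }
})

test_that("likelihood increases as one cell's risk moves toward y/n", {
  ti <- time_index(2011L)
  p <- mortality_panel(data.frame(area_id = "a", year = 2011L,
                                  births = 100L, deaths = 20L))
  alphas <- qlogis(c(0.01, 0.05, 0.1, 0.15, 0.2))
  lls <- vapply(alphas, function(a) {
    log_likelihood(p, zero_state(1L, 1L, alpha = a), ti)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))  # rising toward the MLE at 0.2
})

test_that("gamma precision prior option changes only the hyperprior term", {
  sim <- simulate_panel(scenario_config(n_rows = 2L, n_cols = 2L,
                                        n_years = 3L), seed = 8)
  st <- random_state(sim$panel, sim$adj, seed = 9)
  hg <- log_prior(st, sim$adj, bym_prior("half_gaussian"))
  gm <- log_prior(st, sim$adj, bym_prior("gamma", shape = 0.5, rate = 0.01))
  s2 <- c(st$sigma2_s, st$sigma2_u, st$sigma2_v, st$sigma2_d, st$sigma2_eps)
  diff_oracle <- sum(dgamma(1 / s2, 0.5, rate = 0.01, log = TRUE)) -
    sum(0.5 * log(2 / (pi * 10)) - s2 / 20)
  expect_equal(gm - hg, diff_oracle, tolerance = 1e-10)
})
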