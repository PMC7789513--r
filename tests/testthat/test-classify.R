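test_that("exceedance probabilities equal brute-force indicator counts", {
  p <- panel_with_rates(matrix(20, 2L, 3L))
  adj <- path_adj(2L)
  m <- zero_draw_matrix(p, 4L)
  m[, "s[m01]"] <- c(-2, 0.5, 0.5, 0.5)
  m[, "u[m01]"] <- c(1, 0.5, 0.5, 0.5)   # u+s = -1, 1, 1, 1
  m[, "d1[m01]"] <- c(-0.1, -0.2, 0.3, -0.4)
  m[, "d1[m02]"] <- -m[, "d1[m01]"]      # keep sum-to-zero
  m[, "s[m02]"] <- -m[, "s[m01]"]
  m[, "u[m02]"] <- 0
  fit <- fake_fit(list(m), p, adj)
  expect_equal(excess_risk_probability(fit, 1L), 0.75)
  expect_equal(trend_probability(fit, 1L), 0.25)
  # brute-force oracle on arbitrary draws
  set.seed(3)
  m2 <- zero_draw_matrix(p, 200L)
  m2[, "s[m01]"] <- rnorm(200L)
  m2[, "u[m01]"] <- rnorm(200L)
  fit2 <- fake_fit(list(m2), p, adj)
  oracle <- sum(m2[, "s[m01]"] + m2[, "u[m01]"] > 0) / 200
  expect_equal(excess_risk_probability(fit2, 1L), oracle)
  # all-negative draws give probability zero
  m3 <- zero_draw_matrix(p, 10L)
  m3[, "s[m01]"] <- -abs(rnorm(10L)) - 0.1
  fit3 <- fake_fit(list(m3), p, adj)
  expect_equal(excess_risk_probability(fit3, 1L), 0)
})

test_that("threshold rules follow the strict 0.8/0.2 mapping", {
  expect_equal(as.character(classify_risk(c(0.9, 0.5, 0.1))),
               c("high", "medium", "low"))
  # boundaries are NOT extreme classes: strict inequalities
  expect_equal(as.character(classify_risk(c(0.8, 0.2))),
               c("medium", "medium"))
  expect_equal(as.character(classify_trend(c(0.85, 0.1, 0.5))),
               c("increasing", "decreasing", "stable"))
  expect_equal(as.character(classify_trend(c(0.8, 0.2))),
               c("stable", "stable"))
  # numeric risk codes: high=1, low=2, medium=3
  cls <- classify_risk(c(0.95, 0.05, 0.5))
  codes <- c(high = 1L, low = 2L, medium = 3L)[as.character(cls)]
  expect_equal(unname(codes), c(1L, 2L, 3L))
})

test_that("classification partitions areas and counts add up", {
  sim <- simulate_panel(scenario_config(n_rows = 3L, n_cols = 3L,
                                        n_years = 3L), seed = 5)
  fit <- suppressWarnings(
    bym_st(sim$panel, sim$adj, seed = 2,
           control = bym_control(n_iterations = 800L, n_burnin = 300L,
                                 n_chains = 1L, adapt_until = 300L)))
  cls <- classify_areas(fit)
  expect_equal(nrow(cls), 9L)
  expect_false(anyNA(cls$risk_category))
  expect_false(anyNA(cls$trend_category))
  rep <- classification_report(cls)
  expect_equal(sum(rep$risk$count), 9L)
  for (rc in rep$risk$risk_category) {
    within <- rep$trend_within_risk[rep$trend_within_risk$risk_category == rc, ]
    expect_equal(sum(within$count),
                 rep$risk$count[rep$risk$risk_category == rc])
  }
  # percentages are integer-rounded shares of N
  expect_equal(rep$risk$percent,
               as.integer(round(100 * rep$risk$count / 9)))
})

test_that("27 of 75 areas is reported as 36 percent", {
  p <- panel_with_rates(matrix(20, 75L, 3L))
  adj <- make_lattice(5L, 15L)
  m <- zero_draw_matrix(p, 10L)
  # 27 areas clearly positive, 19 clearly negative, 29 mixed draws
  ids <- p$area_ids
  for (i in seq_len(75L)) {
    col <- paste0("u[", ids[i], "]")
    m[, col] <- if (i <= 27L) 1 else if (i <= 27L + 19L) -1 else
      rep(c(1, -1), 5L)
  }
  cls <- classify_areas(fake_fit(list(m), p, adj))
  rep <- classification_report(cls)
  risk <- rep$risk
  expect_equal(risk$count[risk$risk_category == "high"], 27L)
  expect_equal(risk$percent[risk$risk_category == "high"], 36L)
  expect_equal(risk$count[risk$risk_category == "low"], 19L)
  expect_equal(risk$percent[risk$risk_category == "low"], 25L)
  expect_equal(risk$count[risk$risk_category == "medium"], 29L)
  expect_equal(risk$percent[risk$risk_category == "medium"], 39L)
})

test_that("classification is a pure function of persisted draws", {
  sim <- simulate_panel(scenario_config(n_rows = 3L, n_cols = 3L,
                                        n_years = 3L), seed = 6)
  fit <- suppressWarnings(
    bym_st(sim$panel, sim$adj, seed = 4,
           control = bym_control(n_iterations = 600L, n_burnin = 200L,
                                 n_chains = 1L, adapt_until = 200L)))
  f <- tempfile(fileext = ".csv")
  write_draws(fit, f)
  fit2 <- read_draws(f, sim$panel, sim$adj)
  expect_equal(classify_areas(fit2), classify_areas(fit))
})

test_that("raising every u+s draw cannot lower the exceedance probability", {
  p <- panel_with_rates(matrix(20, 2L, 3L))
  adj <- path_adj(2L)
  set.seed(8)
  m <- zero_draw_matrix(p, 100L)
  m[, "u[m01]"] <- rnorm(100L)
  base <- excess_risk_probability(fake_fit(list(m), p, adj), 1L)
  m_up <- m
  m_up[, "u[m01]"] <- m[, "u[m01]"] + 0.5
  up <- excess_risk_probability(fake_fit(list(m_up), p, adj), 1L)
  expect_gte(up, base)
})

test_that("risk surface brackets its mean and degenerates correctly", {
  p <- panel_with_rates(matrix(20, 2L, 3L))
  adj <- path_adj(2L)
  # identical draws: zero-width intervals at the point risk
  m <- zero_draw_matrix(p, 5L)
  m[, "alpha"] <- qlogis(0.02)
  fit <- fake_fit(list(m), p, adj)
  surf <- risk_surface(fit)
  expect_true(all(abs(surf$cells$risk_mean_per1000 - 20) < 1e-9))
  expect_true(all(surf$cells$risk_lo == surf$cells$risk_hi))
  # d0 = 0, v = 0: overall trend flat at 1
  expect_true(all(surf$trend$rel_trend == 1))
  # random draws: CI brackets the mean everywhere
  set.seed(9)
  m2 <- zero_draw_matrix(p, 300L)
  m2[, "alpha"] <- rnorm(300L, qlogis(0.02), 0.2)
  m2[, "d0"] <- rnorm(300L, 0, 0.05)
  surf2 <- risk_surface(fake_fit(list(m2), p, adj))
  expect_true(all(surf2$cells$risk_lo <= surf2$cells$risk_mean_per1000 &
                  surf2$cells$risk_mean_per1000 <= surf2$cells$risk_hi))
  expect_true(all(surf2$trend$lo <= surf2$trend$rel_trend &
                  surf2$trend$rel_trend <= surf2$trend$hi))
})

test_that("strongly elevated areas are flagged high risk", {
  # large exposures + a big known spatial bump: the posterior must find it
  sc <- scenario_config(n_rows = 3L, n_cols = 3L, n_years = 3L,
                        sigma2_s = 1e-12, sigma2_u = 1e-12,
                        sigma2_d = 1e-12, sigma2_v = 1e-12,
                        sigma2_eps = 1e-12,
                        births_range = c(50000, 60000))
  sim <- simulate_panel(sc, seed = 7)
  # inject a known elevated block by rebuilding deaths with u+s = +0.6 in
  # areas 1-3
  bump <- c(rep(0.6, 3L), rep(-0.225, 6L))
  eta <- qlogis(0.018) + outer(bump, rep(1, 3L))
  set.seed(77)
  deaths <- matrix(rbinom(27L, as.vector(sim$panel$births),
                          as.vector(plogis(eta))), 9L, 3L)
  df <- as.data.frame(sim$panel)
  df$deaths <- as.vector(deaths)
  panel <- mortality_panel(df)
  fit <- suppressWarnings(
    bym_st(panel, sim$adj, seed = 5,
           control = bym_control(n_iterations = 3000L, n_burnin = 1000L,
                                 n_chains = 1L, adapt_until = 1000L)))
  cls <- classify_areas(fit)
  expect_true(all(cls$risk_category[1:3] == "high"))
})
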