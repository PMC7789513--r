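#' Exceedance probability of the spatial component for one area
#'
#' `p(exp(u_i + s_i) > 1 | data)`: the fraction of pooled retained draws
#' with `u_i + s_i > 0`, i.e. the posterior probability that the area's
#' average odds exceed the overall odds.
#'
#' @param fit a [bym_st()] fit.
#' @param i area index (1-based, in panel order).
#' @return probability in `[0, 1]`.
#' @export
excess_risk_probability <- function(fit, i) {
  stopifnot(inherits(fit, "bym_st"))
  id <- fit$panel$area_ids[i]
  mat <- pooled_draws(fit)
  x <- mat[, paste0("s[", id, "]")] + mat[, paste0("u[", id, "]")]
  mean(x > 0)
}

#' Posterior probability of a positive differential trend for one area
#'
#' Fraction of pooled retained draws with `d1_i > 0`.
#'
#' @inheritParams excess_risk_probability
#' @return probability in `[0, 1]`.
#' @export
trend_probability <- function(fit, i) {
  stopifnot(inherits(fit, "bym_st"))
  id <- fit$panel$area_ids[i]
  mean(pooled_draws(fit)[, paste0("d1[", id, "]")] > 0)
}

#' Classify an exceedance probability into a risk category
#'
#' Probabilities above 0.8 are high risk (coded 1), below 0.2 low risk
#' (coded 2), and in between medium risk (coded 3).  The inequalities are
#' strict, so the boundary values 0.8 and 0.2 fall in the medium class.
#'
#' @param excess_prob probability (vectorized).
#' @return factor with levels `high, low, medium` and codes 1/2/3.
#' @export
classify_risk <- function(excess_prob) {
  stopifnot(all(excess_prob >= 0 & excess_prob <= 1))
  lab <- ifelse(excess_prob > 0.8, "high",
                ifelse(excess_prob < 0.2, "low", "medium"))
  factor(lab, levels = c("high", "low", "medium"))
}

#' Classify a trend probability into a trend category
#'
#' `p(d1_i > 0 | data)` above 0.8 is an increasing local trend, below 0.2
#' decreasing, otherwise stable (boundaries fall in stable).
#'
#' @param trend_prob probability (vectorized).
#' @return factor with levels `increasing, decreasing, stable`.
#' @export
classify_trend <- function(trend_prob) {
  stopifnot(all(trend_prob >= 0 & trend_prob <= 1))
  lab <- ifelse(trend_prob > 0.8, "increasing",
                ifelse(trend_prob < 0.2, "decreasing", "stable"))
  factor(lab, levels = c("increasing", "decreasing", "stable"))
}

#' Risk and trend classification of all areas
#'
#' Combines the exceedance probabilities with posterior summaries of the
#' relative risk `exp(u_i + s_i)` and the differential slope `d1_i`.
#'
#' @param fit a [bym_st()] fit.
#' @return an object of class `bym_classification`: data frame with columns
#'   `area_id, excess_prob, risk_category, risk_code, trend_prob,
#'   trend_category, rr_mean, rr_lo, rr_hi, d1_mean, d1_lo, d1_hi`.
#' @export
classify_areas <- function(fit) {
  stopifnot(inherits(fit, "bym_st"))
  mat <- pooled_draws(fit)
  ids <- fit$panel$area_ids
  s <- mat[, paste0("s[", ids, "]"), drop = FALSE]
  u <- mat[, paste0("u[", ids, "]"), drop = FALSE]
  d1 <- mat[, paste0("d1[", ids, "]"), drop = FALSE]
  rr <- exp(s + u)
  excess <- colMeans(s + u > 0)
  trendp <- colMeans(d1 > 0)
  risk <- classify_risk(excess)
  qs <- function(m) apply(m, 2L, stats::quantile, probs = c(0.025, 0.975))
  rr_q <- qs(rr); d1_q <- qs(d1)
  out <- data.frame(area_id = ids,
                    excess_prob = excess,
                    risk_category = risk,
                    risk_code = c(high = 1L, low = 2L, medium = 3L)[
                      as.character(risk)],
                    trend_prob = trendp,
                    trend_category = classify_trend(trendp),
                    rr_mean = colMeans(rr), rr_lo = rr_q[1L, ],
                    rr_hi = rr_q[2L, ],
                    d1_mean = colMeans(d1), d1_lo = d1_q[1L, ],
                    d1_hi = d1_q[2L, ],
                    row.names = NULL)
  class(out) <- c("bym_classification", "data.frame")
  out
}

#' Category-count report
#'
#' Counts and integer percentages of areas per risk category, and within
#' each risk category per trend category.
#'
#' @param classification a [classify_areas()] result.
#' @return list with `risk` (data frame `risk_category, count, percent`)
#'   and `trend_within_risk` (data frame `risk_category, trend_category,
#'   count, percent` where percent is of the risk-category count).
#' @export
classification_report <- function(classification) {
  stopifnot(inherits(classification, "bym_classification"))
  n <- nrow(classification)
  rc <- table(classification$risk_category)
  risk <- data.frame(risk_category = names(rc),
                     count = as.integer(rc),
                     percent = as.integer(round(100 * as.integer(rc) / n)))
  tw <- as.data.frame(table(risk_category = classification$risk_category,
                            trend_category = classification$trend_category))
  names(tw)[3L] <- "count"
  denom <- rc[as.character(tw$risk_category)]
  tw$percent <- ifelse(denom > 0,
                       as.integer(round(100 * tw$count / as.integer(denom))),
                       0L)
  list(risk = risk, trend_within_risk = tw)
}

#' Posterior risk surface and overall trend
#'
#' For every retained draw the fitted risk `mu_it` is evaluated through the
#' model's linear predictor; cells report the pooled posterior mean and
#' equal-tailed 95% interval of `1000 mu_it`.  The overall relative trend
#' is `exp(d0 t* + v_t)` per year with its interval.
#'
#' @param fit a [bym_st()] fit.
#' @return an object of class `bym_surface`: list with `cells` (data frame
#'   `area_id, year, risk_mean_per1000, risk_lo, risk_hi`) and `trend`
#'   (data frame `year, rel_trend, lo, hi`).
#' @export
risk_surface <- function(fit) {
  stopifnot(inherits(fit, "bym_st"))
  mat <- pooled_draws(fit)
  n <- fit$n_areas; t_len <- fit$n_years
  ids <- fit$panel$area_ids; years <- fit$panel$years
  ts <- fit$tindex$t_star

  alpha <- mat[, "alpha"]; d0 <- mat[, "d0"]
  s <- mat[, paste0("s[", ids, "]"), drop = FALSE]
  u <- mat[, paste0("u[", ids, "]"), drop = FALSE]
  d1 <- mat[, paste0("d1[", ids, "]"), drop = FALSE]
  v <- mat[, paste0("v[", years, "]"), drop = FALSE]

  cells <- vector("list", t_len)
  for (t in seq_len(t_len)) {
    eps_t <- mat[, paste0("eps[", ids, ",", years[t], "]"), drop = FALSE]
    eta <- alpha + (s + u) + (d0 * ts[t] + v[, t]) + d1 * ts[t] + eps_t
    mu <- 1000 * stats::plogis(eta)
    q <- apply(mu, 2L, stats::quantile, probs = c(0.025, 0.975))
    cells[[t]] <- data.frame(area_id = ids, year = years[t],
                             risk_mean_per1000 = colMeans(mu),
                             risk_lo = q[1L, ], risk_hi = q[2L, ],
                             row.names = NULL)
  }
  trend_draws <- exp(outer(d0, ts) + v)
  tq <- apply(trend_draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  structure(list(
    cells = do.call(rbind, cells),
    trend = data.frame(year = years, rel_trend = colMeans(trend_draws),
                       lo = tq[1L, ], hi = tq[2L, ], row.names = NULL)
  ), class = "bym_surface")
}

#' @rdname risk_surface
#' @export
overall_trend <- function(fit) risk_surface(fit)$trend

#' @export
print.bym_classification <- function(x, ...) {
  rep <- classification_report(x)
  cat(sprintf("Risk classification of %d areas:\n", nrow(x)))
  print(rep$risk, row.names = FALSE)
  invisible(x)
}

#' Export a classification to GeoJSON feature properties
#'
#' Attaches `excess_prob`, `risk_category`, `trend_prob`, `trend_category`
#' to the features of an existing GeoJSON file (matched on `area_id`) so
#' external tools can map them.
#'
#' @param classification a [classify_areas()] result.
#' @param geojson_in path to the source GeoJSON.
#' @param path output path.
#' @param id_property feature property holding the area id.
#' @return `path`, invisibly.
#' @export
write_classification_geojson <- function(classification, geojson_in, path,
                                         id_property = "area_id") {
  stopifnot(inherits(classification, "bym_classification"))
  gj <- jsonlite::read_json(geojson_in)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  idx <- stats::setNames(seq_len(nrow(classification)),
                         classification$area_id)
  gj$features <- lapply(gj$features, function(f) {
    id <- as.character(f$properties[[id_property]])
    if (!is.na(idx[id])) {
      r <- classification[idx[id], ]
      f$properties$excess_prob <- r$excess_prob
      f$properties$risk_category <- as.character(r$risk_category)
      f$properties$trend_prob <- r$trend_prob
      f$properties$trend_category <- as.character(r$trend_category)
    }
    f
  })
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
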