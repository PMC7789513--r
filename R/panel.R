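#' Construct a mortality panel
#'
#' A mortality panel is a complete area-by-year table of exposures (live
#' births) and events (child deaths).  Internally it is stored as two
#' integer matrices with one row per area and one column per year; the
#' binomial model treats cell `(i, t)` as `deaths[i, t] ~
#' Binomial(births[i, t], mu[i, t])`.
#'
#' @param data a data frame with columns for area id, calendar year, births
#'   and deaths (long format, one row per area-year cell).
#' @param area_col,year_col,births_col,deaths_col column names in `data`.
#' @return an object of class `mortality_panel`: a list with `area_ids`
#'   (character, sorted), `years` (integer, consecutive), `births` and
#'   `deaths` (N x T integer matrices with dimnames).
#'
#' @details Validation enforces the panel contract: every (area, year) cell
#'   present exactly once; years consecutive; `0 <= deaths <= births`;
#'   `births >= 1` (a zero-exposure cell carries no binomial information and
#'   breaks rate computation, so it is rejected rather than imputed).  Areas
#'   are ordered by lexicographic id sort and that order is used everywhere
#'   downstream (adjacency matrix rows, random-effect vectors).
#' @export
mortality_panel <- function(data, area_col = "area_id", year_col = "year",
                            births_col = "births", deaths_col = "deaths") {
  stopifnot(is.data.frame(data))
  need <- c(area_col, year_col, births_col, deaths_col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0L) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  area <- as.character(data[[area_col]])
  year <- as.integer(data[[year_col]])
  births <- data[[births_col]]
  deaths <- data[[deaths_col]]
  if (any(is.na(area)) || any(is.na(year)) || any(is.na(births)) ||
      any(is.na(deaths))) {
    stop("panel contains missing values")
  }
  if (any(births != round(births)) || any(deaths != round(deaths))) {
    stop("births and deaths must be integer counts")
  }
  births <- as.integer(round(births))
  deaths <- as.integer(round(deaths))
  if (any(deaths < 0L)) stop("negative death counts")
  if (any(births < 1L)) {
    bad <- which(births < 1L)[1L]
    stop(sprintf("zero-birth cell at (area %s, year %d): cells need births >= 1",
                 area[bad], year[bad]))
  }
  bad <- which(deaths > births)
  if (length(bad) > 0L) {
    stop(sprintf("deaths exceed births at (area %s, year %d): %d > %d",
                 area[bad[1L]], year[bad[1L]], deaths[bad[1L]], births[bad[1L]]))
  }

  area_ids <- sort(unique(area))
  years <- sort(unique(year))
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("years must be consecutive; got gaps at ",
         paste(years[which(diff(years) != 1L)], collapse = ", "))
  }
  key <- paste(area, year, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop(sprintf("duplicate (area %s, year %d) row",
                 area[which(dup)[1L]], year[which(dup)[1L]]))
  }
  full <- expand.grid(area = area_ids, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full_key <- paste(full$area, full$year, sep = "\r")
  absent <- setdiff(full_key, key)
  if (length(absent) > 0L) {
    parts <- strsplit(absent[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("incomplete panel: missing (area %s, year %s)",
                 parts[1L], parts[2L]))
  }

  n <- length(area_ids); t_len <- length(years)
  idx_a <- match(area, area_ids)
  idx_t <- match(year, years)
  b_mat <- matrix(NA_integer_, n, t_len,
                  dimnames = list(area_ids, as.character(years)))
  d_mat <- b_mat
  b_mat[cbind(idx_a, idx_t)] <- births
  d_mat[cbind(idx_a, idx_t)] <- deaths

  structure(list(area_ids = area_ids, years = as.integer(years),
                 births = b_mat, deaths = d_mat),
            class = "mortality_panel")
}

#' Read a mortality panel from CSV
#'
#' Expects a UTF-8 CSV with a header; default columns
#' `area_id,year,births,deaths`, remappable via the `*_col` arguments.
#'
#' @inheritParams mortality_panel
#' @param path path to the CSV file.
#' @return a validated [mortality_panel()].
#' @export
read_panel <- function(path, area_col = "area_id", year_col = "year",
                       births_col = "births", deaths_col = "deaths") {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mortality_panel(df, area_col, year_col, births_col, deaths_col)
}

#' Write a mortality panel to CSV (long format)
#' @param panel a [mortality_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mortality_panel"))
  df <- as.data.frame(panel)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.mortality_panel <- function(x, ...) {
  data.frame(
    area_id = rep(x$area_ids, times = length(x$years)),
    year = rep(x$years, each = length(x$area_ids)),
    births = as.vector(x$births),
    deaths = as.vector(x$deaths),
    stringsAsFactors = FALSE
  )
}

#' Observed event rates per 1000 exposures
#'
#' @param panel a [mortality_panel()].
#' @return N x T numeric matrix, `1000 * deaths / births`.
#' @export
panel_rates <- function(panel) {
  stopifnot(inherits(panel, "mortality_panel"))
  1000 * panel$deaths / panel$births
}

#' Per-year descriptive statistics of area-level rates
#'
#' Summarizes the observed rate surface the way descriptive tables in
#' disease-mapping studies do: for each year, the mean, sample standard
#' deviation (N - 1 denominator), minimum and maximum over areas of the rate
#' per 1000, plus the per-year mean/variance pair used to inspect
#' overdispersion (for a binomial panel with constant risk the across-area
#' variance of rates should be close to the sampling variance; a large
#' excess indicates extra-binomial variation).
#'
#' @param panel a [mortality_panel()].
#' @return an object of class `panel_summary`: a list with `table` (rows
#'   mean/sd/min/max, one column per year), `overall_rate` (pooled deaths /
#'   pooled births * 1000) and `mean_var` (per-year mean and variance of
#'   rates).
#' @export
yearly_summary <- function(panel) {
  stopifnot(inherits(panel, "mortality_panel"))
  r <- panel_rates(panel)
  n_areas <- nrow(r)
  if (n_areas == 1L) {
    warning("single-area panel: standard deviation reported as 0")
    sds <- rep(0, ncol(r))
  } else {
    sds <- apply(r, 2, stats::sd)
  }
  tab <- rbind(mean = colMeans(r), sd = sds,
               min = apply(r, 2, min), max = apply(r, 2, max))
  colnames(tab) <- as.character(panel$years)
  structure(list(
    table = tab,
    overall_rate = 1000 * sum(panel$deaths) / sum(panel$births),
    mean_var = rbind(mean = colMeans(r), var = sds^2)
  ), class = "panel_summary")
}

#' Write a yearly summary table to CSV (one row per statistic)
#' @param summary a [yearly_summary()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "panel_summary"))
  df <- data.frame(statistic = rownames(summary$table),
                   summary$table, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mortality_panel <- function(x, ...) {
  cat(sprintf("Mortality panel: %d areas x %d years (%d-%d)\n",
              length(x$area_ids), length(x$years),
              min(x$years), max(x$years)))
  cat(sprintf("  total births %d, total deaths %d, pooled rate %.2f per 1000\n",
              sum(x$births), sum(x$deaths),
              1000 * sum(x$deaths) / sum(x$births)))
  invisible(x)
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("Observed rates per 1000 exposures, by year:\n")
  print(round(x$table, 2))
  cat(sprintf("Overall pooled rate: %.2f per 1000\n", x$overall_rate))
  invisible(x)
}

#' @export
summary.mortality_panel <- function(object, ...) yearly_summary(object)
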