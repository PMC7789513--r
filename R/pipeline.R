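#' Read a pipeline run configuration
#'
#' Runs are driven by a YAML file with sections `paths` (panel, edges,
#' outdir), `scenario` (overrides for [scenario_config()]), `prior`
#' (arguments of [bym_prior()]), `sampler` (arguments of [bym_control()])
#' and `diagnostics` (`n_permutations`, `credible_level`), plus a top-level
#' `seed`.  Every value has a default, so an empty file is a valid config;
#' the full merged config is echoed into the run metadata of each step for
#' reproducibility.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @param overrides named list merged over the file contents (CLI-style
#'   overrides; deepest keys win).
#' @return an object of class `bym_run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  cfg <- modifyList(cfg, overrides)
  defaults <- list(
    seed = 1L,
    paths = list(panel = NULL, edges = NULL, outdir = "."),
    scenario = list(),
    prior = list(),
    sampler = list(n_iterations = 100000L, n_burnin = 30000L,
                   n_chains = 2L, thin = 1L),
    diagnostics = list(n_permutations = 999L, credible_level = 0.95)
  )
  cfg <- modifyList(defaults, cfg)
  class(cfg) <- "bym_run_config"
  cfg
}

out_path <- function(config, file) {
  dir <- config$paths$outdir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, file)
}

write_metadata <- function(config, file, extra = list()) {
  meta <- c(list(config = unclass(config),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  jsonlite::write_json(meta, out_path(config, file), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

#' Pipeline step: simulate a synthetic panel to disk
#'
#' Writes `panel.csv`, `edges.csv`, `truth.json` (true parameter values)
#' and `simulate_meta.json` into the configured output directory.
#'
#' @param config a [read_run_config()] result.
#' @return the [simulate_panel()] result, invisibly.
#' @export
pipeline_simulate <- function(config = read_run_config()) {
  sc <- do.call(scenario_config, config$scenario)
  sim <- simulate_panel(sc, seed = config$seed)
  write_panel(sim$panel, out_path(config, "panel.csv"))
  write_edges(sim$adj, out_path(config, "edges.csv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(alpha = truth$alpha, d0 = truth$d0, s = truth$s, u = truth$u,
         d1 = truth$d1, v = truth$v,
         sigma2 = list(s = truth$sigma2_s, u = truth$sigma2_u,
                       v = truth$sigma2_v, d = truth$sigma2_d,
                       eps = truth$sigma2_eps)),
    out_path(config, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_metadata(config, "simulate_meta.json")
  invisible(sim)
}

#' Pipeline step: diagnostics and model fit
#'
#' Reads the panel and edge list named in the config (defaulting to the
#' files [pipeline_simulate()] writes), runs the preliminary diagnostics
#' (per-year Moran permutation tests, mean lag-1 ACF), fits the model, and
#' writes `moran.csv`, `summary.csv`, `draws.csv` (one column per scalar
#' parameter, one row per retained draw, with a chain id column) and
#' `fit_meta.json` (config echo, seed, R-hat, acceptance rates, ACF mean).
#' A warning lists any parameter whose R-hat exceeds the threshold.
#'
#' @param config a [read_run_config()] result.
#' @return the fitted [bym_st()] object, invisibly.
#' @export
pipeline_fit <- function(config = read_run_config()) {
  panel_path <- config$paths$panel %||% out_path(config, "panel.csv")
  edges_path <- config$paths$edges %||% out_path(config, "edges.csv")
  panel <- read_panel(panel_path)
  adj <- read_edges(edges_path, area_ids = panel$area_ids)

  moran <- moran_by_year(panel, adj,
                         n_permutations = config$diagnostics$n_permutations,
                         seed = config$seed)
  utils::write.csv(moran, out_path(config, "moran.csv"), row.names = FALSE)
  acf_mean <- mean_lag1_acf(panel)

  control <- do.call(bym_control, config$sampler)
  prior <- do.call(bym_prior, config$prior)
  fit <- bym_st(panel, adj, prior = prior, control = control,
                seed = config$seed)

  utils::write.csv(summary(fit), out_path(config, "summary.csv"),
                   row.names = FALSE)
  write_draws(fit, out_path(config, "draws.csv"))
  write_metadata(config, "fit_meta.json", extra = list(
    rhat = as.list(fit$rhat[!is.na(fit$rhat)]),
    acceptance = as.data.frame(fit$acceptance),
    acf_mean = acf_mean,
    moran_mean = mean(moran$I)))
  invisible(fit)
}

#' Pipeline step: classification outputs
#'
#' From a fitted model (or draws re-read from `draws.csv` via
#' [read_draws()]), writes `classification.csv`, `risk_surface.csv`,
#' `overall_trend.csv` and `category_counts.csv`.
#'
#' @param config a [read_run_config()] result.
#' @param fit optional [bym_st()] fit; when missing, draws are reloaded
#'   from the output directory (so classification can re-run without
#'   re-sampling).
#' @return the [classify_areas()] result, invisibly.
#' @export
pipeline_classify <- function(config = read_run_config(), fit = NULL) {
  if (is.null(fit)) {
    draws_path <- out_path(config, "draws.csv")
    if (!file.exists(draws_path)) {
      stop("no fitted draws found at ", draws_path,
           ": run pipeline_fit() first")
    }
    panel <- read_panel(config$paths$panel %||% out_path(config, "panel.csv"))
    adj <- read_edges(config$paths$edges %||% out_path(config, "edges.csv"),
                      area_ids = panel$area_ids)
    fit <- read_draws(draws_path, panel, adj)
  }
  cls <- classify_areas(fit)
  utils::write.csv(as.data.frame(cls), out_path(config, "classification.csv"),
                   row.names = FALSE)
  surf <- risk_surface(fit)
  utils::write.csv(surf$cells, out_path(config, "risk_surface.csv"),
                   row.names = FALSE)
  utils::write.csv(surf$trend, out_path(config, "overall_trend.csv"),
                   row.names = FALSE)
  rep <- classification_report(cls)
  utils::write.csv(rep$trend_within_risk,
                   out_path(config, "category_counts.csv"),
                   row.names = FALSE)
  invisible(cls)
}

#' Persist retained draws as columnar CSV
#'
#' One row per retained draw, one column per scalar parameter, plus a
#' leading `chain` column.
#'
#' @param fit a [bym_st()] fit.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "bym_st"))
  rows <- lapply(seq_along(fit$draws), function(c) {
    data.frame(chain = c, fit$draws[[c]], check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Rebuild a minimal fit object from persisted draws
#'
#' Restores enough of a [bym_st()] object (draw matrices, parameter names,
#' panel, adjacency, time index) for [classify_areas()], [risk_surface()]
#' and [summary.bym_st()] to run without re-sampling.  Sampler settings
#' and acceptance rates are not recoverable from the CSV.
#'
#' @param path CSV written by [write_draws()].
#' @param panel,adj the panel and adjacency the fit used.
#' @return a `bym_st` object (with `control`/`acceptance` absent).
#' @export
read_draws <- function(path, panel, adj) {
  df <- utils::read.csv(path, check.names = FALSE)
  chains <- sort(unique(df$chain))
  draws <- lapply(chains, function(c) {
    as.matrix(df[df$chain == c, -1L, drop = FALSE])
  })
  par_names <- colnames(draws[[1L]])
  rhat <- if (length(chains) >= 2L) {
    vapply(seq_along(par_names), function(j) {
      mat <- t(vapply(draws, function(d) d[, j], numeric(nrow(draws[[1L]]))))
      tryCatch(gelman_rubin(mat), error = function(e) NA_real_)
    }, numeric(1))
  } else rep(NA_real_, length(par_names))
  names(rhat) <- par_names
  structure(list(draws = draws, parameters = par_names, rhat = rhat,
                 acceptance = NULL, panel = panel, adj = adj,
                 tindex = time_index(panel$years), prior = NULL,
                 control = NULL, seed = NA_integer_,
                 n_areas = length(panel$area_ids),
                 n_years = length(panel$years),
                 use_likelihood = TRUE),
            class = "bym_st")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
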