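# shared fixtures and independent oracles, built in code at test time

# small complete panel as a data frame
panel_df <- function(n_areas = 3L, years = 2011:2013, births = 1000L,
                     deaths = NULL) {
  ids <- sprintf("m%02d", seq_len(n_areas))
  df <- expand.grid(area_id = ids, year = years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$births <- births
  df$deaths <- if (is.null(deaths)) 20L else deaths
  df
}

# panel whose observed rates per 1000 are given by an N x T matrix
panel_with_rates <- function(rate_mat, births = 1000L) {
  n <- nrow(rate_mat); t_len <- ncol(rate_mat)
  df <- panel_df(n, 2011:(2010 + t_len), births = births)
  # rows of expand.grid vary area fastest, matching as.vector(matrix)
  df$deaths <- as.integer(round(as.vector(rate_mat) * births / 1000))
  mortality_panel(df)
}

# path graph on n nodes
path_adj <- function(n) {
  ids <- sprintf("m%02d", seq_len(n))
  adjacency_from_edges(ids, cbind(ids[-n], ids[-1L]))
}

# random connected graph: random spanning tree plus extra random edges
random_adj <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  ids <- sprintf("m%02d", seq_len(n))
  perm <- sample(n)
  edges <- cbind(ids[perm[-n]], ids[perm[-1L]])
  for (k in seq_len(extra)) {
    pair <- sample(n, 2L)
    edges <- rbind(edges, ids[pair])
  }
  adjacency_from_edges(ids, edges)
}

# dense Moran's I by explicit double loop (independent of the package path)
moran_oracle <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
    s0 <- s0 + W[i, j]
  }
  (n / s0) * num / sum((x - xb)^2)
}

# brute-force binomial log-likelihood, term by term
loglik_oracle <- function(panel, eta) {
  total <- 0
  for (i in seq_len(nrow(panel$births))) {
    for (t in seq_len(ncol(panel$births))) {
      mu <- 1 / (1 + exp(-eta[i, t]))
      total <- total + stats::dbinom(panel$deaths[i, t],
                                     panel$births[i, t], mu, log = TRUE)
    }
  }
  total
}

# Moore-Penrose pseudo-inverse via eigendecomposition (dense oracle)
pinv_sym <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

# minimal fit object around a given pooled draw matrix (named columns),
# enough for the classification and surface functions
fake_fit <- function(draws_list, panel, adj) {
  structure(list(draws = draws_list,
                 parameters = colnames(draws_list[[1L]]),
                 rhat = NULL, acceptance = NULL, panel = panel, adj = adj,
                 tindex = time_index(panel$years), prior = NULL,
                 control = NULL, seed = NA_integer_,
                 n_areas = length(panel$area_ids),
                 n_years = length(panel$years), use_likelihood = TRUE),
            class = "bym_st")
}

# full named draw matrix for a model of given panel dims, all columns zero
zero_draw_matrix <- function(panel, n_draws) {
  ids <- panel$area_ids; years <- panel$years
  n <- length(ids); t_len <- length(years)
  par_names <- c("alpha", "d0",
                 paste0("s[", ids, "]"), paste0("u[", ids, "]"),
                 paste0("d1[", ids, "]"), paste0("v[", years, "]"),
                 "sigma2_s", "sigma2_u", "sigma2_v", "sigma2_d", "sigma2_eps",
                 paste0("eps[", rep(ids, t_len), ",",
                        rep(years, each = n), "]"))
  m <- matrix(0, n_draws, length(par_names),
              dimnames = list(NULL, par_names))
  m[, c("sigma2_s", "sigma2_u", "sigma2_v", "sigma2_d", "sigma2_eps")] <- 1
  m
}

# GeoJSON text for a grid of unit squares, row-major ids g01..g(n)
grid_geojson <- function(rows, cols) {
  feats <- character(0)
  k <- 0L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    k <- k + 1L
    x0 <- c - 1; y0 <- r - 1
    ring <- sprintf("[[%d,%d],[%d,%d],[%d,%d],[%d,%d],[%d,%d]]",
                    x0, y0, x0 + 1L, y0, x0 + 1L, y0 + 1L, x0, y0 + 1L,
                    x0, y0)
    feats <- c(feats, sprintf(
      '{"type":"Feature","properties":{"area_id":"g%02d"},"geometry":{"type":"Polygon","coordinates":[%s]}}',
      k, ring))
  }
  paste0('{"type":"FeatureCollection","features":[',
         paste(feats, collapse = ","), "]}")
}
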