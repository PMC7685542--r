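# Shared fixtures and small oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

path3_graph <- function() graph_from_edge_list(rbind(c(1L, 2L), c(2L, 3L)), 3L)

# Weakly-informative log-scale Gamma priors used for simulation studies
# (see the methods vignette); the package default prior is deliberately
# not used here because it is near-degenerate for weakly identified
# variance components.
recovery_prior <- function() {
  prior_config(gamma_shape = 0.1, gamma_rate = 0.1, shape_r = 0.1, rate_r = 0.1)
}

# tiny fully observed panel with hand-controllable counts
tiny_panel <- function(cases, denom) {
  count_panel(as.matrix(cases), as.matrix(denom))
}

# an all-missing panel (used for prior-recovery runs)
empty_panel <- function(I, T) {
  suppressWarnings(count_panel(matrix(NA_integer_, I, T),
                               matrix(NA_integer_, I, T)))
}

# GeoJSON FeatureCollection of axis-aligned unit squares at given origins
squares_geojson <- function(origins, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%02d", seq_along(origins))
  feats <- vapply(seq_along(origins), function(k) {
    x <- origins[[k]][1]; y <- origins[[k]][2]
    ring <- sprintf("[[%s]]", paste(
      sprintf("[%s,%s]", c(x, x + 1, x + 1, x, x), c(y, y, y + 1, y + 1, y)),
      collapse = ","))
    sprintf(paste0('{"type":"Feature","properties":{"area_id":"%s"},',
                   '"geometry":{"type":"Polygon","coordinates":%s}}'),
            ids[[k]], ring)
  }, character(1))
  paste0('{"type":"FeatureCollection","features":[',
         paste(feats, collapse = ","), "]}")
}

write_geojson <- function(txt) {
  f <- tempfile(fileext = ".geojson")
  writeLines(txt, f)
  f
}

# Numerical oracle: conditional density of u[i] given the rest, obtained by
# grid evaluation of the joint ICAR kernel, compared with the Gaussian
# full conditional.
icar_conditional_gap <- function(u, i, tau, graph, ngrid = 401) {
  fc <- icar_full_conditional(u, i, tau, graph)
  sdv <- 1 / sqrt(fc$precision)
  z <- seq(fc$mean - 6 * sdv, fc$mean + 6 * sdv, length.out = ngrid)
  lk <- vapply(z, function(val) {
    uu <- u; uu[i] <- val
    icar_log_density(uu, tau, graph)
  }, numeric(1))
  w <- exp(lk - max(lk)); w <- w / sum(w)
  g <- stats::dnorm(z, fc$mean, sdv); g <- g / sum(g)
  max(abs(w - g))
}

# Constant-draw posterior_chains with pi = exp(alpha) everywhere: lets
# reporting functions be tested against hand-computable truths.
const_chains <- function(I, T, alpha = 0, u = 0, n_draws = 20L,
                         n_chains = 2L, jitter = 0) {
  pn <- anaemap:::.param_names(I, T)
  u <- rep_len(u, I)
  one <- function(seed) {
    set.seed(seed)
    m <- matrix(0, n_draws, length(pn), dimnames = list(NULL, pn))
    m[, "alpha"] <- alpha + (if (jitter > 0) rnorm(n_draws, 0, jitter) else 0)
    m[, paste0("u[", seq_len(I), "]")] <-
      matrix(u, n_draws, I, byrow = TRUE)
    m[, "r"] <- 0.1
    m[, c("tau_u", "tau_v", "tau_xi", "tau_nu")] <- 1
    m
  }
  chains <- lapply(seq_len(n_chains), one)
  structure(
    list(chains = chains, param_names = pn,
         idx = anaemap:::.param_index(I, T), n_areas = I, n_times = T,
         area_ids = NULL, calendar = NULL,
         config = mcmc_config(n_chains = n_chains, n_iter = n_draws + 1L,
                              n_burnin = 0L, thin = 1L, seed = 1L),
         seed = 1L),
    class = "posterior_chains"
  )
}
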