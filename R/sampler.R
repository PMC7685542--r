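#' MCMC configuration
#'
#' Defaults follow the documented full-run protocol: two chains of 71,000
#' iterations with a 4,000-iteration burn-in. [desk_config()] is the
#' desk-scale preset (2 x 6,000 draws, 1,000 burn-in) used for simulation
#' studies and tests.
#'
#' @param n_chains number of chains (>= 1; convergence diagnostics need 2).
#' @param n_iter total iterations per chain.
#' @param n_burnin burn-in iterations discarded (and used for adaptation).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain `k` uses `seed + k - 1`.
#' @param adapt_interval proposal scales are retuned every this many sweeps
#'   *during burn-in only*; the post-burn-in kernel is fixed.
#' @param target_accept target acceptance rate for scalar random-walk
#'   proposals.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 71000L, n_burnin = 4000L,
                        thin = 1L, seed = 1L, adapt_interval = 100L,
                        target_accept = 0.44) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin); thin <- as.integer(thin)
  if (n_chains < 1L) stop("`n_chains` must be >= 1", call. = FALSE)
  if (n_burnin >= n_iter) stop("`n_burnin` must be smaller than `n_iter`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  structure(
    list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
         thin = thin, seed = as.integer(seed),
         adapt_interval = as.integer(adapt_interval),
         target_accept = target_accept),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @param ... overrides passed on to [mcmc_config()].
#' @export
desk_config <- function(...) {
  args <- utils::modifyList(
    list(n_chains = 2L, n_iter = 6000L, n_burnin = 1000L), list(...)
  )
  do.call(mcmc_config, args)
}

#' Deterministic chain initialisation
#'
#' The intercept starts at the log ratio of observed to expected totals
#' (exactly zero under internal standardisation), random effects at small
#' Normal(0, 0.1^2) jitter, precisions at 1, `rho` at 0 and `r` at 0.5.
#' The jitter is drawn after `set.seed(seed)`, so each chain gets a
#' reproducible, seed-specific starting point. Island areas start (and
#' stay) at structured effect zero, and `u` is recentred per component.
#'
#' @inheritParams log_posterior
#' @param seed integer seed.
#' @return a [model_state()].
#' @export
initialize_state <- function(panel, E, graph, seed) {
  set.seed(as.integer(seed))
  I <- panel$n_areas; T <- panel$n_times
  obs <- panel$obs
  alpha <- 0
  if (any(obs)) {
    tot <- sum(panel$cases[obs])
    if (tot > 0) alpha <- log(tot / sum(E[obs]))
  }
  u <- stats::rnorm(I, 0, 0.1)
  u[graph$degree == 0L] <- 0
  for (cc in seq_len(graph$n_components)) {
    sel <- graph$component == cc
    if (any(graph$degree[sel] > 0L)) u[sel] <- u[sel] - mean(u[sel])
  }
  model_state(
    alpha = alpha, u = u,
    v = stats::rnorm(I, 0, 0.1),
    xi = stats::rnorm(T, 0, 0.1),
    nu = matrix(stats::rnorm(I * T, 0, 0.1), I, T),
    rho = 0, tau_u = 1, tau_v = 1, tau_xi = 1, tau_nu = 1, r = 0.5
  )
}

.param_names <- function(I, T) {
  c("alpha", "rho", "r", "tau_u", "tau_v", "tau_xi", "tau_nu",
    paste0("u[", seq_len(I), "]"), paste0("v[", seq_len(I), "]"),
    paste0("xi[", seq_len(T), "]"),
    paste0("nu[", rep(seq_len(I), times = T), ".", rep(seq_len(T), each = I), "]"))
}

.param_index <- function(I, T) {
  list(alpha = 1L, rho = 2L, r = 3L, tau_u = 4L, tau_v = 5L, tau_xi = 6L,
       tau_nu = 7L, u = 7L + seq_len(I), v = 7L + I + seq_len(I),
       xi = 7L + 2L * I + seq_len(T),
       nu = 7L + 2L * I + T + seq_len(I * T))
}

#' Fit the spatio-temporal count model by Metropolis-within-Gibbs MCMC
#'
#' Runs `config$n_chains` independent chains of the sampler. Each sweep
#' updates, in order: the structured spatial field `u` site-by-site (ICAR
#' full-conditional proposals corrected by the negative binomial likelihood),
#' a per-component sum-to-zero recentring of `u` whose shift is absorbed
#' into the intercept, the unstructured effects `v`, the temporal effects
#' `xi`, the interaction `nu`, the intercept, the AR(1) coefficient (random
#' walk on the logit of `(rho + 1) / 2`), the four precisions by conjugate
#' Gibbs draws, and the overdispersion `r` (random walk on `log r`).
#' Random-walk scales adapt towards `config$target_accept` during burn-in
#' only. Effects with no likelihood contribution (missing cells, empty
#' areas or quarters) are drawn exactly from their prior full conditionals,
#' so a fully missing panel samples the joint prior.
#'
#' Given identical inputs, configuration and seed the returned draws are
#' bit-identical across runs.
#'
#' @inheritParams log_posterior
#' @param config an [mcmc_config()].
#' @return An object of class `posterior_chains`: kept draws per chain
#'   (matrices with one named column per scalar parameter), acceptance
#'   rates, adapted proposal scales, and the provenance (seed, config,
#'   area ids, calendar).
#' @export
run_mcmc <- function(panel, E, graph, priors = prior_config(),
                     config = mcmc_config()) {
  stopifnot(inherits(panel, "count_panel"), inherits(graph, "adjacency_graph"))
  I <- panel$n_areas; T <- panel$n_times
  if (graph$n_areas != I) {
    stop("adjacency graph has ", graph$n_areas, " areas but panel has ", I, call. = FALSE)
  }
  if (!all(dim(E) == c(I, T))) stop("E has wrong dimensions", call. = FALSE)

  Ecpp <- E
  Ecpp[is.na(Ecpp) | Ecpp <= 0] <- 1  # placeholder on missing cells only
  if (any(Ecpp[panel$obs] != E[panel$obs])) {
    stop("E must be positive on observed cells", call. = FALSE)
  }
  y <- panel$cases
  y[!panel$obs] <- 0
  storage.mode(y) <- "double"

  nb_flat <- unlist(lapply(graph$neighbours, function(x) x - 1L))
  if (is.null(nb_flat)) nb_flat <- integer(0)
  nb_ptr <- c(0L, cumsum(graph$degree))

  pn <- .param_names(I, T)
  chains <- vector("list", config$n_chains)
  acceptance <- vector("list", config$n_chains)
  prop_sds <- vector("list", config$n_chains)
  sds0 <- c(s_v = 0.3, s_xi = 0.2, s_nu = 0.5, s_alpha = 0.05,
            s_rho = 0.6, s_r = 0.3,
            s_uv = 0.3, s_nv = 0.2, s_nx = 0.2, s_xa = 0.3)

  for (ch in seq_len(config$n_chains)) {
    init <- initialize_state(panel, E, graph, seed = config$seed + ch - 1L)
    lp0 <- log_posterior(panel, E, graph, priors, init)
    if (!is.finite(lp0)) {
      stop("non-finite log posterior at the initial state (chain ", ch,
           "); initial state dump:\n",
           paste(utils::capture.output(utils::str(init)), collapse = "\n"),
           call. = FALSE)
    }
    out <- .run_chain_cpp(
      y, Ecpp, panel$obs, as.integer(nb_flat), as.integer(nb_ptr),
      as.integer(graph$component - 1L), graph$n_components,
      init, unclass(priors),
      list(n_iter = config$n_iter, n_burnin = config$n_burnin,
           thin = config$thin, adapt_interval = config$adapt_interval,
           target_accept = config$target_accept, sds = sds0)
    )
    colnames(out$draws) <- pn
    chains[[ch]] <- out$draws
    acceptance[[ch]] <- out$acceptance
    prop_sds[[ch]] <- out$proposal_sds
  }

  structure(
    list(chains = chains, acceptance = acceptance, proposal_sds = prop_sds,
         param_names = pn, idx = .param_index(I, T),
         n_areas = I, n_times = T, area_ids = panel$area_ids,
         calendar = panel$calendar, config = config, priors = priors,
         seed = config$seed),
    class = "posterior_chains"
  )
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("<posterior_chains> ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]), " kept draws; ", length(x$param_names),
      " parameters (", x$n_areas, " areas x ", x$n_times, " quarters)\n",
      sep = "")
  cat("  iterations ", x$config$n_iter, ", burn-in ", x$config$n_burnin,
      ", thin ", x$config$thin, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Stack all chains into one draws matrix
#' @param x a `posterior_chains` object.
#' @param ... unused.
#' @return matrix of draws (rows) by named parameters (columns).
#' @export
as.matrix.posterior_chains <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Posterior summary table
#'
#' Median and central 95% uncertainty interval for each scalar parameter,
#' with split Gelman-Rubin statistic (when >= 2 chains) and effective
#' sample size.
#'
#' @param object a `posterior_chains`.
#' @param pars optional character vector restricting the parameters.
#' @param ... unused.
#' @return data frame, one row per parameter.
#' @export
summary.posterior_chains <- function(object, pars = NULL, ...) {
  m <- as.matrix(object)
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  qs <- t(apply(m, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  rh <- if (length(object$chains) >= 2L) {
    gelman_rubin(object, pars = colnames(m))
  } else rep(NA_real_, ncol(m))
  ess <- vapply(colnames(m), function(p) {
    suppressWarnings(effective_sample_size(m[, p]))
  }, numeric(1))
  data.frame(
    parameter = colnames(m), median = qs[, 1L], lower95 = qs[, 2L],
    upper95 = qs[, 3L], rhat = unname(rh[colnames(m)]), ess = unname(ess),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
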