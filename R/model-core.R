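#' Negative binomial log pmf in the (mean, overdispersion) parameterisation
#'
#' Mean `mu` and overdispersion `r`, so the variance is
#' `mu * (1 + r * mu)`; this is `stats::dnbinom()` with size `1/r`. As
#' the overdispersion shrinks to zero the distribution converges to
#' Poisson(`mu`), which is the limit
#' used throughout: for `r` below `1e-12` the Poisson log pmf is returned
#' directly to avoid overflowing the size parameter.
#'
#' @param y non-negative integer count (vectorised).
#' @param mu positive mean.
#' @param r positive overdispersion.
#' @return log probability mass.
#' @export
nb_log_pmf <- function(y, mu, r) {
  if (any(y < 0)) stop("`y` must be non-negative", call. = FALSE)
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  if (length(r) == 1L && r < 1e-12) {
    stats::dpois(y, lambda = mu, log = TRUE)
  } else {
    stats::dnbinom(y, size = 1 / r, mu = mu, log = TRUE)
  }
}

#' Model state: one draw of every unknown
#'
#' @param alpha global log relative risk (intercept).
#' @param u per-area structured (ICAR) spatial effect.
#' @param v per-area unstructured spatial effect; `u + v` is the BYM field.
#' @param xi per-quarter temporal effect (stationary AR(1)).
#' @param nu areas x times matrix of space-time interaction effects.
#' @param rho AR(1) coefficient in (-1, 1).
#' @param tau_u,tau_v,tau_xi,tau_nu positive precisions of the random
#'   effects.
#' @param r positive negative binomial overdispersion.
#' @return An object of class `model_state`.
#' @export
model_state <- function(alpha, u, v, xi, nu, rho, tau_u, tau_v, tau_xi,
                        tau_nu, r) {
  nu <- as.matrix(nu)
  if (length(u) != length(v)) stop("u and v must have equal length", call. = FALSE)
  if (nrow(nu) != length(u) || ncol(nu) != length(xi)) {
    stop("nu must be length(u) x length(xi)", call. = FALSE)
  }
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  for (nm in c("tau_u", "tau_v", "tau_xi", "tau_nu", "r")) {
    val <- get(nm)
    if (!is.finite(val) || val <= 0) stop("`", nm, "` must be positive", call. = FALSE)
  }
  structure(
    list(alpha = alpha, u = as.numeric(u), v = as.numeric(v),
         xi = as.numeric(xi), nu = nu, rho = rho,
         tau_u = tau_u, tau_v = tau_v, tau_xi = tau_xi, tau_nu = tau_nu,
         r = r),
    class = "model_state"
  )
}

#' Relative risk surface of a model state
#'
#' `relative_risk()` returns `exp(alpha + u[i] + v[i] + xi[t] + nu[i, t])`
#' for one cell; `risk_matrix()` the full areas x times surface.
#'
#' @param state a [model_state()].
#' @param i,t area and time index.
#' @return positive scalar (or matrix).
#' @export
relative_risk <- function(state, i, t) {
  stopifnot(inherits(state, "model_state"))
  i <- as.integer(i); t <- as.integer(t)
  if (i < 1L || i > length(state$u) || t < 1L || t > length(state$xi)) {
    stop("cell index out of range", call. = FALSE)
  }
  exp(state$alpha + state$u[i] + state$v[i] + state$xi[t] + state$nu[i, t])
}

#' @rdname relative_risk
#' @export
risk_matrix <- function(state) {
  stopifnot(inherits(state, "model_state"))
  lp <- state$alpha + outer(state$u + state$v, state$xi, "+") + state$nu
  exp(lp)
}

#' Panel log likelihood
#'
#' Sum of negative binomial log pmfs over observed cells with cell means
#' `E[i, t] * relative_risk(state, i, t)`; missing cells contribute zero.
#'
#' @param panel a [count_panel()].
#' @param E expected-count matrix from [compute_expected()].
#' @param state a [model_state()].
#' @return scalar log likelihood.
#' @export
panel_log_likelihood <- function(panel, E, state) {
  stopifnot(inherits(panel, "count_panel"))
  if (!all(dim(E) == c(panel$n_areas, panel$n_times))) {
    stop("E has wrong dimensions", call. = FALSE)
  }
  if (length(state$u) != panel$n_areas || length(state$xi) != panel$n_times) {
    stop("state dimensions do not match the panel", call. = FALSE)
  }
  obs <- panel$obs
  if (!any(obs)) return(0)
  mu <- E * risk_matrix(state)
  sum(nb_log_pmf(panel$cases[obs], mu[obs], state$r))
}

#' Stationary AR(1) log density
#'
#' Full (normalised) log density of a zero-mean stationary first-order
#' autoregressive sequence: `xi[1] ~ N(0, 1 / (tau * (1 - rho^2)))` and
#' `xi[t] | xi[t-1] ~ N(rho * xi[t-1], 1 / tau)`.
#'
#' @param xi numeric vector, length >= 2.
#' @param rho autoregressive coefficient, `|rho| < 1`.
#' @param tau positive innovation precision.
#' @return scalar log density.
#' @export
ar1_log_density <- function(xi, rho, tau) {
  if (length(xi) < 2L) stop("AR(1) needs at least two time points", call. = FALSE)
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive", call. = FALSE)
  T <- length(xi)
  ld <- stats::dnorm(xi[1L], 0, sqrt(1 / (tau * (1 - rho^2))), log = TRUE)
  ld + sum(stats::dnorm(xi[-1L], rho * xi[-T], sqrt(1 / tau), log = TRUE))
}

#' Modelled prevalence of one cell
#'
#' The modelled share of new clients presenting with anaemia:
#' `E[i, t] * relative_risk / N[i, t]`. Values above 1 are possible in
#' principle (the count model is unbounded) and trigger a warning, not an
#' error.
#'
#' @inheritParams panel_log_likelihood
#' @param i,t cell index.
#' @return prevalence (proportion).
#' @export
prevalence <- function(panel, E, state, i, t) {
  N <- panel$denominators[i, t]
  if (is.na(N) || N <= 0) stop("denominator missing or non-positive for this cell", call. = FALSE)
  p <- unname(E[i, t] * relative_risk(state, i, t) / N)
  if (p > 1) warning("modelled prevalence exceeds 1 for cell (", i, ",", t, ")", call. = FALSE)
  p
}

#' Prior configuration
#'
#' Weakly-informative defaults of the WinBUGS disease-mapping tradition:
#' Gamma(shape, rate) on every random-effect precision, a flat improper
#' prior on the intercept, Normal(0, sd) on any regression coefficients
#' (none are used by the covariate-free model; kept for forward
#' compatibility), Uniform(-1, 1) on the AR(1) coefficient, and
#' Gamma(shape_r, rate_r) on the *inverse* overdispersion `1/r`.
#'
#' @param gamma_shape,gamma_rate Gamma prior on each precision.
#' @param shape_r,rate_r Gamma prior on `1/r`.
#' @param normal_sd_coeff sd of the (unused) coefficient prior.
#' @return object of class `prior_config`.
#' @export
prior_config <- function(gamma_shape = 0.5, gamma_rate = 0.0005,
                         shape_r = 0.5, rate_r = 0.0005,
                         normal_sd_coeff = 10) {
  for (v in c(gamma_shape, gamma_rate, shape_r, rate_r, normal_sd_coeff)) {
    if (!is.finite(v) || v <= 0) stop("prior hyperparameters must be positive", call. = FALSE)
  }
  structure(
    list(gamma_shape = gamma_shape, gamma_rate = gamma_rate,
         shape_r = shape_r, rate_r = rate_r,
         normal_sd_coeff = normal_sd_coeff),
    class = "prior_config"
  )
}

# log prior density of the overdispersion r implied by 1/r ~ Gamma(a, b):
# p(r) proportional to r^(-a-1) exp(-b / r).
log_prior_r <- function(r, priors) {
  -(priors$shape_r + 1) * log(r) - priors$rate_r / r
}

#' Joint log posterior (up to a constant)
#'
#' Likelihood plus ICAR(`u`), iid-normal(`v`), stationary AR(1)(`xi`),
#' iid-normal(`nu`), Gamma priors on precisions, Uniform(-1,1) on `rho`,
#' and the `1/r ~ Gamma` overdispersion prior. The intercept prior is flat.
#' Used by tests and initial-state checks; the sampler evaluates the same
#' quantity incrementally in compiled code.
#'
#' @inheritParams panel_log_likelihood
#' @param graph an `adjacency_graph`.
#' @param priors a [prior_config()].
#' @return scalar log posterior density (unnormalised).
#' @export
log_posterior <- function(panel, E, graph, priors, state) {
  I <- panel$n_areas; T <- panel$n_times
  ll <- panel_log_likelihood(panel, E, state)
  lp <- icar_log_density(state$u, state$tau_u, graph) +
    sum(stats::dnorm(state$v, 0, sqrt(1 / state$tau_v), log = TRUE)) +
    ar1_log_density(state$xi, state$rho, state$tau_xi) +
    sum(stats::dnorm(state$nu, 0, sqrt(1 / state$tau_nu), log = TRUE)) +
    stats::dgamma(state$tau_u, priors$gamma_shape, priors$gamma_rate, log = TRUE) +
    stats::dgamma(state$tau_v, priors$gamma_shape, priors$gamma_rate, log = TRUE) +
    stats::dgamma(state$tau_xi, priors$gamma_shape, priors$gamma_rate, log = TRUE) +
    stats::dgamma(state$tau_nu, priors$gamma_shape, priors$gamma_rate, log = TRUE) +
    log_prior_r(state$r, priors)
  ll + lp
}
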