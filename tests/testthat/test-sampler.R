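test_that("initialisation is seed-deterministic with chain-specific jitter", {
  sim <- suppressWarnings(generate_panel(generator_config(n_areas = 12L,
                                                          n_times = 4L,
                                                          seed = 2)))
  E <- compute_expected(sim$panel)
  s1 <- initialize_state(sim$panel, E, sim$graph, seed = 5)
  s2 <- initialize_state(sim$panel, E, sim$graph, seed = 5)
  expect_identical(s1, s2)

  # alpha starts at 0 under internal standardisation
  expect_equal(s1$alpha, 0)
  expect_equal(s1$rho, 0)
  expect_equal(s1$r, 0.5)
  expect_equal(s1$tau_u, 1)

  # different seeds differ in every random-effect vector
  s3 <- initialize_state(sim$panel, E, sim$graph, seed = 6)
  expect_true(all(s1$u != s3$u))
  expect_true(all(s1$v != s3$v))
  expect_true(all(s1$xi != s3$xi))
  expect_true(all(s1$nu != s3$nu))
})

test_that("log posterior is the sum of its independently computed parts", {
  g <- grid_graph(1, 3)
  p <- tiny_panel(matrix(c(10L, 14L, 9L, 20L, 12L, 16L), 3, 2),
                  matrix(120L, 3, 2))
  E <- compute_expected(p)
  pr <- prior_config()
  st <- model_state(alpha = 0.05, u = c(0.1, -0.05, -0.05),
                    v = c(-0.2, 0.1, 0.1), xi = c(0.15, -0.15),
                    nu = matrix(seq(-0.1, 0.15, length.out = 6), 3, 2),
                    rho = 0.4, tau_u = 2, tau_v = 3, tau_xi = 1.5,
                    tau_nu = 4, r = 0.25)
  ref <- panel_log_likelihood(p, E, st) +
    icar_log_density(st$u, st$tau_u, g) +
    sum(dnorm(st$v, 0, sqrt(1 / st$tau_v), log = TRUE)) +
    ar1_log_density(st$xi, st$rho, st$tau_xi) +
    sum(dnorm(st$nu, 0, sqrt(1 / st$tau_nu), log = TRUE)) +
    sum(dgamma(c(st$tau_u, st$tau_v, st$tau_xi, st$tau_nu),
               pr$gamma_shape, pr$gamma_rate, log = TRUE)) +
    (-(pr$shape_r + 1) * log(st$r) - pr$rate_r / st$r)
  expect_equal(log_posterior(p, E, g, pr, st), ref)
})

test_that("log posterior is invariant to shifting u against alpha", {
  g <- grid_graph(2, 3)
  set.seed(11)
  p <- tiny_panel(matrix(rpois(12, 25), 6, 2), matrix(150L, 6, 2))
  E <- compute_expected(p)
  st <- initialize_state(p, E, g, seed = 1)
  stsh <- st
  stsh$u <- st$u + 0.37
  stsh$alpha <- st$alpha - 0.37
  expect_equal(log_posterior(p, E, g, prior_config(), stsh),
               log_posterior(p, E, g, prior_config(), st), tolerance = 1e-10)
})

test_that("chains are bit-identical under a fixed seed", {
  sim <- suppressWarnings(generate_panel(generator_config(n_areas = 9L,
                                                          n_times = 4L,
                                                          seed = 3)))
  E <- compute_expected(sim$panel)
  cfg <- mcmc_config(n_chains = 2L, n_iter = 400L, n_burnin = 100L, seed = 7L)
  f1 <- run_mcmc(sim$panel, E, sim$graph, recovery_prior(), cfg)
  f2 <- run_mcmc(sim$panel, E, sim$graph, recovery_prior(), cfg)
  expect_identical(f1$chains, f2$chains)
  # chains with different seeds differ
  expect_false(identical(f1$chains[[1]], f1$chains[[2]]))
})

test_that("adaptive scaling runs during burn-in only", {
  sim <- suppressWarnings(generate_panel(generator_config(n_areas = 9L,
                                                          n_times = 4L,
                                                          seed = 3)))
  E <- compute_expected(sim$panel)
  no_burn <- run_mcmc(sim$panel, E, sim$graph, recovery_prior(),
                      mcmc_config(n_chains = 1L, n_iter = 600L,
                                  n_burnin = 0L, seed = 5L))
  with_burn <- run_mcmc(sim$panel, E, sim$graph, recovery_prior(),
                        mcmc_config(n_chains = 1L, n_iter = 600L,
                                    n_burnin = 400L, seed = 5L))
  sds0 <- c(s_v = 0.3, s_xi = 0.2, s_nu = 0.5, s_alpha = 0.05,
            s_rho = 0.6, s_r = 0.3, s_uv = 0.3, s_nv = 0.2, s_nx = 0.2,
            s_xa = 0.3)
  expect_equal(no_burn$proposal_sds[[1]], sds0)
  expect_false(isTRUE(all.equal(with_burn$proposal_sds[[1]], sds0)))
})

test_that("a no-signal panel concentrates the intercept at zero", {
  # counts exactly at the expected level in every cell, large denominators
  N <- matrix(20000L, 12, 4)
  p <- tiny_panel(matrix(3000L, 12, 4), N)  # constant rate 0.15
  E <- compute_expected(p)
  g <- grid_graph(3, 4)
  fit <- run_mcmc(p, E, g, recovery_prior(),
                  mcmc_config(n_chains = 2L, n_iter = 2500L,
                              n_burnin = 500L, seed = 2L))
  s <- summary(fit, pars = "alpha")
  expect_lt(abs(s$median), 0.05)
  expect_true(s$lower95 < 0 && 0 < s$upper95)
})

test_that("the likelihood profile in r peaks near the generating value", {
  # all effects at truth, only r unknown: 1-D profile oracle
  cfg <- generator_config(n_areas = 48L, n_times = 8L, nr = 6L, nc = 8L,
                          tau_u = 1e8, tau_v = 1e8, tau_xi = 1e8,
                          tau_nu = 1e8, rho = 0, r = 0.3,
                          denom_meanlog = log(3000), seed = 4)
  sim <- suppressWarnings(generate_panel(cfg))
  E <- compute_expected(sim$panel)
  st <- sim$truth
  st$alpha <- sim$alpha_offset
  grid <- seq(0.1, 0.7, by = 0.01)
  ll <- vapply(grid, function(r) {
    st$r <- r
    panel_log_likelihood(sim$panel, E, st)
  }, numeric(1))
  expect_lt(abs(grid[which.max(ll)] - 0.3), 0.1)
})

test_that("an all-missing panel runs and samples precisions from the prior", {
  p <- empty_panel(4, 4)
  pr <- prior_config(gamma_shape = 2, gamma_rate = 1, shape_r = 2, rate_r = 1)
  fit <- run_mcmc(p, matrix(1, 4, 4), grid_graph(2, 2), pr,
                  mcmc_config(n_chains = 1L, n_iter = 21000L,
                              n_burnin = 1000L, thin = 10L, seed = 3L))
  m <- fit$chains[[1]]
  # Gamma(2, 1) prior: mean 2, variance 2 (loose Monte-Carlo bands)
  expect_equal(mean(m[, "tau_v"]), 2, tolerance = 0.15)
  expect_equal(mean(m[, "tau_nu"]), 2, tolerance = 0.15)
  expect_equal(mean(m[, "rho"]), 0, tolerance = 0.1)
})

test_that("dimension mismatches and bad expected counts are rejected", {
  sim <- suppressWarnings(generate_panel(generator_config(n_areas = 9L,
                                                          n_times = 4L,
                                                          seed = 3)))
  E <- compute_expected(sim$panel)
  expect_error(run_mcmc(sim$panel, E, grid_graph(2, 2), recovery_prior(),
                        mcmc_config(n_iter = 50L, n_burnin = 10L)),
               "areas")
  Ebad <- E; Ebad[1, 1] <- -1
  expect_error(run_mcmc(sim$panel, Ebad, sim$graph, recovery_prior(),
                        mcmc_config(n_iter = 50L, n_burnin = 10L)),
               "positive")
})
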