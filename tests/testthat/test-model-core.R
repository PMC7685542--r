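test_that("relative risk is the exponentiated sum of effects", {
  st <- model_state(alpha = 0, u = c(0, 0), v = c(0, 0), xi = c(0, 0),
                    nu = matrix(0, 2, 2), rho = 0, tau_u = 1, tau_v = 1,
                    tau_xi = 1, tau_nu = 1, r = 0.5)
  expect_equal(relative_risk(st, 1, 1), 1)

  st$alpha <- log(2)
  expect_equal(relative_risk(st, 2, 2), 2)

  st2 <- model_state(alpha = 0.1, u = c(0.2, 0), v = c(-0.1, 0),
                     xi = c(0.3, 0), nu = matrix(c(-0.2, 0, 0, 0), 2, 2),
                     rho = 0, tau_u = 1, tau_v = 1, tau_xi = 1, tau_nu = 1,
                     r = 0.5)
  expect_equal(relative_risk(st2, 1, 1), exp(0.1 + 0.2 - 0.1 + 0.3 - 0.2))
  expect_equal(risk_matrix(st2)[1, 1], relative_risk(st2, 1, 1))
  expect_error(relative_risk(st2, 3, 1), "out of range")
})

test_that("negative binomial pmf normalises and has the stated moments", {
  # brute-force normalisation
  expect_equal(sum(exp(nb_log_pmf(0:500, mu = 3, r = 0.5))), 1,
               tolerance = 1e-10)

  # Poisson limit value: log P(0) at mu = 1 is -1
  expect_equal(nb_log_pmf(0L, 1, 1e-10), -1, tolerance = 1e-6)

  # moment oracle
  set.seed(42)
  y <- rnbinom(1e5, size = 1 / 0.4, mu = 5)
  expect_equal(mean(y), 5, tolerance = 0.02)
  expect_equal(var(y), 5 * (1 + 0.4 * 5), tolerance = 0.05)

  expect_error(nb_log_pmf(-1L, 1, 0.5), "non-negative")
  expect_error(nb_log_pmf(1L, -1, 0.5), "positive")
})

test_that("negative binomial matches Poisson in the small-r limit", {
  for (mu in c(0.5, 5, 50)) {
    expect_equal(nb_log_pmf(0:50, mu, r = 1e-8),
                 dpois(0:50, mu, log = TRUE), tolerance = 1e-5)
  }
})

test_that("panel log likelihood sums term-by-term over observed cells", {
  st <- model_state(alpha = 0.1, u = c(0.2, -0.2), v = c(0, 0.1),
                    xi = c(-0.1, 0.05), nu = matrix(0.03 * (1:4), 2, 2),
                    rho = 0, tau_u = 1, tau_v = 1, tau_xi = 1, tau_nu = 1,
                    r = 0.3)
  p <- tiny_panel(matrix(c(10L, 25L, 7L, 40L), 2, 2),
                  matrix(c(100L, 200L, 80L, 300L), 2, 2))
  E <- compute_expected(p)
  ref <- 0
  for (i in 1:2) for (t in 1:2) {
    ref <- ref + unname(nb_log_pmf(p$cases[i, t],
                                   E[i, t] * relative_risk(st, i, t), st$r))
  }
  expect_equal(panel_log_likelihood(p, E, st), ref)

  # a single-cell panel replicates nb_log_pmf (constant risk state)
  st1 <- model_state(alpha = 0.25, u = 0, v = 0, xi = c(0, 0),
                     nu = matrix(0, 1, 2), rho = 0, tau_u = 1, tau_v = 1,
                     tau_xi = 1, tau_nu = 1, r = 0.2)
  p1 <- suppressWarnings(count_panel(matrix(c(12L, NA), 1, 2),
                                     matrix(c(90L, NA), 1, 2)))
  E1 <- compute_expected(p1)
  expect_equal(panel_log_likelihood(p1, E1, st1),
               unname(nb_log_pmf(12L, E1[1, 1] * exp(0.25), 0.2)))

  # all-missing panel contributes zero
  pe <- empty_panel(2, 2)
  expect_equal(panel_log_likelihood(pe, matrix(1, 2, 2), st), 0)
})

test_that("panel log likelihood is additive over observed-cell partitions", {
  set.seed(1)
  p <- tiny_panel(matrix(rpois(12, 30), 3, 4), matrix(200L, 3, 4))
  E <- compute_expected(p)
  st <- initialize_state(p, E, grid_graph(1, 3), seed = 4)
  mask1 <- matrix(rep(c(TRUE, FALSE), 6), 3, 4)
  p1 <- p; p1$cases[!mask1] <- NA; p1$denominators[!mask1] <- NA; p1$obs <- mask1
  p2 <- p; p2$cases[mask1] <- NA; p2$denominators[mask1] <- NA; p2$obs <- !mask1
  expect_equal(panel_log_likelihood(p1, E, st) + panel_log_likelihood(p2, E, st),
               panel_log_likelihood(p, E, st))
})

test_that("internal standardisation yields expected counts with matched totals", {
  # uniform-rate panel: E = rate * N exactly
  N <- matrix(c(100L, 300L, 250L, 150L), 2, 2)
  p <- tiny_panel(matrix(as.integer(0.1 * N), 2, 2), N)
  E <- compute_expected(p)
  expect_equal(E, 0.1 * N, ignore_attr = TRUE)

  # totals match by construction
  set.seed(2)
  p2 <- tiny_panel(matrix(rpois(6, 40), 2, 3), matrix(250L, 2, 3))
  E2 <- compute_expected(p2)
  expect_equal(sum(E2), sum(p2$cases))

  # two-cell hand computation
  p3 <- tiny_panel(matrix(c(10L, 30L), 2, 1), matrix(c(100L, 100L), 2, 1))
  expect_equal(compute_expected(p3), matrix(c(20, 20), 2, 1),
               ignore_attr = TRUE)

  # invariant to proportional rescaling of cases and denominators
  p4 <- tiny_panel(2L * matrix(c(10L, 30L), 2, 1), 2L * matrix(c(100L, 100L), 2, 1))
  expect_equal(attr(compute_expected(p4), "crude_rate"),
               attr(compute_expected(p3), "crude_rate"))

  expect_error(compute_expected(empty_panel(2, 2)), "no observed cells")
})

test_that("stationary AR(1) density has the stated closed forms", {
  # independence limit
  xi <- c(0.4, -1, 0.2, 0.9)
  expect_equal(ar1_log_density(xi, 0, 2.5),
               sum(dnorm(xi, 0, sqrt(1 / 2.5), log = TRUE)))

  # T = 2: dense stationary covariance oracle
  rho <- 0.65; tau <- 1.8
  x <- c(0.7, -0.4)
  S <- matrix(c(1, rho, rho, 1) / (tau * (1 - rho^2)), 2, 2)
  ref <- -log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
    0.5 * drop(t(x) %*% solve(S) %*% x)
  expect_equal(ar1_log_density(x, rho, tau), ref, tolerance = 1e-10)

  # reversibility: density invariant under time reversal
  set.seed(3)
  z <- rnorm(6)
  for (r in c(-0.8, 0.3, 0.9)) {
    expect_equal(ar1_log_density(rev(z), r, 1.2), ar1_log_density(z, r, 1.2))
  }

  expect_error(ar1_log_density(xi, 1, 1), "rho")
  expect_error(ar1_log_density(0.5, 0.2, 1), "two time points")
})

test_that("modelled prevalence is E*pi/N with a warning above 1", {
  p <- tiny_panel(matrix(c(10L, 30L), 2, 1), matrix(c(100L, 100L), 2, 1))
  E <- compute_expected(p)
  st <- model_state(alpha = 0, u = c(0, 0), v = c(0, 0), xi = 0,
                    nu = matrix(0, 2, 1), rho = 0, tau_u = 1, tau_v = 1,
                    tau_xi = 1, tau_nu = 1, r = 0.1)
  # pi = 1: prevalence equals the overall crude rate
  expect_equal(prevalence(p, E, st, 1, 1), 0.2)

  # E = 20, N = 100, pi = 1.5 -> 0.30
  st$alpha <- log(1.5)
  expect_equal(prevalence(p, E, st, 1, 1), 0.30)

  st$alpha <- log(6)
  expect_warning(prevalence(p, E, st, 1, 1), "exceeds 1")
})

test_that("panel construction validates and orders areas lexicographically", {
  p <- count_panel(matrix(1:4, 2, 2), matrix(10L, 2, 2),
                   area_ids = c("b", "a"))
  expect_equal(p$area_ids, c("a", "b"))
  expect_equal(p$cases[, 1], c(2L, 1L), ignore_attr = TRUE)

  expect_warning(count_panel(matrix(c(20L, 1L), 1, 2), matrix(10L, 1, 2)),
                 "more cases than new clients")
  expect_error(count_panel(matrix(1L, 1, 1), matrix(0L, 1, 1)),
               "positive")
  expect_error(count_panel(matrix(-1L, 1, 1), matrix(5L, 1, 1)),
               "negative")
})

test_that("panel CSV round-trips including missing cells and zones", {
  sim <- suppressWarnings(generate_panel(generator_config(
    n_areas = 12L, n_times = 4L, missing_rate = 0.15, seed = 8)))
  f <- tempfile(fileext = ".csv")
  write_count_panel(sim$panel, f)
  p2 <- suppressWarnings(read_count_panel(f))
  expect_equal(p2$cases, sim$panel$cases)
  expect_equal(p2$denominators, sim$panel$denominators)
  expect_equal(p2$zone, sim$panel$zone)
  expect_equal(p2$calendar, sim$panel$calendar)

  # renamed headers via col_map
  df <- utils::read.csv(f)
  names(df)[names(df) == "cases"] <- "anaemia_cases"
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  p3 <- suppressWarnings(read_count_panel(f2, col_map = c(cases = "anaemia_cases")))
  expect_equal(p3$cases, sim$panel$cases)
})
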