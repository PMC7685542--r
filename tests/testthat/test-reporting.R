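test_that("WHO severity thresholds classify exactly at the boundaries", {
  expect_equal(as.character(classify_prevalence(0.049)), "Normal")
  expect_equal(as.character(classify_prevalence(0.05)), "Mild")
  expect_equal(as.character(classify_prevalence(0.199)), "Mild")
  expect_equal(as.character(classify_prevalence(0.20)), "Moderate")
  expect_equal(as.character(classify_prevalence(0.399)), "Moderate")
  expect_equal(as.character(classify_prevalence(0.40)), "Severe")
  expect_equal(as.character(classify_prevalence(0)), "Normal")
  expect_equal(as.character(classify_prevalence(1)), "Severe")
  expect_error(classify_prevalence(-0.01), "\\[0, 1\\]")
  expect_error(classify_prevalence(1.2), "\\[0, 1\\]")
})

test_that("severity classification is monotone in prevalence", {
  set.seed(5)
  p <- sort(runif(200))
  cl <- classify_prevalence(p)
  expect_true(all(diff(as.integer(cl)) >= 0))
})

test_that("severity proportions match constructed fixtures", {
  # 3 of 10 areas engineered above 0.40, pi = 1 draws
  targets <- c(0.02, 0.10, 0.15, 0.25, 0.30, 0.35, 0.45, 0.50, 0.60, 0.03)
  panel <- generate_severity_fixture(targets, N = 1000L)
  E <- compute_expected(panel)
  crude <- attr(E, "crude_rate")
  # encode each area's engineered risk in the structured effect
  ch <- const_chains(panel$n_areas, panel$n_times, alpha = 0,
                     u = log(targets / crude))
  tab <- severity_proportions(ch, panel, E)
  expect_equal(tab$class, factor(severity_levels(),
                                 levels = severity_levels(), ordered = TRUE))
  expect_equal(tab$median[tab$class == "Severe"], 30)
  expect_equal(tab$median[tab$class == "Normal"], 20)
  expect_equal(sum(tab$median), 100)

  # all areas pushed to severe: crude rate 0.25 scaled by pi = 2
  panel2 <- generate_severity_fixture(rep(0.25, 6), N = 1000L)
  E2 <- compute_expected(panel2)
  ch2 <- const_chains(6, panel2$n_times, alpha = log(2))
  tab2 <- severity_proportions(ch2, panel2, E2)
  expect_equal(tab2$median[tab2$class == "Severe"], 100)
  expect_equal(sum(tab2$median[tab2$class != "Severe"]), 0)

  # single-draw chains: reported medians are per-draw values, summing to 100
  ch1 <- const_chains(panel$n_areas, panel$n_times, alpha = 0.1, n_draws = 1L,
                      n_chains = 1L)
  tab3 <- severity_proportions(ch1, panel, E)
  expect_equal(sum(tab3$median), 100)
})

test_that("severity-proportion intervals stabilise as draws accumulate", {
  targets <- seq(0.03, 0.48, length.out = 10)
  panel <- generate_severity_fixture(targets, N = 1000L)
  E <- compute_expected(panel)
  u_fix <- log(targets / attr(E, "crude_rate"))
  width <- function(n_draws) {
    ch <- const_chains(panel$n_areas, panel$n_times, alpha = 0, u = u_fix,
                       n_draws = n_draws, n_chains = 1L, jitter = 0.08)
    tab <- severity_proportions(ch, panel, E, max_draws = n_draws)
    sum(tab$upper95 - tab$lower95)
  }
  w_small <- width(40)
  w_big <- width(4000)
  ref <- width(20000)
  expect_lt(abs(w_big - ref), abs(w_small - ref) + 5)
  expect_gt(w_big, 0)
})

test_that("zone stratification reproduces per-zone engineered severities", {
  # two zones with disjoint severity: Coast all severe, Lake all normal
  targets <- c(0.45, 0.5, 0.55, 0.01, 0.02, 0.03)
  zone <- c("Coast", "Coast", "Coast", "Lake", "Lake", "Lake")
  panel <- generate_severity_fixture(targets, N = 1000L, zone = zone)
  E <- compute_expected(panel)
  ch <- const_chains(6, panel$n_times, alpha = 0,
                     u = log(targets / attr(E, "crude_rate")))
  tab <- stratify_by_zone(ch, panel, E)
  coast <- tab[tab$zone == "Coast", ]
  lake <- tab[tab$zone == "Lake", ]
  expect_equal(coast$median[coast$class == "Severe"], 100)
  expect_equal(lake$median[lake$class == "Normal"], 100)
  # per-zone proportions are a partition
  expect_equal(sum(coast$median), 100)
  expect_equal(sum(lake$median), 100)

  # a single-zone panel reproduces the unstratified result
  panel1 <- generate_severity_fixture(targets, N = 1000L,
                                      zone = rep("Seasonal", 6))
  E1 <- compute_expected(panel1)
  t_all <- severity_proportions(ch, panel1, E1)
  t_str <- stratify_by_zone(ch, panel1, E1)
  expect_equal(t_str$median, t_all$median)

  # missing zones produce an error naming the offending areas
  panelNA <- generate_severity_fixture(targets, N = 1000L,
                                       zone = c(zone[1:5], NA))
  expect_error(stratify_by_zone(ch, panelNA, compute_expected(panelNA)),
               "A006")
})

test_that("annual totals reduce to observed sums when pi is 1", {
  sim <- suppressWarnings(generate_panel(generator_config(n_areas = 9L,
                                                          n_times = 8L,
                                                          seed = 4)))
  panel <- sim$panel
  E <- compute_expected(panel)
  ch <- const_chains(panel$n_areas, panel$n_times, alpha = 0)
  tot <- annual_case_totals(ch, panel, E)
  expect_equal(tot$year, c(2016L, 2017L))
  for (k in seq_len(nrow(tot))) {
    cols <- which(panel$calendar$year == tot$year[k])
    expect_equal(tot$observed[k], sum(panel$cases[, cols]))
    expect_equal(tot$estimated[k], sum(E[, cols]))  # pi = 1 draw
  }
})

test_that("percent change reproduces the published arithmetic", {
  expect_equal(percent_change(155539, 171682), 10.4)
  expect_equal(percent_change(155539, 263305), 69.3)
  expect_equal(percent_change(155539, 295642), 90.1)
  expect_equal(percent_change(123, 123), 0)
  expect_error(percent_change(0, 10), "positive")
  expect_error(percent_change(-5, 10), "positive")
})

test_that("quarterly shares reproduce the published arithmetic", {
  expect_equal(unname(quarterly_shares(c(213350, 222250, 215273, 235295))),
               c(24.1, 25.1, 24.3, 26.6))
  expect_equal(unname(quarterly_shares(c(1, 1, 1, 1))), rep(25, 4))
  expect_equal(unname(quarterly_shares(c(100, 0, 0, 0))), c(100, 0, 0, 0))
  expect_error(quarterly_shares(c(0, 0, 0, 0)), "all-zero")
  expect_error(quarterly_shares(c(-1, 2, 3, 4)), "non-negative")
})

test_that("prevalence summaries round-trip losslessly and class the median", {
  sim <- suppressWarnings(generate_panel(generator_config(n_areas = 9L,
                                                          n_times = 4L,
                                                          seed = 10)))
  panel <- sim$panel
  E <- compute_expected(panel)
  ch <- const_chains(9, 4, alpha = 0.1, jitter = 0.05)
  ps <- prevalence_summary(ch, panel, E, level = "year")
  expect_true(all(ps$lower95 <= ps$median & ps$median <= ps$upper95))
  expect_equal(as.character(ps$class),
               as.character(classify_prevalence(pmin(ps$median, 1))))

  f <- tempfile(fileext = ".csv")
  write_prevalence_summary(ps, f)
  back <- read_prevalence_summary(f)
  expect_equal(back$median, ps$median, tolerance = 1e-15)
  expect_equal(back$lower95, ps$lower95, tolerance = 1e-15)
  expect_equal(as.character(back$class), as.character(ps$class))

  psq <- prevalence_summary(ch, panel, E, level = "quarter")
  expect_equal(nrow(psq), 9L * 4L)
  expect_false(any(is.na(psq$quarter)))
})

test_that("reported national totals are internally consistent", {
  kt <- kenya_reported_totals()
  expect_equal(sum(kt$annual$cases), 886168)
  expect_equal(sum(kt$quarterly$cases), 886168)
  expect_equal(kt$annual$year, 2016:2019)
})
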