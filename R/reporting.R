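#' WHO anaemia severity classes
#'
#' Classifies a prevalence proportion by the WHO public-health significance
#' thresholds: below 5% Normal, 5 to below 20% Mild, 20 to below 40%
#' Moderate, 40% and above Severe.
#'
#' @param p numeric vector of proportions in `[0, 1]`.
#' @return ordered factor with levels Normal < Mild < Moderate < Severe.
#' @examples
#' classify_prevalence(c(0.049, 0.05, 0.199, 0.20, 0.40))
#' @export
classify_prevalence <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  cut(p, breaks = c(-Inf, 0.05, 0.20, 0.40, Inf),
      labels = severity_levels(), right = FALSE, ordered_result = TRUE)
}

#' @rdname classify_prevalence
#' @export
severity_levels <- function() c("Normal", "Mild", "Moderate", "Severe")

# evenly thin a draws matrix to at most max_draws rows
.subsample_draws <- function(m, max_draws) {
  if (is.null(max_draws) || nrow(m) <= max_draws) return(m)
  m[unique(round(seq(1L, nrow(m), length.out = max_draws))), , drop = FALSE]
}

# Per-draw area-level prevalence pooled over the time indices `cols`:
# (sum_t E * pi) / (sum_t N) over cells with a denominator. Returns a
# draws x areas matrix.
.area_prevalence_draws <- function(m, idx, panel, E, cols) {
  I <- panel$n_areas
  N <- panel$denominators[, cols, drop = FALSE]
  Ec <- E[, cols, drop = FALSE]
  ok <- !is.na(N) & !is.na(Ec)
  if (any(rowSums(ok) == 0L)) {
    stop("area(s) without any usable cell in the requested period: ",
         paste(panel$area_ids[rowSums(ok) == 0L], collapse = ", "), call. = FALSE)
  }
  denom <- rowSums(N * ok, na.rm = TRUE)
  out <- matrix(NA_real_, nrow(m), I)
  for (d in seq_len(nrow(m))) {
    nu <- matrix(m[d, idx$nu], I, panel$n_times)[, cols, drop = FALSE]
    lp <- m[d, idx$alpha] + (m[d, idx$u] + m[d, idx$v]) +
      matrix(m[d, idx$xi[cols]], I, length(cols), byrow = TRUE) + nu
    numer <- rowSums(Ec * exp(lp) * ok, na.rm = TRUE)
    out[d, ] <- numer / denom
  }
  out
}

.resolve_cols <- function(panel, year) {
  if (is.null(year)) return(seq_len(panel$n_times))
  cols <- which(panel$calendar$year == year)
  if (!length(cols)) stop("year ", year, " not in the panel calendar", call. = FALSE)
  cols
}

#' Posterior proportions of areas per WHO severity class
#'
#' For every posterior draw, each area's prevalence (pooled over the
#' requested year, or the full period) is classified by
#' [classify_prevalence()] and the fraction of areas in each class is
#' recorded; the table reports the median and central 95% uncertainty
#' interval of those fractions over draws, as percentages. Within every
#' single draw the four proportions sum to 100.
#'
#' @param chains a `posterior_chains` fit.
#' @param panel the fitted [count_panel()].
#' @param E expected counts used in the fit.
#' @param year calendar year to pool over (`NULL` = full period).
#' @param areas optional integer subset of areas (used by zone
#'   stratification).
#' @param max_draws cap on posterior draws used (evenly thinned).
#' @return data frame with columns `class`, `median`, `lower95`, `upper95`
#'   (percent scale).
#' @export
severity_proportions <- function(chains, panel, E, year = NULL, areas = NULL,
                                 max_draws = 2000L) {
  stopifnot(inherits(chains, "posterior_chains"))
  m <- .subsample_draws(as.matrix(chains), max_draws)
  if (nrow(m) < 1L) stop("no posterior draws", call. = FALSE)
  cols <- .resolve_cols(panel, year)
  prev <- .area_prevalence_draws(m, chains$idx, panel, E, cols)
  if (!is.null(areas)) prev <- prev[, areas, drop = FALSE]
  lv <- severity_levels()
  prop <- matrix(NA_real_, nrow(prev), 4L, dimnames = list(NULL, lv))
  for (d in seq_len(nrow(prev))) {
    cl <- classify_prevalence(pmin(prev[d, ], 1))
    prop[d, ] <- 100 * as.numeric(table(cl)) / length(cl)
  }
  qs <- apply(prop, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975))
  data.frame(class = factor(lv, levels = lv, ordered = TRUE),
             median = unname(qs[1L, ]), lower95 = unname(qs[2L, ]),
             upper95 = unname(qs[3L, ]), row.names = NULL)
}

#' Severity-class proportions stratified by malaria endemicity zone
#'
#' [severity_proportions()] computed within each endemicity zone over the
#' full study period, mirroring the zone-by-class reporting table.
#'
#' @inheritParams severity_proportions
#' @return data frame with columns `zone`, `class`, `median`, `lower95`,
#'   `upper95`.
#' @export
stratify_by_zone <- function(chains, panel, E, max_draws = 2000L) {
  missing_zone <- is.na(panel$zone)
  if (any(missing_zone)) {
    stop("zone stratification requested but these areas lack a zone label: ",
         paste(panel$area_ids[missing_zone], collapse = ", "), call. = FALSE)
  }
  zones <- intersect(zone_levels(), unique(panel$zone))
  out <- lapply(zones, function(z) {
    tab <- severity_proportions(chains, panel, E, year = NULL,
                                areas = which(panel$zone == z),
                                max_draws = max_draws)
    cbind(zone = z, tab)
  })
  do.call(rbind, out)
}

#' Annual case totals, estimated and observed
#'
#' Observed totals are plain sums of reported cases per calendar year.
#' Estimated totals are, per posterior draw, the sum of `E * pi` over the
#' year's observed cells, summarised by median and 95% uncertainty
#' interval.
#'
#' @inheritParams severity_proportions
#' @return data frame with one row per year: `year`, `observed`,
#'   `estimated`, `lower95`, `upper95`.
#' @export
annual_case_totals <- function(chains, panel, E, max_draws = 2000L) {
  stopifnot(inherits(chains, "posterior_chains"))
  m <- .subsample_draws(as.matrix(chains), max_draws)
  idx <- chains$idx
  I <- panel$n_areas
  years <- sort(unique(panel$calendar$year))
  res <- lapply(years, function(yr) {
    cols <- which(panel$calendar$year == yr)
    ok <- panel$obs[, cols, drop = FALSE]
    obs_tot <- sum(panel$cases[, cols, drop = FALSE][ok])
    tots <- numeric(nrow(m))
    Ec <- E[, cols, drop = FALSE]
    for (d in seq_len(nrow(m))) {
      nu <- matrix(m[d, idx$nu], I, panel$n_times)[, cols, drop = FALSE]
      lp <- m[d, idx$alpha] + (m[d, idx$u] + m[d, idx$v]) +
        matrix(m[d, idx$xi[cols]], I, length(cols), byrow = TRUE) + nu
      tots[d] <- sum((Ec * exp(lp))[ok])
    }
    q <- stats::quantile(tots, c(0.5, 0.025, 0.975))
    data.frame(year = yr, observed = obs_tot, estimated = unname(q[1L]),
               lower95 = unname(q[2L]), upper95 = unname(q[3L]))
  })
  do.call(rbind, res)
}

#' Percent change between two counts
#'
#' `100 * (new - base) / base`, reported to one decimal place
#' (round-half-even, R's default rounding).
#'
#' @param base baseline count (> 0).
#' @param new comparison count.
#' @return percentage, one decimal place.
#' @examples
#' percent_change(155539, 295642)  # 90.1
#' @export
percent_change <- function(base, new) {
  if (any(!is.finite(base)) || any(base <= 0)) {
    stop("`base` must be a positive count", call. = FALSE)
  }
  round(100 * (new - base) / base, 1L)
}

#' Quarter-of-year shares of a total
#'
#' Each quarter's percentage of the overall total, to one decimal place;
#' shares sum to 100 up to rounding.
#'
#' @param totals numeric vector of per-quarter-of-year counts (typically
#'   length 4, named or in Q1..Q4 order).
#' @return numeric vector of percentages.
#' @examples
#' quarterly_shares(c(213350, 222250, 215273, 235295))
#' @export
quarterly_shares <- function(totals) {
  if (any(!is.finite(totals)) || any(totals < 0)) {
    stop("quarterly totals must be non-negative", call. = FALSE)
  }
  if (sum(totals) <= 0) stop("all-zero quarterly totals", call. = FALSE)
  out <- round(100 * totals / sum(totals), 1L)
  if (is.null(names(out)) && length(out) == 4L) {
    names(out) <- paste0("Q", 1:4)
  }
  out
}

#' Posterior prevalence summary per area
#'
#' Median and 95% uncertainty interval of modelled prevalence per area and
#' quarter (`level = "quarter"`) or pooled per area and year
#' (`level = "year"`), with the WHO severity class of the posterior
#' median. Year-level prevalence pools counts, `sum(E * pi) / sum(N)`,
#' weighting quarters by client volume.
#'
#' @inheritParams severity_proportions
#' @param level `"quarter"` or `"year"`.
#' @return data frame of class `prevalence_summary` with columns
#'   `area_id`, `zone`, `year`, `quarter` (`NA` at year level), `median`,
#'   `lower95`, `upper95`, `class`.
#' @export
prevalence_summary <- function(chains, panel, E, level = c("year", "quarter"),
                               max_draws = 2000L) {
  level <- match.arg(level)
  stopifnot(inherits(chains, "posterior_chains"))
  m <- .subsample_draws(as.matrix(chains), max_draws)
  blocks <- if (level == "year") {
    yrs <- sort(unique(panel$calendar$year))
    lapply(yrs, function(yr) list(year = yr, quarter = NA_integer_,
                                  cols = which(panel$calendar$year == yr)))
  } else {
    lapply(seq_len(panel$n_times), function(t) {
      list(year = panel$calendar$year[t], quarter = panel$calendar$quarter[t],
           cols = t)
    })
  }
  out <- lapply(blocks, function(b) {
    prev <- .area_prevalence_draws(m, chains$idx, panel, E, b$cols)
    qs <- apply(prev, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975))
    med <- qs[1L, ]
    capped <- pmin(med, 1)
    if (any(med > 1)) {
      warning("median prevalence exceeds 1 for ", sum(med > 1),
              " area-period(s); classified at 1", call. = FALSE)
    }
    data.frame(area_id = panel$area_ids, zone = panel$zone,
               year = b$year, quarter = b$quarter,
               median = med, lower95 = qs[2L, ], upper95 = qs[3L, ],
               class = classify_prevalence(capped),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("prevalence_summary", class(res))
  res
}

#' Read / write a prevalence summary CSV
#'
#' The writer emits full double precision (so a read round-trip is
#' lossless); presentation rounding is left to the final report tables.
#'
#' @param x a [prevalence_summary()] data frame.
#' @param path CSV path.
#' @export
write_prevalence_summary <- function(x, path) {
  y <- as.data.frame(x)
  for (cc in c("median", "lower95", "upper95")) {
    y[[cc]] <- formatC(y[[cc]], digits = 17, format = "g")
  }
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prevalence_summary
#' @export
read_prevalence_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$class <- factor(df$class, levels = severity_levels(), ordered = TRUE)
  class(df) <- c("prevalence_summary", class(df))
  df
}

#' Reported national counts used for the arithmetic checks
#'
#' The published annual and quarter-of-year reported case totals for Kenya
#' 2016-2019, shipped as a small CSV in `inst/extdata`. These are inputs to
#' the percent-change and share computations, not model output.
#'
#' @return list with data frames `annual` (`year`, `cases`) and
#'   `quarterly` (`quarter`, `cases`).
#' @export
kenya_reported_totals <- function() {
  path <- system.file("extdata", "kenya_reported_totals.csv",
                      package = "anaemap", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(
    annual = df[df$period_type == "year", c("period", "cases")] |>
      (\(d) data.frame(year = as.integer(d$period), cases = d$cases))(),
    quarterly = df[df$period_type == "quarter", c("period", "cases")] |>
      (\(d) data.frame(quarter = d$period, cases = d$cases))()
  )
}
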