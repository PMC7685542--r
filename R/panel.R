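#' Quarterly area-level count panel
#'
#' The central data container: an areas x quarters panel of reported case
#' counts (`cases`) with matching denominators (`denominators`, the number
#' of new antenatal-care clients, used to offset facility-utilisation
#' differences), an optional malaria-endemicity zone label per area, and a
#' calendar mapping each time index to a (year, quarter-of-year) pair.
#'
#' A cell is *observed* when both its count and its denominator are present;
#' otherwise it is *missing* and contributes nothing to the likelihood.
#' Routine surveillance data may report more cases than new clients in a
#' cell; this is retained but flagged with a data-quality warning.
#'
#' @param cases integer matrix (areas x times) of reported counts; `NA`
#'   marks missing cells.
#' @param denominators positive integer matrix, same shape, of new-client
#'   counts; `NA` marks missing cells.
#' @param area_ids character vector of area identifiers; the panel is
#'   stored in lexicographic `area_ids` order.
#' @param calendar data frame with columns `year` and `quarter` (1-4), one
#'   row per time index; defaults to consecutive quarters starting 2016 Q1.
#' @param zone optional per-area endemicity label among Coast, Highland,
#'   Lake, Low risk, Seasonal (or `NA`).
#' @return An object of class `count_panel`.
#' @export
count_panel <- function(cases, denominators, area_ids = NULL, calendar = NULL,
                        zone = NULL) {
  cases <- as.matrix(cases)
  denominators <- as.matrix(denominators)
  if (!all(dim(cases) == dim(denominators))) {
    stop("`cases` and `denominators` must have identical dimensions", call. = FALSE)
  }
  I <- nrow(cases); T <- ncol(cases)
  if (I < 1L || T < 1L) stop("panel must have at least one area and one quarter", call. = FALSE)
  if (is.null(area_ids)) area_ids <- sprintf("A%03d", seq_len(I))
  area_ids <- as.character(area_ids)
  if (length(area_ids) != I) stop("`area_ids` length must equal nrow(cases)", call. = FALSE)
  if (anyDuplicated(area_ids)) stop("duplicate area ids", call. = FALSE)

  ord <- order(area_ids)
  cases <- cases[ord, , drop = FALSE]
  denominators <- denominators[ord, , drop = FALSE]
  area_ids <- area_ids[ord]
  if (!is.null(zone)) {
    zone <- as.character(zone)[ord]
    bad <- !is.na(zone) & !zone %in% zone_levels()
    if (any(bad)) {
      stop("unknown zone label(s): ", paste(unique(zone[bad]), collapse = ", "), call. = FALSE)
    }
  } else {
    zone <- rep(NA_character_, I)
  }
  if (is.null(calendar)) calendar <- default_calendar(T)
  if (!all(c("year", "quarter") %in% names(calendar)) || nrow(calendar) != T) {
    stop("`calendar` needs columns year, quarter and one row per time index", call. = FALSE)
  }
  if (any(!calendar$quarter %in% 1:4)) stop("calendar quarter must be in 1..4", call. = FALSE)

  obs <- !is.na(cases) & !is.na(denominators)
  # enforce the observed/missing dichotomy
  cases[!obs] <- NA_integer_
  denominators[!obs] <- NA_integer_
  if (any(cases[obs] < 0)) stop("negative case counts", call. = FALSE)
  if (any(denominators[obs] <= 0)) {
    stop("denominators must be positive on observed cells", call. = FALSE)
  }
  n_exceed <- sum(cases[obs] > denominators[obs])
  if (n_exceed > 0L) {
    warning(n_exceed, " observed cell(s) report more cases than new clients ",
            "(kept; routine-data quality flag)", call. = FALSE)
  }
  rownames(cases) <- rownames(denominators) <- area_ids
  structure(
    list(
      n_areas = I, n_times = T,
      cases = cases, denominators = denominators,
      obs = obs, zone = zone, area_ids = area_ids,
      calendar = as.data.frame(calendar)[, c("year", "quarter")]
    ),
    class = "count_panel"
  )
}

#' Recognised malaria endemicity zone labels
#' @return character vector of the five Kenyan transmission strata.
#' @export
zone_levels <- function() c("Coast", "Highland", "Lake", "Low risk", "Seasonal")

default_calendar <- function(T, start_year = 2016L) {
  q <- ((seq_len(T) - 1L) %% 4L) + 1L
  y <- start_year + (seq_len(T) - 1L) %/% 4L
  data.frame(year = y, quarter = q)
}

#' @export
print.count_panel <- function(x, ...) {
  cat("<count_panel> ", x$n_areas, " areas x ", x$n_times, " quarters; ",
      sum(x$obs), " observed cells (", sum(!x$obs), " missing)\n", sep = "")
  yrs <- range(x$calendar$year)
  cat("  calendar ", yrs[1], "Q", x$calendar$quarter[1], " - ", yrs[2], "Q",
      x$calendar$quarter[nrow(x$calendar)], "; zones: ",
      if (all(is.na(x$zone))) "none" else paste(unique(stats::na.omit(x$zone)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read / write the long-format panel CSV
#'
#' Schema: one row per area-quarter with columns `area_id`, `year`,
#' `quarter` (1-4), `cases`, `new_clients` and optionally `zone`. Missing
#' cells may be absent rows or rows with empty counts. `col_map` lets
#' renamed headers be mapped onto the canonical schema.
#'
#' @param path CSV path.
#' @param col_map optional named character vector, e.g.
#'   `c(cases = "anaemia_cases")`, mapping canonical names to file headers.
#' @return [count_panel()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_count_panel <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- c("area_id", "year", "quarter", "cases", "new_clients", "zone")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (col_map[[nm]] %in% names(df)) names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  need <- setdiff(canon[1:5], names(df))
  if (length(need)) stop("panel CSV missing column(s): ", paste(need, collapse = ", "), call. = FALSE)
  df$area_id <- as.character(df$area_id)
  ids <- sort(unique(df$area_id))
  key <- paste(df$year, df$quarter)
  times <- unique(df[order(df$year, df$quarter), c("year", "quarter")])
  tkey <- paste(times$year, times$quarter)
  I <- length(ids); T <- nrow(times)
  cases <- matrix(NA_integer_, I, T)
  denom <- matrix(NA_integer_, I, T)
  ri <- match(df$area_id, ids)
  ci <- match(key, tkey)
  cases[cbind(ri, ci)] <- suppressWarnings(as.integer(df$cases))
  denom[cbind(ri, ci)] <- suppressWarnings(as.integer(df$new_clients))
  zone <- NULL
  if ("zone" %in% names(df)) {
    zmap <- tapply(df$zone, df$area_id, function(z) {
      z <- unique(z[!is.na(z) & nzchar(z)])
      if (length(z) > 1L) stop("conflicting zone labels within an area", call. = FALSE)
      if (length(z)) z else NA_character_
    })
    zone <- as.character(zmap[ids])
  }
  count_panel(cases, denom, area_ids = ids, calendar = times, zone = zone)
}

#' @rdname read_count_panel
#' @param panel a `count_panel`.
#' @export
write_count_panel <- function(panel, path) {
  stopifnot(inherits(panel, "count_panel"))
  rows <- expand.grid(a = seq_len(panel$n_areas), t = seq_len(panel$n_times))
  df <- data.frame(
    area_id = panel$area_ids[rows$a],
    year = panel$calendar$year[rows$t],
    quarter = panel$calendar$quarter[rows$t],
    cases = panel$cases[cbind(rows$a, rows$t)],
    new_clients = panel$denominators[cbind(rows$a, rows$t)],
    zone = panel$zone[rows$a],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$area_id, df$year, df$quarter), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Expected counts by internal standardisation
#'
#' Computes the offset `E[i, t] = N[i, t] * (sum of cases / sum of N)` over
#' observed cells: each cell's denominator scaled by the overall crude rate,
#' so that the expected counts sum exactly to the observed total and the
#' fitted global intercept is centred at zero. A single global rate (rather
#' than per-quarter rates) is used so that temporal signal stays in the
#' temporal random effect.
#'
#' @param panel a [count_panel()].
#' @return numeric matrix of expected counts (`NA` on missing cells) with
#'   attribute `crude_rate`.
#' @export
compute_expected <- function(panel) {
  stopifnot(inherits(panel, "count_panel"))
  obs <- panel$obs
  if (!any(obs)) stop("cannot standardise: no observed cells", call. = FALSE)
  total_cases <- sum(panel$cases[obs])
  total_n <- sum(panel$denominators[obs])
  if (total_cases <= 0) stop("cannot standardise: zero cases in total", call. = FALSE)
  rate <- total_cases / total_n
  E <- panel$denominators * rate
  attr(E, "crude_rate") <- rate
  E
}
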