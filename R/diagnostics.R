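#' Gelman-Rubin potential scale reduction factor
#'
#' Split form by default: each chain is halved and the classic between/
#' within variance ratio is computed on the resulting `2 * n_chains`
#' sequences of length `n`:
#' `Rhat = sqrt(((n - 1) / n * W + B / n) / W)`. Splitting also detects
#' within-chain drift and is slightly more conservative than the classic
#' 1992 statistic, which remains available with `split = FALSE` for
#' comparability.
#'
#' @param chains a `posterior_chains` object, or a list of draws matrices
#'   (equal sizes, one named column per parameter).
#' @param pars optional character vector of parameter names (defaults to
#'   all).
#' @param split halve each chain before computing the statistic?
#' @return named numeric vector of PSRF values (`NA` for parameters with
#'   zero total variance).
#' @export
gelman_rubin <- function(chains, pars = NULL, split = TRUE) {
  mats <- if (inherits(chains, "posterior_chains")) chains$chains else chains
  if (!is.list(mats)) stop("`chains` must hold multiple chains", call. = FALSE)
  mats <- lapply(mats, function(m) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L, dimnames = list(NULL, "par"))
    m
  })
  if (length(mats) < 2L) {
    stop("Gelman-Rubin needs >= 2 chains; rerun with n_chains >= 2", call. = FALSE)
  }
  len <- unique(vapply(mats, nrow, integer(1)))
  if (length(len) != 1L) stop("chains must have equal length", call. = FALSE)
  if (len < 10L) stop("chains must each have length >= 10", call. = FALSE)
  if (is.null(pars)) pars <- colnames(mats[[1L]])

  vapply(pars, function(p) {
    seqs <- lapply(mats, function(m) m[, p])
    if (split) {
      n2 <- floor(len / 2L)
      seqs <- do.call(c, lapply(seqs, function(x) {
        list(x[seq_len(n2)], x[seq.int(len - n2 + 1L, len)])
      }))
    }
    n <- length(seqs[[1L]])
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, stats::var, numeric(1))
    W <- mean(vars)
    B_over_n <- stats::var(means)
    if (!is.finite(W) || W == 0) {
      return(if (isTRUE(B_over_n == 0)) NA_real_ else Inf)
    }
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
}

#' Effective sample size of one parameter's draws
#'
#' Autocorrelation-based estimate using Geyer's initial positive sequence:
#' the integrated autocorrelation time is `-1 + 2 * sum(G_k)` where
#' `G_k = rho(2k) + rho(2k + 1)` summed while positive, and
#' `ESS = n / max(tau, 1/n)`. Constant (zero-variance) chains have no
#' defined ESS and return `NA` with a warning.
#'
#' @param x numeric vector of draws from one chain, length >= 10.
#' @return estimated effective sample size (scalar).
#' @export
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("need at least 10 draws", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant chain: effective sample size undefined", call. = FALSE)
    return(NA_real_)
  }
  lag_max <- min(n - 1L, max(100L, floor(10 * log10(n)) * 10L))
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  tau <- -1
  k <- 0L
  repeat {
    i1 <- 2L * k + 1L  # rho index for lag 2k (acf[1] is lag 0)
    i2 <- 2L * k + 2L
    if (i1 > length(rho)) break
    G <- rho[i1] + (if (i2 <= length(rho)) rho[i2] else 0)
    if (G <= 0) break
    tau <- tau + 2 * G
    k <- k + 1L
  }
  n / max(tau, 1 / n)
}

#' Holdout predictive validation
#'
#' Implements the random-holdout protocol: sample `n_holdout` observed
#' cells uniformly without replacement, mask them (the cell becomes fully
#' missing, so its count cannot inform the fit), refit the model once on
#' the masked panel, and predict each held-out count from the posterior:
#' for every kept draw the cell mean `E * pi` is pushed through the
#' negative binomial to give a predictive count draw, and the posterior
#' predictive median is compared with the held-out observation. Expected
#' counts for the masked fit (and for prediction at held-out cells) use
#' internal standardisation on the masked panel only.
#'
#' @inheritParams run_mcmc
#' @param n_holdout number of observed cells to hold out (paper protocol:
#'   500; desk-scale default 50).
#' @param seed seed for the holdout draw (the fit uses `config$seed`).
#' @return object of class `validation_report`: data frame `cells` (cell
#'   index, ids, observed, predicted median, 95% predictive interval),
#'   `correlation` (Pearson), `spearman`, `n_holdout`, plus the masked
#'   panel and the fitted chains.
#' @export
holdout_validate <- function(panel, E, graph, priors = prior_config(),
                             config = desk_config(), n_holdout = 50L,
                             seed = 1L) {
  stopifnot(inherits(panel, "count_panel"))
  obs_idx <- which(panel$obs)
  n_holdout <- as.integer(n_holdout)
  if (n_holdout >= length(obs_idx)) {
    stop("`n_holdout` (", n_holdout, ") must be smaller than the number of ",
         "observed cells (", length(obs_idx), ")", call. = FALSE)
  }
  if (n_holdout < 2L) stop("need at least 2 held-out cells", call. = FALSE)
  set.seed(as.integer(seed))
  held <- sort(sample(obs_idx, n_holdout))

  masked <- panel
  masked$cases[held] <- NA_integer_
  masked$denominators[held] <- NA_integer_
  masked$obs[held] <- FALSE

  E_fit <- compute_expected(masked)
  rate <- attr(E_fit, "crude_rate")
  fit <- run_mcmc(masked, E_fit, graph, priors, config)

  m <- as.matrix(fit)
  idx <- fit$idx
  I <- panel$n_areas
  ai <- ((held - 1L) %% I) + 1L
  ti <- ((held - 1L) %/% I) + 1L
  E_pred <- panel$denominators[held] * rate

  pred <- matrix(NA_real_, nrow(m), n_holdout)
  for (j in seq_len(n_holdout)) {
    lp <- m[, idx$alpha] + m[, idx$u[ai[j]]] + m[, idx$v[ai[j]]] +
      m[, idx$xi[ti[j]]] + m[, idx$nu[(ti[j] - 1L) * I + ai[j]]]
    mu <- E_pred[j] * exp(lp)
    size <- 1 / m[, idx$r]
    pred[, j] <- stats::rnbinom(nrow(m), size = size, mu = mu)
  }
  med <- apply(pred, 2L, stats::median)
  lo <- apply(pred, 2L, stats::quantile, probs = 0.025)
  hi <- apply(pred, 2L, stats::quantile, probs = 0.975)
  obs_y <- panel$cases[held]

  pearson <- if (stats::sd(med) > 0 && stats::sd(obs_y) > 0) {
    stats::cor(med, obs_y)
  } else NA_real_
  spearman <- if (stats::sd(med) > 0 && stats::sd(obs_y) > 0) {
    stats::cor(med, obs_y, method = "spearman")
  } else NA_real_

  structure(
    list(
      cells = data.frame(
        cell = held, area = ai, time = ti,
        area_id = panel$area_ids[ai],
        year = panel$calendar$year[ti], quarter = panel$calendar$quarter[ti],
        observed = obs_y, predicted = med, lower95 = lo, upper95 = hi,
        stringsAsFactors = FALSE
      ),
      correlation = pearson, spearman = spearman,
      n_holdout = n_holdout, seed = as.integer(seed),
      masked_panel = masked, fit = fit
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$n_holdout, " held-out cells; Pearson r = ",
      round(x$correlation, 3), ", Spearman r = ", round(x$spearman, 3),
      "\n", sep = "")
  invisible(x)
}

#' Write a validation report as CSV
#' @param report a `validation_report`.
#' @param path output CSV path.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  utils::write.csv(report$cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
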