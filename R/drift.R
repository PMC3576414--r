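#' Wright-Fisher drift variance of allele frequency
#'
#' Under the haploid Wright-Fisher model, pure drift generates a variance in
#' allele frequency of `pq/Ne` after one generation; after `t` generations the
#' accumulated variance is
#' \deqn{V(t) = p q \left(1 - e^{-t/N_e}\right),}
#' which is 0 at `t = 0` and approaches the fixation variance `pq` as
#' `t` grows. For `p = q = 0.5` (the fastest-drifting frequency),
#' `t = 82` generations (the average spacing of the fossil-record samples) and
#' `Ne = 3.3e7`, the variance is 6.21e-7 (s.d. 7.88e-4, i.e. about 0.08%).
#'
#' @param p Allele frequency at the start of the interval (in \[0, 1\]).
#' @param t Elapsed generations (non-negative; vectorised).
#' @param ne Effective population size (positive; default 3.3e7, the value
#'   estimated for *E. coli* in comparable serial-batch conditions).
#'
#' @return Numeric vector of variances.
#' @examples
#' drift_variance(p = 0.5, t = 82)        # 6.21e-7
#' drift_sd(p = 0.5, t = 82)              # 7.88e-4
#' @export
drift_variance <- function(p, t, ne = 3.3e7) {
  check_drift_params(p, t, ne)
  p * (1 - p) * (1 - exp(-t / ne))
}

#' @rdname drift_variance
#' @export
drift_sd <- function(p, t, ne = 3.3e7) {
  sqrt(drift_variance(p, t, ne))
}

check_drift_params <- function(p, t, ne) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("`p` must lie in [0, 1].", call. = FALSE)
  }
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be non-negative.", call. = FALSE)
  if (any(ne <= 0, na.rm = TRUE)) stop("`ne` must be positive.", call. = FALSE)
  invisible(TRUE)
}

#' Probability that drift alone produces an allele-frequency change
#'
#' Normal approximation to the Wright-Fisher binomial: the probability that
#' pure drift moves an allele starting at frequency `p` by at least `|delta|`
#' over `t` generations, using the drift standard deviation from
#' [drift_sd()]. The tail is evaluated in log space, so extreme changes
#' (e.g. a 1% change at `Ne = 3.3e7` over 82 generations, whose probability
#' is below 1e-12) do not silently underflow: the log10 tail probability is
#' always available via the `"log10_p"` attribute.
#'
#' @inheritParams drift_variance
#' @param delta Observed allele-frequency change (sign is ignored).
#' @param tails 2 (default) for a two-sided change of at least `|delta|` in
#'   either direction, 1 for one-sided.
#' @param coverage Optional sequencing depth; when finite, a binomial
#'   sampling-noise term `pq/coverage` is added to the null variance
#'   (default `Inf`: drift only).
#'
#' @return Numeric vector of p-values, with attributes `log10_p` and `flags`
#'   (`"degenerate_null"` where the null s.d. is zero but `delta` is not).
#' @examples
#' drift_change_probability(0.01, p = 0.5, t = 82)  # << 1e-12
#' @export
drift_change_probability <- function(delta, p, t, ne = 3.3e7, tails = 2,
                                     coverage = Inf) {
  if (!tails %in% c(1, 2)) stop("`tails` must be 1 or 2.", call. = FALSE)
  v <- drift_variance(p, t, ne)
  if (is.finite(coverage)) v <- v + p * (1 - p) / coverage
  sd0 <- sqrt(v)
  n <- max(length(delta), length(sd0))
  delta <- rep_len(delta, n)
  sd0 <- rep_len(sd0, n)

  pval <- numeric(n)
  log10p <- numeric(n)
  flags <- character(n)
  degenerate <- sd0 == 0
  zero_delta <- abs(delta) == 0

  # log-space two-sided tail: log(p) = log(tails) + log Phi(-z)
  ok <- !degenerate
  z <- abs(delta[ok]) / sd0[ok]
  logp <- log(tails) + stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  logp <- pmin(logp, 0)
  pval[ok] <- exp(logp)
  log10p[ok] <- logp / log(10)

  pval[degenerate & zero_delta] <- 1
  log10p[degenerate & zero_delta] <- 0
  pval[degenerate & !zero_delta] <- 0
  log10p[degenerate & !zero_delta] <- -Inf
  flags[degenerate & !zero_delta] <- "degenerate_null"

  structure(pval, log10_p = log10p, flags = flags)
}

#' Scan a fossil record for non-drift allele-frequency changes
#'
#' For every mutation and every pair of consecutive time points at which its
#' frequency is defined, tests the observed frequency change against the
#' Wright-Fisher drift null: the change is compared to a normal distribution
#' with variance [drift_variance()] computed from the frequency at the
#' interval start and the interval length in generations. Intervals with a
#' missing frequency at either end are skipped. Multiple testing is corrected
#' across all tests performed in the population (Bonferroni by default); raw
#' p-values are always reported.
#'
#' @param series A [frequency_series()].
#' @param ne Effective population size for the null (default 3.3e7).
#' @param alpha Significance level for the selection flag (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param tails 1 or 2 (default 2).
#' @param coverage_noise If `TRUE`, add the per-interval binomial sequencing
#'   noise `pq/coverage` of the starting sample to the null variance
#'   (default `FALSE`: the pure drift null).
#'
#' @return An object of class `drift_scan`: a list with `results` (tibble with
#'   one row per mutation per tested interval: `mutation_id`, `gen_start`,
#'   `gen_end`, `p_start`, `delta`, `variance`, `sd`, `z`, `p_value`,
#'   `log10_p`, `adjusted_p`, `selection_flag`, `flag`), `skipped` (tibble of
#'   untestable intervals), and the test parameters.
#' @export
classify_trajectory <- function(series, ne = 3.3e7, alpha = 0.05,
                                correction = c("bonferroni", "none"),
                                tails = 2, coverage_noise = FALSE) {
  stopifnot(inherits(series, "frequency_series"))
  correction <- match.arg(correction)

  intervals <- series$counts |>
    dplyr::arrange(.data$mutation_id, .data$day) |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::mutate(
      gen_start = .data$gen,
      gen_end = dplyr::lead(.data$gen),
      p_start = .data$freq,
      p_end = dplyr::lead(.data$freq),
      cov_start = .data$total_reads
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gen_end)) |>
    dplyr::select("mutation_id", "gen_start", "gen_end",
                  "p_start", "p_end", "cov_start")

  testable <- !is.na(intervals$p_start) & !is.na(intervals$p_end)
  skipped <- intervals[!testable, c("mutation_id", "gen_start", "gen_end")]
  tests <- intervals[testable, , drop = FALSE]

  if (nrow(tests) > 0) {
    tt <- tests$gen_end - tests$gen_start
    variance <- drift_variance(tests$p_start, tt, ne)
    if (coverage_noise) {
      variance <- variance +
        tests$p_start * (1 - tests$p_start) / tests$cov_start
    }
    sd0 <- sqrt(variance)
    delta <- tests$p_end - tests$p_start
    pv <- drift_change_probability(
      delta, p = tests$p_start, t = tt, ne = ne, tails = tails,
      coverage = if (coverage_noise) tests$cov_start else Inf
    )
    m <- nrow(tests)
    adjusted <- switch(correction,
      bonferroni = pmin(1, as.numeric(pv) * m),
      none = as.numeric(pv)
    )
    results <- tibble::tibble(
      mutation_id = tests$mutation_id,
      gen_start = tests$gen_start,
      gen_end = tests$gen_end,
      p_start = tests$p_start,
      delta = delta,
      variance = variance,
      sd = sd0,
      z = ifelse(sd0 > 0, abs(delta) / sd0, ifelse(delta == 0, 0, Inf)),
      p_value = as.numeric(pv),
      log10_p = attr(pv, "log10_p"),
      adjusted_p = adjusted,
      selection_flag = adjusted < alpha,
      flag = attr(pv, "flags")
    )
  } else {
    results <- tibble::tibble(
      mutation_id = character(0), gen_start = integer(0), gen_end = integer(0),
      p_start = numeric(0), delta = numeric(0), variance = numeric(0),
      sd = numeric(0), z = numeric(0), p_value = numeric(0),
      log10_p = numeric(0), adjusted_p = numeric(0),
      selection_flag = logical(0), flag = character(0)
    )
  }

  structure(
    list(results = results, skipped = skipped,
         params = list(ne = ne, alpha = alpha, correction = correction,
                       tails = tails, coverage_noise = coverage_noise,
                       n_tests = nrow(results),
                       population_id = series$population_id)),
    class = "drift_scan"
  )
}

#' @export
print.drift_scan <- function(x, ...) {
  cat(sprintf(
    "<drift_scan> population %s: %d interval test(s), %d flagged at alpha = %g (%s)\n",
    x$params$population_id, nrow(x$results), sum(x$results$selection_flag),
    x$params$alpha, x$params$correction
  ))
  invisible(x)
}

#' @rdname classify_trajectory
#' @param x A `drift_scan` object.
#' @param ... Unused.
#' @export
tidy.drift_scan <- function(x, ...) x$results

#' @rdname classify_trajectory
#' @export
glance.drift_scan <- function(x, ...) {
  tibble::tibble(
    population_id = x$params$population_id,
    n_tests = nrow(x$results),
    n_skipped = nrow(x$skipped),
    n_flagged = sum(x$results$selection_flag),
    n_mutations_flagged = dplyr::n_distinct(
      x$results$mutation_id[x$results$selection_flag]),
    ne = x$params$ne,
    alpha = x$params$alpha,
    correction = x$params$correction
  )
}

#' Plot a drift scan
#'
#' @param object A `drift_scan`.
#' @param ... Unused.
#' @return A ggplot of per-interval log10 p-values over time, with flagged
#'   intervals highlighted.
#' @export
autoplot.drift_scan <- function(object, ...) {
  dat <- object$results
  ggplot2::ggplot(dat, ggplot2::aes(
    x = (.data$gen_start + .data$gen_end) / 2,
    y = pmax(.data$log10_p, -320),
    colour = .data$selection_flag
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Interval midpoint (generations)",
                  y = "log10 p-value (drift null)",
                  colour = "Selection\ncandidate") +
    ggplot2::theme_minimal()
}

#' Write a drift report TSV
#'
#' @param scan A `drift_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drift_report <- function(scan, path) {
  stopifnot(inherits(scan, "drift_scan"))
  readr::write_tsv(
    dplyr::select(scan$results, "mutation_id",
                  interval_start_gen = "gen_start",
                  interval_end_gen = "gen_end",
                  "p_start", "delta", "sd", "z", "p_value", "adjusted_p",
                  flag = "selection_flag"),
    path, progress = FALSE
  )
  invisible(path)
}
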