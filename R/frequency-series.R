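#' Per-population mutation frequency time series
#'
#' The central container for a pooled-sequencing "fossil record": for one
#' population, the alt-read and total-read counts of every tracked mutation at
#' every sampled time point, with frequencies derived as `alt/total`.
#'
#' Frequencies are defined only where `total_reads > 0`; a time point with
#' zero total reads is a *missing* observation (`freq = NA`), not an observed
#' zero. Infinite-coverage series (from the simulator's noise-free sampling
#' mode) carry `total_reads = Inf`, `alt_reads = NA`, and an exact `freq`.
#'
#' @param counts Data frame with columns `mutation_id`, `day`, `alt_reads`,
#'   `total_reads`, and (only required where `total_reads` is infinite)
#'   `freq`. Any (mutation, day) combination absent from `counts` is treated
#'   as missing (zero total reads).
#' @param population_id Single string naming the population.
#' @param scale A [generation_scale()] (or a bare `gens_per_day` number) used
#'   to derive the generation of each sampled day.
#'
#' @return An object of class `frequency_series`: a list with elements
#'   `population_id`, `timepoints` (tibble of `day`, `gen`), `counts` (long
#'   tibble of `mutation_id`, `day`, `gen`, `alt_reads`, `total_reads`,
#'   `freq`), and `scale`.
#' @examples
#' fs <- frequency_series(
#'   tibble::tibble(
#'     mutation_id = rep(c("m1", "m2"), each = 2),
#'     day = rep(c(0, 6), 2),
#'     alt_reads = c(0, 10, 5, 50),
#'     total_reads = c(100, 100, 100, 100)
#'   ),
#'   population_id = "p18"
#' )
#' fs
#' @export
frequency_series <- function(counts, population_id, scale = generation_scale()) {
  if (!inherits(scale, "generation_scale")) scale <- generation_scale(scale)
  stopifnot(is.character(population_id), length(population_id) == 1)
  counts <- tibble::as_tibble(counts)
  required <- c("mutation_id", "day", "alt_reads", "total_reads")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop("`counts` lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"freq" %in% names(counts)) counts$freq <- NA_real_
  if (any(counts$day < 0, na.rm = TRUE)) {
    stop("Sampled days must be non-negative.", call. = FALSE)
  }

  days <- sort(unique(counts$day))
  counts <- counts |>
    dplyr::select("mutation_id", "day", "alt_reads", "total_reads", "freq") |>
    tidyr::complete(
      mutation_id = unique(counts$mutation_id),
      day = days,
      fill = list(alt_reads = 0L, total_reads = 0, freq = NA_real_)
    )

  finite <- is.finite(counts$total_reads)
  bad <- finite & (counts$alt_reads > counts$total_reads)
  if (any(bad, na.rm = TRUE)) {
    i <- which(bad)[1]
    stop(sprintf(
      "alt_reads (%s) exceeds total_reads (%s) for mutation '%s' at day %s.",
      counts$alt_reads[i], counts$total_reads[i],
      counts$mutation_id[i], counts$day[i]
    ), call. = FALSE)
  }
  if (any(counts$alt_reads < 0 | counts$total_reads < 0, na.rm = TRUE)) {
    stop("Read counts must be non-negative.", call. = FALSE)
  }

  counts$freq <- dplyr::case_when(
    is.infinite(counts$total_reads) ~ counts$freq,
    counts$total_reads > 0 ~ counts$alt_reads / counts$total_reads,
    TRUE ~ NA_real_
  )
  if (any(counts$freq < 0 | counts$freq > 1, na.rm = TRUE)) {
    stop("Frequencies must lie in [0, 1].", call. = FALSE)
  }

  counts$gen <- day_to_generation(counts$day, scale)
  counts <- counts |>
    dplyr::arrange(.data$mutation_id, .data$day) |>
    dplyr::select("mutation_id", "day", "gen", "alt_reads", "total_reads", "freq")

  structure(
    list(
      population_id = population_id,
      timepoints = tibble::tibble(day = days, gen = day_to_generation(days, scale)),
      counts = counts,
      scale = scale
    ),
    class = "frequency_series"
  )
}

#' @export
print.frequency_series <- function(x, ...) {
  if (nrow(x$timepoints) == 0) {
    cat(sprintf("<frequency_series> population %s: empty\n", x$population_id))
    return(invisible(x))
  }
  cat(sprintf(
    "<frequency_series> population %s: %d mutation(s) x %d time point(s) (days %s..%s)\n",
    x$population_id, length(series_mutations(x)), nrow(x$timepoints),
    min(x$timepoints$day), max(x$timepoints$day)
  ))
  print(x$counts, n = 6)
  invisible(x)
}

#' Mutation identifiers tracked by a frequency series
#' @param series A [frequency_series()].
#' @return Character vector of mutation ids.
#' @export
series_mutations <- function(series) {
  stopifnot(inherits(series, "frequency_series"))
  unique(series$counts$mutation_id)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a frequency series into a long tibble
#'
#' @param x A [frequency_series()].
#' @param ... Unused.
#' @return Long tibble with one row per mutation per time point.
#' @export
tidy.frequency_series <- function(x, ...) {
  dplyr::mutate(x$counts, population_id = x$population_id, .before = 1)
}

# Detection indicator used by the reporting filters and dating rules:
# at finite coverage a mutation is detected where at least one alt read was
# observed; at infinite coverage where its exact frequency is positive.
# Missing observations (total_reads == 0) are never detections.
series_detected <- function(series) {
  counts <- series$counts
  dplyr::mutate(
    counts,
    detected = dplyr::case_when(
      is.infinite(.data$total_reads) ~ !is.na(.data$freq) & .data$freq > 0,
      .data$total_reads > 0 ~ .data$alt_reads >= 1,
      TRUE ~ FALSE
    )
  )
}

#' Plot mutation frequency trajectories
#'
#' @param object A [frequency_series()].
#' @param ... Unused.
#' @return A ggplot object: one line per mutation over generations.
#' @export
autoplot.frequency_series <- function(object, ...) {
  dat <- dplyr::filter(tidy(object), !is.na(.data$freq))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$gen, y = .data$freq,
    colour = .data$mutation_id, group = .data$mutation_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Generation", y = "Allele frequency", colour = "Mutation",
      title = paste0("Fossil record, population ", object$population_id)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
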