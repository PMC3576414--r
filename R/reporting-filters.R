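#' Apply the variant-reporting filters to a fossil record
#'
#' Implements the reporting rules used for pooled time-series variant calls:
#'
#' 1. *Single-read masking*: an observation supported by exactly one alt read
#'    at a time point is treated as undetected unless the next time point has
#'    at least two supporting reads. Masked observations are zeroed in the
#'    output series and listed in the returned mask. Masking is applied
#'    before the retention rules are evaluated.
#' 2. *Retention*: a mutation is kept iff it is detected in at least
#'    `min_samples` time points *and* reaches frequency `min_freq` in at
#'    least one sample — or it is carried by at least one sequenced clone,
#'    in which case it is reported regardless of its pooled frequencies.
#'
#' Detection means at least one alt read (after masking) at a time point with
#' nonzero total reads; time points with zero coverage are missing, not zero.
#' The filter is idempotent and never adds mutations.
#'
#' @param series A [frequency_series()].
#' @param clones Clone genotype tibble (see [clone_genotypes()]) from the same
#'   population, or `NULL` if no clones were sequenced.
#' @param min_freq Minimum frequency a mutation must reach in at least one
#'   sample (default 0.05). Must lie in (0, 1].
#' @param min_samples Minimum number of time points at which the mutation must
#'   be detected (default 2, i.e. "more than one time point sample").
#'
#' @return A list with elements `series` (the filtered [frequency_series()]),
#'   `mask` (tibble of suppressed single-read observations: `mutation_id`,
#'   `day`), and `removed` (character vector of dropped mutation ids).
#' @export
apply_reporting_filters <- function(series, clones = NULL,
                                    min_freq = 0.05, min_samples = 2) {
  stopifnot(inherits(series, "frequency_series"))
  if (!is.numeric(min_freq) || length(min_freq) != 1 ||
      min_freq <= 0 || min_freq > 1) {
    stop("`min_freq` must lie in (0, 1].", call. = FALSE)
  }
  clone_muts <- character(0)
  if (!is.null(clones)) {
    clones <- clone_genotypes(clones)
    same_pop <- clones$population_id == series$population_id
    if (!all(same_pop)) {
      stop("Clones and series must share a population_id.", call. = FALSE)
    }
    clone_muts <- unique(unlist(clones$mutations))
  }

  counts <- series$counts |> dplyr::arrange(.data$mutation_id, .data$day)

  # single-read masking: alt == 1 suppressed unless next time point has >= 2
  masked <- counts |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::mutate(
      next_alt = dplyr::lead(.data$alt_reads),
      masked = is.finite(.data$total_reads) & .data$total_reads > 0 &
        .data$alt_reads == 1 &
        (is.na(.data$next_alt) | .data$next_alt < 2)
    ) |>
    dplyr::ungroup()

  mask <- masked |>
    dplyr::filter(.data$masked) |>
    dplyr::select("mutation_id", "day")

  counts2 <- masked |>
    dplyr::mutate(alt_reads = ifelse(.data$masked, 0L, .data$alt_reads)) |>
    dplyr::select("mutation_id", "day", "alt_reads", "total_reads", "freq")

  masked_series <- frequency_series(
    dplyr::mutate(counts2,
                  freq = ifelse(is.infinite(.data$total_reads), .data$freq, NA_real_)),
    population_id = series$population_id, scale = series$scale
  )

  det <- series_detected(masked_series) |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::summarise(
      n_detected = sum(.data$detected),
      max_freq = if (any(.data$detected)) max(.data$freq[.data$detected]) else NA_real_,
      .groups = "drop"
    )
  keep <- det$mutation_id[
    (det$n_detected >= min_samples &
       !is.na(det$max_freq) & det$max_freq >= min_freq) |
      det$mutation_id %in% clone_muts
  ]
  removed <- setdiff(series_mutations(series), keep)

  kept_counts <- masked_series$counts |>
    dplyr::filter(.data$mutation_id %in% keep) |>
    dplyr::select("mutation_id", "day", "alt_reads", "total_reads", "freq")

  filtered <- if (nrow(kept_counts) > 0) {
    frequency_series(
      dplyr::mutate(kept_counts,
                    freq = ifelse(is.infinite(.data$total_reads), .data$freq, NA_real_)),
      population_id = series$population_id, scale = series$scale
    )
  } else {
    frequency_series(
      tibble::tibble(mutation_id = character(0), day = integer(0),
                     alt_reads = integer(0), total_reads = numeric(0)),
      population_id = series$population_id, scale = series$scale
    )
  }

  list(series = filtered,
       mask = mask |> dplyr::filter(.data$mutation_id %in% keep),
       removed = removed)
}
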