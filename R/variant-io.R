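#' Build a validated mutation record table
#'
#' One row per mutation: genomic identity (1-based position, ref and alt
#' alleles), mutation class, and gene/codon annotation. Intergenic mutations
#' carry a two-gene label `"geneA/geneB"` and no codon.
#'
#' @param mutations Data frame with columns `mutation_id`, `population_id`,
#'   `position`, `ref_allele`, `alt_allele`, `mclass` (one of `"SNP"`,
#'   `"insertion"`, `"deletion"`, `"IS_insertion"`, `"large_deletion"`),
#'   `gene`, and optionally `codon` (positive integer or `NA`) and
#'   `synonymous` (logical or `NA`).
#'
#' @return A validated tibble of mutation records.
#' @export
mutation_records <- function(mutations) {
  mutations <- tibble::as_tibble(mutations)
  required <- c("mutation_id", "population_id", "position", "ref_allele",
                "alt_allele", "mclass", "gene")
  missing_cols <- setdiff(required, names(mutations))
  if (length(missing_cols) > 0) {
    stop("Mutation table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"codon" %in% names(mutations)) mutations$codon <- NA_integer_
  if (!"synonymous" %in% names(mutations)) mutations$synonymous <- NA
  mutations$codon <- as.integer(mutations$codon)
  mutations$synonymous <- as.logical(mutations$synonymous)

  classes <- c("SNP", "insertion", "deletion", "IS_insertion", "large_deletion")
  bad_class <- !mutations$mclass %in% classes
  if (any(bad_class)) {
    stop("Unknown mutation class(es): ",
         paste(unique(mutations$mclass[bad_class]), collapse = ", "),
         call. = FALSE)
  }
  if (any(mutations$position < 1 | mutations$position != floor(mutations$position))) {
    stop("`position` must be a positive integer (1-based).", call. = FALSE)
  }
  snp <- mutations$mclass == "SNP"
  if (any(snp & (nchar(mutations$ref_allele) != 1 | nchar(mutations$alt_allele) != 1))) {
    stop("SNP records must have single-base ref and alt alleles.", call. = FALSE)
  }
  intergenic <- grepl("/", mutations$gene, fixed = TRUE)
  if (any(intergenic & !is.na(mutations$codon))) {
    stop("Intergenic records (gene 'a/b') cannot carry a codon.", call. = FALSE)
  }
  if (anyDuplicated(mutations[c("population_id", "mutation_id")])) {
    stop("Duplicated mutation_id within a population.", call. = FALSE)
  }
  mutations
}

#' Read a pooled-sequencing variant table
#'
#' Reads the wide TSV dialect used for fossil-record variant tables: one row
#' per mutation with annotation columns (`population`, `mutation_id`,
#' `position`, `ref`, `alt`, `class`, `gene`, `codon`, `synonymous`) followed
#' by a pair of count columns `day<d>_alt` / `day<d>_total` for each sampled
#' day. Rows whose counts cannot be interpreted as non-negative integers are
#' dropped with a warning naming the row; an alt count exceeding its total is
#' a validation error naming the offending cell.
#'
#' @param path Path to the TSV file.
#' @param scale A [generation_scale()].
#' @return A list with elements `mutations` (tibble of mutation records) and
#'   `series` (a [frequency_series()]). An annotation-only table yields an
#'   empty series.
#' @export
read_variant_table <- function(path, scale = generation_scale()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  anno_cols <- c("population", "mutation_id", "position", "ref", "alt",
                 "class", "gene", "codon", "synonymous")
  missing_cols <- setdiff(setdiff(anno_cols, c("codon", "synonymous")), names(raw))
  if (length(missing_cols) > 0) {
    stop("Variant table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  count_cols <- grep("^day[0-9]+_(alt|total)$", names(raw), value = TRUE)
  days <- sort(unique(as.integer(sub("^day([0-9]+)_.*$", "\\1", count_cols))))
  for (d in days) {
    pair <- paste0("day", d, c("_alt", "_total"))
    if (!all(pair %in% names(raw))) {
      stop("Unpaired count column for day ", d,
           ": need both day<d>_alt and day<d>_total.", call. = FALSE)
    }
  }

  pops <- unique(raw$population)
  if (length(pops) > 1) {
    stop("Variant table mixes populations (", paste(pops, collapse = ", "),
         "); read one population per file.", call. = FALSE)
  }

  # reject rows with malformed counts, reporting their (1-based data) row number
  if (length(count_cols) > 0 && nrow(raw) > 0) {
    count_mat <- suppressWarnings(
      vapply(raw[count_cols], as.numeric, numeric(nrow(raw)))
    )
    count_mat <- matrix(count_mat, nrow = nrow(raw),
                        dimnames = list(NULL, count_cols))
    bad_row <- apply(count_mat, 1, function(v) {
      any(is.na(v)) || any(v < 0) || any(v != floor(v))
    })
    if (any(bad_row)) {
      warning("Dropping row(s) with malformed counts: ",
              paste(which(bad_row), collapse = ", "), call. = FALSE)
      raw <- raw[!bad_row, , drop = FALSE]
    }
  }

  mutations <- mutation_records(tibble::tibble(
    mutation_id = raw$mutation_id,
    population_id = if (nrow(raw) > 0) raw$population else character(0),
    position = as.integer(raw$position),
    ref_allele = raw$ref,
    alt_allele = raw$alt,
    mclass = raw$class,
    gene = raw$gene,
    codon = if ("codon" %in% names(raw)) suppressWarnings(as.integer(raw$codon)) else NA_integer_,
    synonymous = if ("synonymous" %in% names(raw)) as.logical(raw$synonymous) else NA
  ))

  population_id <- if (length(pops) == 1) pops else "unknown"
  counts <- tidyr::expand_grid(mutation_id = raw$mutation_id, day = days)
  if (nrow(counts) > 0) {
    # vapply gives a days x rows matrix; column-major flattening matches
    # expand_grid's day-fastest ordering within each mutation
    counts$alt_reads <- as.integer(vapply(
      seq_len(nrow(raw)),
      function(i) as.numeric(raw[i, paste0("day", days, "_alt"), drop = TRUE]),
      numeric(length(days))
    ))
    counts$total_reads <- as.numeric(vapply(
      seq_len(nrow(raw)),
      function(i) as.numeric(raw[i, paste0("day", days, "_total"), drop = TRUE]),
      numeric(length(days))
    ))
  } else {
    counts$alt_reads <- integer(0)
    counts$total_reads <- numeric(0)
  }
  series <- frequency_series(counts, population_id = population_id, scale = scale)
  list(mutations = mutations, series = series)
}

#' Write a variant table in the wide TSV dialect
#'
#' Inverse of [read_variant_table()]. Infinite-coverage series cannot be
#' written as read counts and are refused.
#'
#' @param mutations Mutation record tibble.
#' @param series A [frequency_series()] over the same mutations.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(mutations, series, path) {
  stopifnot(inherits(series, "frequency_series"))
  if (any(is.infinite(series$counts$total_reads))) {
    stop("Cannot write infinite-coverage series as read counts.", call. = FALSE)
  }
  mutations <- mutation_records(mutations)
  wide_alt <- series$counts |>
    dplyr::select("mutation_id", "day", "alt_reads") |>
    tidyr::pivot_wider(names_from = "day", values_from = "alt_reads",
                       names_glue = "day{day}_alt")
  wide_tot <- series$counts |>
    dplyr::mutate(total_reads = as.integer(.data$total_reads)) |>
    dplyr::select("mutation_id", "day", "total_reads") |>
    tidyr::pivot_wider(names_from = "day", values_from = "total_reads",
                       names_glue = "day{day}_total")
  out <- mutations |>
    dplyr::transmute(
      population = .data$population_id, mutation_id = .data$mutation_id,
      position = .data$position, ref = .data$ref_allele, alt = .data$alt_allele,
      class = .data$mclass, gene = .data$gene, codon = .data$codon,
      synonymous = .data$synonymous
    ) |>
    dplyr::left_join(wide_alt, by = "mutation_id") |>
    dplyr::left_join(wide_tot, by = "mutation_id")
  # interleave day<d>_alt / day<d>_total pairs in day order
  days <- sort(series$timepoints$day)
  ordered <- c(names(out)[1:9], if (length(days) > 0)
    as.vector(rbind(paste0("day", days, "_alt"),
                    paste0("day", days, "_total"))))
  readr::write_tsv(out[ordered], path, progress = FALSE)
  invisible(path)
}

#' Read an endpoint clone genotype table
#'
#' Reads the clone TSV dialect: columns `clone_id`, `population`, `ecotype`,
#' `extraction_day`, and `mutations` (semicolon-separated mutation ids; empty
#' for an ancestral-genotype clone).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `clone_id`, `population_id`, `ecotype`,
#'   `extraction_day`, and a list-column `mutations`.
#' @export
read_clone_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    clone_id = readr::col_character(),
    population = readr::col_character(),
    ecotype = readr::col_character(),
    extraction_day = readr::col_integer(),
    mutations = readr::col_character()
  ), progress = FALSE)
  clone_genotypes(tibble::tibble(
    clone_id = raw$clone_id,
    population_id = raw$population,
    ecotype = raw$ecotype,
    extraction_day = raw$extraction_day,
    mutations = lapply(raw$mutations, function(s) {
      if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  ))
}

#' Validate a clone genotype table
#'
#' @param clones Data frame with columns `clone_id`, `population_id`,
#'   `ecotype` (one of `"FS"`, `"SS"`, `"ancestral"`, `"unknown"`),
#'   `extraction_day`, and list-column `mutations`.
#' @param mutations Optional mutation record tibble; when supplied, every
#'   clone mutation must be a known mutation of the clone's population.
#' @return The validated clone tibble.
#' @export
clone_genotypes <- function(clones, mutations = NULL) {
  clones <- tibble::as_tibble(clones)
  required <- c("clone_id", "population_id", "ecotype", "extraction_day", "mutations")
  missing_cols <- setdiff(required, names(clones))
  if (length(missing_cols) > 0) {
    stop("Clone table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !clones$ecotype %in% c("FS", "SS", "ancestral", "unknown")
  if (any(bad)) {
    stop("Unknown ecotype label(s): ",
         paste(unique(clones$ecotype[bad]), collapse = ", "), call. = FALSE)
  }
  if (!is.list(clones$mutations)) {
    stop("`mutations` must be a list-column of character vectors.", call. = FALSE)
  }
  if (anyDuplicated(clones$clone_id)) {
    stop("Duplicated clone_id.", call. = FALSE)
  }
  if (!is.null(mutations)) {
    mutations <- mutation_records(mutations)
    for (i in seq_len(nrow(clones))) {
      known <- mutations$mutation_id[mutations$population_id == clones$population_id[i]]
      extra <- setdiff(clones$mutations[[i]], known)
      if (length(extra) > 0) {
        stop(sprintf("Clone '%s' carries unknown mutation(s): %s",
                     clones$clone_id[i], paste(extra, collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  clones
}

#' Write a clone genotype table
#'
#' @param clones Clone tibble as returned by [read_clone_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  clones <- clone_genotypes(clones)
  out <- tibble::tibble(
    clone_id = clones$clone_id,
    population = clones$population_id,
    ecotype = clones$ecotype,
    extraction_day = clones$extraction_day,
    mutations = vapply(clones$mutations, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
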