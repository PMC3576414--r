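#' Cross-population parallelism of ecotype-associated mutations
#'
#' For every mutation, finds the finest resolution at which another
#' population carries a mutation associated with the *same* ecotype:
#'
#' * `nucleotide` — identical genetic change: same position and same
#'   ref/alt alleles (an IS-element insertion matches when the element and
#'   the insertion site coincide, which the position + alt encoding captures);
#' * `codon` — same gene and same codon, but a different change;
#' * `gene` — same gene, or same intergenic pair label, at a different site;
#' * `none` — no same-ecotype mutation in that gene anywhere else.
#'
#' A nucleotide match implies a codon match (where a codon is annotated)
#' implies a gene match. The headline quantity is the fraction of mutations
#' matched at *any* level. If the mutation table has a logical `starred`
#' column (mutations found only in clones, never in the pooled samples),
#' totals are additionally reported with the starred mutations excluded,
#' since it is ambiguous whether they belong in the denominator.
#'
#' @param mutations Mutation record tibble (see [mutation_records()]) with an
#'   additional `ecotype` column (`"FS"`/`"SS"`) giving the ecotype each
#'   mutation is associated with, and optionally a logical `starred` column.
#' @return An object of class `parallelism_summary`: list with
#'   `per_mutation` (tibble adding `match_level`), `summary` (counts and
#'   fractions at each level), `n_total`, and `fraction_matched`.
#' @export
parallelism_levels <- function(mutations) {
  mutations <- tibble::as_tibble(mutations)
  if (!"ecotype" %in% names(mutations)) {
    stop("`mutations` needs an `ecotype` column.", call. = FALSE)
  }
  mutations <- dplyr::bind_cols(
    mutation_records(dplyr::select(mutations, -"ecotype",
                                   -dplyr::any_of("starred"))),
    dplyr::select(mutations, "ecotype", dplyr::any_of("starred"))
  )
  if (dplyr::n_distinct(mutations$population_id) < 2) {
    stop("Parallelism requires mutations from at least two populations.",
         call. = FALSE)
  }

  match_level <- vapply(seq_len(nrow(mutations)), function(i) {
    m <- mutations[i, ]
    others <- mutations[mutations$population_id != m$population_id &
                          mutations$ecotype == m$ecotype, , drop = FALSE]
    if (nrow(others) == 0) return("none")
    if (any(others$position == m$position &
              others$ref_allele == m$ref_allele &
              others$alt_allele == m$alt_allele)) {
      return("nucleotide")
    }
    if (!is.na(m$codon) &&
        any(others$gene == m$gene & !is.na(others$codon) &
              others$codon == m$codon)) {
      return("codon")
    }
    if (any(others$gene == m$gene)) return("gene")
    "none"
  }, character(1))

  per_mutation <- dplyr::mutate(mutations, match_level = match_level)
  level_counts <- function(dat) {
    tibble::tibble(
      n_total = nrow(dat),
      n_nucleotide = sum(dat$match_level == "nucleotide"),
      n_codon = sum(dat$match_level == "codon"),
      n_gene = sum(dat$match_level == "gene"),
      n_matched = sum(dat$match_level != "none"),
      fraction_matched = ifelse(nrow(dat) > 0,
                                sum(dat$match_level != "none") / nrow(dat),
                                NA_real_)
    )
  }
  summary <- dplyr::mutate(level_counts(per_mutation), scope = "all", .before = 1)
  if ("starred" %in% names(per_mutation)) {
    summary <- dplyr::bind_rows(
      summary,
      dplyr::mutate(
        level_counts(per_mutation[!per_mutation$starred, , drop = FALSE]),
        scope = "unstarred", .before = 1)
    )
  }

  structure(
    list(per_mutation = per_mutation, summary = summary,
         n_total = nrow(per_mutation),
         fraction_matched = summary$fraction_matched[1]),
    class = "parallelism_summary"
  )
}

#' @export
print.parallelism_summary <- function(x, ...) {
  s <- x$summary[1, ]
  cat(sprintf(
    "<parallelism_summary> %d/%d mutations (%.0f%%) matched cross-population at some level\n  nucleotide %d | codon %d | gene %d | none %d\n",
    s$n_matched, s$n_total, 100 * s$fraction_matched,
    s$n_nucleotide, s$n_codon, s$n_gene, s$n_total - s$n_matched
  ))
  invisible(x)
}

#' @rdname parallelism_levels
#' @param x A `parallelism_summary`.
#' @param ... Unused.
#' @export
tidy.parallelism_summary <- function(x, ...) x$per_mutation

#' @rdname parallelism_levels
#' @export
glance.parallelism_summary <- function(x, ...) x$summary

#' Paired t-test on per-population mutation counts
#'
#' Standard paired t-test on the differences of paired values (e.g. mean
#' mutation counts of FS versus SS clones from the same population, one pair
#' per genealogically independent comparison). Two-tailed p from the t
#' distribution with `n - 1` degrees of freedom. Zero variance of the
#' differences with a nonzero mean gives an infinite t, reported as p = 0
#' with the flag `"zero_variance"`.
#'
#' @param pairs Two-column data frame (or matrix) of paired values; columns
#'   are taken as (first member, second member), e.g. (FS count, SS count).
#' @return An object of class `paired_comparison` with fields `pairs`,
#'   `t_statistic`, `degrees_of_freedom`, `two_tailed_p`, `mean_difference`,
#'   and `flag`.
#' @examples
#' paired_t_test(data.frame(fs = c(3, 4, 5, 6), ss = c(1, 2, 2, 3)))
#' @export
paired_t_test <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) != 2) stop("`pairs` must have exactly two columns.",
                             call. = FALSE)
  n <- nrow(pairs)
  if (n < 2) stop("Need at least two pairs.", call. = FALSE)
  d <- pairs[[1]] - pairs[[2]]
  flag <- ""
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      tstat <- 0
      p <- 1
    } else {
      tstat <- sign(mean(d)) * Inf
      p <- 0
      flag <- "zero_variance"
    }
  } else {
    fit <- stats::t.test(pairs[[1]], pairs[[2]], paired = TRUE)
    tstat <- unname(fit$statistic)
    p <- fit$p.value
  }
  structure(
    list(pairs = tibble::as_tibble(pairs), t_statistic = tstat,
         degrees_of_freedom = n - 1L, two_tailed_p = p,
         mean_difference = mean(d), flag = flag),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> n = %d pairs: mean difference %.3g, t = %.4g (df = %d), two-tailed p = %.4g%s\n",
    nrow(x$pairs), x$mean_difference, x$t_statistic, x$degrees_of_freedom,
    x$two_tailed_p, if (x$flag != "") paste0(" [", x$flag, "]") else ""
  ))
  invisible(x)
}

#' @rdname paired_t_test
#' @param x A `paired_comparison`.
#' @param ... Unused.
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(estimate = x$mean_difference, statistic = x$t_statistic,
                 p.value = x$two_tailed_p, parameter = x$degrees_of_freedom,
                 method = "Paired t-test", flag = x$flag)
}

#' @rdname paired_t_test
#' @export
glance.paired_comparison <- function(x, ...) tidy(x, ...)

#' Genealogically independent FS/SS mutation-count pairs
#'
#' Builds the pairs for [paired_t_test()] from sequenced clones: within each
#' population, FS clones and SS clones are grouped into independent origins
#' (transitive closure of mutation sharing, as in
#' [count_independent_origins()]), the clone mutation counts are averaged
#' within each origin, and one pair is formed for every FS-origin x
#' SS-origin combination in the population. A population with one FS and two
#' independent SS origins therefore contributes two comparisons.
#'
#' @param clones Clone genotype tibble spanning one or more populations.
#' @return Tibble with columns `population_id`, `fs_count`, `ss_count`.
#' @export
fs_ss_pairs <- function(clones) {
  clones <- clone_genotypes(clones)
  origin_means <- function(sub) {
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i && length(intersect(sub$mutations[[i]], sub$mutations[[j]])) > 0) {
          parent[find(i)] <- find(j)
        }
      }
    }
    grp <- vapply(seq_len(n), find, integer(1))
    counts <- lengths(sub$mutations)
    as.numeric(tapply(counts, grp, mean))
  }
  purrr::map_dfr(unique(clones$population_id), function(pop) {
    fs <- clones[clones$population_id == pop & clones$ecotype == "FS", ]
    ss <- clones[clones$population_id == pop & clones$ecotype == "SS", ]
    if (nrow(fs) == 0 || nrow(ss) == 0) return(NULL)
    tidyr::expand_grid(fs_count = origin_means(fs), ss_count = origin_means(ss)) |>
      dplyr::mutate(population_id = pop, .before = 1)
  })
}

#' Write a parallelism report
#'
#' Writes the per-mutation match table as TSV and, optionally, a short text
#' report with the level counts and the paired FS/SS comparison.
#'
#' @param summary A `parallelism_summary`.
#' @param path Output TSV path.
#' @param report_path Optional text report path.
#' @param comparison Optional `paired_comparison` to include in the report.
#' @return `path`, invisibly.
#' @export
write_parallelism_report <- function(summary, path, report_path = NULL,
                                     comparison = NULL) {
  stopifnot(inherits(summary, "parallelism_summary"))
  out <- summary$per_mutation
  out$mutations <- NULL
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(report_path)) {
    lines <- utils::capture.output({
      print(summary)
      print(summary$summary)
      if (!is.null(comparison)) print(comparison)
    })
    writeLines(lines, report_path)
  }
  invisible(path)
}
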