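#' Associate mutations with ecotypes via the sequenced clones
#'
#' A mutation is associated with an ecotype when every sequenced clone that
#' carries it has that ecotype; mutations carried by clones of both ecotypes
#' or by no clone get `NA`. Mutations never detected in the pooled samples
#' (clone-only) are flagged `starred`.
#'
#' @param mutations Mutation record tibble.
#' @param clones Clone genotype tibble of the same population.
#' @param series Optional filtered [frequency_series()] used to set the
#'   `starred` flag.
#' @return `mutations` with added `ecotype` and (if `series` given) `starred`
#'   columns.
#' @export
ecotype_associations <- function(mutations, clones, series = NULL) {
  mutations <- mutation_records(mutations)
  clones <- clone_genotypes(clones)
  eco <- vapply(mutations$mutation_id, function(m) {
    carriers <- clones$ecotype[vapply(clones$mutations, function(s) m %in% s,
                                      logical(1))]
    carriers <- unique(carriers[carriers %in% c("FS", "SS")])
    if (length(carriers) == 1) carriers else NA_character_
  }, character(1))
  out <- dplyr::mutate(mutations, ecotype = unname(eco))
  if (!is.null(series)) {
    det <- series_detected(series) |>
      dplyr::group_by(.data$mutation_id) |>
      dplyr::summarise(ever = any(.data$detected), .groups = "drop")
    out$starred <- !out$mutation_id %in% det$mutation_id[det$ever]
  }
  out
}

#' Run the full fossil-record analysis pipeline
#'
#' Orchestrates, for each population: reporting filters, genealogy
#' reconstruction and dating, lineage assignment and Muller table
#' construction, and the drift-null scan; then, across populations,
#' parallelism levels and the paired FS/SS comparison. All outputs are
#' written under `out_dir` and listed in the returned manifest
#' (`manifest.json`), which also records the configuration hash, seed,
#' executed stages, and accumulated warnings, so a rerun with an identical
#' configuration produces byte-identical outputs.
#'
#' @param config Either a list or a path to a YAML file with entries:
#'   `populations` (list; each with `variant_table` and `clone_table` paths),
#'   and optional `params` (`min_freq`, `min_samples`, `ne`, `alpha`,
#'   `correction`, `tails`, `gens_per_day`, `max_gap`, `tolerance`,
#'   `fallback`), and `seed`.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest, invisibly (also written as JSON).
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$populations))
  p <- config$params %||% list()
  params <- list(
    min_freq = p$min_freq %||% 0.05,
    min_samples = p$min_samples %||% 2,
    ne = p$ne %||% 3.3e7,
    alpha = p$alpha %||% 0.05,
    correction = p$correction %||% "bonferroni",
    tails = p$tails %||% 2,
    gens_per_day = p$gens_per_day %||% 6.7,
    tolerance = p$tolerance %||% 0.05,
    max_gap = p$max_gap %||% NULL,
    fallback = isTRUE(p$fallback)
  )
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    inputs = lapply(config$populations, function(x)
      x[c("variant_table", "clone_table")]),
    config_hash = rlang::hash(config),
    seed = seed,
    stages = character(0),
    outputs = character(0),
    log = character(0),
    warnings = character(0)
  )
  note <- function(w) manifest$log <<- c(manifest$log, w)
  # manifest records outputs relative to out_dir so identical configurations
  # yield byte-identical manifests regardless of where the run lands
  out_path <- function(...) {
    manifest$outputs <<- c(manifest$outputs, paste0(...))
    file.path(out_dir, paste0(...))
  }
  stage <- function(name, expr) {
    manifest$stages <<- c(manifest$stages, name)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        marker <- file.path(out_dir, "manifest.partial")
        jsonlite::write_json(c(manifest, list(failed_stage = name,
                                              error = conditionMessage(e))),
                             marker, auto_unbox = TRUE, digits = NA)
        stop(sprintf("Pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  scale <- generation_scale(params$gens_per_day)
  pop_results <- list()

  for (popcfg in config$populations) {
    dat <- stage("read", {
      vt <- read_variant_table(popcfg$variant_table, scale = scale)
      cl <- read_clone_table(popcfg$clone_table)
      list(mutations = vt$mutations, series = vt$series, clones = cl)
    })
    pop <- dat$series$population_id

    filt <- stage("filter", {
      res <- apply_reporting_filters(dat$series, dat$clones,
                                     min_freq = params$min_freq,
                                     min_samples = params$min_samples)
      note(sprintf("filter[%s]: %d in, %d retained, %d removed, %d obs masked",
                   pop, length(series_mutations(dat$series)),
                   length(series_mutations(res$series)),
                   length(res$removed), nrow(res$mask)))
      res
    })

    tree <- stage("genealogy", {
      tr <- build_genealogy(dat$clones, series = filt$series,
                            fallback = params$fallback)
      if (length(tr$dropped) > 0) {
        note(sprintf("genealogy[%s]: dropped conflicting mutation(s) %s",
                     pop, paste(tr$dropped, collapse = ", ")))
      }
      extraction_gen <- day_to_generation(max(dat$clones$extraction_day), scale)
      tr <- date_genealogy(tr, filt$series, extraction_gen)
      if (nrow(dat$clones) >= 2) {
        ape::write.tree(as.phylo(tr), out_path(pop, "_genealogy.nwk"))
      }
      write_genealogy(tr, out_path(pop, "_genealogy_annotated.nwk"),
                      out_path(pop, "_mutation_dates.tsv"))
      tr
    })

    muller <- stage("muller", {
      lin <- assign_lineages(tree, filt$series)
      mt <- build_muller_table(lin, filt$series, tolerance = params$tolerance)
      write_muller_table(mt, out_path(pop, "_muller.tsv"))
      if (!is.null(params$max_gap)) {
        lumped <- purrr::map_dfr(seq_len(nrow(lin)), function(i) {
          lump_similar(lin[i, ], filt$series, params$max_gap)$clusters |>
            dplyr::mutate(lineage_id = lin$lineage_id[i])
        })
        readr::write_tsv(lumped, out_path(pop, "_lumped.tsv"),
                         progress = FALSE)
      }
      mt
    })

    scan <- stage("drift", {
      sc <- classify_trajectory(filt$series, ne = params$ne,
                                alpha = params$alpha,
                                correction = params$correction,
                                tails = params$tails)
      write_drift_report(sc, out_path(pop, "_drift.tsv"))
      sc
    })

    pop_results[[pop]] <- list(
      mutations = dat$mutations, clones = dat$clones,
      series = filt$series, tree = tree, muller = muller, scan = scan
    )
  }

  if (length(pop_results) >= 2) {
    stage("parallelism", {
      annotated <- purrr::map_dfr(pop_results, function(r) {
        ecotype_associations(r$mutations, r$clones, r$series)
      })
      annotated <- annotated[!is.na(annotated$ecotype), , drop = FALSE]
      if (dplyr::n_distinct(annotated$population_id) >= 2) {
        ps <- parallelism_levels(annotated)
        all_clones <- dplyr::bind_rows(lapply(pop_results, `[[`, "clones"))
        pairs <- fs_ss_pairs(all_clones)
        comparison <- if (nrow(pairs) >= 2) {
          paired_t_test(pairs[c("fs_count", "ss_count")])
        } else NULL
        write_parallelism_report(ps, out_path("parallelism.tsv"),
                                 out_path("parallelism_report.txt"),
                                 comparison)
      } else {
        note("parallelism: fewer than two populations with ecotype-associated mutations; skipped")
      }
    })
  } else {
    note("parallelism: single population; skipped")
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest$outputs <- c(manifest$outputs, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
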