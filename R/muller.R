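#' Group mutations into nested lineages from a dated genealogy
#'
#' Every genealogy edge that carries mutations defines one lineage; its parent
#' is the lineage of the nearest ancestral edge that itself carries mutations,
#' so nesting mirrors the genetic backgrounds on which successive mutations
#' arose. Mutations within a lineage are kept in their order of first
#' detection in the fossil record (set during [date_genealogy()]). The
#' lineage's ecotype tag is inherited from the clone(s) below its edge
#' (`"mixed"` where they disagree).
#'
#' @param tree A dated `clone_genealogy`.
#' @param series The population's [frequency_series()] (used only to confirm
#'   the mutations are tracked).
#' @return A tibble with columns `lineage_id`, `parent_id` (`NA` for root
#'   lineages), list-column `defining_mutations` (ordered), `ecotype`, and
#'   `node_id`.
#' @export
assign_lineages <- function(tree, series) {
  stopifnot(inherits(tree, "clone_genealogy"))
  if (!tree$dated) {
    stop("Tree must be dated before lineages are assigned; see date_genealogy().",
         call. = FALSE)
  }
  nodes <- tree$nodes
  has_muts <- lengths(nodes$mutations) > 0
  lineage_nodes <- nodes$node_id[has_muts]
  if (length(lineage_nodes) == 0) {
    return(tibble::tibble(lineage_id = character(0), parent_id = character(0),
                          defining_mutations = list(), ecotype = character(0),
                          node_id = character(0)))
  }
  # nearest ancestor edge carrying mutations
  parent_lineage <- vapply(lineage_nodes, function(n) {
    cur <- nodes$parent_id[nodes$node_id == n]
    while (!is.na(cur)) {
      i <- which(nodes$node_id == cur)
      if (length(nodes$mutations[[i]]) > 0) return(cur)
      cur <- nodes$parent_id[i]
    }
    NA_character_
  }, character(1))

  ecotags <- vapply(lineage_nodes, function(n) {
    below <- nodes$clones[[which(nodes$node_id == n)]]
    ecos <- unique(tree$clones$ecotype[tree$clones$clone_id %in% below])
    if (length(ecos) == 1) ecos else "mixed"
  }, character(1))

  lid <- function(n) paste0("L_", nodes$mutations[[which(nodes$node_id == n)]][1])
  tibble::tibble(
    lineage_id = unname(vapply(lineage_nodes, lid, character(1))),
    parent_id = unname(ifelse(is.na(parent_lineage), NA_character_,
                              vapply(parent_lineage, function(p)
                                if (is.na(p)) NA_character_ else lid(p),
                                character(1)))),
    defining_mutations = nodes$mutations[has_muts],
    ecotype = unname(ecotags),
    node_id = lineage_nodes
  )
}

lineage_frequency <- function(lineages, series, freq_proxy = c("first", "mean")) {
  freq_proxy <- match.arg(freq_proxy)
  counts <- series$counts
  purrr::map_dfr(seq_len(nrow(lineages)), function(i) {
    mm <- lineages$defining_mutations[[i]]
    sel <- counts[counts$mutation_id %in% mm, , drop = FALSE]
    f <- if (freq_proxy == "first") {
      sel[sel$mutation_id == mm[1], c("day", "gen", "freq")]
    } else {
      sel |>
        dplyr::group_by(.data$day, .data$gen) |>
        dplyr::summarise(freq = mean(.data$freq, na.rm = TRUE), .groups = "drop")
    }
    dplyr::mutate(f, lineage_id = lineages$lineage_id[i])
  })
}

#' Build a Muller-style nested band table
#'
#' Converts nested lineage frequencies into the band widths of a Muller plot.
#' A lineage's frequency at a time point is, by default, the frequency of its
#' earliest defining mutation (which tags the whole genetic background; see
#' `freq_proxy` for the mean-of-defining-mutations alternative). Its band
#' width is that frequency minus the summed frequencies of its child
#' lineages, floored at zero; the residual ancestral band is one minus the
#' summed root-lineage frequencies, floored at zero. Flooring is bookkept:
#' the clipped mass is reported per band, so
#' `sum(band) - sum(floored) == 1` holds exactly at every time point.
#' A child lineage exceeding its parent by more than `tolerance` (possible
#' with noisy pooled frequency estimates) is recorded as a nesting violation
#' attached to the output, not an error.
#'
#' @param lineages Lineage tibble from [assign_lineages()].
#' @param series The population's [frequency_series()].
#' @param tolerance Nesting tolerance on the frequency scale (default 0.05,
#'   matching binomial noise at typical pooled coverage).
#' @param freq_proxy `"first"` (default) or `"mean"`.
#' @return An object of class `muller_table`: list with `bands` (tibble of
#'   `day`, `gen`, `lineage_id`, `parent_id`, `frequency`, `band`,
#'   `floored`), `violations` (tibble of `day`, `gen`, `lineage_id`,
#'   `excess`), and `tolerance`. The ancestral residual appears as lineage
#'   `"ancestral"`.
#' @export
build_muller_table <- function(lineages, series, tolerance = 0.05,
                               freq_proxy = c("first", "mean")) {
  freq_proxy <- match.arg(freq_proxy)
  stopifnot(inherits(series, "frequency_series"))
  tp <- series$timepoints

  if (nrow(lineages) == 0) {
    bands <- tibble::tibble(
      day = tp$day, gen = tp$gen, lineage_id = "ancestral",
      parent_id = NA_character_, frequency = 1, band = 1, floored = 0
    )
    return(structure(list(bands = bands,
                          violations = tibble::tibble(day = integer(0),
                                                      gen = integer(0),
                                                      lineage_id = character(0),
                                                      excess = numeric(0)),
                          tolerance = tolerance),
                     class = "muller_table"))
  }

  lf <- lineage_frequency(lineages, series, freq_proxy) |>
    dplyr::mutate(freq = ifelse(is.na(.data$freq), 0, .data$freq))

  children_of <- split(lineages$lineage_id, factor(lineages$parent_id,
                                                   levels = lineages$lineage_id))
  roots <- lineages$lineage_id[is.na(lineages$parent_id)]

  bands <- purrr::map_dfr(seq_len(nrow(tp)), function(ti) {
    d <- tp$day[ti]
    f <- stats::setNames(lf$freq[lf$day == d], lf$lineage_id[lf$day == d])
    raw <- vapply(lineages$lineage_id, function(l) {
      kids <- children_of[[l]]
      f[[l]] - sum(f[kids])
    }, numeric(1))
    raw <- c(raw, ancestral = 1 - sum(f[roots]))
    band <- pmax(raw, 0)
    tibble::tibble(
      day = d, gen = tp$gen[ti],
      lineage_id = c(lineages$lineage_id, "ancestral"),
      parent_id = c(lineages$parent_id, NA_character_),
      frequency = c(unname(f[lineages$lineage_id]), 1 - sum(f[roots])),
      band = unname(band),
      floored = unname(band - raw)
    )
  })

  violations <- bands |>
    dplyr::filter(.data$floored > tolerance) |>
    dplyr::transmute(.data$day, .data$gen, .data$lineage_id,
                     excess = .data$floored)
  if (nrow(violations) > 0) {
    warning(sprintf("%d nesting violation(s) beyond tolerance %g; see $violations.",
                    nrow(violations), tolerance), call. = FALSE)
  }

  structure(list(bands = bands, violations = violations, tolerance = tolerance),
            class = "muller_table")
}

#' @export
print.muller_table <- function(x, ...) {
  cat(sprintf("<muller_table> %d lineage band(s) x %d time point(s), %d nesting violation(s)\n",
              dplyr::n_distinct(x$bands$lineage_id),
              dplyr::n_distinct(x$bands$day), nrow(x$violations)))
  invisible(x)
}

#' @rdname build_muller_table
#' @param x A `muller_table`.
#' @param ... Unused.
#' @export
tidy.muller_table <- function(x, ...) x$bands

#' Lump similar-frequency mutations within a lineage
#'
#' Greedy single-linkage clustering along the lineage's within-edge order:
#' each mutation joins the cluster of its predecessor when the maximum
#' absolute per-time-point difference between their trajectories is at most
#' `max_gap` (so clusters can chain). The displayed trajectory of a cluster
#' is the per-time-point mean over its members. With `max_gap = 0` only
#' identical trajectories merge, leaving every displayed trajectory
#' unchanged.
#'
#' @param lineage A one-row lineage tibble (from [assign_lineages()]) or a
#'   character vector of mutation ids in within-lineage order.
#' @param series The population's [frequency_series()].
#' @param max_gap Maximum tolerated per-time-point frequency difference
#'   between adjacent mutations, in \[0, 1\]. No default: the lumping
#'   granularity is a presentation choice the caller must make.
#' @return List with `clusters` (tibble `mutation_id`, `cluster`) and
#'   `trajectories` (tibble `cluster`, `day`, `gen`, `freq` of per-cluster
#'   mean frequencies).
#' @export
lump_similar <- function(lineage, series, max_gap) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 ||
      is.na(max_gap) || max_gap < 0 || max_gap > 1) {
    stop("`max_gap` must be a single value in [0, 1].", call. = FALSE)
  }
  muts <- if (is.data.frame(lineage)) {
    stopifnot(nrow(lineage) == 1)
    lineage$defining_mutations[[1]]
  } else {
    as.character(lineage)
  }
  stopifnot(inherits(series, "frequency_series"))
  missing_ids <- setdiff(muts, series_mutations(series))
  if (length(missing_ids) > 0) {
    stop("Mutation(s) not in series: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  counts <- series$counts
  traj <- lapply(muts, function(m) {
    v <- counts[counts$mutation_id == m, , drop = FALSE]
    stats::setNames(v$freq, v$day)
  })
  cluster <- integer(length(muts))
  cur <- 0L
  for (i in seq_along(muts)) {
    if (i == 1) {
      cur <- 1L
    } else {
      diffs <- abs(traj[[i]] - traj[[i - 1]])
      gap <- if (all(is.na(diffs))) Inf else max(diffs, na.rm = TRUE)
      if (gap > max_gap) cur <- cur + 1L
    }
    cluster[i] <- cur
  }
  clusters <- tibble::tibble(mutation_id = muts, cluster = cluster)
  trajectories <- counts |>
    dplyr::filter(.data$mutation_id %in% muts) |>
    dplyr::left_join(clusters, by = "mutation_id") |>
    dplyr::group_by(.data$cluster, .data$day, .data$gen) |>
    dplyr::summarise(freq = mean(.data$freq), .groups = "drop") |>
    dplyr::arrange(.data$cluster, .data$day)
  list(clusters = clusters, trajectories = trajectories)
}

#' Write a Muller table TSV
#'
#' Long format consumable by standard Muller-plot renderers: `time_gen`,
#' `lineage_id`, `parent_id`, `band_frequency`, `flags`.
#'
#' @param muller A `muller_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_muller_table <- function(muller, path) {
  stopifnot(inherits(muller, "muller_table"))
  out <- muller$bands |>
    dplyr::transmute(
      time_gen = .data$gen, .data$lineage_id, .data$parent_id,
      band_frequency = .data$band,
      flags = ifelse(.data$floored > muller$tolerance, "nesting_violation", "")
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Plot a Muller table as stacked bands
#'
#' @param object A `muller_table`.
#' @param ... Unused.
#' @return A ggplot stacked-area chart of band widths over generations, with
#'   bands stacked in hierarchy (depth-first) order so children sit next to
#'   their parents.
#' @export
autoplot.muller_table <- function(object, ...) {
  bands <- object$bands
  lin <- unique(bands[c("lineage_id", "parent_id")])
  dfs_order <- function(parent) {
    kids <- lin$lineage_id[!is.na(lin$parent_id) & lin$parent_id %in% parent]
    if (length(kids) == 0) return(character(0))
    unlist(lapply(kids, function(k) c(k, dfs_order(k))))
  }
  roots <- setdiff(lin$lineage_id[is.na(lin$parent_id)], "ancestral")
  ord <- c("ancestral", unlist(lapply(roots, function(r) c(r, dfs_order(r)))))
  bands$lineage_id <- factor(bands$lineage_id, levels = rev(ord))
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$gen, y = .data$band,
                                      fill = .data$lineage_id)) +
    ggplot2::geom_area(position = "stack", colour = "grey30",
                       linewidth = 0.2) +
    ggplot2::labs(x = "Generation", y = "Frequency", fill = "Lineage") +
    ggplot2::theme_minimal()
}
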