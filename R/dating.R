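#' Date a mutation from the fossil record
#'
#' A mutation found in a sequenced clone is assumed to have arisen at the
#' midpoint (on the generation axis) between the first time point at which it
#' was detected in the fossil record and the previous sampled time point; a
#' mutation first detected at the very first sample is dated at the midpoint
#' of generation 0 and that sample. A mutation never detected in the record
#' (too rare to sample — the asterisked case) is assumed to have arisen near
#' the end: at the midpoint of the clone-extraction generation and the last
#' sample generation strictly before it, flagged `"near-end"`.
#'
#' The series should already have passed [apply_reporting_filters()], so that
#' single-read observations have been masked; detection here is at least one
#' alt read (positive exact frequency at infinite coverage).
#'
#' @param mutation_id Mutation identifier(s) present in `series`.
#' @param series A filtered [frequency_series()].
#' @param extraction_gen Generation at which the clones were extracted (e.g.
#'   `day_to_generation(156)` = 1045 for day-156 clones).
#' @return For [date_mutation()], a one-row tibble (`mutation_id`,
#'   `origin_gen`, `flag`); [date_mutations()] vectorises over ids.
#' @examples
#' # first detected at gen 482, previous sample gen 408 -> dated 445
#' @export
date_mutation <- function(mutation_id, series, extraction_gen) {
  stopifnot(length(mutation_id) == 1)
  date_mutations(mutation_id, series, extraction_gen)
}

#' @rdname date_mutation
#' @export
date_mutations <- function(mutation_id, series, extraction_gen) {
  stopifnot(inherits(series, "frequency_series"),
            is.numeric(extraction_gen), length(extraction_gen) == 1)
  known <- series_mutations(series)
  unknown <- setdiff(mutation_id, known)
  if (length(unknown) > 0) {
    stop("Unknown mutation id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  det <- series_detected(series)
  gens <- sort(series$timepoints$gen)
  pre_extraction <- gens[gens < extraction_gen]
  near_end_origin <- if (length(pre_extraction) == 0) {
    extraction_gen / 2
  } else {
    (max(pre_extraction) + extraction_gen) / 2
  }
  purrr::map_dfr(mutation_id, function(m) {
    d <- det[det$mutation_id == m & det$detected, , drop = FALSE]
    if (nrow(d) == 0) {
      return(tibble::tibble(mutation_id = m, origin_gen = near_end_origin,
                            flag = "near-end"))
    }
    first_gen <- min(d$gen)
    prev <- gens[gens < first_gen]
    prev_gen <- if (length(prev) == 0) 0 else max(prev)
    tibble::tibble(mutation_id = m, origin_gen = (prev_gen + first_gen) / 2,
                   flag = "")
  })
}

#' Date all mutations and divergences on a genealogy
#'
#' Dates every mutation on the tree with [date_mutations()], re-orders the
#' mutations within each edge by origin generation (ties broken by descending
#' mean frequency, then id), and dates each divergence (internal node,
#' including the root) at the midpoint between the last mutation the
#' diverging clones share (the latest mutation on the edge above the node)
#' and the first mutation they do not share (the earliest mutation on the
#' node's child edges). When either set is empty the divergence takes the
#' boundary of the non-empty set and is flagged `"one-sided"`; when both are
#' empty it is left undated and flagged `"undated"`.
#'
#' @param tree A `clone_genealogy` from [build_genealogy()].
#' @param series The filtered [frequency_series()] of the same population.
#' @param extraction_gen Clone-extraction generation (defaults to the clones'
#'   recorded extraction day converted with the series' generation scale).
#' @return The tree, dated: `mutation_dates` populated, `divergence_gen` and
#'   `divergence_flag` set on internal nodes, `dated = TRUE`.
#' @export
date_genealogy <- function(tree, series,
                           extraction_gen = day_to_generation(
                             max(tree$clones$extraction_day), series$scale)) {
  stopifnot(inherits(tree, "clone_genealogy"))
  muts <- unique(unlist(tree$nodes$mutations))
  dates <- if (length(muts) > 0) {
    date_mutations(muts, series, extraction_gen)
  } else {
    tibble::tibble(mutation_id = character(0), origin_gen = numeric(0),
                   flag = character(0))
  }
  origin <- stats::setNames(dates$origin_gen, dates$mutation_id)

  nodes <- tree$nodes
  nodes$mutations <- lapply(nodes$mutations, function(mm) {
    if (length(mm) <= 1) return(mm)
    ord <- order_edge_mutations(mm, series)
    ord[order(origin[ord])]  # stable: origin first, prior key breaks ties
  })

  for (i in which(nodes$type %in% c("internal", "root"))) {
    shared <- nodes$mutations[[i]]
    children <- which(nodes$parent_id == nodes$node_id[i] & !is.na(nodes$parent_id))
    unshared <- unlist(nodes$mutations[children])
    has_shared <- length(shared) > 0
    has_unshared <- length(unshared) > 0
    if (has_shared && has_unshared) {
      nodes$divergence_gen[i] <- (max(origin[shared]) + min(origin[unshared])) / 2
      nodes$divergence_flag[i] <- ""
    } else if (has_shared) {
      nodes$divergence_gen[i] <- max(origin[shared])
      nodes$divergence_flag[i] <- "one-sided"
    } else if (has_unshared) {
      nodes$divergence_gen[i] <- min(origin[unshared])
      nodes$divergence_flag[i] <- "one-sided"
    } else {
      nodes$divergence_gen[i] <- NA_real_
      nodes$divergence_flag[i] <- "undated"
    }
  }

  tree$nodes <- nodes
  tree$mutation_dates <- dates
  tree$dated <- TRUE
  tree$extraction_gen <- extraction_gen
  tree
}

#' Divergence date of one internal node
#'
#' @param tree A dated `clone_genealogy`.
#' @param node_id Node identifier (see `tree$nodes`).
#' @return One-row tibble with `node_id`, `divergence_gen`, `flag`.
#' @export
date_divergence <- function(tree, node_id) {
  stopifnot(inherits(tree, "clone_genealogy"))
  if (!tree$dated) stop("Tree must be dated first; see date_genealogy().",
                        call. = FALSE)
  i <- match(node_id, tree$nodes$node_id)
  if (is.na(i)) stop("Unknown node_id: ", node_id, call. = FALSE)
  tibble::tibble(node_id = node_id,
                 divergence_gen = tree$nodes$divergence_gen[i],
                 flag = tree$nodes$divergence_flag[i])
}

#' Tidy a genealogy into its mutation-edge table
#'
#' @param x A `clone_genealogy`.
#' @param ... Unused.
#' @return Tibble with one row per mutation: `mutation_id`, `edge` (the node
#'   below the edge carrying it), `origin_gen`, `flag` (dated trees only).
#' @export
tidy.clone_genealogy <- function(x, ...) {
  rows <- purrr::map_dfr(seq_len(nrow(x$nodes)), function(i) {
    mm <- x$nodes$mutations[[i]]
    if (length(mm) == 0) return(NULL)
    tibble::tibble(mutation_id = mm, edge = x$nodes$node_id[i])
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(mutation_id = character(0), edge = character(0),
                          origin_gen = numeric(0), flag = character(0)))
  }
  if (x$dated) {
    dplyr::left_join(rows, x$mutation_dates, by = "mutation_id")
  } else {
    dplyr::mutate(rows, origin_gen = NA_real_, flag = NA_character_)
  }
}

#' Convert a clone genealogy to an ape phylo tree
#'
#' Branch lengths are generation spans between dated divergences (leaves end
#' at the extraction generation); undated trees get unit branch lengths.
#' Internal node labels carry the divergence generation.
#'
#' @param x A `clone_genealogy` with at least two clones.
#' @param ... Unused.
#' @return An [ape][ape::read.tree] `phylo` object.
#' @export
as.phylo.clone_genealogy <- function(x, ...) {
  nodes <- x$nodes
  tips <- nodes$node_id[nodes$type == "leaf"]
  if (length(tips) < 2) {
    stop("Need at least two clones to build a phylo object.", call. = FALSE)
  }
  internals <- nodes$node_id[nodes$type %in% c("root", "internal")]
  internals <- c("root", setdiff(internals, "root"))
  idx <- stats::setNames(seq_along(c(tips, internals)), c(tips, internals))
  nonroot <- nodes[!is.na(nodes$parent_id), , drop = FALSE]
  edge <- cbind(unname(idx[nonroot$parent_id]), unname(idx[nonroot$node_id]))
  node_time <- function(i) {
    if (nodes$type[i] == "leaf") {
      if (x$dated) x$extraction_gen else NA_real_
    } else {
      nodes$divergence_gen[i]
    }
  }
  times <- vapply(seq_len(nrow(nodes)), node_time, numeric(1))
  names(times) <- nodes$node_id
  el <- times[nonroot$node_id] - times[nonroot$parent_id]
  el[!is.finite(el)] <- NA_real_
  if (all(is.na(el))) el <- rep(1, nrow(edge)) else el[is.na(el)] <- 0
  el <- pmax(el, 0)
  phy <- list(
    edge = edge,
    edge.length = unname(el),
    tip.label = tips,
    node.label = vapply(internals, function(n) {
      g <- nodes$divergence_gen[nodes$node_id == n]
      if (is.na(g)) "" else sprintf("gen%.1f", g)
    }, character(1)),
    Nnode = length(internals)
  )
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Write a genealogy as annotated Newick plus a mutation table
#'
#' Writes a Newick tree in which every edge carries a comment listing its
#' mutations and their origin generations, and a companion TSV of
#' `mutation_id`, `edge`, `origin_gen`, `flag` (see
#' [tidy.clone_genealogy()]). Plain unannotated Newick is also available via
#' [as.phylo.clone_genealogy()] and [ape::write.tree()].
#'
#' @param tree A `clone_genealogy`.
#' @param newick_path Output Newick path.
#' @param tsv_path Optional output TSV path.
#' @return `newick_path`, invisibly.
#' @export
write_genealogy <- function(tree, newick_path, tsv_path = NULL) {
  stopifnot(inherits(tree, "clone_genealogy"))
  nodes <- tree$nodes
  origin <- if (tree$dated) {
    stats::setNames(tree$mutation_dates$origin_gen, tree$mutation_dates$mutation_id)
  } else {
    numeric(0)
  }
  edge_comment <- function(i) {
    mm <- nodes$mutations[[i]]
    if (length(mm) == 0) return("")
    ann <- vapply(mm, function(m) {
      if (m %in% names(origin)) sprintf("%s:%.1f", m, origin[[m]]) else m
    }, character(1))
    paste0("[&mutations=", paste(ann, collapse = "|"), "]")
  }
  render <- function(node_id) {
    i <- which(nodes$node_id == node_id)
    children <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == node_id]
    label <- if (nodes$type[i] == "leaf") nodes$clone_id[i] else ""
    body <- if (length(children) == 0) label else {
      paste0("(", paste(vapply(children, render, character(1)), collapse = ","),
             ")", label)
    }
    paste0(body, edge_comment(i))
  }
  writeLines(paste0(render("root"), ";"), newick_path)
  if (!is.null(tsv_path)) {
    readr::write_tsv(tidy(tree), tsv_path, progress = FALSE)
  }
  invisible(newick_path)
}
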