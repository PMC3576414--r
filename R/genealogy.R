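#' Test clone genotypes for perfect-phylogeny compatibility
#'
#' Under the single-origin (infinite-sites, no-reversion) assumption, every
#' mutation arises exactly once, so the binary clone-by-mutation matrix rooted
#' at the all-zeros ancestor must pass the three-gamete test: no pair of
#' mutations may show all three patterns 11, 10, 01 across clones.
#'
#' @param clones Clone genotype tibble (see [clone_genotypes()]).
#' @return A tibble (the conflict report) with one row per violating mutation
#'   pair: `mutation_a`, `mutation_b`, and witnessing clones `clone_11`,
#'   `clone_10`, `clone_01`. Empty iff the matrix admits a perfect phylogeny.
#' @examples
#' clones <- tibble::tibble(
#'   clone_id = c("c1", "c2", "c3"), population_id = "p",
#'   ecotype = "SS", extraction_day = 156,
#'   mutations = list(c("A", "B"), "A", "B")
#' )
#' check_perfect_phylogeny(clones)  # A and B conflict
#' @export
check_perfect_phylogeny <- function(clones) {
  empty <- tibble::tibble(mutation_a = character(0), mutation_b = character(0),
                          clone_11 = character(0), clone_10 = character(0),
                          clone_01 = character(0))
  if (nrow(clones) == 0) return(empty)
  clones <- clone_genotypes(clones)
  muts <- sort(unique(unlist(clones$mutations)))
  if (length(muts) < 2) return(empty)
  sets <- lapply(muts, function(m) {
    clones$clone_id[vapply(clones$mutations, function(s) m %in% s, logical(1))]
  })
  names(sets) <- muts
  out <- list()
  for (i in seq_along(muts)[-length(muts)]) {
    for (j in seq((i + 1), length(muts))) {
      both <- intersect(sets[[i]], sets[[j]])
      only_a <- setdiff(sets[[i]], sets[[j]])
      only_b <- setdiff(sets[[j]], sets[[i]])
      if (length(both) > 0 && length(only_a) > 0 && length(only_b) > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          mutation_a = muts[i], mutation_b = muts[j],
          clone_11 = both[1], clone_10 = only_a[1], clone_01 = only_b[1]
        )
      }
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

#' Reconstruct a clone genealogy by perfect phylogeny
#'
#' Builds the rooted genealogy of sequenced endpoint clones from their shared
#' mutations: mutations carried by exactly the same subset of clones define
#' one edge, nested subsets define nested edges, and clones sharing no
#' mutations attach independently at the ancestral root. The construction
#' requires the genotype matrix to pass [check_perfect_phylogeny()].
#'
#' If the matrix conflicts (possible with miscalled linkage in pooled data),
#' the default is to fail with an error of class
#' `"clonetrace_phylogeny_conflict"` carrying the conflict report in its
#' `report` field. With `fallback = TRUE` and a frequency series, conflicting
#' mutations are dropped greedily (lowest maximum observed frequency first)
#' until the matrix is compatible; dropped ids are recorded on the result.
#'
#' @param clones Clone genotype tibble from one population.
#' @param series Optional [frequency_series()]; used to order mutations within
#'   an edge by first detection (falling back to descending mean frequency,
#'   then lexicographic id) and required for the conflict fallback.
#' @param fallback Drop conflicting mutations greedily instead of failing.
#' @return An object of class `clone_genealogy`: a list with `nodes` (tibble
#'   of `node_id`, `parent_id`, `type`, `clone_id`, list-columns `clones` and
#'   `mutations`, `divergence_gen`, `divergence_flag`), the input `clones`
#'   (minus any dropped mutations), `dropped`, and `dated` (FALSE until
#'   [date_genealogy()] is applied).
#' @export
build_genealogy <- function(clones, series = NULL, fallback = FALSE) {
  clones <- clone_genotypes(clones)
  if (nrow(clones) == 0) stop("Need at least one clone.", call. = FALSE)
  if (length(unique(clones$population_id)) > 1) {
    stop("A genealogy is reconstructed within one population.", call. = FALSE)
  }

  dropped <- character(0)
  repeat {
    report <- check_perfect_phylogeny(clones)
    if (nrow(report) == 0) break
    if (!fallback) {
      rlang::abort(
        message = sprintf(
          "Clone genotypes violate perfect phylogeny (%d conflicting pair(s), e.g. %s vs %s).",
          nrow(report), report$mutation_a[1], report$mutation_b[1]),
        class = "clonetrace_phylogeny_conflict",
        report = report
      )
    }
    if (is.null(series)) {
      stop("Conflict fallback requires a frequency series to rank mutations.",
           call. = FALSE)
    }
    in_conflict <- unique(c(report$mutation_a, report$mutation_b))
    maxf <- series$counts |>
      dplyr::filter(.data$mutation_id %in% in_conflict) |>
      dplyr::group_by(.data$mutation_id) |>
      dplyr::summarise(max_freq = max(.data$freq, 0, na.rm = TRUE),
                       .groups = "drop")
    maxf <- maxf[match(in_conflict, maxf$mutation_id), ]
    maxf$max_freq[is.na(maxf$max_freq)] <- 0
    drop_id <- in_conflict[order(maxf$max_freq, in_conflict)][1]
    dropped <- c(dropped, drop_id)
    clones$mutations <- lapply(clones$mutations, setdiff, y = drop_id)
  }

  muts <- sort(unique(unlist(clones$mutations)))
  carrier_key <- vapply(muts, function(m) {
    paste(sort(clones$clone_id[vapply(clones$mutations, function(s) m %in% s,
                                      logical(1))]), collapse = "\r")
  }, character(1))
  groups <- split(muts, carrier_key)
  set_keys <- names(groups)
  set_clones <- lapply(set_keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  sizes <- lengths(set_clones)

  # laminar family: parent of a set is its smallest proper superset
  parent_of_set <- vapply(seq_along(set_keys), function(i) {
    supersets <- which(sizes > sizes[i] &
                         vapply(set_clones, function(s)
                           all(set_clones[[i]] %in% s), logical(1)))
    if (length(supersets) == 0) return(NA_integer_)
    supersets[which.min(sizes[supersets])]
  }, integer(1))

  node_ids <- paste0("n", seq_along(set_keys))
  nodes <- tibble::tibble(
    node_id = node_ids,
    parent_id = ifelse(is.na(parent_of_set), "root", node_ids[parent_of_set]),
    type = "internal",
    clone_id = NA_character_,
    clones = set_clones,
    mutations = unname(groups)
  )

  # attach each clone below the smallest set containing it (or the root)
  leaf_rows <- lapply(seq_len(nrow(clones)), function(i) {
    cid <- clones$clone_id[i]
    containing <- which(vapply(set_clones, function(s) cid %in% s, logical(1)))
    parent <- if (length(containing) == 0) "root" else
      node_ids[containing[which.min(sizes[containing])]]
    tibble::tibble(node_id = cid, parent_id = parent, type = "leaf",
                   clone_id = cid, clones = list(cid),
                   mutations = list(character(0)))
  })
  nodes <- dplyr::bind_rows(
    tibble::tibble(node_id = "root", parent_id = NA_character_, type = "root",
                   clone_id = NA_character_, clones = list(clones$clone_id),
                   mutations = list(character(0))),
    nodes, dplyr::bind_rows(leaf_rows)
  )

  # suppress unary nodes: an internal node whose only child is a single leaf
  # (its carrier set is that one clone) merges with the leaf
  repeat {
    child_count <- table(nodes$parent_id[!is.na(nodes$parent_id)])
    unary <- nodes$node_id[nodes$type == "internal" &
                             nodes$node_id %in% names(child_count)[child_count == 1]]
    if (length(unary) == 0) break
    u <- unary[1]
    child <- which(nodes$parent_id == u)
    urow <- which(nodes$node_id == u)
    nodes$mutations[[child]] <- c(nodes$mutations[[urow]], nodes$mutations[[child]])
    nodes$parent_id[child] <- nodes$parent_id[urow]
    nodes <- nodes[-urow, , drop = FALSE]
  }

  nodes$divergence_gen <- NA_real_
  nodes$divergence_flag <- ""
  if (!is.null(series)) {
    nodes$mutations <- lapply(nodes$mutations, order_edge_mutations,
                              series = series)
  } else {
    nodes$mutations <- lapply(nodes$mutations, sort)
  }

  structure(
    list(nodes = nodes, clones = clones, dropped = dropped,
         dated = FALSE, extraction_gen = NA_real_, mutation_dates = NULL,
         population_id = clones$population_id[1]),
    class = "clone_genealogy"
  )
}

# order mutations on one edge: first-detection generation, then descending
# mean frequency across samples, then lexicographic id
order_edge_mutations <- function(muts, series) {
  if (length(muts) <= 1) return(muts)
  det <- series_detected(series) |>
    dplyr::filter(.data$mutation_id %in% muts) |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::summarise(
      first_gen = if (any(.data$detected)) min(.data$gen[.data$detected]) else Inf,
      mean_freq = mean(.data$freq, na.rm = TRUE),
      .groups = "drop"
    )
  det <- det[match(muts, det$mutation_id), ]
  first_gen <- ifelse(is.na(det$first_gen), Inf, det$first_gen)
  mean_freq <- ifelse(is.na(det$mean_freq), 0, det$mean_freq)
  muts[order(first_gen, -mean_freq, muts)]
}

#' @export
print.clone_genealogy <- function(x, ...) {
  cat(sprintf(
    "<clone_genealogy> population %s: %d clone(s), %d mutation(s) on %d edge(s)%s%s\n",
    x$population_id, nrow(x$clones),
    length(unlist(x$nodes$mutations)),
    sum(x$nodes$type != "root"),
    if (x$dated) ", dated" else "",
    if (length(x$dropped) > 0)
      paste0(" [dropped: ", paste(x$dropped, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' Reconstruct clone genotypes from a genealogy
#'
#' Unions the mutations along each root-to-leaf path; with an intact perfect
#' phylogeny this reproduces the input genotypes exactly.
#'
#' @param tree A `clone_genealogy`.
#' @return Tibble of `clone_id` and list-column `mutations`.
#' @export
reconstruct_clones <- function(tree) {
  stopifnot(inherits(tree, "clone_genealogy"))
  nodes <- tree$nodes
  leaf <- nodes$node_id[nodes$type == "leaf"]
  tibble::tibble(
    clone_id = leaf,
    mutations = lapply(leaf, function(l) {
      path <- character(0)
      cur <- l
      while (!is.na(cur)) {
        i <- which(nodes$node_id == cur)
        path <- c(path, nodes$mutations[[i]])
        cur <- nodes$parent_id[i]
      }
      sort(path)
    })
  )
}

#' Count independent origins of an ecotype
#'
#' Within each population, same-ecotype clones are grouped by the transitive
#' closure of "shares at least one mutation"; clones in different populations
#' never merge. The count of such groups is the number of independent origins
#' of the ecotype implied by the sequenced clones (e.g. two populations whose
#' SS clone pairs share mutations plus one population whose SS pair shares
#' none give 2x1 + 2 = 4 origins).
#'
#' @param clones Clone genotype tibble, possibly spanning populations.
#' @param ecotype Ecotype label to count (must be a valid label).
#' @return Integer count of independent origins.
#' @export
count_independent_origins <- function(clones, ecotype) {
  clones <- clone_genotypes(clones)
  if (!is.character(ecotype) || length(ecotype) != 1 ||
      !ecotype %in% c("FS", "SS", "ancestral", "unknown")) {
    stop("`ecotype` must be one of \"FS\", \"SS\", \"ancestral\", \"unknown\".",
         call. = FALSE)
  }
  sel <- clones[clones$ecotype == ecotype, , drop = FALSE]
  if (nrow(sel) == 0) return(0L)
  total <- 0L
  for (pop in unique(sel$population_id)) {
    sub <- sel[sel$population_id == pop, , drop = FALSE]
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
    total <- total + length(unique(vapply(seq_len(n), find, integer(1))))
  }
  total
}
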