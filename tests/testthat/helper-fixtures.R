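# fixture builders shared across the suite; everything is generated in code

paper_days <- c(0, 6, 12, 19, 30, 40, 51, 61, 72, 82, 96, 111, 124, 138, 156, 183)

# series from named list of alt-read vectors (one per mutation), fixed coverage
make_series <- function(alt, days, total = 100, pop = "p1", gens_per_day = 6.7) {
  counts <- purrr::map_dfr(names(alt), function(m) {
    tibble::tibble(mutation_id = m, day = days, alt_reads = alt[[m]],
                   total_reads = total)
  })
  frequency_series(counts, population_id = pop,
                   scale = generation_scale(gens_per_day))
}

# exact-frequency (infinite coverage) series from named list of freq vectors
make_exact_series <- function(freqs, days, pop = "p1", gens_per_day = 6.7) {
  counts <- purrr::map_dfr(names(freqs), function(m) {
    tibble::tibble(mutation_id = m, day = days, alt_reads = NA_integer_,
                   total_reads = Inf, freq = freqs[[m]])
  })
  frequency_series(counts, population_id = pop,
                   scale = generation_scale(gens_per_day))
}

make_clones <- function(mutations, ecotype = "SS", pop = "p1",
                        extraction_day = 156) {
  n <- length(mutations)
  clone_genotypes(tibble::tibble(
    clone_id = if (is.null(names(mutations))) paste0("c", seq_len(n)) else names(mutations),
    population_id = pop,
    ecotype = rep_len(ecotype, n),
    extraction_day = extraction_day,
    mutations = unname(mutations)
  ))
}

write_fastq <- function(path, seqs, quals, ids = paste0("r", seq_along(seqs))) {
  stopifnot(length(seqs) == length(quals))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# random genotypes guaranteed to admit a perfect phylogeny: a laminar family
# built by recursive random partition of the clone set (each group is split
# at most once, so children are disjoint), with mutations scattered over it
random_perfect_genotypes <- function(n_clones, n_mut, seed, pop = "p1") {
  set.seed(seed)
  family <- list(seq_len(n_clones))
  frontier <- family
  while (length(frontier) > 0) {
    g <- frontier[[1]]
    frontier <- frontier[-1]
    if (length(g) > 1 && stats::runif(1) < 0.8) {
      left <- sort(sample(g, sample.int(length(g) - 1, 1)))
      right <- sort(setdiff(g, left))
      family <- c(family, list(left), list(right))
      frontier <- c(frontier, list(left), list(right))
    }
  }
  sets <- replicate(n_clones, character(0), simplify = FALSE)
  for (m in seq_len(n_mut)) {
    g <- family[[sample.int(length(family), 1)]]
    id <- sprintf("m%03d", m)
    for (i in g) sets[[i]] <- c(sets[[i]], id)
  }
  make_clones(lapply(sets, sort), ecotype = "unknown", pop = pop)
}

mutation_row <- function(id, pop, position, ref, alt, gene, codon = NA,
                         mclass = "SNP", ecotype = NULL, starred = NULL) {
  out <- tibble::tibble(mutation_id = id, population_id = pop,
                        position = as.integer(position), ref_allele = ref,
                        alt_allele = alt, mclass = mclass, gene = gene,
                        codon = as.integer(codon), synonymous = NA)
  if (!is.null(ecotype)) out$ecotype <- ecotype
  if (!is.null(starred)) out$starred <- starred
  out
}
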