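#' Configuration for the Wright-Fisher fossil-record simulator
#'
#' Defines the study conditions the simulator emulates: a well-mixed asexual
#' population of constant effective size `ne` evolving by Wright-Fisher
#' resampling under beneficial mutation, drift, and (optionally) two-ecotype
#' negative frequency-dependent selection; sampled at discrete days with
#' binomial sequencing noise, plus clone draws at an extraction day. Defaults
#' mirror the serial-batch experiment the analysis is designed for:
#' `ne = 3.3e7`, 183 days at 6.7 generations per day (1226 generations), the
#' canonical 16 sampling days, and clone extraction at day 156
#' (generation 1045).
#'
#' @param ne Effective population size (positive integer).
#' @param n_generations Number of generations to simulate.
#' @param mu Beneficial-mutation rate per genome per generation; new
#'   mutations arise `Poisson(mu * ne)` per generation, each on a random
#'   genome. The default `1e-8` gives a beneficial supply `mu * ne` of
#'   order 0.3 per generation at the default `ne`.
#' @param s_dist Selection-coefficient distribution for new mutations:
#'   `list(kind = "fixed", value = s)` or
#'   `list(kind = "exponential", mean = m)` (default: exponential with
#'   mean 0.05, a typical scale for large-effect beneficial mutations in
#'   glucose-limited *E. coli*).
#' @param ecotype_model `NULL` (off) or the result of [ecotype_model()]:
#'   two-ecotype negative frequency dependence.
#' @param sampling_days Ordered integer days at which the fossil record is
#'   sampled.
#' @param gens_per_day Generations per day (default 6.7).
#' @param coverage Mean sequencing depth per time point: a single count, a
#'   vector (one per sampling day), or `Inf` for noise-free frequencies.
#' @param n_clones Number of endpoint clones to draw.
#' @param clone_day Day at which clones are drawn.
#' @param drift If `FALSE`, replace multinomial resampling by its
#'   expectation (the deterministic replicator limit; useful for fixed-point
#'   and recovery tests).
#' @param initial_genotypes Optional tibble to seed the population with named
#'   genotypes: columns `mutations` (list of mutation ids), `s_total`,
#'   `ecotype`, `freq` (summing to at most 1; the remainder is the
#'   mutation-free ancestor).
#' @param population_id Population label stamped on all outputs.
#' @param seed Integer seed; all randomness in [simulate_wf()],
#'   [sample_fossil_record()] and [sample_clones()] flows from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(ne = 3.3e7,
                       n_generations = day_to_generation(183),
                       mu = 1e-8,
                       s_dist = list(kind = "exponential", mean = 0.05),
                       ecotype_model = NULL,
                       sampling_days = c(0, 6, 12, 19, 30, 40, 51, 61, 72, 82,
                                         96, 111, 124, 138, 156, 183),
                       gens_per_day = 6.7,
                       coverage = 500,
                       n_clones = 4,
                       clone_day = 156,
                       drift = TRUE,
                       initial_genotypes = NULL,
                       population_id = "sim",
                       seed = 1L) {
  stopifnot(ne > 0, n_generations > 0, mu >= 0, gens_per_day > 0,
            n_clones >= 0, is.numeric(seed), length(seed) == 1)
  if (!s_dist$kind %in% c("fixed", "exponential")) {
    stop("`s_dist$kind` must be \"fixed\" or \"exponential\".", call. = FALSE)
  }
  scale <- generation_scale(gens_per_day)
  sampling_days <- sort(unique(as.integer(sampling_days)))
  if (any(day_to_generation(sampling_days, scale) > n_generations)) {
    stop("`sampling_days` extend beyond the simulated range.", call. = FALSE)
  }
  if (day_to_generation(clone_day, scale) > n_generations) {
    stop("`clone_day` is beyond the simulated range.", call. = FALSE)
  }
  if (length(coverage) != 1 && length(coverage) != length(sampling_days)) {
    stop("`coverage` must be scalar or one value per sampling day.",
         call. = FALSE)
  }
  structure(
    list(ne = ne, n_generations = as.integer(n_generations), mu = mu,
         s_dist = s_dist, ecotype_model = ecotype_model,
         sampling_days = sampling_days, gens_per_day = gens_per_day,
         scale = scale, coverage = coverage, n_clones = as.integer(n_clones),
         clone_day = as.integer(clone_day), drift = isTRUE(drift),
         initial_genotypes = initial_genotypes,
         population_id = population_id, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Two-ecotype negative frequency-dependent fitness model
#'
#' The simplest fitness scheme consistent with reciprocal niche construction:
#' a genotype of ecotype E gets a fitness contribution `a_E - b_E * x_E`,
#' linear and decreasing in the current total frequency `x_E` of its own
#' ecotype, on top of `1 +` the summed selection coefficients of its
#' mutations. With both `b` positive, each ecotype is favoured when rare,
#' admitting a protected interior equilibrium (coexistence); it is a labelled
#' stand-in for the unquantified ecological interaction, not an inference
#' about any real system.
#'
#' @param a Named numeric: base advantage per ecotype, e.g.
#'   `c(FS = 0.1, SS = 0.05)`. Names must be `"FS"` and `"SS"`.
#' @param b Named numeric: own-frequency penalty coefficient per ecotype.
#' @param switch_prob Probability that a new mutation switches its carrier's
#'   ecotype to the other label.
#' @param initial Ecotype of the founding genotype.
#' @return A list of class `ecotype_model`.
#' @export
ecotype_model <- function(a = c(FS = 0.1, SS = 0.05),
                          b = c(FS = 0.2, SS = 0.1),
                          switch_prob = 0.1,
                          initial = "FS") {
  labels <- c("FS", "SS")
  stopifnot(setequal(names(a), labels), setequal(names(b), labels),
            switch_prob >= 0, switch_prob <= 1, initial %in% labels)
  structure(list(labels = labels, a = a[labels], b = b[labels],
                 switch_prob = switch_prob, initial = initial),
            class = "ecotype_model")
}

draw_s <- function(s_dist, n) {
  switch(s_dist$kind,
    fixed = rep(s_dist$value, n),
    exponential = stats::rexp(n, rate = 1 / s_dist$mean)
  )
}

#' Simulate a Wright-Fisher population with full ground truth
#'
#' Discrete-generation Wright-Fisher dynamics on whole-genome genotypes (no
#' recombination, infinite sites): each generation, offspring counts are
#' multinomial with expected proportions `x_g * w_g / sum(x * w)`, where
#' `w_g = 1 + sum(s)` plus the frequency-dependent ecotype term when the
#' ecotype model is on; then `Poisson(mu * ne)` new mutations arise, each in
#' a random individual (parent genotype chosen by frequency), founding a new
#' genotype that carries its parent's mutations plus one new unique mutation.
#' Every event is recorded, so downstream reconstructions can be scored
#' against truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: list with `genotypes` (tibble:
#'   `genotype_id`, `parent_id`, `ecotype`, `origin_gen`, `new_mutation`,
#'   `s_total`, list-column `mutations` of the full mutation set), `mutations`
#'   (tibble: `mutation_id`, `genotype_id`, `origin_gen`, `s`,
#'   `ecotype_switch`), `freq` (genotype x generation frequency matrix with
#'   column names `"0" ... n_generations`), and `config`.
#' @export
simulate_wf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ne <- config$ne
  ngen <- config$n_generations
  em <- config$ecotype_model

  init_eco <- if (is.null(em)) "unknown" else em$initial
  gt_parent <- NA_integer_
  gt_eco <- init_eco
  gt_s <- 0
  gt_new_mut <- NA_character_
  gt_origin <- 0L
  count <- ne

  if (!is.null(config$initial_genotypes)) {
    ig <- tibble::as_tibble(config$initial_genotypes)
    stopifnot(all(c("mutations", "s_total", "ecotype", "freq") %in% names(ig)))
    if (sum(ig$freq) > 1 + 1e-12) stop("Initial frequencies exceed 1.",
                                       call. = FALSE)
    extra_counts <- if (config$drift) round(ig$freq * ne) else ig$freq * ne
    gt_parent <- c(gt_parent, rep(1L, nrow(ig)))
    gt_eco <- c(gt_eco, ig$ecotype)
    gt_s <- c(gt_s, ig$s_total)
    gt_new_mut <- c(gt_new_mut, vapply(seq_len(nrow(ig)), function(i)
      paste0("seed", i), character(1)))
    gt_origin <- c(gt_origin, rep(0L, nrow(ig)))
    count <- c(ne - sum(extra_counts), extra_counts)
    seed_muts <- ig$mutations
  } else {
    seed_muts <- list()
  }

  mut_id <- character(0)
  mut_genotype <- integer(0)
  mut_gen <- integer(0)
  mut_s <- numeric(0)
  mut_switch <- logical(0)

  freq_cols <- vector("list", ngen + 1)
  freq_cols[[1]] <- count / ne
  n_mut_counter <- 0L

  for (g in seq_len(ngen)) {
    x <- count / ne
    w <- 1 + gt_s
    if (!is.null(em)) {
      x_eco <- vapply(em$labels, function(l) sum(x[gt_eco == l]), numeric(1))
      contrib <- em$a[gt_eco] - em$b[gt_eco] * x_eco[gt_eco]
      contrib[!gt_eco %in% em$labels] <- 0
      w <- w + unname(contrib)
    }
    w <- pmax(w, 0)
    props <- x * w
    if (sum(props) <= 0) stop("Population fitness collapsed to zero.",
                              call. = FALSE)
    props <- props / sum(props)
    count <- if (config$drift) {
      as.numeric(stats::rmultinom(1, ne, props))
    } else {
      props * ne
    }

    if (config$mu > 0) {
      n_new <- stats::rpois(1, config$mu * ne)
      n_new <- min(n_new, floor(sum(count)))
      if (n_new > 0) {
        s_new <- draw_s(config$s_dist, n_new)
        for (k in seq_len(n_new)) {
          if (all(count < 1)) break
          parent <- sample.int(length(count), 1, prob = pmax(count, 0))
          if (count[parent] < 1) next
          count[parent] <- count[parent] - 1
          n_mut_counter <- n_mut_counter + 1L
          mid <- sprintf("m%04d", n_mut_counter)
          switch_eco <- !is.null(em) && stats::runif(1) < em$switch_prob
          eco <- gt_eco[parent]
          if (switch_eco && eco %in% em$labels) {
            eco <- setdiff(em$labels, eco)
          }
          gt_parent <- c(gt_parent, parent)
          gt_eco <- c(gt_eco, eco)
          gt_s <- c(gt_s, gt_s[parent] + s_new[k])
          gt_new_mut <- c(gt_new_mut, mid)
          gt_origin <- c(gt_origin, g)
          count <- c(count, 1)
          mut_id <- c(mut_id, mid)
          mut_genotype <- c(mut_genotype, length(count))
          mut_gen <- c(mut_gen, g)
          mut_s <- c(mut_s, s_new[k])
          mut_switch <- c(mut_switch, switch_eco)
        }
      }
    }
    freq_cols[[g + 1]] <- count / ne
  }

  n_gt <- length(count)
  freq <- matrix(0, nrow = n_gt, ncol = ngen + 1,
                 dimnames = list(NULL, as.character(0:ngen)))
  for (g in 0:ngen) {
    v <- freq_cols[[g + 1]]
    freq[seq_along(v), g + 1] <- v
  }

  # full mutation set per genotype: union along the parent chain
  full_sets <- vector("list", n_gt)
  for (i in seq_len(n_gt)) {
    own <- if (!is.na(gt_new_mut[i])) {
      if (startsWith(gt_new_mut[i], "seed")) {
        seed_muts[[as.integer(sub("seed", "", gt_new_mut[i]))]]
      } else {
        gt_new_mut[i]
      }
    } else {
      character(0)
    }
    full_sets[[i]] <- if (is.na(gt_parent[i])) own else
      union(full_sets[[gt_parent[i]]], own)
  }

  structure(
    list(
      genotypes = tibble::tibble(
        genotype_id = seq_len(n_gt), parent_id = gt_parent, ecotype = gt_eco,
        origin_gen = gt_origin, new_mutation = gt_new_mut, s_total = gt_s,
        mutations = full_sets
      ),
      mutations = tibble::tibble(
        mutation_id = mut_id, genotype_id = mut_genotype,
        origin_gen = mut_gen, s = mut_s, ecotype_switch = mut_switch
      ),
      freq = freq,
      config = config
    ),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d genotype(s), %d mutation(s) over %d generations (Ne = %g%s)\n",
    nrow(x$genotypes), nrow(x$mutations), x$config$n_generations, x$config$ne,
    if (is.null(x$config$ecotype_model)) "" else ", ecotype model on"
  ))
  invisible(x)
}

#' True mutation frequencies at chosen generations
#'
#' A mutation's true frequency is the summed frequency of the genotypes
#' carrying it (its origin genotype and all descendants).
#'
#' @param truth A `sim_truth`.
#' @param gens Generations at which to evaluate (default: all simulated).
#' @param mutation_id Mutations to include (default: all).
#' @return Tibble of `mutation_id`, `gen`, `freq`.
#' @export
mutation_frequencies <- function(truth, gens = NULL, mutation_id = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(gens)) gens <- as.integer(colnames(truth$freq))
  all_muts <- unique(c(truth$mutations$mutation_id,
                       unlist(truth$genotypes$mutations)))
  if (is.null(mutation_id)) mutation_id <- all_muts
  unknown <- setdiff(mutation_id, all_muts)
  if (length(unknown) > 0) {
    stop("Unknown mutation id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  muts <- mutation_id
  carrier <- lapply(muts, function(m) {
    which(vapply(truth$genotypes$mutations, function(s) m %in% s, logical(1)))
  })
  cols <- match(as.character(gens), colnames(truth$freq))
  if (any(is.na(cols))) stop("Generation(s) outside the simulated range.",
                             call. = FALSE)
  purrr::map_dfr(seq_along(muts), function(i) {
    f <- unname(colSums(truth$freq[carrier[[i]], cols, drop = FALSE]))
    tibble::tibble(mutation_id = muts[i], gen = as.integer(gens), freq = f)
  })
}

#' Sample a fossil record from simulated truth
#'
#' At each sampling day (converted to generations), each mutation's alt-read
#' count is drawn `Binomial(coverage, true frequency)` with
#' `total_reads = coverage`; infinite coverage records the exact true
#' frequencies. Mutations never present at any sampled generation are
#' omitted (they are unobservable in the record by construction).
#'
#' @param truth A `sim_truth`.
#' @param config A [sim_config()] (defaults to the one used to simulate).
#' @return A [frequency_series()].
#' @export
sample_fossil_record <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  days <- config$sampling_days
  gens <- day_to_generation(days, config$scale)
  gens <- pmin(gens, config$n_generations)
  coverage <- rep_len(config$coverage, length(days))

  tf <- mutation_frequencies(truth, gens = gens)
  tf$day <- days[match(tf$gen, gens)]
  present <- tf |>
    dplyr::group_by(.data$mutation_id) |>
    dplyr::summarise(any_present = any(.data$freq > 0), .groups = "drop")
  tf <- tf[tf$mutation_id %in% present$mutation_id[present$any_present], ,
           drop = FALSE]

  if (nrow(tf) == 0) {
    return(frequency_series(
      tibble::tibble(mutation_id = character(0), day = integer(0),
                     alt_reads = integer(0), total_reads = numeric(0)),
      population_id = config$population_id, scale = config$scale
    ))
  }

  cov_at <- coverage[match(tf$day, days)]
  finite <- is.finite(cov_at)
  alt <- rep(NA_integer_, nrow(tf))
  alt[finite] <- stats::rbinom(sum(finite), cov_at[finite], tf$freq[finite])
  counts <- tibble::tibble(
    mutation_id = tf$mutation_id, day = tf$day,
    alt_reads = alt, total_reads = cov_at,
    freq = ifelse(finite, NA_real_, tf$freq)
  )
  frequency_series(counts, population_id = config$population_id,
                   scale = config$scale)
}

#' Draw endpoint clones from simulated truth
#'
#' Draws `n_clones` genotypes at the clone day with probability proportional
#' to their frequency, copying mutation sets and ecotype labels from truth.
#'
#' @inheritParams sample_fossil_record
#' @return A clone genotype tibble (see [clone_genotypes()]).
#' @export
sample_clones <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  gen <- min(day_to_generation(config$clone_day, config$scale),
             config$n_generations)
  f <- truth$freq[, as.character(gen)]
  if (config$n_clones == 0) {
    return(clone_genotypes(tibble::tibble(
      clone_id = character(0), population_id = character(0),
      ecotype = character(0), extraction_day = integer(0), mutations = list()
    )))
  }
  picks <- sample.int(length(f), config$n_clones, replace = TRUE, prob = f)
  eco <- truth$genotypes$ecotype[picks]
  eco[lengths(truth$genotypes$mutations[picks]) == 0] <- "ancestral"
  eco[!eco %in% c("FS", "SS", "ancestral")] <- "unknown"
  clone_genotypes(tibble::tibble(
    clone_id = sprintf("%s_clone%02d", config$population_id, seq_along(picks)),
    population_id = config$population_id,
    ecotype = eco,
    extraction_day = config$clone_day,
    mutations = lapply(truth$genotypes$mutations[picks], sort)
  ))
}

#' Neutral Wright-Fisher trajectory replicates
#'
#' Vectorised binomial-chain simulation of a single neutral biallelic locus:
#' `n_rep` independent Wright-Fisher populations of size `ne` starting at
#' frequency `p0`, run for `n_generations`. This is the exact neutral special
#' case of [simulate_wf()] (two genotypes, no mutation, no selection) and is
#' the workhorse for calibrating the drift null: the across-replicate
#' variance of the frequency change over `t` generations should match
#' [drift_variance()]`(p0, t, ne)`.
#'
#' @param n_rep Number of replicate populations.
#' @param ne Population size.
#' @param p0 Initial allele frequency.
#' @param n_generations Generations to simulate.
#' @param record Generations at which to record frequencies (default: final
#'   generation only).
#' @param seed Integer seed.
#' @return Matrix of dimension `n_rep x length(record)` of allele
#'   frequencies, with `record` as column names.
#' @export
simulate_neutral_trajectories <- function(n_rep, ne, p0, n_generations,
                                          record = n_generations, seed = 1L) {
  stopifnot(ne > 0, p0 >= 0, p0 <= 1, n_generations >= 1)
  set.seed(seed)
  record <- sort(unique(as.integer(record)))
  stopifnot(all(record >= 0), all(record <= n_generations))
  p <- rep(p0, n_rep)
  out <- matrix(NA_real_, n_rep, length(record),
                dimnames = list(NULL, as.character(record)))
  if (0 %in% record) out[, "0"] <- p
  for (g in seq_len(n_generations)) {
    p <- stats::rbinom(n_rep, ne, p) / ne
    if (g %in% record) out[, as.character(g)] <- p
  }
  out
}

#' Serialise simulated truth to JSON
#'
#' @param truth A `sim_truth`.
#' @param path Output JSON path.
#' @param keep_freq Keep the full genotype-by-generation frequency matrix
#'   (can be large); default records only generations at the sampling days.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path, keep_freq = FALSE) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  keep_gens <- if (keep_freq) colnames(truth$freq) else
    as.character(unique(pmin(day_to_generation(cfg$sampling_days, cfg$scale),
                             cfg$n_generations)))
  obj <- list(
    config = cfg[c("ne", "n_generations", "mu", "sampling_days",
                   "gens_per_day", "n_clones", "clone_day", "drift",
                   "population_id", "seed")],
    genotypes = truth$genotypes |>
      dplyr::mutate(mutations = vapply(.data$mutations, paste, character(1),
                                       collapse = ";")),
    mutations = truth$mutations,
    freq = list(gens = as.integer(keep_gens),
                matrix = unname(truth$freq[, keep_gens, drop = FALSE]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# synthetic annotations so simulated mutations can be written in the variant
# TSV dialect (positions/alleles are arbitrary but consistent per id)
synthesize_annotations <- function(mutation_ids, population_id) {
  n <- length(mutation_ids)
  idx <- as.integer(factor(mutation_ids, levels = sort(mutation_ids)))
  bases <- c("A", "C", "G", "T")
  mutation_records(tibble::tibble(
    mutation_id = mutation_ids,
    population_id = population_id,
    position = 1000L * idx + 1L,
    ref_allele = bases[(idx %% 4) + 1],
    alt_allele = bases[((idx + 1) %% 4) + 1],
    mclass = "SNP",
    gene = paste0("gene", sprintf("%04d", idx)),
    codon = (idx %% 300) + 1L,
    synonymous = FALSE
  ))
}

#' Write a simulated dataset in the analysis input dialects
#'
#' Writes the sampled fossil record as a variant TSV (with synthetic
#' annotations) and the sampled clones as a clone TSV, exactly the formats
#' [read_variant_table()] and [read_clone_table()] read.
#'
#' @param truth A `sim_truth`.
#' @param variant_path Output variant TSV path.
#' @param clone_path Output clone TSV path.
#' @param config A [sim_config()].
#' @return Invisibly, list of the two paths.
#' @export
write_sim_tables <- function(truth, variant_path, clone_path,
                             config = truth$config) {
  series <- sample_fossil_record(truth, config)
  clones <- sample_clones(truth, config)
  muts <- union(series_mutations(series), unique(unlist(clones$mutations)))
  # the series must cover clone-only mutations too (all-zero rows)
  extra <- setdiff(muts, series_mutations(series))
  if (length(extra) > 0) {
    cov <- rep_len(config$coverage, length(config$sampling_days))
    add <- tidyr::expand_grid(mutation_id = extra,
                              day = config$sampling_days) |>
      dplyr::mutate(alt_reads = 0L,
                    total_reads = cov[match(.data$day, config$sampling_days)],
                    freq = ifelse(is.finite(.data$total_reads), NA_real_, 0))
    series <- frequency_series(dplyr::bind_rows(series$counts, add),
                               population_id = config$population_id,
                               scale = config$scale)
  }
  write_variant_table(synthesize_annotations(series_mutations(series),
                                             config$population_id),
                      series, variant_path)
  write_clone_table(clones, clone_path)
  invisible(list(variant = variant_path, clones = clone_path))
}
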