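small_cfg <- function(...) {
  args <- utils::modifyList(
    list(ne = 2000, n_generations = 150, mu = 5e-5,
         sampling_days = c(0, 50, 100, 150), gens_per_day = 1,
         coverage = 200, n_clones = 3, clone_day = 150, seed = 3),
    list(...))
  do.call(sim_config, args)
}

test_that("identical configurations reproduce bit-identical truth", {
  t1 <- simulate_wf(small_cfg())
  t2 <- simulate_wf(small_cfg())
  expect_identical(t1$freq, t2$freq)
  expect_identical(t1$genotypes, t2$genotypes)
  expect_identical(t1$mutations, t2$mutations)
  # and sampling is reproducible too
  expect_identical(sample_fossil_record(t1)$counts,
                   sample_fossil_record(t2)$counts)
  expect_identical(sample_clones(t1), sample_clones(t2))
  # a different seed gives different realisations
  t3 <- simulate_wf(small_cfg(seed = 4))
  expect_false(identical(t1$freq, t3$freq))
})

test_that("genotype frequencies are conserved exactly every generation", {
  truth <- simulate_wf(small_cfg())
  expect_equal(unname(colSums(truth$freq)), rep(1, ncol(truth$freq)),
               tolerance = 1e-12)
  expect_true(all(truth$freq >= 0))
})

test_that("without mutation a single genotype persists at frequency one", {
  cfg <- sim_config(ne = 500, n_generations = 50, mu = 0,
                    sampling_days = c(0, 25, 50), gens_per_day = 1,
                    coverage = 100, n_clones = 2, clone_day = 50, seed = 5)
  truth <- simulate_wf(cfg)
  expect_equal(nrow(truth$genotypes), 1)
  expect_true(all(truth$freq == 1))
  clones <- sample_clones(truth)
  expect_equal(clones$mutations, list(character(0), character(0)))
  expect_true(all(clones$ecotype == "ancestral"))
})

test_that("infinite coverage returns the exact true frequencies", {
  cfg <- small_cfg(coverage = Inf)
  truth <- simulate_wf(cfg)
  series <- sample_fossil_record(truth)
  gens <- day_to_generation(cfg$sampling_days, cfg$scale)
  tf <- mutation_frequencies(truth, gens = gens,
                             mutation_id = series_mutations(series))
  joined <- dplyr::left_join(series$counts, tf, by = c("mutation_id", "gen"),
                             suffix = c("", "_true"))
  expect_equal(joined$freq, joined$freq_true)
  expect_true(all(is.infinite(joined$total_reads)))
})

test_that("finite-coverage sampling has binomial moments", {
  # constant truth at frequency 0.3 (deterministic mode, no mutation)
  draws <- vapply(1:300, function(s) {
    cfg <- sim_config(
      ne = 1000, n_generations = 1, mu = 0, drift = FALSE,
      sampling_days = 1, gens_per_day = 1, coverage = 1000,
      n_clones = 0, clone_day = 1, seed = s,
      initial_genotypes = tibble::tibble(
        mutations = list("m1"), s_total = 0, ecotype = "unknown", freq = 0.3)
    )
    truth <- simulate_wf(cfg)
    fs <- sample_fossil_record(truth)
    fs$counts$alt_reads[fs$counts$mutation_id == "m1"] / 1000
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / 1000) / sqrt(300)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
  # true frequency zero draws zero reads
  expect_true(all(draws >= 0))
})

test_that("clone draws follow the genotype frequencies", {
  base <- function(s, n_clones) sim_config(
    ne = 1000, n_generations = 1, mu = 0, drift = FALSE,
    sampling_days = 1, gens_per_day = 1, coverage = 100,
    n_clones = n_clones, clone_day = 1, seed = s,
    initial_genotypes = tibble::tibble(
      mutations = list("m1"), s_total = 0, ecotype = "unknown", freq = 0.5)
  )
  # two genotypes at 0.5/0.5, two clones: one-each should occur about half
  # the time (2 * 0.5 * 0.5)
  one_each <- vapply(1:200, function(s) {
    cl <- sample_clones(simulate_wf(base(s, 2)))
    length(unique(vapply(cl$mutations, paste, character(1), collapse = ","))) == 2
  }, logical(1))
  expect_lt(abs(mean(one_each) - 0.5), 3 * sqrt(0.25 / 200))
  # n_clones = 0 gives an empty table
  expect_equal(nrow(sample_clones(simulate_wf(base(1, 0)))), 0)
})

test_that("the deterministic limit converges to the replicator fixed point", {
  # FS: 1 + 0.1 - 0.2 x_FS ; SS: 1 + 0.05 - 0.1 x_SS -> equal at x_FS = 0.5
  cfg <- sim_config(
    ne = 1e6, n_generations = 2000, mu = 0, drift = FALSE,
    ecotype_model = ecotype_model(a = c(FS = 0.1, SS = 0.05),
                                  b = c(FS = 0.2, SS = 0.1),
                                  switch_prob = 0, initial = "FS"),
    sampling_days = c(0, 2000), gens_per_day = 1, coverage = Inf,
    n_clones = 0, clone_day = 0, seed = 1,
    initial_genotypes = tibble::tibble(
      mutations = list("ssmut"), s_total = 0, ecotype = "SS", freq = 0.3)
  )
  truth <- simulate_wf(cfg)
  x_fs_final <- unname(truth$freq[1, ncol(truth$freq)])
  expect_equal(x_fs_final, 0.5, tolerance = 1e-4)
})

test_that("simulated tables round-trip through the analysis input formats", {
  cfg <- small_cfg()
  truth <- simulate_wf(cfg)
  vpath <- withr::local_tempfile(fileext = ".tsv")
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_sim_tables(truth, vpath, cpath)
  vt <- read_variant_table(vpath, scale = cfg$scale)
  cl <- read_clone_table(cpath)
  expect_identical(sort(series_mutations(vt$series)),
                   sort(union(series_mutations(sample_fossil_record(truth)),
                              unique(unlist(cl$mutations)))))
  expect_equal(vt$series$counts$alt_reads >= 0, rep(TRUE, nrow(vt$series$counts)))
  expect_true(all(unlist(cl$mutations) %in% vt$mutations$mutation_id))
  # truth serialises to JSON
  jpath <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(truth, jpath)
  obj <- jsonlite::read_json(jpath)
  expect_equal(length(obj$genotypes), nrow(truth$genotypes))
  expect_equal(obj$config$ne, cfg$ne)
})

test_that("neutral replicate trajectories start and stay in [0, 1]", {
  m <- simulate_neutral_trajectories(500, ne = 1000, p0 = 0.5,
                                     n_generations = 20,
                                     record = c(0, 10, 20), seed = 2)
  expect_equal(dim(m), c(500, 3))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(m[, "0"]), rep(0.5, 500))
  # unbiased: mean change centred on zero
  expect_lt(abs(mean(m[, "20"]) - 0.5), 4 * sqrt(drift_variance(0.5, 20, 1000) / 500))
})
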