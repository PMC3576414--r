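test_that("match levels resolve nucleotide, codon, gene, and none correctly", {
  muts <- dplyr::bind_rows(
    # identical intergenic insertion in two populations, same ecotype
    mutation_row("ins18", "p18", 5000, "-", "T", "yfbV/ackA",
                 mclass = "insertion", ecotype = "FS"),
    mutation_row("ins19", "p19", 5000, "-", "T", "yfbV/ackA",
                 mclass = "insertion", ecotype = "FS"),
    # same gene, same codon, different substitution, same ecotype
    mutation_row("n18", "p18", 881, "C", "T", "nadR", codon = 294, ecotype = "SS"),
    mutation_row("n19", "p19", 882, "C", "A", "nadR", codon = 294, ecotype = "SS"),
    # same gene but different ecotype: no match
    mutation_row("s18", "p18", 1200, "G", "A", "spoT", codon = 414, ecotype = "FS"),
    mutation_row("s19", "p19", 1300, "G", "T", "spoT", codon = 369, ecotype = "SS"),
    # unique to one population
    mutation_row("u20", "p20", 9999, "A", "C", "wecF", codon = 244, ecotype = "FS")
  )
  ps <- parallelism_levels(muts)
  lvl <- function(id) ps$per_mutation$match_level[ps$per_mutation$mutation_id == id]
  expect_equal(lvl("ins18"), "nucleotide")
  expect_equal(lvl("ins19"), "nucleotide")
  expect_equal(lvl("n18"), "codon")
  expect_equal(lvl("n19"), "codon")
  expect_equal(lvl("s18"), "none")
  expect_equal(lvl("s19"), "none")
  expect_equal(lvl("u20"), "none")
  expect_equal(ps$summary$n_matched[1], 4)
  expect_equal(ps$fraction_matched, 4 / 7)
})

test_that("a nucleotide match implies codon and gene agreement", {
  # same position/alleles in annotated genes: finest level wins, and the
  # coarser relations necessarily hold
  muts <- dplyr::bind_rows(
    mutation_row("a", "p18", 100, "A", "G", "pykF", codon = 10, ecotype = "SS"),
    mutation_row("b", "p19", 100, "A", "G", "pykF", codon = 10, ecotype = "SS")
  )
  ps <- parallelism_levels(muts)
  expect_true(all(ps$per_mutation$match_level == "nucleotide"))
  expect_true(all(ps$per_mutation$gene[ps$per_mutation$match_level == "nucleotide"] ==
                    "pykF"))
})

test_that("parallelism totals are invariant to population relabeling", {
  muts <- dplyr::bind_rows(
    mutation_row("a", "p18", 100, "A", "G", "nadR", codon = 290, ecotype = "SS"),
    mutation_row("b", "p19", 101, "A", "G", "nadR", codon = 290, ecotype = "SS"),
    mutation_row("c", "p20", 500, "C", "T", "ptsG", codon = 12, ecotype = "FS")
  )
  ps1 <- parallelism_levels(muts)
  relabeled <- dplyr::mutate(muts, population_id = dplyr::recode(
    population_id, p18 = "pA", p19 = "pB", p20 = "pC"))
  ps2 <- parallelism_levels(relabeled)
  expect_equal(ps1$summary[-1], ps2$summary[-1])
})

test_that("adding a mutation never worsens another mutation's match level", {
  rank <- c(none = 0, gene = 1, codon = 2, nucleotide = 3)
  base <- dplyr::bind_rows(
    mutation_row("a", "p18", 100, "A", "G", "nadR", codon = 290, ecotype = "SS"),
    mutation_row("b", "p19", 200, "C", "T", "nadR", codon = 294, ecotype = "SS")
  )
  before <- parallelism_levels(base)$per_mutation
  added <- dplyr::bind_rows(
    base, mutation_row("c", "p20", 100, "A", "G", "nadR", codon = 290,
                       ecotype = "SS"))
  after <- parallelism_levels(added)$per_mutation
  for (id in before$mutation_id) {
    expect_gte(rank[after$match_level[after$mutation_id == id]],
               rank[before$match_level[before$mutation_id == id]])
  }
})

test_that("starred (clone-only) mutations are reported in both denominators", {
  muts <- dplyr::bind_rows(
    mutation_row("a", "p18", 100, "A", "G", "nadR", codon = 290,
                 ecotype = "SS", starred = FALSE),
    mutation_row("b", "p19", 100, "A", "G", "nadR", codon = 290,
                 ecotype = "SS", starred = TRUE)
  )
  ps <- parallelism_levels(muts)
  expect_equal(ps$summary$scope, c("all", "unstarred"))
  expect_equal(ps$summary$n_total, c(2L, 1L))
  expect_error(parallelism_levels(muts[1, ]), "two populations")
})

test_that("the paired t-test matches the textbook formula on its worked case", {
  pc <- paired_t_test(data.frame(fs = c(3, 4, 5, 6), ss = c(1, 2, 2, 3)))
  # diffs {2,2,3,3}: t = 2.5 / (0.57735/2) = 8.660, df = 3
  expect_equal(pc$t_statistic, 8.660254, tolerance = 1e-6)
  expect_equal(pc$degrees_of_freedom, 3L)
  expect_equal(pc$two_tailed_p, 0.0032, tolerance = 0.02)
  # antisymmetry under column swap
  pc2 <- paired_t_test(data.frame(ss = c(1, 2, 2, 3), fs = c(3, 4, 5, 6)))
  expect_equal(pc2$t_statistic, -pc$t_statistic)
  expect_equal(pc2$two_tailed_p, pc$two_tailed_p)
})

test_that("paired t-test degenerate and error cases behave as specified", {
  same <- paired_t_test(data.frame(a = c(2, 3, 4), b = c(2, 3, 4)))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$two_tailed_p, 1)
  shifted <- paired_t_test(data.frame(a = c(3, 4, 5), b = c(1, 2, 3)))
  expect_equal(shifted$t_statistic, Inf)
  expect_equal(shifted$two_tailed_p, 0)
  expect_equal(shifted$flag, "zero_variance")
  expect_error(paired_t_test(data.frame(a = 1, b = 2)), "two pairs")
  expect_error(paired_t_test(data.frame(a = 1:3)), "two columns")
})

test_that("the implementation agrees with a closed-form oracle on random pairs", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- stats::rnorm(n, 5, 2)
    y <- stats::rnorm(n, 4, 2)
    pc <- paired_t_test(data.frame(x, y))
    d <- x - y
    t_oracle <- mean(d) / (stats::sd(d) / sqrt(n))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 1)
    expect_equal(pc$t_statistic, t_oracle, tolerance = 1e-10)
    expect_equal(pc$two_tailed_p, p_oracle, tolerance = 1e-10)
  }
})

test_that("independent FS/SS pairs reproduce the four-comparison structure", {
  # pop18: FS pair shares, SS pair shares -> 1 comparison
  # pop19: FS pair shares, SS pair disjoint -> 2 comparisons
  # pop20: FS pair shares, SS pair shares -> 1 comparison
  clones <- clone_genotypes(tibble::tibble(
    clone_id = paste0("k", 1:12),
    population_id = rep(c("p18", "p19", "p20"), each = 4),
    ecotype = rep(c("FS", "FS", "SS", "SS"), 3),
    extraction_day = 156,
    mutations = list(
      c("f1", "f2", "f3"), c("f1", "f2"), c("s1", "s2"), c("s1"),
      c("g1", "g2", "g3", "g4"), c("g1", "g2", "g3"), c("t1", "t2"), c("u1", "u2"),
      c("h1", "h2", "h3"), c("h1", "h2", "h4"), c("v1", "v2"), c("v1")
    )
  ))
  pairs <- fs_ss_pairs(clones)
  expect_equal(nrow(pairs), 4)
  expect_equal(sum(pairs$population_id == "p19"), 2)
  # within-origin clone counts are averaged before pairing
  p18 <- pairs[pairs$population_id == "p18", ]
  expect_equal(p18$fs_count, 2.5)
  expect_equal(p18$ss_count, 1.5)
  pc <- paired_t_test(pairs[c("fs_count", "ss_count")])
  expect_equal(pc$degrees_of_freedom, 3L)
})
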