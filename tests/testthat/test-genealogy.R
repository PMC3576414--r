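test_that("three-gamete test flags exactly the incompatible mutation pairs", {
  nested <- make_clones(list(c("A", "B"), "A", character(0)))
  expect_equal(nrow(check_perfect_phylogeny(nested)), 0)

  conflict <- make_clones(list(c("A", "B"), "A", "B"))
  rep <- check_perfect_phylogeny(conflict)
  expect_equal(nrow(rep), 1)
  expect_equal(c(rep$mutation_a, rep$mutation_b), c("A", "B"))
  expect_equal(rep$clone_11, "c1")

  # clones sharing no mutations are always compatible
  disjoint <- make_clones(list(c("s1", "s2"), c("s3", "s4")))
  expect_equal(nrow(check_perfect_phylogeny(disjoint)), 0)
  expect_equal(nrow(check_perfect_phylogeny(make_clones(list()[0]))), 0)
})

test_that("perfect-phylogeny construction recovers forced topologies", {
  clones <- make_clones(list(c("A", "B"), c("A", "C"), "D"))
  tree <- build_genealogy(clones)
  nodes <- tree$nodes
  # ((c1,c2),c3): one internal node above c1,c2 carrying A
  internal <- nodes[nodes$type == "internal", ]
  expect_equal(nrow(internal), 1)
  expect_setequal(internal$clones[[1]], c("c1", "c2"))
  expect_equal(internal$mutations[[1]], "A")
  expect_equal(nodes$parent_id[nodes$node_id == "c3"], "root")
  # private mutations sit on the leaf edges
  expect_equal(nodes$mutations[[which(nodes$node_id == "c1")]], "B")
  expect_equal(nodes$mutations[[which(nodes$node_id == "c3")]], "D")
})

test_that("independently arisen clones attach separately at the root", {
  # one population: two SS clones sharing nothing, two FS clones sharing most
  clones <- clone_genotypes(tibble::tibble(
    clone_id = c("SS1", "SS2", "FS1", "FS2"),
    population_id = "p19", ecotype = c("SS", "SS", "FS", "FS"),
    extraction_day = 156,
    mutations = list(c("s1", "s2"), c("s3", "s4"),
                     c("f1", "f2", "f3"), c("f1", "f2", "f4"))
  ))
  tree <- build_genealogy(clones)
  nodes <- tree$nodes
  expect_equal(nodes$parent_id[nodes$node_id == "SS1"], "root")
  expect_equal(nodes$parent_id[nodes$node_id == "SS2"], "root")
  cherry <- nodes[nodes$type == "internal", ]
  expect_equal(nrow(cherry), 1)
  expect_setequal(cherry$clones[[1]], c("FS1", "FS2"))
  expect_setequal(cherry$mutations[[1]], c("f1", "f2"))
})

test_that("a single clone yields a root-leaf tree with all mutations on one edge", {
  clones <- make_clones(list(c("A", "B", "C")))
  tree <- build_genealogy(clones)
  nodes <- tree$nodes
  expect_equal(nrow(nodes), 2)
  leaf <- nodes[nodes$type == "leaf", ]
  expect_equal(leaf$parent_id, "root")
  expect_setequal(leaf$mutations[[1]], c("A", "B", "C"))
})

test_that("conflicting genotypes fail loudly, carrying the conflict report", {
  clones <- make_clones(list(c("A", "B"), "A", "B"))
  err <- tryCatch(build_genealogy(clones), condition = function(c) c)
  expect_s3_class(err, "clonetrace_phylogeny_conflict")
  expect_equal(nrow(err$report), 1)
})

test_that("the greedy fallback drops the lowest-frequency conflicting mutation", {
  clones <- make_clones(list(c("A", "B"), "A", "B"))
  series <- make_series(list(A = c(0L, 30L, 60L), B = c(0L, 5L, 10L)),
                        days = c(0, 6, 12))
  tree <- build_genealogy(clones, series = series, fallback = TRUE)
  expect_equal(tree$dropped, "B")
  expect_false("B" %in% unlist(tree$nodes$mutations))
  expect_equal(nrow(check_perfect_phylogeny(tree$clones)), 0)
})

test_that("root-to-leaf unions reproduce the input genotypes on random instances", {
  for (seed in 1:8) {
    clones <- random_perfect_genotypes(n_clones = 6, n_mut = 15, seed = seed)
    expect_equal(nrow(check_perfect_phylogeny(clones)), 0)
    tree <- build_genealogy(clones)
    back <- reconstruct_clones(tree)
    for (i in seq_len(nrow(clones))) {
      expect_equal(back$mutations[[match(clones$clone_id[i], back$clone_id)]],
                   sort(clones$mutations[[i]]))
    }
    # no unary internal nodes
    kids <- table(tree$nodes$parent_id)
    internal <- tree$nodes$node_id[tree$nodes$type == "internal"]
    expect_true(all(kids[internal] >= 2))
  }
})

test_that("independent-origin counting matches the clone sharing structure", {
  # pop18 SS pair share, pop19 SS pair share none, pop20 SS pair share -> 4
  clones <- clone_genotypes(tibble::tibble(
    clone_id = paste0("s", 1:6),
    population_id = rep(c("p18", "p19", "p20"), each = 2),
    ecotype = "SS", extraction_day = 156,
    mutations = list(c("a1", "a2"), "a1", "b1", "b2", "c1", c("c1", "c2"))
  ))
  expect_identical(count_independent_origins(clones, "SS"), 4L)

  # all clones identical in one population -> 1
  same <- make_clones(list(c("x", "y"), c("x", "y"), c("x", "y")))
  expect_identical(count_independent_origins(same, "SS"), 1L)

  # pairwise-disjoint mutation sets -> n
  disjoint <- make_clones(list("a", "b", "c", "d"))
  expect_identical(count_independent_origins(disjoint, "SS"), 4L)

  # transitive closure: a-b share, b-c share, a-c do not -> one origin
  chain <- make_clones(list(c("u", "v"), c("v", "w"), c("w", "x")))
  expect_identical(count_independent_origins(chain, "SS"), 1L)

  expect_error(count_independent_origins(disjoint, "XX"), "ecotype")
})

test_that("origin counting is invariant to clone ordering", {
  clones <- clone_genotypes(tibble::tibble(
    clone_id = paste0("s", 1:6),
    population_id = rep(c("p18", "p19", "p20"), each = 2),
    ecotype = "SS", extraction_day = 156,
    mutations = list(c("a1", "a2"), "a1", "b1", "b2", "c1", c("c1", "c2"))
  ))
  set.seed(11)
  for (i in 1:5) {
    shuffled <- clones[sample.int(nrow(clones)), ]
    expect_identical(count_independent_origins(shuffled, "SS"), 4L)
  }
})
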