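# nested SS chain: background (rbs) -> insertion (mok) -> late nadR mutation,
# mirrored by three clones sampling successive backgrounds
nested_fixture <- function() {
  days <- c(0, 100, 200, 300, 400, 500, 600, 700)
  det_from <- function(day0, level) as.integer(days >= day0) * level
  series <- make_series(
    list(rbs = det_from(100, 80L), spoT = det_from(200, 75L),
         mok = det_from(300, 40L), nadR = det_from(650, 20L)),
    days = days, total = 100, gens_per_day = 1
  )
  clones <- make_clones(
    list(c("rbs", "spoT"), c("rbs", "spoT", "mok"),
         c("rbs", "spoT", "mok", "nadR")),
    ecotype = "SS", extraction_day = 700
  )
  tree <- date_genealogy(build_genealogy(clones, series = series), series,
                         extraction_gen = 700)
  list(series = series, clones = clones, tree = tree)
}

test_that("lineages nest parent-to-child along the genetic background chain", {
  fx <- nested_fixture()
  lin <- assign_lineages(fx$tree, fx$series)
  expect_equal(nrow(lin), 3)
  expect_equal(lin$lineage_id, c("L_rbs", "L_mok", "L_nadR"))
  expect_equal(lin$parent_id, c(NA, "L_rbs", "L_mok"))
  # rbs detected before spoT -> leads its edge; ecotype tag inherited
  expect_equal(lin$defining_mutations[[1]], c("rbs", "spoT"))
  expect_true(all(lin$ecotype == "SS"))
})

test_that("degenerate trees yield the expected lineage sets", {
  days <- c(0, 100, 200)
  series <- make_series(list(A = c(0L, 30L, 40L)), days = days,
                        gens_per_day = 1)
  one <- make_clones(list("A"))
  tree <- date_genealogy(build_genealogy(one, series = series), series, 200)
  lin <- assign_lineages(tree, series)
  expect_equal(nrow(lin), 1)
  expect_true(is.na(lin$parent_id))

  series2 <- make_series(list(A = c(0L, 30L, 40L), B = c(0L, 20L, 30L)),
                         days = days, gens_per_day = 1)
  two <- make_clones(list("A", "B"))
  tree2 <- date_genealogy(build_genealogy(two, series = series2), series2, 200)
  lin2 <- assign_lineages(tree2, series2)
  expect_equal(nrow(lin2), 2)
  expect_true(all(is.na(lin2$parent_id)))
})

test_that("band arithmetic follows the nesting definition", {
  days <- c(0, 10)
  series <- make_series(list(P = c(80L, 80L), K = c(30L, 30L)),
                        days = days, gens_per_day = 1)
  lineages <- tibble::tibble(
    lineage_id = c("L_P", "L_K"), parent_id = c(NA, "L_P"),
    defining_mutations = list("P", "K"), ecotype = "SS",
    node_id = c("n1", "n2")
  )
  mt <- build_muller_table(lineages, series)
  b <- dplyr::filter(mt$bands, day == 0)
  expect_equal(b$band[b$lineage_id == "L_P"], 0.5)   # 0.8 - 0.3
  expect_equal(b$band[b$lineage_id == "L_K"], 0.3)
  expect_equal(b$band[b$lineage_id == "ancestral"], 0.2)
  expect_equal(nrow(mt$violations), 0)
})

test_that("an empty lineage set gives an all-ancestral table", {
  series <- make_series(list(m = c(0L, 10L)), days = c(0, 10), gens_per_day = 1)
  mt <- build_muller_table(
    tibble::tibble(lineage_id = character(0), parent_id = character(0),
                   defining_mutations = list(), ecotype = character(0),
                   node_id = character(0)),
    series)
  expect_true(all(mt$bands$lineage_id == "ancestral"))
  expect_true(all(mt$bands$band == 1))
})

test_that("nesting violations are floored, reported, and bookkept exactly", {
  days <- c(0, 10)
  series <- make_series(list(P = c(50L, 50L), K = c(60L, 60L)),
                        days = days, gens_per_day = 1)
  lineages <- tibble::tibble(
    lineage_id = c("L_P", "L_K"), parent_id = c(NA, "L_P"),
    defining_mutations = list("P", "K"), ecotype = "SS",
    node_id = c("n1", "n2")
  )
  expect_warning(mt <- build_muller_table(lineages, series, tolerance = 0.05),
                 "violation")
  b <- dplyr::filter(mt$bands, day == 0)
  expect_equal(b$band[b$lineage_id == "L_K"], 0.6)
  expect_equal(b$band[b$lineage_id == "L_P"], 0)
  expect_equal(b$floored[b$lineage_id == "L_P"], 0.1)
  expect_equal(nrow(mt$violations), 2)  # both time points
  # conservation identity holds exactly even under flooring
  sums <- mt$bands |>
    dplyr::group_by(day) |>
    dplyr::summarise(s = sum(band) - sum(floored))
  expect_equal(sums$s, rep(1, 2))
})

test_that("conservation holds to machine precision on nested fixtures", {
  fx <- nested_fixture()
  lin <- assign_lineages(fx$tree, fx$series)
  mt <- build_muller_table(lin, fx$series)
  expect_equal(nrow(mt$violations), 0)
  sums <- mt$bands |>
    dplyr::group_by(day) |>
    dplyr::summarise(s = sum(band) - sum(floored))
  expect_equal(sums$s, rep(1, nrow(fx$series$timepoints)), tolerance = 1e-12)
})

test_that("similar-frequency lumping chains adjacent mutations greedily", {
  days <- c(0, 10, 20)
  series <- make_series(
    list(a = c(10L, 20L, 30L), b = c(13L, 17L, 30L), c = c(16L, 14L, 30L),
         z = c(50L, 60L, 70L)),
    days = days, gens_per_day = 1
  )
  # adjacent gaps 0.03, 0.03; end-to-end gap 0.06 > max_gap: still one
  # cluster by chaining
  out <- lump_similar(c("a", "b", "c"), series, max_gap = 0.05)
  expect_equal(out$clusters$cluster, c(1L, 1L, 1L))
  expect_equal(out$trajectories$freq[out$trajectories$day == 0],
               mean(c(0.10, 0.13, 0.16)))

  # max_gap = 0: identical trajectories merge, distinct ones stay apart
  out0 <- lump_similar(c("a", "b", "z"), series, max_gap = 0)
  expect_equal(out0$clusters$cluster, c(1L, 2L, 3L))
  dup <- make_series(list(a = c(10L, 20L, 30L), a2 = c(10L, 20L, 30L)),
                     days = days, gens_per_day = 1)
  outdup <- lump_similar(c("a", "a2"), dup, max_gap = 0)
  expect_equal(outdup$clusters$cluster, c(1L, 1L))
  expect_equal(outdup$trajectories$freq, c(0.1, 0.2, 0.3))

  expect_error(lump_similar(c("a", "b"), series, max_gap = -0.1), "max_gap")
  expect_error(lump_similar(c("a", "b"), series, max_gap = 1.5), "max_gap")
})
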