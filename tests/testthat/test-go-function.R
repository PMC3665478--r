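test_that("ancestor closure is transitive, total, and drops obsolete terms", {
  g <- read_obo(toy_obo_lines())
  expect_equal(ancestor_closure(g, "GO:0000003"),
               c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(ancestor_closure(g, character()), character())
  expect_error(ancestor_closure(g, "GO:9999999"),
               class = "sappred_lookup_error")
  # obsolete terms never appear in a closure
  expect_equal(ancestor_closure(g, "GO:0000004"), character())
})

test_that("closure equals brute-force reachability on random DAGs", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (i in 1:5) {
    g <- sappred:::synth_go_dag(30)
    live <- g$terms$id[!g$terms$obsolete]
    for (t in sample(live, 6)) {
      expect_equal(ancestor_closure(g, t), reachable_ancestors(g, t))
    }
    # multi-term input: union of closures
    pick <- sample(live, 3)
    expect_equal(ancestor_closure(g, pick), reachable_ancestors(g, pick))
  }
})

test_that("a part_of-free closure is available by config", {
  g <- read_obo(c("[Term]", "id: a", "",
                  "[Term]", "id: b", "relationship: part_of a", "",
                  "[Term]", "id: c", "is_a: b", ""))
  expect_equal(ancestor_closure(g, "c"), c("a", "b", "c"))
  expect_equal(ancestor_closure(g, "c", relations = "is_a"), c("b", "c"))
})

test_that("term statistics count variants, not proteins, over closures", {
  fx <- go_fixture()
  stats <- fit_term_stats(fx$train, fx$annotations, fx$graph)
  expect_equal(stats$d_tot, 5)
  expect_equal(stats$n_tot, 5)
  # closures: A -> {t1,t2,t3}; B -> {t1,t4}; C -> {t1,t2}
  # exhaustive hand tally per term over the 10 variants:
  #   t1: all 10 -> d=5, n=5
  #   t2: A's 3 + C's 3 -> d=4, n=2
  #   t3: A's 3 -> d=2, n=1
  #   t4: B's 4 -> d=1, n=3
  cnt <- function(t) unlist(stats$counts[stats$counts$term == t, c("d", "n")])
  expect_equal(unname(cnt("t1")), c(5, 5))
  expect_equal(unname(cnt("t2")), c(4, 2))
  expect_equal(unname(cnt("t3")), c(2, 1))
  expect_equal(unname(cnt("t4")), c(1, 3))

  # single-variant sanity: d_{t1}=1, totals (1, 0)
  one <- fit_term_stats(fx$train[1, ], fx$annotations, fx$graph)
  expect_equal(one$d_tot, 1)
  expect_equal(one$n_tot, 0)
  expect_equal(unname(unlist(
    one$counts[one$counts$term == "t1", c("d", "n")])), c(1, 0))

  # a protein with no annotations contributes only to the totals
  extra <- dplyr::bind_rows(fx$train,
                            tibble::tibble(protein_id = "Z", wt = "A",
                                           pos = 11L, mut = "V",
                                           label = "Disease"))
  s2 <- fit_term_stats(extra, fx$annotations, fx$graph)
  expect_equal(s2$d_tot, 6)
  expect_equal(s2$counts, stats$counts)

  expect_error(fit_term_stats(fx$train[0, ], fx$annotations, fx$graph),
               class = "sappred_fit_error")
})

test_that("the GO score matches a hand evaluation of the log-odds formula", {
  fx <- go_fixture()
  stats <- fit_term_stats(fx$train, fx$annotations, fx$graph)
  # protein annotated {t3}: closure {t1, t2, t3}; pi = 1, D = N = 5
  hand <- log2(((5 + 1) / 7) / ((5 + 1) / 7)) +
    log2(((4 + 1) / 7) / ((2 + 1) / 7)) +
    log2(((2 + 1) / 7) / ((1 + 1) / 7))
  got <- go_features("t3", stats, fx$graph)
  expect_equal(unname(got[["go_score"]]), hand, tolerance = 1e-12)
  expect_equal(unname(got[["n_terms"]]), 3)

  # no annotation -> the fixed (0, 0) fallback
  expect_equal(unname(go_features(character(), stats, fx$graph)),
               c(0, 0))

  # a term unseen in training contributes the smoothed zero-count ratio
  g2 <- read_obo(c("[Term]", "id: t1", "",
                   "[Term]", "id: t2", "is_a: t1", "",
                   "[Term]", "id: t3", "is_a: t2", "",
                   "[Term]", "id: t4", "is_a: t1", "",
                   "[Term]", "id: t5", "is_a: t1", ""))
  got2 <- go_features("t5", stats, g2)
  expect_equal(unname(got2[["n_terms"]]), 2)
  # closure {t1, t5}: t1 symmetric (0), t5 unseen -> log2(1/1) = 0
  expect_equal(unname(got2[["go_score"]]), 0)
})

test_that("symmetric counts give score zero and evidence shifts it monotonically", {
  fx <- go_fixture()
  stats <- fit_term_stats(fx$train, fx$annotations, fx$graph)
  # every-term-symmetric statistics: d == n, D == N -> score 0
  sym <- stats
  sym$counts$n <- sym$counts$d
  expect_equal(unname(go_features("t3", sym, fx$graph)[["go_score"]]), 0)
  # adding a disease-leaning term strictly increases the score
  base <- unname(go_features("t2", stats, fx$graph)[["go_score"]])
  more <- unname(go_features(c("t2", "t3"), stats, fx$graph)[["go_score"]])
  expect_gt(more, base)  # t3 has d=2 > n=1
  # set semantics: duplicated annotations change nothing
  expect_equal(go_features(c("t3", "t3", "t2"), stats, fx$graph),
               go_features(c("t2", "t3"), stats, fx$graph))
})

test_that("the leakage guard refuses proteins that shaped the statistics", {
  fx <- go_fixture()
  stats <- fit_term_stats(fx$train, fx$annotations, fx$graph, fold = 3)
  expect_error(go_features("t3", stats, fx$graph, protein_id = "A"),
               class = "sappred_leakage_error")
  # an unseen protein passes
  expect_silent(go_features("t3", stats, fx$graph, protein_id = "NEW"))
})
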