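test_that("metapath text notation parses and prints roundtrip", {
  s <- "PHSU-[AFFECTS>]-GNGM-[ASSOCIATED_WITH>]-DSYN"
  mp <- parse_metapath(s)
  expect_s3_class(mp, "metapath")
  expect_equal(nrow(mp), 2)
  expect_identical(format(mp), s)
  srev <- "DSYN-[ASSOCIATED_WITH<]-GNGM-[AFFECTS<]-PHSU"
  expect_identical(format(reverse_metapath(mp)), srev)
  expect_identical(format(parse_metapath(srev)), srev)
  expect_error(parse_metapath("PHSU-GNGM"), "not a metapath")
  expect_error(metapath(rbind(metapath_step("PHSU", "AFFECTS", "GNGM"),
                              metapath_step("DSYN", "TREATS", "DSYN"))),
               "type-compatible")
})

test_that("enumerate_metapaths finds exactly the instantiated templates", {
  g <- toy_graph()
  mps <- enumerate_metapaths(g, "PHSU", toy_cui[["D"]], max_len = 2)
  expect_length(mps, 1)
  expect_identical(format(mps[[1]]),
                   "PHSU-[AFFECTS>]-GNGM-[ASSOCIATED_WITH>]-DSYN")
  expect_length(enumerate_metapaths(g, "PHSU", toy_cui[["D"]], max_len = 1), 0)
  expect_error(enumerate_metapaths(g, "PHSU", toy_cui[["D"]], max_len = 0),
               "max_len")
  expect_error(enumerate_metapaths(g, "PHSU", "C9999999"), "not in graph")
})

test_that("reverse traversal steps are discovered", {
  # only connection: D-CAUSES->g (so PHSU reaches D via a reverse step)
  g <- knowledge_graph(
    data.frame(cui = c("C9000011", "C9000012", "C9000013"),
               name = c("d", "g", "D"),
               semtype = c("PHSU", "GNGM", "DSYN")),
    data.frame(subject_cui = c("C9000011", "C9000013"),
               predicate = c("AFFECTS", "CAUSES"),
               object_cui = c("C9000012", "C9000012"))
  )
  mps <- enumerate_metapaths(g, "PHSU", "C9000013", max_len = 2)
  expect_length(mps, 1)
  expect_identical(format(mps[[1]]), "PHSU-[AFFECTS>]-GNGM-[CAUSES<]-DSYN")
})

test_that("count_paths matches hand enumeration and reversal symmetry holds", {
  g <- toy_graph()
  mp <- toy_mp()
  expect_equal(count_paths(g, toy_cui[["d1"]], toy_cui[["D"]], mp), 2)
  expect_equal(count_paths(g, toy_cui[["d2"]], toy_cui[["D"]], mp), 1)
  # no instance
  expect_equal(count_paths(g, toy_cui[["g1"]], toy_cui[["g2"]],
                           parse_metapath("GNGM-[AFFECTS>]-GNGM")), 0)
  expect_error(count_paths(g, toy_cui[["g1"]], toy_cui[["D"]], mp),
               "semtype")
  # reversal symmetry on random graphs
  for (seed in 1:5) {
    gr <- random_kg(seed)
    cases <- random_scored_cases(gr, seed + 100, max_len = 3)
    for (cs in cases) {
      expect_equal(
        count_paths(gr, cs$s, cs$t, cs$mp),
        count_paths(gr, cs$t, cs$s, reverse_metapath(cs$mp))
      )
    }
  }
})

test_that("dwpc reproduces hand-computed values and reduces to path count at w = 0", {
  g <- toy_graph()
  mp <- toy_mp()
  # degrees: d1 = 2, d2 = 1, g1 = 3, g2 = 2, D = 2
  expect_equal(dwpc(g, toy_cui[["d1"]], toy_cui[["D"]], mp, w = 0.5),
               (2 * 3 * 2)^-0.5 + (2 * 2 * 2)^-0.5, tolerance = 1e-12)
  expect_equal(dwpc(g, toy_cui[["d1"]], toy_cui[["D"]], mp, 0.5), 0.6423,
               tolerance = 2e-4)
  expect_equal(dwpc(g, toy_cui[["d2"]], toy_cui[["D"]], mp, 0.5), 0.4082,
               tolerance = 2e-4)
  for (seed in 1:5) {
    gr <- random_kg(seed)
    for (cs in random_scored_cases(gr, seed + 200)) {
      expect_equal(dwpc(gr, cs$s, cs$t, cs$mp, w = 0),
                   count_paths(gr, cs$s, cs$t, cs$mp))
      # non-increasing in w when at least one instance exists
      vals <- vapply(c(0, 0.25, 0.5, 1),
                     function(w) dwpc(gr, cs$s, cs$t, cs$mp, w), numeric(1))
      expect_true(all(diff(vals) <= 1e-12))
    }
  }
})

test_that("enumerate_metapaths is invariant to triple-file row order", {
  g <- random_kg(3)
  t <- g$nodes$cui[which(node_degree(g) > 0)[1]]
  mps1 <- enumerate_metapaths(g, unique(g$nodes$semtype), t, max_len = 2)
  e <- g$edges
  shuffled <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  g2 <- knowledge_graph(g$nodes[sample(nrow(g$nodes)), , drop = FALSE],
                        shuffled)
  mps2 <- enumerate_metapaths(g2, unique(g$nodes$semtype), t, max_len = 2)
  expect_identical(vapply(mps1, format, character(1)),
                   vapply(mps2, format, character(1)))
})
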