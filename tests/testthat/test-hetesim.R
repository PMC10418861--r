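test_that("transition operators are row-stochastic with the expected masses", {
  g <- toy_graph()
  step <- metapath_step("PHSU", "AFFECTS", "GNGM")
  op <- transition_operator(g, step)
  expect_equal(unname(op[toy_cui[["d1"]], c(toy_cui[["g1"]], toy_cui[["g2"]])]),
               c(0.5, 0.5))
  rs <- Matrix::rowSums(op)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  # weighted: 3:1 support splits 0.75 / 0.25
  gw <- knowledge_graph(
    g$nodes,
    data.frame(subject_cui = c("C9000001", "C9000001"),
               predicate = "AFFECTS",
               object_cui = c("C9000003", "C9000004"),
               support_count = c(3L, 1L)))
  opw <- transition_operator(gw, step, weighted = TRUE)
  expect_equal(unname(opw[toy_cui[["d1"]], c(toy_cui[["g1"]], toy_cui[["g2"]])]),
               c(0.75, 0.25))
  # relation with zero edges: all-zero operator plus a warning
  expect_warning(op0 <- transition_operator(g, metapath_step("PHSU", "TREATS", "DSYN")),
                 "no edges")
  expect_equal(sum(op0), 0)
})

test_that("hetesim reproduces the hand-computed toy values", {
  g <- toy_graph()
  mp <- toy_mp()
  expect_equal(hetesim_score(g, toy_cui[["d1"]], toy_cui[["D"]], mp), 1.0,
               tolerance = 1e-12)
  expect_equal(hetesim_score(g, toy_cui[["d2"]], toy_cui[["D"]], mp),
               1 / sqrt(2), tolerance = 1e-12)
  expect_error(hetesim_score(g, toy_cui[["g1"]], toy_cui[["D"]], mp),
               "semtype")
})

test_that("unreachable pairs score zero and palindromes score one", {
  g <- knowledge_graph(
    rbind(toy_graph()$nodes,
          data.frame(cui = "C9000006", name = "d3", semtype = "PHSU")),
    toy_graph()$edges)
  mp <- toy_mp()
  expect_equal(hetesim_score(g, "C9000006", toy_cui[["D"]], mp), 0)
  expect_equal(hetesim_brute_force(g, "C9000006", toy_cui[["D"]], mp), 0)
  pal <- concat_metapaths(mp, reverse_metapath(mp))
  expect_equal(hetesim_score(g, toy_cui[["d1"]], toy_cui[["d1"]], pal), 1.0,
               tolerance = 1e-12)
  expect_equal(hetesim_score(g, toy_cui[["d2"]], toy_cui[["d2"]], pal), 1.0,
               tolerance = 1e-12)
})

test_that("matrix and walk-enumeration implementations agree on random graphs", {
  for (seed in 1:12) {
    g <- random_kg(seed, n_nodes = 25, n_edges = 50)
    for (cs in random_scored_cases(g, seed + 300, max_len = 3)) {
      expect_equal(hetesim_score(g, cs$s, cs$t, cs$mp),
                   hetesim_brute_force(g, cs$s, cs$t, cs$mp),
                   tolerance = 1e-9)
    }
  }
})

test_that("hetesim scores stay in [0, 1] and obey reversal symmetry", {
  for (seed in 1:8) {
    g <- random_kg(seed + 40)
    for (cs in random_scored_cases(g, seed + 400, max_len = 3)) {
      all_scores <- hetesim_all_sources(g, cs$t, cs$mp)
      expect_true(all(all_scores >= 0 & all_scores <= 1))
      expect_equal(hetesim_score(g, cs$s, cs$t, cs$mp),
                   hetesim_score(g, cs$t, cs$s, reverse_metapath(cs$mp)),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding a shared midpoint neighbor never decreases a length-2 score", {
  # s and t share g1; adding shared neighbor g2 must not lower the score
  nodes <- data.frame(cui = sprintf("C910000%d", 1:4),
                      name = c("s", "t", "g1", "g2"),
                      semtype = c("PHSU", "DSYN", "GNGM", "GNGM"))
  mp <- parse_metapath("PHSU-[AFFECTS>]-GNGM-[ASSOCIATED_WITH<]-DSYN")
  base_edges <- data.frame(
    subject_cui = c("C9100001", "C9100002"),
    predicate = c("AFFECTS", "ASSOCIATED_WITH"),
    object_cui = c("C9100003", "C9100003"))
  g0 <- knowledge_graph(nodes, base_edges)
  extra <- data.frame(
    subject_cui = c("C9100001", "C9100002"),
    predicate = c("AFFECTS", "ASSOCIATED_WITH"),
    object_cui = c("C9100004", "C9100004"))
  g1 <- knowledge_graph(nodes, rbind(base_edges, extra))
  s0 <- hetesim_score(g0, "C9100001", "C9100002", mp)
  s1 <- hetesim_score(g1, "C9100001", "C9100002", mp)
  expect_gte(s1 + 1e-12, s0)
})

test_that("brute-force oracle guard refuses oversized enumerations", {
  g <- random_kg(99, n_nodes = 30, n_edges = 120)
  cs <- random_scored_cases(g, 99, max_len = 3)
  expect_error(
    hetesim_brute_force(g, cs[[1]]$s, cs[[1]]$t, cs[[1]]$mp,
                        max_extensions = 0),
    "guard")
})

test_that("aggregate_hetesim averages over metapaths then targets", {
  g <- toy_graph()
  mp <- toy_mp()
  mp_dead <- parse_metapath("PHSU-[TREATS>]-GNGM-[ASSOCIATED_WITH>]-DSYN")
  # d1: scores {1.0 on mp, 0 on dead metapath} -> 0.5
  expect_equal(
    suppressWarnings(
      aggregate_hetesim(g, toy_cui[["d1"]], toy_cui[["D"]],
                        list(mp, mp_dead))),
    0.5, tolerance = 1e-12)
  # two targets average per-target aggregates
  g2 <- knowledge_graph(
    rbind(g$nodes, data.frame(cui = "C9000007", name = "D2", semtype = "DSYN")),
    rbind(g$edges, data.frame(subject_cui = "C9000003", predicate = "ASSOCIATED_WITH",
                              object_cui = "C9000007", support_count = 1L)))
  v1 <- aggregate_hetesim(g2, toy_cui[["d1"]], toy_cui[["D"]], list(mp))
  v2 <- aggregate_hetesim(g2, toy_cui[["d1"]], "C9000007", list(mp))
  both <- aggregate_hetesim(g2, toy_cui[["d1"]], c(toy_cui[["D"]], "C9000007"),
                            list(mp))
  expect_equal(both, (v1 + v2) / 2, tolerance = 1e-12)
  expect_error(aggregate_hetesim(g, toy_cui[["d1"]], toy_cui[["D"]], list()),
               "non-empty")
})
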