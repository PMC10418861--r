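test_that("normalize_scores follows the min-max contract", {
  expect_equal(normalize_scores(c(0.8, 0.5, 0.2)), c(1.0, 0.5, 0.0))
  expect_equal(normalize_scores(c(0.4, 0.4)), c(1.0, 1.0))
  expect_equal(normalize_scores(0.9), 1.0)
  expect_equal(normalize_scores(c(0.8, 0.2), method = "none"), c(0.8, 0.2))
  expect_error(normalize_scores(numeric(0)), "empty")
})

test_that("rank aggregation fixed points, tie-breaks and invariances", {
  rk <- list(c("x", "y", "z"), c("x", "y", "z"))
  for (m in c("mean_rank", "weighted_iterative")) {
    out <- aggregate_ranks(rk, method = m)
    expect_identical(out$cui, c("x", "y", "z"))
  }
  # hand-computed mean-rank example: means x 1.5, y 1.5, z 3.0
  out <- aggregate_ranks(list(c("x", "y", "z"), c("y", "x", "z")),
                         method = "mean_rank")
  expect_identical(out$cui, c("x", "y", "z"))
  expect_equal(out$consensus, c(1.5, 1.5, 3.0))
  # permutation invariance of the input rankings
  rks <- list(c("a", "b", "c"), c("b", "c", "a"), c("c", "a", "b"))
  for (m in c("mean_rank", "weighted_iterative")) {
    o1 <- aggregate_ranks(rks, method = m)
    o2 <- aggregate_ranks(rev(rks), method = m)
    expect_identical(o1$cui, o2$cui)
  }
  # single ranker reduces to its own order
  expect_identical(
    aggregate_ranks(list(c("q", "p", "r")), method = "weighted_iterative")$cui,
    c("q", "p", "r"))
  # absent candidates are imputed rank length + 1
  out <- aggregate_ranks(list(c("a", "b"), c("a", "c")), method = "mean_rank")
  expect_identical(out$cui[1], "a")
  expect_error(aggregate_ranks(list()), "at least one")
})

test_that("weighted aggregation down-weights an adversarially inverted ranker", {
  set.seed(5)
  truth <- sprintf("c%02d", 1:15)
  rks <- c(replicate(3, truth, simplify = FALSE), list(rev(truth)))
  out <- aggregate_ranks(rks, method = "weighted_iterative")
  tau <- stats::cor(match(truth, out$cui), seq_along(truth),
                    method = "kendall")
  expect_gt(tau, 0)
  expect_identical(out$cui, truth)
})

test_that("run_simulation ranks the toy graph as hand-computed", {
  g <- toy_graph()
  spec <- simulation_spec("toy", toy_cui[["D"]], "PHSU",
                          max_metapath_length = 2)
  res <- run_simulation(g, spec)
  expect_s3_class(res, "ranked_result")
  expect_identical(res$source_cui, unname(toy_cui[c("d1", "d2")]))
  expect_equal(res$raw_score, c(1.0, 1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(res$normalized_score, c(1.0, 0.0))
  expect_equal(res$rank, c(1, 2))
  expect_equal(res$n_metapaths, c(1L, 1L))
})

test_that("run_simulation handles missing candidates and absent targets", {
  g <- toy_graph()
  expect_warning(
    res <- run_simulation(g, simulation_spec("none", toy_cui[["D"]], "CLND")),
    "no candidate")
  expect_equal(nrow(res), 0)
  expect_error(
    run_simulation(g, simulation_spec("bad", "C9999999", "PHSU")),
    "C9999999")
  # targets are never returned as sources
  res2 <- run_simulation(g, simulation_spec("t", toy_cui[["d1"]], "PHSU",
                                            max_metapath_length = 2))
  expect_false(toy_cui[["d1"]] %in% res2$source_cui)
})

test_that("run_simulation is a pure function of graph and spec", {
  gen <- generate_kg(synthetic_config(seed = 11,
                                      background_edge_count = 800))
  spec <- simulation_spec("det", gen$truth$target_disease_cui,
                          c("PHSU", "CLND"), max_metapath_length = 2,
                          dwpc_exponent = 0.8)
  r1 <- run_simulation(gen$graph, spec)
  r2 <- run_simulation(gen$graph, spec)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_ranked_results(r1, f1)
  write_ranked_results(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("rank-aggregation scoring mode produces a full consistent ranking", {
  g <- toy_graph()
  spec <- simulation_spec("ra", toy_cui[["D"]], "PHSU",
                          max_metapath_length = 2,
                          aggregation = "rank_aggregation")
  res <- run_simulation(g, spec)
  expect_equal(nrow(res), 2)
  expect_identical(res$source_cui[1], toy_cui[["d1"]])
  expect_true(all(res$normalized_score >= 0 & res$normalized_score <= 1))
})
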