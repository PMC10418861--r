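make_ranked <- function(cuis, scores, semtypes = "PHSU",
                        names = cuis, sim = "test") {
  ord <- order(-scores, cuis)
  r <- data.frame(rank = seq_along(cuis), source_cui = cuis[ord],
                  source_name = names[ord],
                  source_semtype = rep_len(semtypes, length(cuis))[ord],
                  raw_score = scores[ord], normalized_score = scores[ord],
                  hetesim_score = scores[ord], dwpc_score = scores[ord],
                  n_metapaths = 1L, stringsAsFactors = FALSE)
  attr(r, "spec") <- simulation_spec(sim, "C9000001", "PHSU")
  class(r) <- c("ranked_result", "data.frame")
  r
}

test_that("select_hubs applies threshold, cap and semtype quota", {
  r <- make_ranked(c("C9300001", "C9300002", "C9300003"),
                   c(0.927, 0.499, 0.341),
                   names = c("granuloma", "liver injury", "renal"),
                   semtypes = c("DSYN", "DSYN", "DSYN"))
  sel <- select_hubs(r, threshold = 0.2, max_hubs = 14)
  expect_equal(sel$hubs$name, c("granuloma", "liver injury", "renal"))
  expect_equal(sel$hubs$normalized_score, c(0.927, 0.499, 0.341))

  low <- make_ranked("C9300009", 0.19)
  expect_equal(nrow(select_hubs(low, threshold = 0.2)$hubs), 0)

  capped <- select_hubs(r, threshold = 0.2, max_hubs = 2)
  expect_equal(capped$hubs$name, c("granuloma", "liver injury"))

  mixed <- make_ranked(sprintf("C93000%02d", 1:6), seq(0.9, 0.4, by = -0.1),
                       semtypes = c("DSYN", "DSYN", "DSYN", "GNGM", "GNGM",
                                    "GNGM"))
  quota <- select_hubs(mixed, threshold = 0.2, per_semtype_cap = 2)
  expect_equal(as.integer(table(quota$hubs$semtype)[c("DSYN", "GNGM")]),
               c(2L, 2L))
})

test_that("run_hub_layer runs one simulation per hub with self-exclusion", {
  g <- toy_graph()
  hubs <- data.frame(cui = c(toy_cui[["g1"]], toy_cui[["g2"]]),
                     name = c("g1", "g2"), semtype = "GNGM",
                     normalized_score = c(0.9, 0.8))
  out <- run_hub_layer(g, hubs,
                       template = list(source_semtypes = c("PHSU", "GNGM"),
                                       max_metapath_length = 2))
  expect_named(out, c(toy_cui[["g1"]], toy_cui[["g2"]]))
  # a hub never appears among its own candidates
  expect_false(toy_cui[["g1"]] %in% out[[toy_cui[["g1"]]]]$source_cui)
  # missing hub is recorded as an error, others proceed
  hubs2 <- rbind(hubs, data.frame(cui = "C9999999", name = "gone",
                                  semtype = "GNGM", normalized_score = 0.5))
  expect_warning(out2 <- run_hub_layer(g, hubs2,
                                       template = list(source_semtypes = "PHSU",
                                                       max_metapath_length = 2)),
                 "failed")
  expect_length(out2, 2)
  expect_named(attr(out2, "errors"), "C9999999")
})

test_that("back-evaluation over the published score table recovers the printed hubs", {
  hr <- read_hub_results(fixture_path())
  be <- back_evaluate("C9200005", hr, threshold = 0.2)  # ebastine
  expect_equal(be$count, 5)
  expect_equal(be$passed$hub_cui,
               c("C9100005", "C3536809", "C9100007", "C9100008", "C9100009"))
  expect_equal(be$passed$normalized_score,
               c(0.585, 0.446, 0.399, 0.398, 0.369))
  # absent candidate
  none <- back_evaluate("C9999999", hr, threshold = 0.2)
  expect_equal(none$count, 0)
  expect_equal(nrow(none$passed), 0)
  # zero threshold returns every hub containing the candidate
  all_hubs <- back_evaluate("C9200005", hr, threshold = 0)
  expect_equal(all_hubs$count, 5)
})

test_that("cross-evaluation recurrences, ordering and masking match the table", {
  hr <- read_hub_results(fixture_path())
  ce <- cross_evaluate(hr, threshold = 0.2)
  s <- ce$summary
  expect_equal(s$recurrence[match(
    c("C9200001", "C9200002", "C9200003", "C9200005", "C9200004"),
    s$candidate_cui)], c(8L, 8L, 6L, 5L, 4L))
  expect_equal(s$mean_score[s$candidate_cui == "C9200005"],
               (0.585 + 0.446 + 0.399 + 0.398 + 0.369) / 5)
  # rendered columns are in descending score order
  mat <- render_crosseval(ce, hub_names = attr(hr, "hub_names"))
  eb <- mat[, "C9200005"]
  expect_equal(eb[eb != ""],
               c("SLC33A1 (0.585)", "Antihistamine (0.446)", "DRD2 (0.399)",
                 "EEF1A2 (0.398)", "GRM1 (0.369)"),
               ignore_attr = TRUE)
  for (cc in colnames(mat)) {
    sc <- as.numeric(sub(".*\\((.*)\\)", "\\1", mat[mat[, cc] != "", cc]))
    expect_true(all(diff(sc) <= 0))
  }
  # masking: a sub-threshold score disappears at 0.2 but shows at 0
  hr2 <- hr
  extra <- hr2[["C9100001"]][1, ]
  extra$source_cui <- "C9200004"; extra$normalized_score <- 0.19
  hr2[["C9100001"]] <- rbind(hr2[["C9100001"]], extra)
  class(hr2[["C9100001"]]) <- c("ranked_result", "data.frame")
  ce2 <- cross_evaluate(hr2, threshold = 0.2)
  expect_equal(ce2$summary$recurrence[ce2$summary$candidate_cui == "C9200004"],
               4L)
  ce0 <- cross_evaluate(hr2, threshold = 0.1)
  expect_equal(ce0$summary$recurrence[ce0$summary$candidate_cui == "C9200004"],
               5L)
  expect_error(cross_evaluate(hr["C9100001"], 0.2), "at least 2")
})

test_that("cross-evaluation invariants hold against back-evaluation", {
  hr <- read_hub_results(fixture_path())
  for (thr in c(0.2, 0.3, 0.45)) {
    ce <- cross_evaluate(hr, threshold = thr)
    expect_true(all(ce$summary$recurrence <= length(hr)))
    for (cc in ce$summary$candidate_cui) {
      expect_equal(back_evaluate(cc, hr, threshold = thr)$count,
                   ce$summary$recurrence[ce$summary$candidate_cui == cc])
    }
  }
  # raising the threshold never increases any recurrence
  lo <- cross_evaluate(hr, threshold = 0.2)$summary
  hi <- cross_evaluate(hr, threshold = 0.4)$summary
  for (cc in hi$candidate_cui) {
    expect_lte(hi$recurrence[hi$candidate_cui == cc],
               lo$recurrence[lo$candidate_cui == cc])
  }
  # two hubs with disjoint passing candidates -> all recurrences 1
  disj <- list(A = make_ranked(c("C9400001", "C9400002"), c(0.9, 0.8)),
               B = make_ranked(c("C9400003", "C9400004"), c(0.7, 0.6)))
  expect_true(all(cross_evaluate(disj, 0.2)$summary$recurrence == 1L))
})

test_that("final ranking puts recurrence before mean score, then CUI", {
  hr <- list(
    h1 = make_ranked(c("A", "B", "C") , c(0.44, 0.51, 1.00)),
    h2 = make_ranked(c("A", "B"), c(0.44, 0.51)),
    h3 = make_ranked(c("A", "B"), c(0.44, 0.51))
  )
  # fix CUIs to valid format
  hr <- lapply(hr, function(r) {
    r$source_cui <- c(A = "C9500001", B = "C9500002",
                      C = "C9500003")[r$source_cui]
    r
  })
  ce <- cross_evaluate(hr, threshold = 0.2)
  fin <- final_ranking(list(), ce, candidate_semtypes = "PHSU")
  # B (recurrence 3, mean .51) over A (recurrence 3, mean .44) over
  # C (single appearance, score 1.0): recurrence dominates the mean
  expect_identical(fin$cui, c("C9500002", "C9500001", "C9500003"))
  expect_equal(fin$recurrence, c(3L, 3L, 1L))
})
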