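# Shared fixtures, all built in code.

# Toy graph: two drugs, two genes, one disease.
# d1-AFFECTS->g1, d1-AFFECTS->g2, d2-AFFECTS->g1,
# g1-ASSOCIATED_WITH->D, g2-ASSOCIATED_WITH->D
toy_graph <- function() {
  knowledge_graph(
    data.frame(cui = sprintf("C900000%d", 1:5),
               name = c("d1", "d2", "g1", "g2", "D"),
               semtype = c("PHSU", "PHSU", "GNGM", "GNGM", "DSYN"),
               stringsAsFactors = FALSE),
    data.frame(
      subject_cui = c("C9000001", "C9000001", "C9000002", "C9000003",
                      "C9000004"),
      predicate = c("AFFECTS", "AFFECTS", "AFFECTS", "ASSOCIATED_WITH",
                    "ASSOCIATED_WITH"),
      object_cui = c("C9000003", "C9000004", "C9000003", "C9000005",
                     "C9000005"),
      stringsAsFactors = FALSE)
  )
}

toy_cui <- c(d1 = "C9000001", d2 = "C9000002", g1 = "C9000003",
             g2 = "C9000004", D = "C9000005")

toy_mp <- function() {
  parse_metapath("PHSU-[AFFECTS>]-GNGM-[ASSOCIATED_WITH>]-DSYN")
}

# Small random predication graph (<= 50 nodes) for property tests.
random_kg <- function(seed, n_nodes = 30, n_edges = 60) {
  set.seed(seed)
  semtypes <- c("PHSU", "GNGM", "DSYN", "AAPP")
  preds <- c("AFFECTS", "TREATS", "ASSOCIATED_WITH", "INHIBITS")
  st <- sample(semtypes, n_nodes, replace = TRUE)
  nodes <- data.frame(cui = sprintf("C95%05d", seq_len(n_nodes)),
                      name = sprintf("node %d", seq_len(n_nodes)),
                      semtype = st, stringsAsFactors = FALSE)
  s <- sample(nodes$cui, n_edges, replace = TRUE)
  o <- sample(nodes$cui, n_edges, replace = TRUE)
  keep <- s != o
  edges <- data.frame(subject_cui = s[keep],
                      predicate = sample(preds, sum(keep), replace = TRUE),
                      object_cui = o[keep],
                      support_count = sample(1:3, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  suppressWarnings(knowledge_graph(nodes, edges))
}

# Pick random (source, target, metapath) triples with at least one instance.
random_scored_cases <- function(graph, seed, max_len = 3, n_cases = 3) {
  set.seed(seed)
  out <- list()
  targets <- sample(graph$nodes$cui, min(5, nrow(graph$nodes)))
  for (t in targets) {
    mps <- tryCatch(
      enumerate_metapaths(graph, unique(graph$nodes$semtype), t,
                          max_len = max_len),
      error = function(e) list())
    if (!length(mps)) next
    mp <- mps[[sample.int(length(mps), 1)]]
    sources <- graph$semtype_index[[mp$from_semtype[1]]]
    s <- sample(sources, 1)
    out[[length(out) + 1]] <- list(s = s, t = t, mp = mp)
    if (length(out) >= n_cases) break
  }
  out
}

fixture_path <- function() {
  system.file("extdata", "pd_hub_scores_synthetic_cuis.tsv",
              package = "hetepath")
}
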