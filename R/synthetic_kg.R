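# Seeded generator of SemMedDB-like predication graphs with planted ground
# truth, standing in for a full literature-scale knowledge graph so that the
# whole ranking pipeline can be exercised and validated at desk scale.

.synth_predicates <- c(TREATS = 0.15, INHIBITS = 0.10, CAUSES = 0.08,
                       AFFECTS = 0.25, ASSOCIATED_WITH = 0.20,
                       INTERACTS_WITH = 0.10, PREDISPOSES = 0.07,
                       COEXISTS_WITH = 0.05)

# SemMedDB-like type compatibility: which semtypes may appear as subject /
# object of each predicate in background sampling.
.synth_compat <- list(
  TREATS          = list(s = c("PHSU", "CLND", "TOPP"), o = "DSYN"),
  INHIBITS        = list(s = c("PHSU", "CLND"), o = c("GNGM", "AAPP")),
  CAUSES          = list(s = c("DSYN", "GNGM"), o = "DSYN"),
  AFFECTS         = list(s = c("PHSU", "CLND", "GNGM", "AAPP"),
                         o = c("GNGM", "AAPP", "DSYN")),
  ASSOCIATED_WITH = list(s = c("GNGM", "AAPP"), o = "DSYN"),
  INTERACTS_WITH  = list(s = c("PHSU", "CLND"), o = c("PHSU", "CLND")),
  PREDISPOSES     = list(s = c("DSYN", "GNGM"), o = "DSYN"),
  COEXISTS_WITH   = list(s = "DSYN", o = "DSYN")
)

#' Configure the synthetic predication-graph generator
#'
#' Parameters of the emulated literature graph: node counts per semantic
#' type, a SemMedDB-like predicate vocabulary with sampling probabilities, a
#' skewed (Zipf-like) background degree distribution, planted adjuvant
#' drugs wired to a disease target through several metapath families, and
#' high-degree "popular" decoy drugs that stress the degree correction.
#'
#' @param n_per_semtype named integer vector of node counts per semantic
#'   type.
#' @param predicate_vocab named numeric vector of predicate sampling
#'   probabilities.
#' @param background_edge_count number of background predication rows
#'   sampled (duplicates aggregate, so the edge count of the final graph
#'   may be slightly lower).
#' @param degree_skew exponent of the Zipf-like node-popularity weights
#'   used for background endpoint sampling (1 = classic skew, 0 = uniform).
#' @param n_planted number of planted adjuvant drugs (PHSU).
#' @param planted_path_multiplicity concrete planted-family path instances
#'   per planted drug to the disease target (spread over up to three
#'   families: drug-AFFECTS-gene-ASSOCIATED_WITH-disease,
#'   drug-INTERACTS_WITH-standard-TREATS-disease,
#'   drug-TREATS-comorbidity-COEXISTS_WITH-disease). 0 plants nothing (the
#'   negative control).
#' @param n_popular_decoys number of high-degree decoy drugs (PHSU) kept
#'   off every planted family.
#' @param decoy_degree_factor decoys receive extra background edges until
#'   their degree is this multiple of the 95th degree percentile.
#' @param seed integer RNG seed; generation is deterministic given the
#'   config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_semtype = c(PHSU = 200, CLND = 50,
                                               GNGM = 100, AAPP = 100,
                                               DSYN = 40, TOPP = 30),
                             predicate_vocab = .synth_predicates,
                             background_edge_count = 2600,
                             degree_skew = 0.75,
                             n_planted = 3,
                             planted_path_multiplicity = 6,
                             n_popular_decoys = 5,
                             decoy_degree_factor = 1.5,
                             seed = 1L) {
  if (any(n_per_semtype <= 0)) stop("all node counts must be positive")
  if (!all(c("PHSU", "GNGM", "DSYN") %in% names(n_per_semtype)))
    stop("PHSU, GNGM and DSYN node pools are required")
  need_phsu <- 1 + n_planted + n_popular_decoys
  if (n_per_semtype[["PHSU"]] < need_phsu)
    stop("PHSU pool too small for standard drug + planted + decoys (need ",
         need_phsu, ")")
  if (n_per_semtype[["DSYN"]] < 3 || n_per_semtype[["GNGM"]] < 4)
    stop("need at least 3 DSYN and 4 GNGM nodes for the planted structure")
  if (planted_path_multiplicity < 0) stop("multiplicity must be >= 0")
  structure(list(
    n_per_semtype = n_per_semtype, predicate_vocab = predicate_vocab,
    background_edge_count = as.integer(background_edge_count),
    degree_skew = degree_skew, n_planted = as.integer(n_planted),
    planted_path_multiplicity = as.integer(planted_path_multiplicity),
    n_popular_decoys = as.integer(n_popular_decoys),
    decoy_degree_factor = decoy_degree_factor,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic predication knowledge graph with planted truth
#'
#' Builds a typed multigraph that emulates a SemMedDB extract: skewed-degree
#' background predications sampled under type-compatibility rules; one
#' disease target and one standard-of-care drug connected by `TREATS`;
#' `n_planted` adjuvant drugs each connected to the target through
#' `planted_path_multiplicity` concrete instances across up to three
#' metapath families (shared hub genes, the standard drug, comorbid
#' diseases); and high-degree decoy drugs with at most one incidental
#' planted-family instance, whose extra edges are kept away from the
#' planted structure. All synthetic CUIs live in the reserved `C9xxxxxx`
#' range.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `graph` (a `predication_kg`) and `truth`
#'   (list: `target_disease_cui`, `standard_drug_cui`, `planted_cuis`,
#'   `planted_hub_cuis`, `decoy_popular_cuis`).
#' @export
generate_kg <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, {
    nst <- config$n_per_semtype
    sts <- rep(names(nst), nst)
    cuis <- sprintf("C9%06d", seq_along(sts))
    names_by_type <- stats::ave(seq_along(sts), sts, FUN = seq_along)
    nodes <- data.frame(
      cui = cuis,
      name = sprintf("%s %03d", tolower(sts), names_by_type),
      semtype = sts, stringsAsFactors = FALSE
    )
    pool <- split(nodes$cui, nodes$semtype)

    target <- pool$DSYN[1]
    comorbid <- pool$DSYN[2:3]
    standard <- pool$PHSU[1]
    planted <- if (config$n_planted > 0)
      pool$PHSU[1 + seq_len(config$n_planted)] else character(0)
    decoys <- if (config$n_popular_decoys > 0)
      pool$PHSU[1 + config$n_planted + seq_len(config$n_popular_decoys)] else
        character(0)
    genes <- pool$GNGM[1:4]
    nodes$name[nodes$cui == target] <- "target syndrome (synthetic)"
    nodes$name[nodes$cui == standard] <- "standard-of-care drug (synthetic)"
    nodes$name[match(planted, nodes$cui)] <-
      sprintf("planted adjuvant %02d (synthetic)", seq_along(planted))
    nodes$name[match(decoys, nodes$cui)] <-
      sprintf("popular decoy %02d (synthetic)", seq_along(decoys))

    ed <- function(s, p, o, n = 1L)
      data.frame(subject_cui = s, predicate = p, object_cui = o,
                 support_count = n, stringsAsFactors = FALSE)
    planted_edges <- list(ed(standard, "TREATS", target, 5L))
    m <- config$planted_path_multiplicity
    if (m > 0) {
      planted_edges <- c(planted_edges, list(
        ed(genes, "ASSOCIATED_WITH", target),
        ed(genes, "CAUSES", target),
        ed(genes, "PREDISPOSES", target),
        ed(rep(genes, each = 2), "ASSOCIATED_WITH", rep(comorbid, 4)),
        ed(comorbid, "COEXISTS_WITH", target)
      ))
      for (i in seq_along(planted)) {
        p <- planted[i]
        fams <- list(ed(p, "INTERACTS_WITH", standard))
        if (m >= 2)
          fams <- c(fams, list(ed(p, "TREATS", comorbid[(i - 1) %% 2 + 1])))
        n_gene <- max(0, m - 2)
        if (n_gene > 0) {
          gi <- ((i - 1 + seq_len(n_gene) - 1) %% length(genes)) + 1
          fams <- c(fams, list(ed(p, "AFFECTS", genes[unique(gi)])))
        }
        planted_edges <- c(planted_edges, fams)
      }
    }
    planted_edges <- do.call(rbind, planted_edges)

    # Zipf-like popularity weights over all nodes (shuffled so popularity is
    # not aligned with CUI order); protected planted structure and decoys
    # are kept quiet in the background.
    wt <- (seq_len(nrow(nodes)))^(-config$degree_skew)
    wt <- sample(wt)
    names(wt) <- nodes$cui
    protected <- c(target, standard, planted, genes, comorbid)
    wt[protected] <- stats::quantile(wt, 0.25)
    preds <- sample(names(config$predicate_vocab),
                    config$background_edge_count, replace = TRUE,
                    prob = config$predicate_vocab)
    bg <- lapply(names(config$predicate_vocab), function(pr) {
      k <- sum(preds == pr)
      if (!k) return(NULL)
      compat <- .synth_compat[[pr]]
      if (is.null(compat)) return(NULL)
      s_pool <- unlist(pool[intersect(compat$s, names(pool))], use.names = FALSE)
      o_pool <- unlist(pool[intersect(compat$o, names(pool))], use.names = FALSE)
      if (!length(s_pool) || !length(o_pool)) return(NULL)
      s <- sample(s_pool, k, replace = TRUE, prob = wt[s_pool])
      o <- sample(o_pool, k, replace = TRUE, prob = wt[o_pool])
      keep <- s != o &
        !(s %in% decoys & o %in% protected) &
        !(o %in% decoys & s %in% protected)
      if (!any(keep)) return(NULL)
      ed(s[keep], pr, o[keep], sample(1:3, sum(keep), replace = TRUE,
                                      prob = c(0.7, 0.2, 0.1)))
    })
    bg <- do.call(rbind, bg)

    # Decoy boost: extra edges until each decoy clears the 95th degree
    # percentile, never touching the planted structure.
    deg_tab <- table(c(bg$subject_cui, bg$object_cui,
                       planted_edges$subject_cui, planted_edges$object_cui))
    q95 <- stats::quantile(as.numeric(deg_tab), 0.95)
    target_deg <- ceiling(q95 * config$decoy_degree_factor)
    open <- setdiff(nodes$cui, c(protected, decoys))
    boost <- lapply(decoys, function(d) {
      cur <- if (d %in% names(deg_tab)) deg_tab[[d]] else 0
      k <- max(0, target_deg - cur)
      if (!k) return(NULL)
      st_open <- .node_semtype_vec(nodes)
      nb <- sample(open, k, replace = FALSE, prob = wt[open])
      pr <- ifelse(st_open[nb] %in% c("GNGM", "AAPP"), "AFFECTS",
            ifelse(st_open[nb] %in% c("PHSU", "CLND"), "INTERACTS_WITH",
            ifelse(st_open[nb] == "DSYN", "TREATS", "AFFECTS")))
      ok <- st_open[nb] %in% c("GNGM", "AAPP", "PHSU", "CLND", "DSYN")
      ed(d, pr[ok], nb[ok])
    })
    boost <- do.call(rbind, boost)

    edges <- rbind(planted_edges, bg, boost)
    graph <- suppressWarnings(knowledge_graph(nodes, edges))
    truth <- list(
      target_disease_cui = target,
      standard_drug_cui = standard,
      planted_cuis = planted,
      planted_hub_cuis = c(genes, comorbid),
      decoy_popular_cuis = decoys
    )
    list(graph = graph, truth = truth)
  })
}

.node_semtype_vec <- function(nodes) {
  stats::setNames(nodes$semtype, nodes$cui)
}

#' Default pipeline configuration for a synthetic run
#'
#' The study conditions under which the planted signal is recovered: a
#' preliminary adjuvant screen with the disease and the standard drug as
#' targets over drug-like source types, a hub scan over gene / disease /
#' drug types with the disease as target, and per-hub simulations over
#' `PHSU`/`AAPP`/`DSYN` sources -- each with metapaths up to length 2 and
#' the degree-weighted path-count correction at exponent 0.8.
#'
#' @param truth ground-truth list from [generate_kg()].
#' @param dwpc_exponent damping exponent for the correction; `NULL`
#'   disables it.
#' @return Argument list for [run_hub_pipeline()] (without `graph`).
#' @export
default_pipeline_config <- function(truth, dwpc_exponent = 0.8) {
  list(
    prelim_specs = list(simulation_spec(
      name = "adjuvant-screen",
      target_cuis = c(truth$target_disease_cui, truth$standard_drug_cui),
      source_semtypes = c("PHSU", "CLND", "TOPP"),
      max_metapath_length = 2, dwpc_exponent = dwpc_exponent
    )),
    hub_spec = simulation_spec(
      name = "hub-scan",
      target_cuis = truth$target_disease_cui,
      source_semtypes = c("GNGM", "DSYN", "PHSU"),
      max_metapath_length = 2, dwpc_exponent = dwpc_exponent
    ),
    hub_template = list(source_semtypes = c("PHSU", "AAPP", "DSYN"),
                        max_metapath_length = 2,
                        dwpc_exponent = dwpc_exponent),
    threshold = 0.2, max_hubs = 14, hub_per_semtype_cap = 7,
    hub_semtypes = c("GNGM", "DSYN"),
    candidate_semtypes = c("PHSU", "CLND")
  )
}

#' Parameter-recovery experiment
#'
#' The generator-side validation of the whole pipeline: for `n_runs`
#' consecutive seeds, generate a graph, run the two-layer hub pipeline with
#' the disease target and the standard drug as preliminary targets, and
#' record where the planted adjuvant drugs land in the final report. The
#' summary reports the fraction of runs in which every planted drug sits in
#' the top `top_k`, whether any popular decoy ever outranked all planted
#' drugs, and how often the planted drugs' aggregate HeteSim beat the
#' median candidate's.
#'
#' @param config a [synthetic_config()] (its `seed` is the first run seed).
#' @param n_runs number of seeded runs (`>= 1`).
#' @param pipeline_config optional [run_hub_pipeline()] argument list; the
#'   default is [default_pipeline_config()] per run.
#' @param top_k top-k cutoff for the hit-rate summary (default 10).
#' @return List of class `recovery_report`: `runs` (one row per run:
#'   planted ranks, best decoy rank, flags), `all_top_k_rate`,
#'   `decoy_outranked_all_planted` (any run), `planted_above_median_rate`,
#'   `errors`.
#' @export
parameter_recovery <- function(config, n_runs = 20, pipeline_config = NULL,
                               top_k = 10) {
  stopifnot(inherits(config, "synthetic_config"), n_runs >= 1)
  rows <- list()
  errors <- list()
  for (r in seq_len(n_runs)) {
    run_seed <- config$seed + r - 1L
    res <- tryCatch({
      cfg <- config
      cfg$seed <- run_seed
      gen <- generate_kg(cfg)
      pc <- pipeline_config %||% default_pipeline_config(gen$truth)
      pipe <- do.call(run_hub_pipeline, c(list(graph = gen$graph), pc))
      fin <- pipe$final
      worst <- nrow(fin) + 1L
      prank <- fin$rank[match(gen$truth$planted_cuis, fin$cui)]
      prank[is.na(prank)] <- worst
      drank <- fin$rank[match(gen$truth$decoy_popular_cuis, fin$cui)]
      drank[is.na(drank)] <- worst
      prelim <- pipe$prelim[[1]]
      planted_het <- prelim$hetesim_score[match(gen$truth$planted_cuis,
                                                prelim$source_cui)]
      med <- stats::median(prelim$hetesim_score)
      data.frame(
        seed = run_seed,
        n_candidates = nrow(fin),
        planted_ranks = paste(prank, collapse = ","),
        worst_planted_rank = max(prank),
        best_decoy_rank = if (length(drank)) min(drank) else NA_integer_,
        all_planted_top_k = all(prank <= top_k),
        decoy_outranks_all_planted =
          length(drank) > 0 && min(drank) < min(prank),
        planted_above_median = all(planted_het > med),
        stringsAsFactors = FALSE
      )
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[as.character(run_seed)]] <-
        conditionMessage(res)
    else rows[[length(rows) + 1]] <- res
  }
  runs <- do.call(rbind, rows)
  out <- list(
    runs = runs,
    n_runs = n_runs,
    top_k = top_k,
    all_top_k_rate = if (!is.null(runs)) mean(runs$all_planted_top_k) else NA,
    decoy_outranked_all_planted =
      if (!is.null(runs)) any(runs$decoy_outranks_all_planted) else NA,
    planted_above_median_rate =
      if (!is.null(runs)) mean(runs$planted_above_median) else NA,
    errors = errors
  )
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("parameter-recovery report over", x$n_runs, "run(s)\n")
  cat(sprintf("  all planted in top %d: %.0f%% of runs\n", x$top_k,
              100 * x$all_top_k_rate))
  cat("  any decoy outranked all planted:",
      if (isTRUE(x$decoy_outranked_all_planted)) "yes" else "no", "\n")
  cat(sprintf("  planted HeteSim above median candidate: %.0f%% of runs\n",
              100 * x$planted_above_median_rate))
  if (length(x$errors)) cat("  failed runs:", length(x$errors), "\n")
  invisible(x)
}
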