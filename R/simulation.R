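# One "simulation": rank all source nodes of allowed semantic types against
# one or more target nodes, with score normalization and (optionally)
# unsupervised rank aggregation and a degree-weighted path-count correction.

#' Specify a ranking simulation
#'
#' @param name label used in result files and manifests.
#' @param target_cuis non-empty character vector of target CUIs (resolved
#'   against the graph at run time).
#' @param source_semtypes non-empty character vector of candidate semantic
#'   types (e.g. `c("CLND", "TOPP", "PHSU")`).
#' @param max_metapath_length metapath length cap, between 1 and 4.
#' @param predicate_allowlist optional predicate filter applied before
#'   metapath enumeration and scoring.
#' @param aggregation `"mean_hetesim"` (default): candidates are scored by
#'   the mean HeteSim over the enumerated metapaths; `"rank_aggregation"`:
#'   per-metapath rankings are combined by [aggregate_ranks()].
#' @param normalization `"minmax"` (default) or `"none"`.
#' @param dwpc_exponent optional damping exponent; when non-`NULL`, a
#'   degree-weighted path-count correction is blended into the ranking so
#'   that low-citation relationships through quiet nodes are not drowned
#'   out by promiscuous hubs (and vice versa). `NULL` disables it.
#' @param weighted use support counts as edge mass in transition operators.
#' @param seed integer recorded in the manifest (the computation itself is
#'   deterministic).
#' @return A `simulation_spec` (list).
#' @export
simulation_spec <- function(name, target_cuis, source_semtypes,
                            max_metapath_length = 3,
                            predicate_allowlist = NULL,
                            aggregation = c("mean_hetesim", "rank_aggregation"),
                            normalization = c("minmax", "none"),
                            dwpc_exponent = NULL,
                            weighted = FALSE,
                            seed = 1L) {
  aggregation <- match.arg(aggregation)
  normalization <- match.arg(normalization)
  if (!length(target_cuis)) stop("target_cuis must be non-empty")
  if (!length(source_semtypes)) stop("source_semtypes must be non-empty")
  if (max_metapath_length < 1 || max_metapath_length > 4)
    stop("max_metapath_length must be in [1, 4]")
  structure(list(
    name = name, target_cuis = target_cuis,
    source_semtypes = source_semtypes,
    max_metapath_length = max_metapath_length,
    predicate_allowlist = predicate_allowlist,
    aggregation = aggregation, normalization = normalization,
    dwpc_exponent = dwpc_exponent, weighted = weighted,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Normalize scores
#'
#' Min-max normalization as used to compare nodes across simulations:
#' `(x - min) / (max - min)`, with the degenerate all-equal case mapping to
#' all 1 (every candidate is equally, maximally ranked). `method = "none"`
#' is the identity.
#'
#' @param raw non-empty numeric vector.
#' @param method `"minmax"` or `"none"`.
#' @return Numeric vector the same length as `raw`.
#' @export
normalize_scores <- function(raw, method = c("minmax", "none")) {
  method <- match.arg(method)
  if (!length(raw)) stop("cannot normalize an empty score vector")
  if (method == "none") return(raw)
  rng <- range(raw)
  if (rng[1] == rng[2]) return(rep(1, length(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Unsupervised rank aggregation
#'
#' Combines several rankings of (possibly different subsets of) candidates
#' into one consensus ranking. Candidates absent from a ranking are imputed
#' rank `length + 1`. Two methods:
#'
#' * `"mean_rank"`: sort by the mean of imputed ranks (transparent
#'   baseline, the default).
#' * `"weighted_iterative"`: an unsupervised-learning scheme in the ULARA
#'   family. Ranker weights start uniform; at each iteration the consensus
#'   is the weighted mean of normalized ranks and each ranker's weight is
#'   reset to the inverse of its mean squared deviation from that consensus
#'   (renormalized), until the largest weight change is below `1e-6` or 100
#'   iterations. Rankers that disagree with the emerging consensus are
#'   down-weighted without any labelled relevance data.
#'
#' Ties are broken lexicographically by CUI.
#'
#' @param rankings non-empty list; each element a character vector of
#'   candidate IDs in rank order (best first).
#' @param method `"mean_rank"` or `"weighted_iterative"`.
#' @return Data frame with columns `cui`, `consensus` (lower is better) and
#'   `rank`, sorted best first.
#' @export
aggregate_ranks <- function(rankings,
                            method = c("mean_rank", "weighted_iterative")) {
  method <- match.arg(method)
  if (!length(rankings)) stop("need at least one ranking")
  universe <- sort(unique(unlist(rankings)))
  n <- length(universe)
  if (!n) stop("rankings are all empty")
  R <- vapply(rankings, function(rk) {
    r <- match(universe, rk)
    r[is.na(r)] <- length(rk) + 1
    r
  }, numeric(n))
  R <- matrix(R, nrow = n)
  if (method == "mean_rank") {
    consensus <- rowMeans(R)
  } else {
    lens <- vapply(rankings, length, numeric(1))
    Rn <- sweep(R, 2, lens + 1, "/")
    k <- ncol(Rn)
    wts <- rep(1 / k, k)
    for (iter in seq_len(100)) {
      consensus <- as.numeric(Rn %*% wts)
      msd <- colMeans((Rn - consensus)^2)
      new_w <- 1 / (msd + 1e-12)
      new_w <- new_w / sum(new_w)
      delta <- max(abs(new_w - wts))
      wts <- new_w
      if (delta < 1e-6) break
    }
    consensus <- as.numeric(Rn %*% wts)
  }
  # zap float noise so exact ties break lexicographically, independent of
  # ranker input order
  consensus <- round(consensus, 12)
  ord <- order(consensus, universe)
  out <- data.frame(cui = universe[ord], consensus = consensus[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(n)
  out
}

#' Run one ranking simulation
#'
#' Scores every node whose semantic type is in `spec$source_semtypes`
#' (targets excluded) against the target node(s): metapaths of length up to
#' `spec$max_metapath_length` are enumerated per target, each candidate is
#' scored by the mean HeteSim over the metapaths rooted at its own semantic
#' type (zero where no instance exists), per-target scores are averaged,
#' optionally corrected by a degree-weighted path count, min-max normalized,
#' and sorted. The computation is a pure function of `(graph, spec)`.
#'
#' @param graph a `predication_kg`.
#' @param spec a [simulation_spec()].
#' @return Data frame of class `ranked_result` with columns `rank`,
#'   `source_cui`, `source_name`, `source_semtype`, `raw_score`,
#'   `normalized_score`, `hetesim_score`, `dwpc_score`, `n_metapaths`,
#'   sorted by `normalized_score` descending (ties broken by CUI). The
#'   simulation spec is attached as attribute `spec`.
#' @export
run_simulation <- function(graph, spec) {
  stopifnot(inherits(graph, "predication_kg"),
            inherits(spec, "simulation_spec"))
  miss <- setdiff(spec$target_cuis, graph$nodes$cui)
  if (length(miss))
    stop("target CUI(s) not in graph: ", paste(miss, collapse = ", "))
  cand <- graph$nodes[graph$nodes$semtype %in% spec$source_semtypes, ,
                      drop = FALSE]
  cand <- cand[!cand$cui %in% spec$target_cuis, , drop = FALSE]
  empty <- data.frame(
    rank = integer(0), source_cui = character(0), source_name = character(0),
    source_semtype = character(0), raw_score = numeric(0),
    normalized_score = numeric(0), hetesim_score = numeric(0),
    dwpc_score = numeric(0), n_metapaths = integer(0),
    stringsAsFactors = FALSE
  )
  if (!nrow(cand)) {
    warning("no candidate nodes of semtype(s) ",
            paste(spec$source_semtypes, collapse = ", "))
    attr(empty, "spec") <- spec
    class(empty) <- c("ranked_result", "data.frame")
    return(empty)
  }
  hs <- matrix(0, nrow = nrow(cand), ncol = length(spec$target_cuis),
               dimnames = list(cand$cui, spec$target_cuis))
  dw <- hs
  nmp <- stats::setNames(integer(nrow(cand)), cand$cui)
  per_mp_rankings <- list()
  w <- spec$dwpc_exponent
  for (t in spec$target_cuis) {
    mps <- enumerate_metapaths(graph, spec$source_semtypes, t,
                               max_len = spec$max_metapath_length,
                               predicate_allowlist = spec$predicate_allowlist)
    if (!length(mps)) next
    start_types <- vapply(mps, function(mp) mp$from_semtype[1], character(1))
    n_by_type <- table(start_types)
    scores_t <- stats::setNames(numeric(nrow(cand)), cand$cui)
    dwpc_t <- scores_t
    for (mp in mps) {
      sc <- hetesim_all_sources(graph, t, mp, weighted = spec$weighted)
      sc <- sc[names(sc) %in% cand$cui]
      scores_t[names(sc)] <- scores_t[names(sc)] + sc
      if (!is.null(w)) {
        dv <- .dwpc_all(graph, mp, t, w)
        dv <- dv[names(dv) %in% cand$cui]
        dwpc_t[names(dv)] <- dwpc_t[names(dv)] + dv
      }
      if (spec$aggregation == "rank_aggregation") {
        nzs <- sort(names(sc)[sc > 0])
        nz <- sc[nzs]
        per_mp_rankings[[length(per_mp_rankings) + 1]] <-
          names(nz)[order(-nz, names(nz))]
      }
    }
    cnt <- as.integer(n_by_type[cand$semtype])
    cnt[is.na(cnt)] <- 0L
    hs[, t] <- scores_t[cand$cui] / pmax(cnt, 1L)
    dw[, t] <- dwpc_t[cand$cui]
    nmp <- nmp + cnt
  }
  hetesim_agg <- rowMeans(hs)
  dwpc_agg <- rowMeans(dw)
  if (spec$aggregation == "rank_aggregation" && length(per_mp_rankings)) {
    if (!is.null(w)) {
      nzd <- sort(names(dwpc_agg)[dwpc_agg > 0])
      dv <- dwpc_agg[nzd]
      per_mp_rankings[[length(per_mp_rankings) + 1]] <-
        names(dv)[order(-dv, names(dv))]
    }
    cons <- aggregate_ranks(per_mp_rankings, method = "weighted_iterative")
    worst <- max(cons$consensus) + 1
    raw <- stats::setNames(rep(0, nrow(cand)), cand$cui)
    raw[cons$cui[cons$cui %in% cand$cui]] <-
      (worst - cons$consensus[cons$cui %in% cand$cui]) / worst
  } else if (!is.null(w)) {
    raw <- normalize_scores(hetesim_agg) * normalize_scores(dwpc_agg)
  } else {
    raw <- hetesim_agg
  }
  normalized <- normalize_scores(raw, spec$normalization)
  ord <- order(-normalized, cand$cui)
  out <- data.frame(
    rank = seq_len(nrow(cand)),
    source_cui = cand$cui[ord],
    source_name = cand$name[ord],
    source_semtype = cand$semtype[ord],
    raw_score = unname(raw[ord]),
    normalized_score = unname(normalized[ord]),
    hetesim_score = unname(hetesim_agg[ord]),
    dwpc_score = unname(dwpc_agg[ord]),
    n_metapaths = unname(nmp[cand$cui[ord]]),
    stringsAsFactors = FALSE
  )
  attr(out, "spec") <- spec
  class(out) <- c("ranked_result", "data.frame")
  out
}

#' Write a simulation result table (plus manifest)
#'
#' The result table is a TSV of the ranking; the manifest is a JSON sidecar
#' recording the spec, the graph digest and the seed, sufficient to re-run
#' the simulation exactly. The table itself contains nothing
#' non-deterministic, so identical inputs produce byte-identical files.
#'
#' @param result a `ranked_result` from [run_simulation()].
#' @param path output TSV path.
#' @param graph the graph the simulation ran on (for the manifest digest);
#'   omit to skip the manifest.
#' @param manifest_path JSON manifest path (default: `path` +
#'   `".manifest.json"`).
#' @return `path`, invisibly.
#' @export
write_ranked_results <- function(result, path, graph = NULL,
                                 manifest_path = paste0(path, ".manifest.json")) {
  stopifnot(inherits(result, "ranked_result"))
  cols <- c("rank", "source_cui", "source_name", "source_semtype",
            "raw_score", "normalized_score", "n_metapaths")
  out <- as.data.frame(result)[, cols, drop = FALSE]
  for (col in c("raw_score", "normalized_score"))
    out[[col]] <- sprintf("%.10g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(graph)) {
    spec <- attr(result, "spec")
    manifest <- list(
      simulation = spec$name,
      spec = spec[setdiff(names(spec), "name")],
      graph_digest = kg_digest(graph),
      seed = spec$seed,
      generated_at = format(Sys.time(), tz = "UTC", usetz = TRUE),
      package_version = as.character(utils::packageVersion("hetepath"))
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         null = "null", digits = NA, pretty = TRUE)
  }
  invisible(path)
}
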