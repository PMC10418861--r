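# Layered hub analysis: select high-scoring hub nodes from one simulation,
# run a simulation per hub, back-evaluate a designated candidate, tabulate
# candidates across hub simulations (cross-evaluation), and produce the
# final ranked repurposed-drug candidate report.

#' Select hub nodes from a simulation result
#'
#' Hubs are the top-ranked source nodes whose normalized HeteSim score meets
#' the threshold and whose semantic type is allowed, truncated to
#' `max_hubs`, order preserved. Defaults mirror the published procedure: a
#' 0.2 normalized-score threshold and at most 14 hubs.
#'
#' @param results a `ranked_result` from [run_simulation()].
#' @param threshold normalized-score cutoff in `[0, 1]`.
#' @param max_hubs maximum number of hubs (`>= 1`).
#' @param allowed_semtypes optional semantic-type filter (e.g.
#'   `c("GNGM", "DSYN", "PHSU")`).
#' @param per_semtype_cap optional cap on hubs per semantic type, applied
#'   before the overall `max_hubs` truncation so no single node type
#'   monopolizes the hub layer.
#' @return An object of class `hub_selection`: list with `hubs` (data frame
#'   `cui`, `name`, `semtype`, `normalized_score`), `threshold`, `max_hubs`
#'   and `source_simulation`.
#' @export
select_hubs <- function(results, threshold = 0.2, max_hubs = 14,
                        allowed_semtypes = NULL, per_semtype_cap = NULL) {
  stopifnot(inherits(results, "ranked_result"),
            threshold >= 0, threshold <= 1, max_hubs >= 1)
  keep <- results$normalized_score >= threshold
  if (!is.null(allowed_semtypes))
    keep <- keep & results$source_semtype %in% allowed_semtypes
  sel <- results[keep, , drop = FALSE]
  if (!is.null(per_semtype_cap) && nrow(sel)) {
    within_type <- stats::ave(seq_len(nrow(sel)), sel$source_semtype,
                              FUN = seq_along)
    sel <- sel[within_type <= per_semtype_cap, , drop = FALSE]
  }
  sel <- utils::head(sel, max_hubs)
  spec <- attr(results, "spec")
  out <- list(
    hubs = data.frame(cui = sel$source_cui, name = sel$source_name,
                      semtype = sel$source_semtype,
                      normalized_score = sel$normalized_score,
                      stringsAsFactors = FALSE),
    threshold = threshold, max_hubs = max_hubs,
    source_simulation = if (!is.null(spec)) spec$name else NA_character_
  )
  class(out) <- "hub_selection"
  out
}

#' @export
print.hub_selection <- function(x, ...) {
  cat("hub selection from '", x$source_simulation, "': ", nrow(x$hubs),
      " hub(s) at threshold ", x$threshold, "\n", sep = "")
  if (nrow(x$hubs)) print(x$hubs, row.names = FALSE)
  invisible(x)
}

#' Run one simulation per hub
#'
#' Each selected hub becomes the target of its own simulation built from a
#' shared template ("the hubs identified from one simulation become targets
#' for the next"). A hub missing from the graph is recorded as a per-hub
#' error and the remaining hubs proceed.
#'
#' @param graph a `predication_kg`.
#' @param hubs a [select_hubs()] result (or data frame with a `cui` column).
#' @param template list of [simulation_spec()] arguments shared by all hub
#'   simulations (typically `source_semtypes`, `max_metapath_length`,
#'   `dwpc_exponent`).
#' @return Named list (one `ranked_result` per hub CUI); failed hubs are
#'   dropped and reported in attribute `errors`.
#' @export
run_hub_layer <- function(graph, hubs, template = list()) {
  hub_df <- if (inherits(hubs, "hub_selection")) hubs$hubs else
    as.data.frame(hubs)
  if (!nrow(hub_df)) stop("hub selection is empty")
  results <- list()
  errors <- list()
  for (i in seq_len(nrow(hub_df))) {
    cui <- hub_df$cui[i]
    res <- tryCatch({
      args <- utils::modifyList(
        list(name = paste0("hub:", cui), target_cuis = cui,
             source_semtypes = c("PHSU", "AAPP", "DSYN"),
             max_metapath_length = 2),
        template)
      args$name <- paste0("hub:", cui)
      args$target_cuis <- cui
      spec <- do.call(simulation_spec, args)
      run_simulation(graph, spec)
    }, error = function(e) e)
    if (inherits(res, "error")) errors[[cui]] <- conditionMessage(res)
    else results[[cui]] <- res
  }
  if (length(errors))
    warning(length(errors), " hub simulation(s) failed: ",
            paste(names(errors), collapse = ", "))
  attr(results, "errors") <- errors
  results
}

#' Back-evaluate a candidate against the hub layer
#'
#' Checks in which hub simulations a designated candidate (ebastine in the
#' published analysis) re-emerges with a normalized score at or above the
#' threshold -- evidence that the hubs collectively point back at the
#' candidate.
#'
#' @param candidate_cui CUI of the candidate to back-evaluate.
#' @param hub_results named list of `ranked_result`s from [run_hub_layer()].
#' @param threshold normalized-score cutoff (default 0.2).
#' @return List with `count` (hubs passed) and `passed` (data frame
#'   `hub_cui`, `normalized_score`, sorted by score descending).
#' @export
back_evaluate <- function(candidate_cui, hub_results, threshold = 0.2) {
  if (!length(hub_results)) stop("hub_results must be non-empty")
  rows <- lapply(names(hub_results), function(h) {
    r <- hub_results[[h]]
    i <- match(candidate_cui, r$source_cui)
    if (is.na(i) || r$normalized_score[i] < threshold) return(NULL)
    data.frame(hub_cui = h, normalized_score = r$normalized_score[i],
               stringsAsFactors = FALSE)
  })
  passed <- do.call(rbind, rows)
  if (is.null(passed))
    passed <- data.frame(hub_cui = character(0),
                         normalized_score = numeric(0),
                         stringsAsFactors = FALSE)
  passed <- passed[order(-passed$normalized_score, passed$hub_cui), ,
                   drop = FALSE]
  rownames(passed) <- NULL
  list(count = nrow(passed), passed = passed)
}

#' Cross-evaluate candidates across hub simulations
#'
#' Tabulates every candidate that reaches the threshold in at least one hub
#' simulation: a candidate-by-hub matrix of normalized scores (cells below
#' threshold are empty), each candidate's recurrence (number of filled
#' cells) and mean score over filled cells. Rows are ordered by recurrence,
#' then mean score, then CUI.
#'
#' @inheritParams back_evaluate
#' @return An object of class `crosseval_table`: list with `cells` (long
#'   data frame `candidate_cui`, `hub_cui`, `normalized_score`), `summary`
#'   (data frame `candidate_cui`, `recurrence`, `mean_score`, ordered), and
#'   `hub_cuis`.
#' @export
cross_evaluate <- function(hub_results, threshold = 0.2) {
  if (length(hub_results) < 2)
    stop("cross-evaluation needs at least 2 hub simulations")
  cells <- do.call(rbind, lapply(names(hub_results), function(h) {
    r <- hub_results[[h]]
    keep <- r$normalized_score >= threshold
    if (!any(keep)) return(NULL)
    data.frame(candidate_cui = r$source_cui[keep],
               candidate_name = r$source_name[keep],
               candidate_semtype = r$source_semtype[keep],
               hub_cui = h,
               normalized_score = r$normalized_score[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cells))
    cells <- data.frame(candidate_cui = character(0),
                        candidate_name = character(0),
                        candidate_semtype = character(0),
                        hub_cui = character(0),
                        normalized_score = numeric(0),
                        stringsAsFactors = FALSE)
  if (nrow(cells)) {
    agg <- stats::aggregate(normalized_score ~ candidate_cui, data = cells,
                            FUN = mean)
    cnt <- stats::aggregate(normalized_score ~ candidate_cui, data = cells,
                            FUN = length)
    summary <- data.frame(candidate_cui = agg$candidate_cui,
                          recurrence = as.integer(
                            cnt$normalized_score[match(agg$candidate_cui,
                                                       cnt$candidate_cui)]),
                          mean_score = agg$normalized_score,
                          stringsAsFactors = FALSE)
    summary <- summary[order(-summary$recurrence, -summary$mean_score,
                             summary$candidate_cui), , drop = FALSE]
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(candidate_cui = character(0),
                          recurrence = integer(0), mean_score = numeric(0),
                          stringsAsFactors = FALSE)
  }
  out <- list(cells = cells, summary = summary,
              hub_cuis = names(hub_results), threshold = threshold)
  class(out) <- "crosseval_table"
  out
}

#' @export
print.crosseval_table <- function(x, ...) {
  cat("cross-evaluation over", length(x$hub_cuis), "hub simulations,",
      nrow(x$summary), "candidate(s) at threshold", x$threshold, "\n")
  if (nrow(x$summary)) print(utils::head(x$summary, 10), row.names = FALSE)
  invisible(x)
}

#' Render a cross-evaluation table as a candidate-by-hub matrix
#'
#' Mirrors the published presentation: one column per candidate, the passing
#' hubs listed within each column in descending score order, sub-threshold
#' cells left empty.
#'
#' @param x a `crosseval_table`.
#' @param candidates optional candidate CUIs (columns), default all in
#'   summary order.
#' @param hub_names optional named character vector mapping hub CUIs to
#'   display names.
#' @return Character matrix (one column per candidate) of
#'   `"hub (score)"` strings, padded with empty strings.
#' @export
render_crosseval <- function(x, candidates = NULL, hub_names = NULL) {
  stopifnot(inherits(x, "crosseval_table"))
  if (is.null(candidates)) candidates <- x$summary$candidate_cui
  cols <- lapply(candidates, function(cc) {
    sub <- x$cells[x$cells$candidate_cui == cc, , drop = FALSE]
    sub <- sub[order(-sub$normalized_score, sub$hub_cui), , drop = FALSE]
    lab <- if (!is.null(hub_names)) {
      nm <- hub_names[sub$hub_cui]
      ifelse(is.na(nm), sub$hub_cui, nm)
    } else sub$hub_cui
    sprintf("%s (%.3f)", lab, sub$normalized_score)
  })
  depth <- max(c(1, vapply(cols, length, integer(1))))
  mat <- vapply(cols, function(cl) c(cl, rep("", depth - length(cl))),
                character(depth))
  mat <- matrix(mat, nrow = depth)
  colnames(mat) <- candidates
  mat
}

#' Final repurposed-candidate ranking
#'
#' Combines the preliminary layers with the hub-layer cross-evaluation. The
#' ranking criteria, in order, are (1) total recurrence -- the number of
#' preliminary simulations plus hub simulations in which the candidate's
#' normalized score reaches the threshold -- and (2) mean normalized score
#' over those passing appearances, with CUI as the final tie-break.
#' Candidates are restricted to drug-like semantic types by default because
#' the deliverable is a repurposed-drug list.
#'
#' @param preliminary list of `ranked_result`s (the preliminary layers).
#' @param crosseval a `crosseval_table` from [cross_evaluate()], or `NULL`
#'   (then the report is built from the preliminary layers alone and
#'   flagged with attribute `preliminary_only`).
#' @param candidate_semtypes semantic types eligible for the final report.
#' @param threshold passing threshold for counting a layer appearance.
#' @param exclude CUIs to drop from the report (e.g. the pipeline's own
#'   target nodes).
#' @return Data frame with columns `rank`, `cui`, `name`, `semtype`,
#'   `recurrence`, `prelim_recurrence`, `hub_recurrence`, `mean_score`,
#'   `layers` (per-layer provenance string).
#' @export
final_ranking <- function(preliminary, crosseval,
                          candidate_semtypes = c("PHSU", "CLND"),
                          threshold = 0.2, exclude = character(0)) {
  prelim_cells <- do.call(rbind, lapply(seq_along(preliminary), function(i) {
    r <- preliminary[[i]]
    spec <- attr(r, "spec")
    nm <- if (!is.null(spec)) spec$name else paste0("prelim", i)
    keep <- r$normalized_score >= threshold &
      r$source_semtype %in% candidate_semtypes
    if (!any(keep)) return(NULL)
    data.frame(cui = r$source_cui[keep], name = r$source_name[keep],
               semtype = r$source_semtype[keep],
               layer = paste0("prelim:", nm),
               score = r$normalized_score[keep], stringsAsFactors = FALSE)
  }))
  hub_cells <- NULL
  if (!is.null(crosseval) && nrow(crosseval$cells)) {
    hc <- crosseval$cells
    keep <- hc$candidate_semtype %in% candidate_semtypes
    if (any(keep))
      hub_cells <- data.frame(cui = hc$candidate_cui[keep],
                              name = hc$candidate_name[keep],
                              semtype = hc$candidate_semtype[keep],
                              layer = paste0("hub:", hc$hub_cui[keep]),
                              score = hc$normalized_score[keep],
                              stringsAsFactors = FALSE)
  }
  all_cells <- rbind(prelim_cells, hub_cells)
  if (!is.null(all_cells))
    all_cells <- all_cells[!all_cells$cui %in% exclude, , drop = FALSE]
  if (is.null(all_cells) || !nrow(all_cells)) {
    out <- data.frame(rank = integer(0), cui = character(0),
                      name = character(0), semtype = character(0),
                      recurrence = integer(0), prelim_recurrence = integer(0),
                      hub_recurrence = integer(0), mean_score = numeric(0),
                      layers = character(0), stringsAsFactors = FALSE)
    attr(out, "preliminary_only") <- is.null(crosseval)
    return(out)
  }
  split_cells <- split(all_cells, all_cells$cui)
  rows <- lapply(split_cells, function(sub) {
    sub <- sub[order(-sub$score, sub$layer), , drop = FALSE]
    data.frame(
      cui = sub$cui[1], name = sub$name[1], semtype = sub$semtype[1],
      recurrence = nrow(sub),
      prelim_recurrence = sum(startsWith(sub$layer, "prelim:")),
      hub_recurrence = sum(startsWith(sub$layer, "hub:")),
      mean_score = mean(sub$score),
      layers = paste(sprintf("%s(%.3f)", sub$layer, sub$score),
                     collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$recurrence, -out$mean_score, out$cui), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "preliminary_only") <- is.null(crosseval)
  out
}

#' Run the full layered hub-analysis pipeline
#'
#' Orchestrates the published procedure end to end: preliminary
#' simulations, a hub-scan simulation, hub selection, one simulation per
#' hub, optional back-evaluation of a designated candidate,
#' cross-evaluation, and the final ranked candidate report. Deterministic
#' given `(graph, config)`.
#'
#' @param graph a `predication_kg`.
#' @param prelim_specs list of [simulation_spec()]s for the preliminary
#'   layer.
#' @param hub_spec [simulation_spec()] whose results hubs are selected from.
#' @param hub_template argument list for the per-hub simulations (see
#'   [run_hub_layer()]).
#' @param threshold normalized-score threshold used for hub selection,
#'   cross-evaluation and the final report (default 0.2).
#' @param max_hubs hub cap (default 14).
#' @param hub_per_semtype_cap optional per-semtype hub cap (see
#'   [select_hubs()]).
#' @param hub_semtypes semantic types eligible as hubs.
#' @param backeval_cui optional candidate CUI to back-evaluate.
#' @param candidate_semtypes semantic types eligible for the final report.
#' @param exclude CUIs excluded from the final report (defaults to all
#'   preliminary and hub-scan targets).
#' @return List of class `hub_pipeline_result` with elements `prelim`,
#'   `hub_scan`, `hub_selection`, `hub_results`, `crosseval`, `backeval`,
#'   `final`.
#' @export
run_hub_pipeline <- function(graph, prelim_specs, hub_spec,
                             hub_template = list(),
                             threshold = 0.2, max_hubs = 14,
                             hub_per_semtype_cap = NULL,
                             hub_semtypes = c("GNGM", "DSYN", "PHSU"),
                             backeval_cui = NULL,
                             candidate_semtypes = c("PHSU", "CLND"),
                             exclude = NULL) {
  stopifnot(inherits(graph, "predication_kg"))
  if (inherits(prelim_specs, "simulation_spec"))
    prelim_specs <- list(prelim_specs)
  prelim <- lapply(prelim_specs, function(sp) run_simulation(graph, sp))
  names(prelim) <- vapply(prelim_specs, function(sp) sp$name, character(1))
  hub_scan <- run_simulation(graph, hub_spec)
  hubsel <- select_hubs(hub_scan, threshold = threshold, max_hubs = max_hubs,
                        allowed_semtypes = hub_semtypes,
                        per_semtype_cap = hub_per_semtype_cap)
  if (is.null(exclude))
    exclude <- unique(c(unlist(lapply(prelim_specs, `[[`, "target_cuis")),
                        hub_spec$target_cuis))
  hub_results <- list()
  crosseval <- NULL
  backeval <- NULL
  if (nrow(hubsel$hubs)) {
    hub_results <- run_hub_layer(graph, hubsel, template = hub_template)
    if (length(hub_results) >= 2)
      crosseval <- cross_evaluate(hub_results, threshold = threshold)
    if (!is.null(backeval_cui) && length(hub_results))
      backeval <- back_evaluate(backeval_cui, hub_results,
                                threshold = threshold)
  } else {
    warning("empty hub selection; final report from preliminary layer only")
  }
  final <- final_ranking(prelim, crosseval,
                         candidate_semtypes = candidate_semtypes,
                         threshold = threshold, exclude = exclude)
  out <- list(prelim = prelim, hub_scan = hub_scan, hub_selection = hubsel,
              hub_results = hub_results, crosseval = crosseval,
              backeval = backeval, final = final)
  class(out) <- "hub_pipeline_result"
  out
}

#' @export
print.hub_pipeline_result <- function(x, ...) {
  cat("hub-analysis pipeline:", length(x$prelim), "preliminary simulation(s),",
      nrow(x$hub_selection$hubs), "hub(s),",
      length(x$hub_results), "hub simulation(s)\n")
  cat("final candidates:", nrow(x$final), "\n")
  if (nrow(x$final))
    print(utils::head(x$final[, c("rank", "cui", "name", "recurrence",
                                  "mean_score")], 10), row.names = FALSE)
  invisible(x)
}

#' Read precomputed hub-simulation scores
#'
#' Loads a replay fixture of hub-layer results: a TSV with columns
#' `hub_cui`, `hub_name`, `source_cui`, `source_name`, `source_semtype`,
#' `normalized_score`, one row per (hub simulation, candidate) score. Used
#' to re-run cross- and back-evaluation over published score tables without
#' the original knowledge graph.
#'
#' @param path TSV path.
#' @return Named list of `ranked_result`s keyed by hub CUI, suitable for
#'   [cross_evaluate()] and [back_evaluate()]; hub display names are
#'   attached as attribute `hub_names`.
#' @export
read_hub_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("hub_cui", "hub_name", "source_cui", "source_name",
            "source_semtype", "normalized_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hub-result file missing column(s): ", paste(miss, collapse = ", "))
  df$normalized_score <- as.numeric(df$normalized_score)
  out <- lapply(split(df, df$hub_cui), function(sub) {
    sub <- sub[order(-sub$normalized_score, sub$source_cui), , drop = FALSE]
    r <- data.frame(rank = seq_len(nrow(sub)),
                    source_cui = sub$source_cui,
                    source_name = sub$source_name,
                    source_semtype = sub$source_semtype,
                    raw_score = sub$normalized_score,
                    normalized_score = sub$normalized_score,
                    hetesim_score = sub$normalized_score,
                    dwpc_score = NA_real_,
                    n_metapaths = NA_integer_,
                    stringsAsFactors = FALSE)
    class(r) <- c("ranked_result", "data.frame")
    r
  })
  hub_names <- df$hub_name[!duplicated(df$hub_cui)]
  names(hub_names) <- df$hub_cui[!duplicated(df$hub_cui)]
  attr(out, "hub_names") <- hub_names
  out
}
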