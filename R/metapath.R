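# Metapath engine: type-level path templates over a predication graph,
# concrete instance enumeration/counting, and degree-weighted path counts.

#' Construct a metapath step
#'
#' One typed hop of a metapath: traverse edges labelled `predicate` either
#' in their stated subject-to-object direction (`"forward"`) or against it
#' (`"reverse"`), from nodes of `from` to nodes of `to`.
#'
#' @param from,to 4-letter semantic-type codes.
#' @param predicate uppercase predicate token (e.g. `"TREATS"`).
#' @param direction `"forward"` (subject to object) or `"reverse"`.
#' @return A one-row data frame with columns `from_semtype`, `predicate`,
#'   `to_semtype`, `direction`.
#' @export
metapath_step <- function(from, predicate, to,
                          direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  data.frame(from_semtype = from, predicate = predicate, to_semtype = to,
             direction = direction, stringsAsFactors = FALSE)
}

#' Construct a metapath
#'
#' An ordered chain of [metapath_step()]s in which adjacent steps must be
#' type-compatible (`to_semtype` of step *i* equals `from_semtype` of step
#' *i + 1*). A metapath is the type-level template whose concrete
#' instantiations connect a source concept to a target concept.
#'
#' @param steps a data frame of steps (rows in order), or a list of one-row
#'   step data frames which are bound together.
#' @return An object of class `metapath` (a data frame of steps).
#' @examples
#' mp <- metapath(rbind(
#'   metapath_step("PHSU", "AFFECTS", "GNGM"),
#'   metapath_step("GNGM", "ASSOCIATED_WITH", "DSYN")
#' ))
#' format(mp)
#' @export
metapath <- function(steps) {
  if (is.list(steps) && !is.data.frame(steps)) steps <- do.call(rbind, steps)
  steps <- as.data.frame(steps, stringsAsFactors = FALSE)
  need <- c("from_semtype", "predicate", "to_semtype", "direction")
  if (!all(need %in% names(steps)))
    stop("metapath steps need columns: ", paste(need, collapse = ", "))
  if (nrow(steps) < 1) stop("a metapath has at least one step")
  if (!all(steps$direction %in% c("forward", "reverse")))
    stop("step direction must be 'forward' or 'reverse'")
  if (nrow(steps) > 1) {
    ok <- steps$to_semtype[-nrow(steps)] == steps$from_semtype[-1]
    if (!all(ok))
      stop("adjacent metapath steps are not type-compatible at position(s): ",
           paste(which(!ok), collapse = ", "))
  }
  rownames(steps) <- NULL
  class(steps) <- c("metapath", "data.frame")
  steps
}

#' @export
format.metapath <- function(x, ...) {
  dir <- ifelse(x$direction == "forward", ">", "<")
  paste0(x$from_semtype[1],
         paste0("-[", x$predicate, dir, "]-", x$to_semtype, collapse = ""))
}

#' @export
print.metapath <- function(x, ...) {
  cat("metapath (length ", nrow(x), "): ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse the text notation of a metapath
#'
#' Inverse of `format()` on a metapath. Notation:
#' `"PHSU-[AFFECTS>]-GNGM-[ASSOCIATED_WITH>]-DSYN"`, with `<` in place of
#' `>` marking a reverse-traversed step.
#'
#' @param x a single metapath string.
#' @return A `metapath`.
#' @export
parse_metapath <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  m <- gregexpr("\\[([A-Z_]+)([<>])\\]", x)[[1]]
  if (m[1] == -1) stop("not a metapath string: ", x)
  preds <- regmatches(x, gregexpr("\\[([A-Z_]+)([<>])\\]", x))[[1]]
  types <- strsplit(gsub("-?\\[[A-Z_]+[<>]\\]-?", "\r", x), "\r")[[1]]
  if (length(types) != length(preds) + 1)
    stop("malformed metapath string: ", x)
  metapath(data.frame(
    from_semtype = types[-length(types)],
    predicate = sub("^\\[([A-Z_]+)[<>]\\]$", "\\1", preds),
    to_semtype = types[-1],
    direction = ifelse(grepl(">\\]$", preds), "forward", "reverse"),
    stringsAsFactors = FALSE
  ))
}

#' Reverse a metapath
#'
#' Reverses step order and flips each step's direction and endpoint types, so
#' that instances of `reverse_metapath(mp)` are exactly the reversed
#' instances of `mp`.
#'
#' @param mp a `metapath`.
#' @return A `metapath`.
#' @export
reverse_metapath <- function(mp) {
  stopifnot(inherits(mp, "metapath"))
  rev_steps <- mp[rev(seq_len(nrow(mp))), , drop = FALSE]
  out <- data.frame(
    from_semtype = rev_steps$to_semtype,
    predicate = rev_steps$predicate,
    to_semtype = rev_steps$from_semtype,
    direction = ifelse(rev_steps$direction == "forward", "reverse", "forward"),
    stringsAsFactors = FALSE
  )
  metapath(out)
}

#' Concatenate metapaths
#'
#' @param ... metapaths whose endpoint types chain compatibly.
#' @return A `metapath`.
#' @export
concat_metapaths <- function(...) {
  parts <- list(...)
  metapath(do.call(rbind, lapply(parts, as.data.frame)))
}

# Edge table for one step: data frame (from, to, weight) of concrete hops.
.step_edges <- function(graph, step) {
  e <- graph$edges
  e <- e[e$predicate == step$predicate, , drop = FALSE]
  st <- .node_semtype(graph)
  if (step$direction == "forward") {
    keep <- st[e$subject_cui] == step$from_semtype &
      st[e$object_cui] == step$to_semtype
    data.frame(from = e$subject_cui[keep], to = e$object_cui[keep],
               weight = e$support_count[keep],
               eid = paste(e$subject_cui, e$predicate, e$object_cui,
                           sep = "|")[keep],
               stringsAsFactors = FALSE)
  } else {
    keep <- st[e$object_cui] == step$from_semtype &
      st[e$subject_cui] == step$to_semtype
    data.frame(from = e$object_cui[keep], to = e$subject_cui[keep],
               weight = e$support_count[keep],
               eid = paste(e$subject_cui, e$predicate, e$object_cui,
                           sep = "|")[keep],
               stringsAsFactors = FALSE)
  }
}

# All concrete instances of mp from s (matrix of node CUIs, one row per
# instance, ncol = length + 1, last column constrained to t when given).
.instances <- function(graph, s, mp, t = NULL, mode = c("simple", "walk"),
                       max_rows = 1e6) {
  mode <- match.arg(mode)
  paths <- matrix(s, ncol = 1)
  for (k in seq_len(nrow(mp))) {
    e <- .step_edges(graph, mp[k, , drop = FALSE])
    if (nrow(e) == 0 || nrow(paths) == 0)
      return(matrix(character(0), ncol = nrow(mp) + 1))
    hit <- data.frame(pid = seq_len(nrow(paths)), node = paths[, k],
                      stringsAsFactors = FALSE)
    mrg <- merge(hit, e, by.x = "node", by.y = "from")
    if (nrow(mrg) == 0)
      return(matrix(character(0), ncol = nrow(mp) + 1))
    new_paths <- cbind(paths[mrg$pid, , drop = FALSE], mrg$to)
    if (mode == "simple") {
      seen <- rowSums(new_paths[, seq_len(k), drop = FALSE] ==
                        new_paths[, k + 1]) > 0
      new_paths <- new_paths[!seen, , drop = FALSE]
    }
    if (nrow(new_paths) > max_rows)
      stop("path instance enumeration exceeded ", max_rows, " rows")
    paths <- new_paths
  }
  if (!is.null(t)) paths <- paths[paths[, nrow(mp) + 1] == t, , drop = FALSE]
  paths
}

.check_mp_endpoints <- function(graph, s, t, mp) {
  .check_cui(graph, c(s, t))
  st <- .node_semtype(graph)
  if (st[[s]] != mp$from_semtype[1])
    stop("source ", s, " has semtype ", st[[s]], ", metapath starts at ",
         mp$from_semtype[1])
  if (st[[t]] != mp$to_semtype[nrow(mp)])
    stop("target ", t, " has semtype ", st[[t]], ", metapath ends at ",
         mp$to_semtype[nrow(mp)])
  invisible(TRUE)
}

#' Count concrete instances of a metapath between two nodes
#'
#' Number of node sequences that instantiate `mp` from `s` to `t`. By
#' default instances are simple paths (no node revisited within one
#' instance); `mode = "walk"` counts walks, the semantics under which the
#' matrix HeteSim operates.
#'
#' @param graph a `predication_kg`.
#' @param s,t source and target CUIs; their semantic types must match the
#'   metapath endpoints.
#' @param mp a `metapath`.
#' @param mode `"simple"` (default) or `"walk"`.
#' @return Non-negative integer.
#' @export
count_paths <- function(graph, s, t, mp, mode = c("simple", "walk")) {
  stopifnot(inherits(graph, "predication_kg"), inherits(mp, "metapath"))
  mode <- match.arg(mode)
  .check_mp_endpoints(graph, s, t, mp)
  nrow(.instances(graph, s, mp, t = t, mode = mode))
}

#' Degree-weighted path count
#'
#' Sum over concrete instances of `mp` from `s` to `t` of the product, over
#' every node on the instance (endpoints included), of
#' `degree(node)^(-w)`. Degrees are whole-graph undirected degrees
#' ([node_degree()]). With `w = 0` this equals [count_paths()] exactly;
#' larger `w` increasingly discounts paths through promiscuous hub nodes.
#' Endpoints are included in the product so that high-degree "popular"
#' source drugs are themselves penalized.
#'
#' @inheritParams count_paths
#' @param w damping exponent, finite and `>= 0`.
#' @return Non-negative real.
#' @export
dwpc <- function(graph, s, t, mp, w = 0.4, mode = c("simple", "walk")) {
  stopifnot(inherits(graph, "predication_kg"), inherits(mp, "metapath"),
            is.finite(w), w >= 0)
  mode <- match.arg(mode)
  .check_mp_endpoints(graph, s, t, mp)
  inst <- .instances(graph, s, mp, t = t, mode = mode)
  if (nrow(inst) == 0) return(0)
  degw <- graph$degree^(-w)
  sum(apply(inst, 1, function(p) prod(degw[p])))
}

# Walk-mode DWPC from every node of the metapath's source semtype to t,
# computed by sparse matrix products (used by run_simulation's correction).
.dwpc_all <- function(graph, mp, t, w) {
  from_nodes <- graph$semtype_index[[mp$from_semtype[1]]]
  if (is.null(from_nodes)) return(numeric(0))
  degw <- graph$degree^(-w)
  P <- Matrix::Diagonal(x = degw[from_nodes])
  dimnames(P) <- list(from_nodes, from_nodes)
  for (k in seq_len(nrow(mp))) {
    step <- mp[k, , drop = FALSE]
    to_nodes <- graph$semtype_index[[step$to_semtype]]
    if (is.null(to_nodes)) return(stats::setNames(numeric(length(from_nodes)),
                                                  from_nodes))
    e <- .step_edges(graph, step)
    cn <- colnames(P)
    keep <- e$from %in% cn
    e <- e[keep, , drop = FALSE]
    W <- Matrix::sparseMatrix(i = match(e$from, cn), j = match(e$to, to_nodes),
                              x = rep(1, nrow(e)),
                              dims = c(length(cn), length(to_nodes)),
                              dimnames = list(cn, to_nodes))
    D <- Matrix::Diagonal(x = degw[to_nodes])
    dimnames(D) <- list(to_nodes, to_nodes)
    P <- P %*% W %*% D
  }
  if (!t %in% colnames(P)) return(stats::setNames(numeric(length(from_nodes)),
                                                  from_nodes))
  out <- as.numeric(P[, t])
  names(out) <- from_nodes
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate metapaths reaching a target node
#'
#' Finds every type-level metapath of length `<= max_len` that starts at any
#' semantic type in `source_semtypes` and ends at `target_cui`'s type, for
#' which at least one concrete simple-path instance terminating exactly at
#' `target_cui` exists. The search walks the concrete graph backwards from
#' the target, so only instantiated templates are returned.
#'
#' @param graph a `predication_kg`.
#' @param source_semtypes character vector of starting semantic types.
#' @param target_cui CUI of the target node (must be in the graph).
#' @param max_len maximum metapath length, between 1 and 4.
#' @param predicate_allowlist optional predicate filter; when given, only
#'   edges with these predicates are traversed.
#' @return List of `metapath` objects, deduplicated and ordered by length
#'   then lexicographically by their text notation.
#' @export
enumerate_metapaths <- function(graph, source_semtypes, target_cui,
                                max_len = 3, predicate_allowlist = NULL) {
  stopifnot(inherits(graph, "predication_kg"))
  if (max_len < 1 || max_len > 4)
    stop("max_len must be between 1 and 4")
  .check_cui(graph, target_cui)
  st <- .node_semtype(graph)
  e <- graph$edges
  if (!is.null(predicate_allowlist))
    e <- e[e$predicate %in% predicate_allowlist, , drop = FALSE]
  if (nrow(e) == 0) return(list())
  # incidence table for backward expansion: anchor is the step's *end* node
  inc <- rbind(
    data.frame(anchor = e$object_cui, nbr = e$subject_cui,
               pred = e$predicate, dir = ">", stringsAsFactors = FALSE),
    data.frame(anchor = e$subject_cui, nbr = e$object_cui,
               pred = e$predicate, dir = "<", stringsAsFactors = FALSE)
  )
  inc$stepsig <- paste0(unname(st[inc$nbr]), "-[", inc$pred, inc$dir, "]-")

  sigs <- character(0)
  lens <- integer(0)
  frontier <- data.frame(node = target_cui, sig = unname(st[target_cui]),
                         stringsAsFactors = FALSE)
  hist <- matrix(target_cui, ncol = 1)
  for (d in seq_len(max_len)) {
    mrg <- merge(cbind(frontier, pid = seq_len(nrow(frontier))), inc,
                 by.x = "node", by.y = "anchor")
    if (nrow(mrg) == 0) break
    new_hist <- cbind(hist[mrg$pid, , drop = FALSE], mrg$nbr)
    revisit <- rowSums(new_hist[, seq_len(d), drop = FALSE] ==
                         new_hist[, d + 1]) > 0
    mrg <- mrg[!revisit, , drop = FALSE]
    new_hist <- new_hist[!revisit, , drop = FALSE]
    if (nrow(mrg) == 0) break
    new_sig <- paste0(mrg$stepsig, mrg$sig)
    hit <- unname(st[mrg$nbr]) %in% source_semtypes
    if (any(hit)) {
      add <- unique(new_sig[hit])
      fresh <- !(add %in% sigs)
      sigs <- c(sigs, add[fresh])
      lens <- c(lens, rep(d, sum(fresh)))
    }
    frontier <- data.frame(node = mrg$nbr, sig = new_sig,
                           stringsAsFactors = FALSE)
    hist <- new_hist
  }
  if (!length(sigs)) return(list())
  ord <- order(lens, sigs)
  lapply(sigs[ord], parse_metapath)
}
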