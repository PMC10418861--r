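# HeteSim: midpoint-split cosine relevance along a metapath.
#
# Matrix formulation: for an even-length path, the left distribution is the
# source row of the product of the row-stochastic transition operators of the
# first half; the right distribution is the target row of the product of the
# reversed (transposed, re-normalized) operators of the second half, composed
# from the target inward. The score is the cosine of the two midpoint
# distributions. Odd-length paths split on the middle relation: each edge of
# the middle step becomes an instance point and both halves distribute onto
# those edge instances. Scores are in [0, 1]; an unreachable side scores 0.

.row_normalize <- function(M) {
  rs <- Matrix::rowSums(M)
  nz <- rs > 0
  if (any(nz)) M[nz, ] <- M[nz, , drop = FALSE] / rs[nz]
  M
}

#' Row-stochastic transition operator for a metapath step
#'
#' Maps nodes of the step's `from_semtype` to nodes of its `to_semtype`:
#' entry `(a, b)` is positive iff an edge with the step's predicate connects
#' `a` to `b` in the step's direction, and every nonzero row sums to 1.
#' With `weighted = TRUE` edge mass is proportional to `support_count`
#' before normalization; the default is unweighted binary adjacency (all
#' literature sources treated equally).
#'
#' @param graph a `predication_kg`.
#' @param step one-row step data frame from [metapath_step()].
#' @param weighted use support counts as edge mass.
#' @return A sparse `Matrix` with CUI dimnames.
#' @export
transition_operator <- function(graph, step, weighted = FALSE) {
  stopifnot(inherits(graph, "predication_kg"))
  from_nodes <- graph$semtype_index[[step$from_semtype]]
  to_nodes <- graph$semtype_index[[step$to_semtype]]
  if (is.null(from_nodes) || is.null(to_nodes))
    stop("no nodes of semtype ", step$from_semtype, " or ", step$to_semtype,
         " in graph")
  e <- .step_edges(graph, step)
  if (nrow(e) == 0)
    warning("no edges instantiate step ", step$from_semtype, "-[",
            step$predicate, ifelse(step$direction == "forward", ">", "<"),
            "]-", step$to_semtype)
  M <- Matrix::sparseMatrix(
    i = match(e$from, from_nodes), j = match(e$to, to_nodes),
    x = if (weighted) e$weight else rep(1, nrow(e)),
    dims = c(length(from_nodes), length(to_nodes)),
    dimnames = list(from_nodes, to_nodes)
  )
  .row_normalize(M)
}

# Incidence operators for the middle step of an odd-length metapath:
# AE maps from-side nodes onto edge instances, BE maps to-side nodes onto
# edge instances (both row-normalized).
.edge_incidence <- function(graph, step, weighted = FALSE) {
  from_nodes <- graph$semtype_index[[step$from_semtype]]
  to_nodes <- graph$semtype_index[[step$to_semtype]]
  e <- .step_edges(graph, step)
  eids <- unique(e$eid)
  if (!length(eids)) {
    AE <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(length(from_nodes), 0),
                               dimnames = list(from_nodes, character(0)))
    BE <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(length(to_nodes), 0),
                               dimnames = list(to_nodes, character(0)))
    return(list(AE = AE, BE = BE))
  }
  w <- if (weighted) e$weight else rep(1, nrow(e))
  AE <- Matrix::sparseMatrix(i = match(e$from, from_nodes),
                             j = match(e$eid, eids), x = w,
                             dims = c(length(from_nodes), length(eids)),
                             dimnames = list(from_nodes, eids))
  BE <- Matrix::sparseMatrix(i = match(e$to, to_nodes),
                             j = match(e$eid, eids), x = w,
                             dims = c(length(to_nodes), length(eids)),
                             dimnames = list(to_nodes, eids))
  list(AE = .row_normalize(AE), BE = .row_normalize(BE))
}

.op_cached <- function(graph, step, weighted, reverse = FALSE, cache = NULL) {
  if (reverse) {
    step <- data.frame(from_semtype = step$to_semtype,
                       predicate = step$predicate,
                       to_semtype = step$from_semtype,
                       direction = ifelse(step$direction == "forward",
                                          "reverse", "forward"),
                       stringsAsFactors = FALSE)
  }
  key <- paste(step$from_semtype, step$predicate, step$to_semtype,
               step$direction, weighted, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  op <- suppressWarnings(transition_operator(graph, step, weighted))
  if (!is.null(cache)) cache[[key]] <- op
  op
}

# Midpoint distributions for all source nodes at once.
# Returns list(left = matrix sources x mid, right = numeric vector over mid).
.hetesim_midpoints <- function(graph, t, mp, weighted = FALSE, cache = NULL) {
  L <- nrow(mp)
  m <- L %/% 2
  odd <- L %% 2 == 1
  left <- NULL
  if (m >= 1) {
    for (k in seq_len(m)) {
      op <- .op_cached(graph, mp[k, , drop = FALSE], weighted, cache = cache)
      left <- if (is.null(left)) op else left %*% op
    }
  }
  right <- NULL
  lo <- if (odd) m + 2 else m + 1
  if (L >= lo) {
    for (k in seq(L, lo)) {
      op <- .op_cached(graph, mp[k, , drop = FALSE], weighted,
                       reverse = TRUE, cache = cache)
      right <- if (is.null(right)) op else right %*% op
    }
  }
  if (odd) {
    midinc <- .edge_incidence(graph, mp[m + 1, , drop = FALSE], weighted)
    left <- if (is.null(left)) midinc$AE else left %*% midinc$AE
    right <- if (is.null(right)) midinc$BE else right %*% midinc$BE
  }
  rvec <- if (t %in% rownames(right)) as.numeric(right[t, ]) else
    numeric(ncol(right))
  list(left = left, right = rvec)
}

#' HeteSim relevance of every candidate source node to a target
#'
#' Vectorized form of [hetesim_score()]: one matrix pass computes the score
#' of every node of the metapath's source semantic type against `t`.
#'
#' @inheritParams transition_operator
#' @param t target CUI; its semantic type must equal the metapath's end type.
#' @param mp a `metapath`.
#' @return Named numeric vector (one score per source-semtype node), each in
#'   `[0, 1]`.
#' @export
hetesim_all_sources <- function(graph, t, mp, weighted = FALSE) {
  stopifnot(inherits(graph, "predication_kg"), inherits(mp, "metapath"))
  .check_cui(graph, t)
  st <- .node_semtype(graph)
  if (st[[t]] != mp$to_semtype[nrow(mp)])
    stop("target ", t, " has semtype ", st[[t]], ", metapath ends at ",
         mp$to_semtype[nrow(mp)])
  mids <- .hetesim_midpoints(graph, t, mp, weighted)
  left <- mids$left
  r <- mids$right
  rn <- sqrt(sum(r^2))
  out <- stats::setNames(numeric(nrow(left)), rownames(left))
  if (rn == 0) return(out)
  num <- as.numeric(left %*% r)
  ln <- sqrt(Matrix::rowSums(left^2))
  nz <- ln > 0
  out[nz] <- num[nz] / (ln[nz] * rn)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' HeteSim relevance score along a metapath
#'
#' The canonical HeteSim measure: split the metapath at its midpoint, push a
#' uniform random walk from the source forward along the first half and from
#' the target backward along the second half, and take the cosine similarity
#' of the two midpoint reachability distributions. Odd-length paths split on
#' the middle relation's edge instances. The score is a normalized measure
#' of relatedness in `[0, 1]`; if either side cannot reach the midpoint the
#' score is 0.
#'
#' @inheritParams hetesim_all_sources
#' @param s source CUI; its semantic type must equal the metapath's start
#'   type.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' g <- knowledge_graph(
#'   data.frame(cui = sprintf("C900000%d", 1:5),
#'              name = c("d1", "d2", "g1", "g2", "D"),
#'              semtype = c("PHSU", "PHSU", "GNGM", "GNGM", "DSYN")),
#'   data.frame(subject_cui = c("C9000001", "C9000001", "C9000002",
#'                              "C9000003", "C9000004"),
#'              predicate = c("AFFECTS", "AFFECTS", "AFFECTS",
#'                            "ASSOCIATED_WITH", "ASSOCIATED_WITH"),
#'              object_cui = c("C9000003", "C9000004", "C9000003",
#'                             "C9000005", "C9000005")))
#' mp <- parse_metapath("PHSU-[AFFECTS>]-GNGM-[ASSOCIATED_WITH>]-DSYN")
#' hetesim_score(g, "C9000001", "C9000005", mp)  # 1
#' hetesim_score(g, "C9000002", "C9000005", mp)  # 1/sqrt(2)
#' @export
hetesim_score <- function(graph, s, t, mp, weighted = FALSE) {
  stopifnot(inherits(mp, "metapath"))
  .check_mp_endpoints(graph, s, t, mp)
  unname(hetesim_all_sources(graph, t, mp, weighted)[s])
}

# ---- independent oracle: explicit walk enumeration ------------------------

# Recursively enumerate walks from `start` along `steps`, splitting mass
# uniformly (or by support weight) at each hop, and accumulate the mass
# arriving at each terminal node. `half_edge`, when given, is a middle step
# whose matching incident edges are the terminal points (`side` picks which
# endpoint the walker stands on). No matrix algebra is used.
.walk_mass <- function(graph, start, steps, weighted, half_edge = NULL,
                       side = c("from", "to"), guard) {
  side <- match.arg(side)
  acc <- new.env(parent = emptyenv())
  edge_tabs <- lapply(steps, function(k) .step_edges(graph, k))
  half_tab <- if (!is.null(half_edge)) .step_edges(graph, half_edge) else NULL
  recurse <- function(u, mass, depth) {
    if (depth > length(edge_tabs)) {
      if (is.null(half_tab)) {
        acc[[u]] <- (acc[[u]] %||% 0) + mass
      } else {
        rows <- which(half_tab[[side]] == u)
        guard$n <- guard$n + length(rows)
        if (guard$n > guard$max)
          stop("walk enumeration guard exceeded (", guard$max,
               " extensions); use the matrix implementation")
        if (length(rows)) {
          w <- if (weighted) half_tab$weight[rows] else rep(1, length(rows))
          p <- mass * w / sum(w)
          for (i in seq_along(rows)) {
            eid <- half_tab$eid[rows[i]]
            acc[[eid]] <- (acc[[eid]] %||% 0) + p[i]
          }
        }
      }
      return(invisible(NULL))
    }
    tab <- edge_tabs[[depth]]
    rows <- which(tab$from == u)
    guard$n <- guard$n + length(rows)
    if (guard$n > guard$max)
      stop("walk enumeration guard exceeded (", guard$max,
           " extensions); use the matrix implementation")
    if (!length(rows)) return(invisible(NULL))
    w <- if (weighted) tab$weight[rows] else rep(1, length(rows))
    p <- mass * w / sum(w)
    for (i in seq_along(rows)) recurse(tab$to[rows[i]], p[i], depth + 1)
    invisible(NULL)
  }
  recurse(start, 1, 1)
  vals <- as.list(acc)
  if (!length(vals)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(unlist(vals)), names(vals))
}

#' Brute-force HeteSim oracle
#'
#' Computes the same score as [hetesim_score()] by explicit enumeration of
#' every walk from the source (forward) and the target (backward) to the
#' path midpoint, accumulating midpoint probabilities walk by walk with no
#' matrix algebra. Intended as an independent cross-check on small graphs; a
#' guard refuses inputs that would require more than `max_extensions` walk
#' extensions.
#'
#' @inheritParams hetesim_score
#' @param max_extensions enumeration guard (default `1e6`).
#' @return Numeric scalar in `[0, 1]`.
#' @export
hetesim_brute_force <- function(graph, s, t, mp, weighted = FALSE,
                                max_extensions = 1e6) {
  stopifnot(inherits(mp, "metapath"))
  .check_mp_endpoints(graph, s, t, mp)
  L <- nrow(mp)
  m <- L %/% 2
  odd <- L %% 2 == 1
  guard <- new.env(parent = emptyenv())
  guard$n <- 0
  guard$max <- max_extensions
  left_steps <- lapply(seq_len(m), function(k) mp[k, , drop = FALSE])
  rev_mp <- reverse_metapath(mp)
  right_steps <- lapply(seq_len(m), function(k) rev_mp[k, , drop = FALSE])
  if (odd) {
    mid <- mp[m + 1, , drop = FALSE]
    lvec <- .walk_mass(graph, s, left_steps, weighted, half_edge = mid,
                       side = "from", guard = guard)
    rvec <- .walk_mass(graph, t, right_steps, weighted, half_edge = mid,
                       side = "to", guard = guard)
  } else {
    lvec <- .walk_mass(graph, s, left_steps, weighted, guard = guard)
    rvec <- .walk_mass(graph, t, right_steps, weighted, guard = guard)
  }
  if (!length(lvec) || !length(rvec)) return(0)
  keys <- union(names(lvec), names(rvec))
  l <- stats::setNames(numeric(length(keys)), keys)
  r <- l
  l[names(lvec)] <- lvec
  r[names(rvec)] <- rvec
  ln <- sqrt(sum(l^2))
  rn <- sqrt(sum(r^2))
  if (ln == 0 || rn == 0) return(0)
  min(1, max(0, sum(l * r) / (ln * rn)))
}

#' Aggregate HeteSim over metapaths and targets
#'
#' Per target, the arithmetic mean of [hetesim_score()] over all supplied
#' metapaths, scoring 0 where a metapath has no instance or its endpoint
#' types do not match the pair; the overall value is the arithmetic mean
#' over targets. Always in `[0, 1]`.
#'
#' @inheritParams hetesim_score
#' @param targets non-empty character vector of target CUIs.
#' @param metapaths non-empty list of `metapath` objects.
#' @return Numeric scalar in `[0, 1]`.
#' @export
aggregate_hetesim <- function(graph, s, targets, metapaths, weighted = FALSE) {
  if (!length(metapaths)) stop("metapath list must be non-empty")
  if (!length(targets)) stop("target list must be non-empty")
  .check_cui(graph, c(s, targets))
  st <- .node_semtype(graph)
  per_target <- vapply(targets, function(t) {
    scores <- vapply(metapaths, function(mp) {
      if (st[[s]] != mp$from_semtype[1] ||
          st[[t]] != mp$to_semtype[nrow(mp)]) return(0)
      hetesim_score(graph, s, t, mp, weighted)
    }, numeric(1))
    mean(scores)
  }, numeric(1))
  mean(per_target)
}
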