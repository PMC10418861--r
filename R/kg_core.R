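#' Common UMLS semantic-type codes
#'
#' A small registry of 4-letter UMLS semantic-type abbreviations used
#' throughout the package and by the synthetic generator. The registry is
#' advisory: any 4-letter uppercase code is structurally valid, but codes
#' outside the registry trigger a warning at load so typos surface early.
#'
#' @format Character vector of semantic-type codes.
#' @export
umls_semtypes <- c(
  PHSU = "Pharmacologic Substance",
  CLND = "Clinical Drug",
  TOPP = "Therapeutic or Preventive Procedure",
  DSYN = "Disease or Syndrome",
  GNGM = "Gene or Genome",
  AAPP = "Amino Acid, Peptide, or Protein",
  NEOP = "Neoplastic Process",
  ORCH = "Organic Chemical",
  BACS = "Biologically Active Substance",
  CELL = "Cell",
  MOFT = "Molecular Function",
  PATF = "Pathologic Function"
)

.cui_ok <- function(cui) grepl("^C[0-9]{7}$", cui)

#' Construct a predication knowledge graph
#'
#' Builds the typed multigraph container used by every other function in the
#' package: UMLS-style concept nodes (CUI, preferred name, 4-letter semantic
#' type) joined by directed predication edges with aggregated support counts.
#'
#' Self-loop predications are dropped (with a warning) and duplicate
#' `(subject, predicate, object)` rows are aggregated by summing their
#' `support_count`, mirroring how SemMedDB aggregates sentence-level
#' predications into one record per triple.
#'
#' @param nodes data frame with columns `cui`, `name`, `semtype`.
#' @param edges data frame with columns `subject_cui`, `predicate`,
#'   `object_cui` and optional `support_count` (defaults to 1).
#' @return An object of class `predication_kg`: a list with elements
#'   `nodes`, `edges`, `semtype_index` (list of CUIs per semantic type),
#'   `predicates` (edge predicate vocabulary) and `degree` (named vector of
#'   undirected degrees, one count per aggregated predication).
#' @examples
#' nodes <- data.frame(cui = c("C9000001", "C9000002"),
#'                     name = c("drug a", "disease b"),
#'                     semtype = c("PHSU", "DSYN"))
#' edges <- data.frame(subject_cui = "C9000001", predicate = "TREATS",
#'                     object_cui = "C9000002")
#' g <- knowledge_graph(nodes, edges)
#' node_degree(g, "C9000001")
#' @export
knowledge_graph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_n <- c("cui", "name", "semtype")
  if (!all(need_n %in% names(nodes)))
    stop("nodes must have columns: ", paste(need_n, collapse = ", "))
  need_e <- c("subject_cui", "predicate", "object_cui")
  if (!all(need_e %in% names(edges)))
    stop("edges must have columns: ", paste(need_e, collapse = ", "))
  if (is.null(edges$support_count)) edges$support_count <- rep(1L, nrow(edges))
  edges$support_count <- as.integer(edges$support_count)

  bad <- nodes$cui[!.cui_ok(nodes$cui)]
  if (length(bad)) stop("malformed CUI(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(nodes$cui)) {
    dup <- duplicated(nodes$cui)
    nodes <- nodes[!dup, , drop = FALSE]
  }
  if (any(nodes$semtype == "" | nchar(nodes$semtype) != 4 |
          nodes$semtype != toupper(nodes$semtype)))
    stop("semtype codes must be 4-character uppercase")
  unknown <- setdiff(unique(nodes$semtype), names(umls_semtypes))
  if (length(unknown))
    warning("semtype code(s) outside the registered vocabulary: ",
            paste(unknown, collapse = ", "))

  if (nrow(edges)) {
    if (any(edges$support_count < 1L)) stop("support_count must be >= 1")
    loops <- edges$subject_cui == edges$object_cui
    if (any(loops)) {
      warning(sum(loops), " self-loop predication(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    missing_ep <- setdiff(c(edges$subject_cui, edges$object_cui), nodes$cui)
    if (length(missing_ep))
      stop("edge endpoint(s) not in node table: ",
           paste(utils::head(missing_ep, 5), collapse = ", "))
    if (nrow(edges)) {
      key <- paste(edges$subject_cui, edges$predicate, edges$object_cui, sep = "\r")
      if (anyDuplicated(key)) {
        sc <- rowsum(edges$support_count, key)
        first <- !duplicated(key)
        edges <- edges[first, , drop = FALSE]
        edges$support_count <-
          as.integer(sc[match(paste(edges$subject_cui, edges$predicate,
                                    edges$object_cui, sep = "\r"),
                              rownames(sc)), 1])
      }
    }
  }
  ord <- order(edges$subject_cui, edges$predicate, edges$object_cui)
  edges <- edges[ord, c("subject_cui", "predicate", "object_cui", "support_count"),
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$cui), c("cui", "name", "semtype"), drop = FALSE]
  rownames(nodes) <- NULL

  deg <- integer(nrow(nodes))
  names(deg) <- nodes$cui
  if (nrow(edges)) {
    tab <- table(c(edges$subject_cui, edges$object_cui))
    deg[names(tab)] <- as.integer(tab)
  }
  g <- list(
    nodes = nodes,
    edges = edges,
    semtype_index = split(nodes$cui, nodes$semtype),
    predicates = sort(unique(edges$predicate)),
    degree = deg
  )
  class(g) <- "predication_kg"
  g
}

#' @export
print.predication_kg <- function(x, ...) {
  iso <- sum(x$degree == 0)
  cat("predication knowledge graph\n")
  cat("  nodes:", nrow(x$nodes), "(", length(x$semtype_index), "semantic types",
      if (iso) paste0(", ", iso, " isolated") else "", ")\n")
  cat("  edges:", nrow(x$edges), "aggregated predications,",
      length(x$predicates), "predicates\n")
  invisible(x)
}

.node_semtype <- function(graph, cui = NULL) {
  st <- graph$nodes$semtype
  names(st) <- graph$nodes$cui
  if (is.null(cui)) st else st[cui]
}

.node_name <- function(graph, cui) {
  graph$nodes$name[match(cui, graph$nodes$cui)]
}

.check_cui <- function(graph, cui) {
  miss <- setdiff(cui, graph$nodes$cui)
  if (length(miss)) stop("CUI(s) not in graph: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Node degree
#'
#' Undirected degree of one or all nodes: the count of incident aggregated
#' predications, each counted once regardless of direction or support count.
#' This is the degree used by hub analysis ("a node that has a large degree
#' of connected, related nodes") and by the degree-weighted path count.
#'
#' @param graph a `predication_kg`.
#' @param cui optional CUI (or vector of CUIs); if `NULL`, all degrees.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(graph, cui = NULL) {
  stopifnot(inherits(graph, "predication_kg"))
  if (is.null(cui)) return(graph$degree)
  .check_cui(graph, cui)
  graph$degree[cui]
}

#' Read a predication triple file
#'
#' Parses a "SemMedDB-lite" delimited extract: a header-bearing TSV or CSV
#' with columns `subject_cui`, `subject_name`, `subject_semtype`,
#' `predicate`, `object_cui`, `object_name`, `object_semtype` and optional
#' `support_count` (default 1). Duplicate triples have their support summed
#' and self-loop rows are dropped with a warning; both behaviours mirror
#' [knowledge_graph()].
#'
#' @param path path to the triple file (or a connection).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param nodes_path optional node-only sidecar file (columns `cui`, `name`,
#'   `semtype`) carrying isolated nodes that appear in no predication.
#' @return A `predication_kg`.
#' @export
read_triples <- function(path, dialect = c("tsv", "csv"), nodes_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE, check.names = TRUE)
  mandatory <- c("subject_cui", "subject_name", "subject_semtype", "predicate",
                 "object_cui", "object_name", "object_semtype")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("triple file is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no predications in ", paste(path, collapse = ""))
  bad <- which(!.cui_ok(df$subject_cui) | !.cui_ok(df$object_cui))
  if (length(bad))
    stop("malformed CUI at data line(s): ", paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(df$support_count)) df$support_count <- "1"
  sc <- suppressWarnings(as.integer(df$support_count))
  if (anyNA(sc))
    stop("non-integer support_count at data line(s): ",
         paste(utils::head(which(is.na(sc)), 10), collapse = ", "))
  nodes <- data.frame(
    cui = c(df$subject_cui, df$object_cui),
    name = c(df$subject_name, df$object_name),
    semtype = c(df$subject_semtype, df$object_semtype),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[!duplicated(nodes$cui), , drop = FALSE]
  if (!is.null(nodes_path)) {
    side <- utils::read.table(nodes_path, header = TRUE, sep = sep, quote = "",
                              colClasses = "character", stringsAsFactors = FALSE)
    if (!all(c("cui", "name", "semtype") %in% names(side)))
      stop("node sidecar must have columns cui, name, semtype")
    nodes <- rbind(nodes, side[, c("cui", "name", "semtype")])
    nodes <- nodes[!duplicated(nodes$cui), , drop = FALSE]
  }
  edges <- data.frame(
    subject_cui = df$subject_cui, predicate = df$predicate,
    object_cui = df$object_cui, support_count = sc,
    stringsAsFactors = FALSE
  )
  knowledge_graph(nodes, edges)
}

#' Write a predication triple file
#'
#' Serializes a graph to the interchange format read by [read_triples()],
#' one row per aggregated predication, deterministically ordered by
#' `(subject_cui, predicate, object_cui)` so fixtures diff cleanly.
#'
#' @inheritParams node_degree
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param nodes_path optional path for a node-only sidecar (written only when
#'   given); required to round-trip graphs with isolated nodes.
#' @return Number of predication rows written (invisibly the same count).
#' @export
write_triples <- function(graph, path, dialect = c("tsv", "csv"),
                          nodes_path = NULL) {
  stopifnot(inherits(graph, "predication_kg"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  e <- graph$edges
  out <- data.frame(
    subject_cui = e$subject_cui,
    subject_name = .node_name(graph, e$subject_cui),
    subject_semtype = unname(.node_semtype(graph, e$subject_cui)),
    predicate = e$predicate,
    object_cui = e$object_cui,
    object_name = .node_name(graph, e$object_cui),
    object_semtype = unname(.node_semtype(graph, e$object_cui)),
    support_count = e$support_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(nodes_path))
    utils::write.table(graph$nodes, nodes_path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  nrow(out)
}

#' Filter a graph by semantic type
#'
#' Induced subgraph on the nodes whose semantic type is in `allowed`; edges
#' are kept iff both endpoints survive. This is the "constraining it based on
#' UMLS node type" operation applied before scoring.
#'
#' @inheritParams node_degree
#' @param allowed non-empty character vector of semantic-type codes. Codes
#'   absent from the graph produce a warning, not an error.
#' @return A `predication_kg`.
#' @export
filter_by_semtype <- function(graph, allowed) {
  stopifnot(inherits(graph, "predication_kg"))
  if (length(allowed) == 0) stop("'allowed' must be a non-empty set of semtypes")
  unknown <- setdiff(allowed, names(graph$semtype_index))
  if (length(unknown))
    warning("semtype(s) not present in graph: ", paste(unknown, collapse = ", "))
  keep <- graph$nodes$semtype %in% allowed
  nodes <- graph$nodes[keep, , drop = FALSE]
  e <- graph$edges
  ekeep <- e$subject_cui %in% nodes$cui & e$object_cui %in% nodes$cui
  knowledge_graph(nodes, e[ekeep, , drop = FALSE])
}

# Canonical text rendering of a graph (for digests / byte-level comparison).
.kg_canonical_text <- function(graph) {
  e <- graph$edges
  paste(c(
    paste(graph$nodes$cui, graph$nodes$name, graph$nodes$semtype, sep = "\t"),
    paste(e$subject_cui, e$predicate, e$object_cui, e$support_count, sep = "\t")
  ), collapse = "\n")
}

#' Digest of a knowledge graph
#'
#' MD5 of the canonical node + edge serialization; used in run manifests so a
#' result file records exactly which graph produced it.
#'
#' @inheritParams node_degree
#' @return Character scalar (32 hex digits).
#' @export
kg_digest <- function(graph) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(.kg_canonical_text(graph), tmp)
  unname(tools::md5sum(tmp))
}
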