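# Typed undirected multigraph: nodes carry an entity type, edges carry an
# optional interaction type. At most one edge per (endpoint pair, type)
# combination; parallel edges of different types are allowed.

# byte-wise (locale-independent) pairwise minimum/maximum of two id vectors
swap_endpoints <- function(a, b) {
  n <- length(a)
  if (n == 0L) return(logical(0))
  key <- c(a, b)
  o <- radix_order(key)
  r <- integer(2L * n)
  r[o] <- seq_len(2L * n)
  r[seq_len(n)] > r[n + seq_len(n)]
}

normalize_edges <- function(edges) {
  sw <- swap_endpoints(edges$from, edges$to)
  tmp <- edges$from[sw]
  edges$from[sw] <- edges$to[sw]
  edges$to[sw] <- tmp
  edges[radix_order(edges$from, edges$to, edges$type), , drop = FALSE]
}

check_labels <- function(x, what) {
  bad <- grepl("[,;|]", x)
  if (any(bad))
    abort(sprintf("%s labels may not contain ',', ';' or '|': %s",
                  what, x[which(bad)[1L]]),
          "tnmca_input_error")
}

#' Construct a typed undirected multigraph
#'
#' @param nodes data frame with character columns `id` (unique) and `type`
#'   (non-empty entity type label, e.g. `"chemical"`, `"gene"`, `"disease"`,
#'   `"pathway"`).
#' @param edges data frame with character columns `from`, `to` and optionally
#'   `type`; missing or blank types become [UNTYPED]. Endpoints are unordered:
#'   `{a,b}` and `{b,a}` denote the same edge. `NULL` gives an edgeless graph.
#'
#' @details Validation rejects (rather than silently drops) unknown endpoint
#' ids, self-loops and duplicate `(pair, type)` edges. Type labels may not
#' contain `','`, `';'` or `'|'`, which are reserved as separators in
#' canonical motif keys and output files. Nodes and edges are stored in a
#' deterministic byte order so that repeated writes are identical.
#'
#' @return An object of class `typed_graph` with components `nodes`
#'   (columns `id`, `type`) and `edges` (columns `from`, `to`, `type`).
#' @seealso [read_graph()], [write_graph()], [induced_subgraph()]
#' @export
#' @examples
#' g <- typed_graph(
#'   nodes = data.frame(id = c("d1", "g1", "s1"),
#'                      type = c("chemical", "gene", "disease")),
#'   edges = data.frame(from = c("d1", "g1"), to = c("g1", "s1"),
#'                      type = c("marker", "marker")))
#' g
typed_graph <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("id", "type") %in% names(nodes)))
    abort("nodes must have columns 'id' and 'type'", "tnmca_input_error")
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  if (anyNA(nodes$id) || any(nodes$id == ""))
    abort("node ids must be non-empty", "tnmca_input_error")
  if (anyDuplicated(nodes$id))
    abort(sprintf("duplicate node id: %s", nodes$id[duplicated(nodes$id)][1L]),
          "tnmca_integrity_error")
  if (anyNA(nodes$type) || any(nodes$type == ""))
    abort("node types must be non-empty", "tnmca_input_error")
  check_labels(nodes$type, "node type")

  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      abort("edges must have columns 'from' and 'to'", "tnmca_input_error")
    type <- if ("type" %in% names(edges)) as.character(edges$type)
            else rep(UNTYPED, nrow(edges))
    type[is.na(type) | type == ""] <- UNTYPED
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        type = type, stringsAsFactors = FALSE)
    check_labels(edges$type, "edge type")
    unknown <- !(edges$from %in% nodes$id) | !(edges$to %in% nodes$id)
    if (any(unknown)) {
      i <- which(unknown)[1L]
      abort(sprintf("edge %s -- %s references an undeclared node",
                    edges$from[i], edges$to[i]),
            "tnmca_integrity_error")
    }
    if (any(edges$from == edges$to)) {
      i <- which(edges$from == edges$to)[1L]
      abort(sprintf("self-loop on node %s is not allowed", edges$from[i]),
            "tnmca_integrity_error")
    }
    edges <- normalize_edges(edges)
    dup <- duplicated(edges)
    if (any(dup)) {
      i <- which(dup)[1L]
      abort(sprintf("duplicate edge (%s, %s, %s)",
                    edges$from[i], edges$to[i], edges$type[i]),
            "tnmca_integrity_error")
    }
  }

  nodes <- nodes[radix_order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "typed_graph")
}

#' @export
print.typed_graph <- function(x, ...) {
  nt <- table(x$nodes$type)
  et <- table(x$edges$type)
  cat(sprintf("typed_graph: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  if (length(nt))
    cat("  node types:", paste(sprintf("%s (%d)", names(nt), nt), collapse = ", "), "\n")
  if (length(et))
    cat("  edge types:", paste(sprintf("%s (%d)", names(et), et), collapse = ", "), "\n")
  invisible(x)
}

#' Node identifiers of a typed graph, optionally restricted to one type
#'
#' @param graph a [typed_graph()].
#' @param type entity type label, or `NULL` for all nodes.
#' @return Character vector of ids in deterministic (byte) order.
#' @export
node_ids <- function(graph, type = NULL) {
  stopifnot(inherits(graph, "typed_graph"))
  if (is.null(type)) graph$nodes$id
  else graph$nodes$id[graph$nodes$type %in% type]
}

#' Read a typed graph from node and edge TSV files
#'
#' Both files are UTF-8, tab-separated, with a header row; lines starting
#' with `#` are ignored. The node file has columns `node_id` and
#' `node_type`; the edge file has `source_id`, `target_id` and an optional
#' `edge_type` column whose blank entries map to [UNTYPED].
#'
#' @param nodes_path,edges_path file paths.
#' @return A validated [typed_graph()].
#' @export
read_graph <- function(nodes_path, edges_path) {
  for (p in c(nodes_path, edges_path))
    if (!file.exists(p))
      abort(sprintf("input file not found: %s", p), "tnmca_input_error")
  nd <- read.delim(nodes_path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "#", colClasses = "character",
                   check.names = FALSE, na.strings = character(0),
                   fileEncoding = "UTF-8")
  if (!all(c("node_id", "node_type") %in% names(nd)))
    abort(sprintf("%s: expected columns 'node_id' and 'node_type'", nodes_path),
          "tnmca_input_error")
  ed <- read.delim(edges_path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "#", colClasses = "character",
                   check.names = FALSE, na.strings = character(0),
                   fileEncoding = "UTF-8")
  if (!all(c("source_id", "target_id") %in% names(ed)))
    abort(sprintf("%s: expected columns 'source_id' and 'target_id'", edges_path),
          "tnmca_input_error")
  etype <- if ("edge_type" %in% names(ed)) ed$edge_type else rep("", nrow(ed))

  # pre-check endpoints so integrity errors can name the offending data row
  unknown <- !(ed$source_id %in% nd$node_id) | !(ed$target_id %in% nd$node_id)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    abort(sprintf("%s, data row %d: edge %s -- %s references an undeclared node",
                  edges_path, i, ed$source_id[i], ed$target_id[i]),
          "tnmca_integrity_error")
  }
  typed_graph(nodes = data.frame(id = nd$node_id, type = nd$node_type,
                                 stringsAsFactors = FALSE),
              edges = data.frame(from = ed$source_id, to = ed$target_id,
                                 type = etype, stringsAsFactors = FALSE))
}

#' Write a typed graph to node and edge TSV files
#'
#' Rows are emitted in a deterministic order (nodes by id; edges by
#' endpoint pair then type), so writing the same graph twice produces
#' byte-identical files and `read_graph(write_graph(g))` round-trips.
#'
#' @param graph a [typed_graph()].
#' @param nodes_path,edges_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_graph <- function(graph, nodes_path, edges_path) {
  stopifnot(inherits(graph, "typed_graph"))
  nd <- data.frame(node_id = graph$nodes$id, node_type = graph$nodes$type,
                   stringsAsFactors = FALSE)
  ed <- data.frame(source_id = graph$edges$from, target_id = graph$edges$to,
                   edge_type = graph$edges$type, stringsAsFactors = FALSE)
  write_tsv(nd, nodes_path)
  write_tsv(ed, edges_path)
  invisible(c(nodes_path, edges_path))
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    abort(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
          "tnmca_io_error")
  invisible(path)
}

#' Induced subgraph on a set of node ids
#'
#' Keeps exactly the requested nodes and all parent edges (including
#' parallel typed edges) whose endpoints both lie in the set.
#'
#' @param graph a [typed_graph()].
#' @param ids character vector of node ids, all present in `graph`.
#' @return A [typed_graph()].
#' @export
induced_subgraph <- function(graph, ids) {
  stopifnot(inherits(graph, "typed_graph"))
  ids <- unique(as.character(ids))
  missing <- setdiff(ids, graph$nodes$id)
  if (length(missing))
    abort(sprintf("unknown node id: %s", missing[1L]), "tnmca_lookup_error")
  keep_e <- graph$edges$from %in% ids & graph$edges$to %in% ids
  typed_graph(graph$nodes[graph$nodes$id %in% ids, , drop = FALSE],
              graph$edges[keep_e, , drop = FALSE])
}

# Integer-coded view of a graph for the C++ core. Type codes are assigned
# in sorted label order, which keeps canonical keys comparable across
# graphs whose type vocabularies differ.
graph_handle <- function(graph, extra_edge_labels = character(0)) {
  ids <- graph$nodes$id  # already in radix order
  node_labels <- sort(unique(graph$nodes$type), method = "radix")
  edge_labels <- sort(unique(c(graph$edges$type, extra_edge_labels)),
                      method = "radix")
  list(n = nrow(graph$nodes),
       ids = ids,
       ntype = match(graph$nodes$type, node_labels) - 1L,
       efrom = match(graph$edges$from, ids) - 1L,
       eto = match(graph$edges$to, ids) - 1L,
       etype = match(graph$edges$type, edge_labels) - 1L,
       node_labels = node_labels,
       edge_labels = edge_labels)
}
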