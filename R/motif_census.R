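# Typed network motif census: enumerate connected k-node induced subgraphs,
# map each valid instance to its motif class via canonical labeling, count.

#' Enumerate connected k-node subgraphs
#'
#' Yields every node set of size `k` whose induced subgraph is connected,
#' each exactly once (Wernicke's ESU over the untyped skeleton: parallel
#' typed edges collapse for connectivity). Validity as a motif (minimum
#' degree, distinct types) is judged separately by [is_valid_tnm()].
#'
#' @param graph a [typed_graph()].
#' @param k subgraph size; at least 3 (a two-node subgraph is a relation,
#'   not a pattern) and at most `max_k`.
#' @param max_k configured enumeration ceiling; the census is intended for
#'   small motifs (runtime grows steeply with `k`).
#' @return List of character vectors of node ids (each sorted), in
#'   deterministic order.
#' @export
enumerate_connected_subgraphs <- function(graph, k, max_k = 4L) {
  stopifnot(inherits(graph, "typed_graph"))
  k <- as.integer(k)
  if (is.na(k) || k < 3L)
    abort("k must be at least 3: a smaller subgraph is a relation, not a pattern",
          "tnmca_parameter_error")
  if (k > max_k)
    abort(sprintf("k = %d exceeds the configured maximum %d", k, max_k),
          "tnmca_parameter_error")
  h <- graph_handle(graph)
  if (h$n < k) return(list())
  m <- cpp_enumerate_ksets(h$n, h$ntype, h$efrom, h$eto, h$etype, k)
  if (nrow(m) == 0L) return(list())
  sets <- lapply(seq_len(nrow(m)), function(i) h$ids[m[i, ] + 1L])
  sets[radix_order(vapply(sets, paste, "", collapse = "\r"))]
}

#' Is a node set a valid typed network motif instance?
#'
#' A valid instance has at least 3 nodes, every node with degree >= 2
#' inside the induced subgraph (counting distinct neighbours: one-degree
#' nodes support no inference), and at least `min_distinct_types` distinct
#' node types.
#'
#' @param graph a [typed_graph()].
#' @param ids node ids inducing a connected subgraph.
#' @param min_distinct_types minimum number of distinct node types
#'   (default 3, the strict reading of the motif definition).
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_tnm <- function(graph, ids, min_distinct_types = 3L) {
  stopifnot(inherits(graph, "typed_graph"))
  ids <- as.character(ids)
  idx <- match(ids, graph$nodes$id)
  if (anyNA(idx))
    abort(sprintf("unknown node id: %s", ids[which(is.na(idx))[1L]]),
          "tnmca_lookup_error")
  h <- graph_handle(graph)
  cpp_valid_tnm(h$n, h$ntype, h$efrom, h$eto, h$etype, idx - 1L,
                as.integer(min_distinct_types))
}

#' Canonical form of a typed motif instance
#'
#' Maps the induced typed subgraph on `ids` to its isomorphism class under
#' type-preserving node permutations. Canonicalization is exhaustive
#' minimisation over all node orderings (cheap for motif sizes <= 5), so
#' two instances receive the same `canonical_key` exactly when a
#' type-preserving isomorphism exists between them.
#'
#' @inheritParams is_valid_tnm
#' @return An object of class `tnm_pattern` with fields `k`, `node_types`
#'   (labels in canonical position order), `edges` (data frame of position
#'   pairs and edge types) and `canonical_key` (the class identifier, e.g.
#'   `"chemical,disease,gene|1-2:therapeutic|1-3:marker|2-3:marker"`).
#' @export
canonical_form <- function(graph, ids, min_distinct_types = 3L) {
  if (!is_valid_tnm(graph, ids, min_distinct_types))
    abort("node set is not a valid typed network motif instance",
          "tnmca_contract_error")
  h <- graph_handle(graph)
  idx <- match(as.character(ids), graph$nodes$id)
  key <- cpp_canonical_key(h$n, h$ntype, h$efrom, h$eto, h$etype, idx - 1L,
                           h$node_labels, h$edge_labels)
  parse_pattern_key(key)
}

#' Canonical keys for many motif instances at once
#'
#' Batch form of [canonical_form()]: the graph is indexed once and the
#' canonical key of each node set is returned. All sets must be valid
#' motif instances of the same size.
#'
#' @inheritParams is_valid_tnm
#' @param sets list of node-id vectors, each of the same length.
#' @return Character vector of canonical keys, one per set.
#' @export
canonical_keys <- function(graph, sets, min_distinct_types = 3L) {
  stopifnot(inherits(graph, "typed_graph"))
  if (!length(sets)) return(character(0))
  k <- length(sets[[1L]])
  idx <- vapply(sets, function(s) match(as.character(s), graph$nodes$id),
                integer(k))
  if (anyNA(idx))
    abort("unknown node id in sets", "tnmca_lookup_error")
  h <- graph_handle(graph)
  cpp_canonical_keys(h$n, h$ntype, h$efrom, h$eto, h$etype,
                     t(idx) - 1L, as.integer(min_distinct_types),
                     h$node_labels, h$edge_labels)
}

parse_pattern_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
  node_types <- strsplit(parts[1L], ",", fixed = TRUE)[[1L]]
  ep <- parts[-1L]
  m <- regmatches(ep, regexec("^([0-9]+)-([0-9]+):(.*)$", ep))
  edges <- data.frame(
    a = vapply(m, function(x) as.integer(x[2L]), 1L),
    b = vapply(m, function(x) as.integer(x[3L]), 1L),
    type = vapply(m, function(x) x[4L], ""),
    stringsAsFactors = FALSE)
  structure(list(k = length(node_types), node_types = node_types,
                 edges = edges, canonical_key = key),
            class = "tnm_pattern")
}

#' @export
print.tnm_pattern <- function(x, ...) {
  cat(sprintf("tnm_pattern (k = %d): %s\n", x$k, x$canonical_key))
  invisible(x)
}

#' Build the typed network motif census
#'
#' Enumerates every connected induced `k`-node subgraph, keeps the valid
#' motif instances (see [is_valid_tnm()]) and counts them by canonical
#' key. Overlapping instances all count; the frequency of a motif class is
#' its raw occurrence count, used directly as the significance measure.
#'
#' @inheritParams enumerate_connected_subgraphs
#' @param min_distinct_types passed to the validity rule.
#' @return An object of class `tnm_census`: `k`, `frequencies` (named
#'   numeric vector, sorted by frequency descending then key) and `total`.
#' @export
#' @examples
#' g <- typed_graph(
#'   nodes = data.frame(id = c("d1", "g1", "s1"),
#'                      type = c("chemical", "gene", "disease")),
#'   edges = data.frame(from = c("d1", "g1", "d1"), to = c("g1", "s1", "s1"),
#'                      type = c("marker", "marker", "therapeutic")))
#' build_census(g, k = 3)
build_census <- function(graph, k, min_distinct_types = 3L, max_k = 4L) {
  stopifnot(inherits(graph, "typed_graph"))
  k <- as.integer(k)
  if (is.na(k) || k < 3L)
    abort("k must be at least 3", "tnmca_parameter_error")
  if (k > max_k)
    abort(sprintf("k = %d exceeds the configured maximum %d", k, max_k),
          "tnmca_parameter_error")
  h <- graph_handle(graph)
  res <- cpp_build_census(h$n, h$ntype, h$efrom, h$eto, h$etype, k,
                          as.integer(min_distinct_types),
                          h$node_labels, h$edge_labels)
  freq <- as.numeric(res$count)
  names(freq) <- as.character(res$key)
  freq <- freq[radix_order(-freq, names(freq))]
  structure(list(k = k, frequencies = freq, total = sum(freq)),
            class = "tnm_census")
}

#' @export
print.tnm_census <- function(x, ...) {
  cat(sprintf("tnm_census: %d motif classes of size k = %d, %d instances\n",
              length(x$frequencies), x$k, as.integer(x$total)))
  top <- utils::head(x$frequencies, 5L)
  for (i in seq_along(top))
    cat(sprintf("  %6d  %s\n", as.integer(top[i]), names(top)[i]))
  if (length(x$frequencies) > 5L) cat("  ...\n")
  invisible(x)
}

#' Relative frequency score of a motif class
#'
#' `Score(TNM_i) = Freq(TNM_i) / Freq(TNM_total)`, the proportion of all
#' counted size-`k` instances that fall in the class; always in (0, 1] and
#' summing to 1 over the census.
#'
#' @param census a [build_census()] result.
#' @param key one or more canonical keys present in the census.
#' @return Numeric vector of scores.
#' @export
tnm_score <- function(census, key) {
  stopifnot(inherits(census, "tnm_census"))
  f <- census$frequencies[key]
  if (anyNA(f))
    abort(sprintf("canonical key not present in census: %s",
                  key[which(is.na(f))[1L]]),
          "tnmca_lookup_error")
  unname(f) / census$total
}

#' @export
as.data.frame.tnm_census <- function(x, ...) {
  data.frame(canonical_key = names(x$frequencies),
             k = x$k,
             frequency = as.numeric(x$frequencies),
             score = as.numeric(x$frequencies) / x$total,
             stringsAsFactors = FALSE)
}

#' Write a motif census to disk
#'
#' @param census a [build_census()] result.
#' @param path output file.
#' @param format `"tsv"` (columns `canonical_key`, `k`, `frequency`,
#'   `score`, sorted by frequency descending then key) or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_census <- function(census, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(census)
  if (format == "tsv") {
    write_tsv(df, path)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
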