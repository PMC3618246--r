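# Training-network construction: drug whitelist filtering, disease
# hierarchy restriction, and answer-set hold-out.

#' Read a drug whitelist file
#'
#' One chemical id per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return Character vector of ids.
#' @export
read_whitelist <- function(path) {
  if (!file.exists(path))
    abort(sprintf("input file not found: %s", path), "tnmca_input_error")
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Read a disease tree-number map
#'
#' TSV with header columns `disease_id` and `tree_number` (MeSH-style
#' dot-separated hierarchical codes), one row per number; a disease may
#' have several tree numbers.
#'
#' @param path file path.
#' @return Named list: disease id -> character vector of tree numbers.
#' @export
read_tree_map <- function(path) {
  if (!file.exists(path))
    abort(sprintf("input file not found: %s", path), "tnmca_input_error")
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "#", colClasses = "character",
                   check.names = FALSE, na.strings = character(0),
                   fileEncoding = "UTF-8")
  if (!all(c("disease_id", "tree_number") %in% names(df)))
    abort(sprintf("%s: expected columns 'disease_id' and 'tree_number'", path),
          "tnmca_input_error")
  split(df$tree_number, df$disease_id)
}

#' Keep only whitelisted chemicals
#'
#' Removes every chemical-typed node not on the whitelist, together with
#' its incident edges (emulating restriction of CTD chemicals to DrugBank
#' drugs). Non-chemical nodes are untouched.
#'
#' @param graph a [typed_graph()].
#' @param whitelist non-empty character vector of chemical ids to keep.
#' @param chemical_type entity type label identifying chemicals.
#' @return The filtered [typed_graph()].
#' @export
filter_chemicals <- function(graph, whitelist, chemical_type = "chemical") {
  stopifnot(inherits(graph, "typed_graph"))
  whitelist <- as.character(whitelist)
  if (length(whitelist) == 0L)
    abort("empty whitelist would silently delete every chemical",
          "tnmca_config_error")
  keep <- graph$nodes$type != chemical_type | graph$nodes$id %in% whitelist
  ids <- graph$nodes$id[keep]
  keep_e <- graph$edges$from %in% ids & graph$edges$to %in% ids
  typed_graph(graph$nodes[keep, , drop = FALSE],
              graph$edges[keep_e, , drop = FALSE])
}

tree_prefix <- function(codes, depth) {
  vapply(strsplit(codes, ".", fixed = TRUE), function(seg)
    paste(seg[seq_len(min(depth, length(seg)))], collapse = "."), "")
}

#' Restrict diseases to the target's hierarchy neighbourhood
#'
#' Keeps a disease node iff one of its tree numbers shares a prefix of at
#' least `depth` segments with one of the target's tree numbers (MeSH
#' "same hierarchy" restriction; `depth = 1` keeps the target's top-level
#' category). The target itself is always kept. Removed nodes drop their
#' incident edges; `depth = 0` keeps all diseases.
#'
#' @param graph a [typed_graph()].
#' @param tree_map named list, disease id -> character vector of tree
#'   numbers (see [read_tree_map()]).
#' @param target target disease id; must be present in `tree_map`.
#' @param depth number of leading tree segments that must agree.
#' @param unknown_disease_policy what to do with disease nodes absent from
#'   `tree_map`: `"drop"` (default; a message reports the count) or
#'   `"keep"`.
#' @param disease_type entity type label identifying diseases.
#' @return The filtered [typed_graph()].
#' @export
filter_diseases_by_hierarchy <- function(graph, tree_map, target, depth = 1L,
                                         unknown_disease_policy = c("drop", "keep"),
                                         disease_type = "disease") {
  stopifnot(inherits(graph, "typed_graph"))
  unknown_disease_policy <- match.arg(unknown_disease_policy)
  depth <- as.integer(depth)
  if (!target %in% names(tree_map))
    abort(sprintf("target disease %s has no tree numbers in the map", target),
          "tnmca_config_error")
  if (depth <= 0L) return(graph)

  target_pref <- unique(tree_prefix(tree_map[[target]], depth))
  is_dis <- graph$nodes$type == disease_type
  dis_ids <- graph$nodes$id[is_dis]
  known <- dis_ids %in% names(tree_map)
  related <- vapply(dis_ids, function(d) {
    if (!d %in% names(tree_map)) return(NA)
    any(tree_prefix(tree_map[[d]], depth) %in% target_pref)
  }, logical(1))
  keep_dis <- ifelse(is.na(related), unknown_disease_policy == "keep", related)
  keep_dis[dis_ids == target] <- TRUE
  if (any(!known) && unknown_disease_policy == "drop")
    message(sprintf("dropping %d disease node(s) without tree numbers",
                    sum(!known & dis_ids != target)))

  keep <- !is_dis
  keep[is_dis] <- keep_dis
  ids <- graph$nodes$id[keep]
  keep_e <- graph$edges$from %in% ids & graph$edges$to %in% ids
  typed_graph(graph$nodes[keep, , drop = FALSE],
              graph$edges[keep_e, , drop = FALSE])
}

#' Hold out the target disease's chemical edges as the answer set
#'
#' Moves every chemical-target edge (any interaction type) out of the
#' graph into an answer set for later evaluation. The target node itself
#' remains, as do its non-chemical edges (gene-disease, disease-pathway),
#' so partial motif instances around the target stay available for
#' completion.
#'
#' @param graph a [typed_graph()].
#' @param target target disease id, present in `graph`.
#' @param chemical_type entity type label identifying chemicals.
#' @return List with `graph` (the training graph) and `answers` (data
#'   frame `drug_id`, `disease_id`, `edge_type`, disjoint from the
#'   training edges).
#' @export
holdout_answer_set <- function(graph, target, chemical_type = "chemical") {
  stopifnot(inherits(graph, "typed_graph"))
  if (!target %in% graph$nodes$id)
    abort(sprintf("target disease %s is absent from the graph", target),
          "tnmca_config_error")
  type_of <- function(ids) graph$nodes$type[match(ids, graph$nodes$id)]
  e <- graph$edges
  is_ans <- (e$from == target & type_of(e$to) == chemical_type) |
            (e$to == target & type_of(e$from) == chemical_type)
  drug <- ifelse(e$from == target, e$to, e$from)[is_ans]
  answers <- data.frame(drug_id = drug,
                        disease_id = rep(target, sum(is_ans)),
                        edge_type = e$type[is_ans],
                        stringsAsFactors = FALSE)
  answers <- answers[radix_order(answers$drug_id, answers$edge_type), ,
                     drop = FALSE]
  rownames(answers) <- NULL
  list(graph = typed_graph(graph$nodes, e[!is_ans, , drop = FALSE]),
       answers = answers)
}

#' Re-insert an answer set into a training graph
#'
#' Inverse of [holdout_answer_set()]: adding the held-out edges back
#' reconstructs the pre-holdout graph exactly.
#'
#' @param graph training [typed_graph()].
#' @param answers answer-set data frame (`drug_id`, `disease_id`,
#'   `edge_type`).
#' @return A [typed_graph()].
#' @export
reinsert_answers <- function(graph, answers) {
  stopifnot(inherits(graph, "typed_graph"))
  extra <- data.frame(from = answers$drug_id, to = answers$disease_id,
                      type = answers$edge_type, stringsAsFactors = FALSE)
  typed_graph(graph$nodes, rbind(graph$edges, extra))
}
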