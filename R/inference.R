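# Indication inference by single-edge motif completion: a missing typed
# drug-disease edge whose tentative insertion completes instances of motifs
# already in the census is proposed as a candidate and scored by noisy-OR
# over the distinct supporting motif classes.

#' Configuration for indication inference
#'
#' @param target_disease_id id of the disease whose indications are sought.
#' @param k motif size used for completion (3 or 4; the census must be
#'   built at the same `k`).
#' @param score_threshold minimum candidate score retained by
#'   [apply_threshold()]; default 0 keeps all candidates ranked by score,
#'   appropriate when the downstream evaluation sweeps the full ROC curve.
#' @param edge_types candidate interaction-type vocabulary for the proposed
#'   edge. `NULL` (default) uses the chemical-disease edge types observed
#'   in the training graph plus [UNTYPED].
#' @param chemical_type,disease_type entity type labels identifying drugs
#'   and diseases.
#' @param min_distinct_types motif validity rule, see [is_valid_tnm()].
#' @param all_pairs widen the candidate universe from (drug, target) pairs
#'   to all drug-disease pairs.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(target_disease_id, k = 3L, score_threshold = 0,
                             edge_types = NULL, chemical_type = "chemical",
                             disease_type = "disease", min_distinct_types = 3L,
                             all_pairs = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L)
    abort("k must be at least 3", "tnmca_parameter_error")
  if (!is.numeric(score_threshold) || is.na(score_threshold) ||
      score_threshold < 0 || score_threshold > 1)
    abort("score_threshold must lie in [0, 1]", "tnmca_parameter_error")
  structure(list(target_disease_id = as.character(target_disease_id), k = k,
                 score_threshold = score_threshold, edge_types = edge_types,
                 chemical_type = chemical_type, disease_type = disease_type,
                 min_distinct_types = as.integer(min_distinct_types),
                 all_pairs = isTRUE(all_pairs)),
            class = "inference_config")
}

#' Candidate interaction-type vocabulary
#'
#' The edge types proposed for new indications: the configured vocabulary,
#' or when unset the chemical-disease edge types observed in the training
#' graph together with [UNTYPED].
#'
#' @param graph training [typed_graph()].
#' @param config an [inference_config()].
#' @return Sorted character vector.
#' @export
candidate_edge_types <- function(graph, config) {
  if (!is.null(config$edge_types))
    return(sort(unique(as.character(config$edge_types)), method = "radix"))
  ntype <- graph$nodes$type[match(graph$edges$from, graph$nodes$id)]
  mtype <- graph$nodes$type[match(graph$edges$to, graph$nodes$id)]
  cd <- (ntype == config$chemical_type & mtype == config$disease_type) |
        (ntype == config$disease_type & mtype == config$chemical_type)
  sort(unique(c(graph$edges$type[cd], UNTYPED)), method = "radix")
}

#' Find candidate indications by single-edge motif completion
#'
#' For every drug `d`, candidate edge type `t` and target disease `s` such
#' that the typed edge `(d, s, t)` is absent from the training graph, the
#' edge is tentatively added; every valid k-node motif instance containing
#' the tentative edge whose canonical key exists in the census contributes
#' that key to the candidate's `referenced` set. Candidates with no
#' supporting motif are not emitted, and an edge already present with the
#' same type is never re-proposed (only new knowledge is inferred; a
#' different type may still be proposed for the same pair).
#'
#' @param graph training [typed_graph()].
#' @param census [build_census()] result built from `graph` at `config$k`.
#' @param config an [inference_config()].
#' @return Unscored candidates: data frame with columns `drug_id`,
#'   `disease_id`, `edge_type` and list column `referenced` (canonical
#'   keys). Pass to [score_candidates()].
#' @export
find_candidates <- function(graph, census, config) {
  stopifnot(inherits(graph, "typed_graph"), inherits(census, "tnm_census"),
            inherits(config, "inference_config"))
  if (census$k != config$k)
    abort(sprintf("census was built at k = %d but config requests k = %d",
                  census$k, config$k),
          "tnmca_config_error")
  diseases <- if (config$all_pairs) node_ids(graph, config$disease_type)
              else config$target_disease_id
  present <- diseases %in% graph$nodes$id
  if (!all(present))
    abort(sprintf("target disease %s is absent from the graph",
                  diseases[!present][1L]),
          "tnmca_config_error")
  drugs <- node_ids(graph, config$chemical_type)
  vocab <- candidate_edge_types(graph, config)
  h <- graph_handle(graph, extra_edge_labels = vocab)

  out <- lapply(diseases, function(s) {
    res <- cpp_find_candidates(h$n, h$ntype, h$efrom, h$eto, h$etype,
                               config$k, config$min_distinct_types,
                               h$node_labels, h$edge_labels,
                               match(s, h$ids) - 1L,
                               match(drugs, h$ids) - 1L,
                               match(vocab, h$edge_labels) - 1L,
                               names(census$frequencies))
    data.frame(drug_id = h$ids[res$drug + 1L],
               disease_id = rep(s, length(res$drug)),
               edge_type = h$edge_labels[res$etype + 1L],
               referenced = I(as.list(res$referenced)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Noisy-OR aggregation of referenced motif scores
#'
#' Combines the relative-frequency scores of the distinct motif classes
#' supporting a candidate as `1 - prod(1 - s_i)`. With no supporting
#' pattern the score is 0; with a single pattern it equals that pattern's
#' score; adding patterns never decreases it. For example, support from a
#' 20%-frequent and a 50%-frequent motif gives
#' `1 - (1 - 0.2) * (1 - 0.5) = 0.6`.
#'
#' @param referenced_scores numeric vector of scores in (0, 1], one per
#'   distinct referenced motif class.
#' @return A single score in \[0, 1\].
#' @export
#' @examples
#' score_indication(c(0.2, 0.5))  # 0.6
score_indication <- function(referenced_scores) {
  s <- as.numeric(referenced_scores)
  if (length(s) == 0L) return(0)
  if (anyNA(s) || any(s <= 0) || any(s > 1))
    abort("referenced scores must lie in (0, 1]", "tnmca_contract_error")
  1 - prod(1 - s)
}

#' Score candidates against a census
#'
#' Adds the noisy-OR `score` (over the candidate's distinct referenced
#' motif classes) and the `tiebreak` key (summed frequencies of the
#' referenced classes, used to rank equal-scored candidates).
#'
#' @param candidates output of [find_candidates()].
#' @param census the census the candidates were generated from.
#' @return The candidate data frame with `score` and `tiebreak` columns.
#' @export
score_candidates <- function(candidates, census) {
  stopifnot(inherits(census, "tnm_census"), is.data.frame(candidates))
  candidates$score <- vapply(candidates$referenced, function(keys)
    score_indication(tnm_score(census, keys)), numeric(1))
  candidates$tiebreak <- vapply(candidates$referenced, function(keys)
    sum(census$frequencies[keys]), numeric(1))
  candidates
}

#' Rank scored candidates
#'
#' Descending by score; ties broken by higher summed frequency of the
#' referenced patterns; remaining ties by `(drug_id, edge_type)` byte
#' order so the ranking is a total order, identical across runs.
#'
#' @param candidates scored candidates (see [score_candidates()]).
#' @return The data frame reordered, with a `rank` column prepended.
#' @export
rank_candidates <- function(candidates) {
  stopifnot(is.data.frame(candidates), "score" %in% names(candidates))
  tb <- candidates$tiebreak %||% rep(0, nrow(candidates))
  o <- radix_order(-candidates$score, -tb, candidates$drug_id,
                   candidates$edge_type)
  ranked <- candidates[o, , drop = FALSE]
  rownames(ranked) <- NULL
  cbind(rank = seq_len(nrow(ranked)), ranked)
}

#' Drop candidates below a score threshold
#'
#' @param ranked ranked candidates.
#' @param threshold minimum retained score, in \[0, 1\]; candidates with
#'   `score >= threshold` survive, order preserved.
#' @return The filtered data frame.
#' @export
apply_threshold <- function(ranked, threshold) {
  if (!is.numeric(threshold) || is.na(threshold) || threshold < 0 || threshold > 1)
    abort("threshold must lie in [0, 1]", "tnmca_parameter_error")
  out <- ranked[ranked$score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full indication inference: find, score, rank, threshold
#'
#' @inheritParams find_candidates
#' @return Ranked candidates surviving `config$score_threshold`.
#' @export
infer_indications <- function(graph, census, config) {
  cands <- find_candidates(graph, census, config)
  cands <- score_candidates(cands, census)
  apply_threshold(rank_candidates(cands), config$score_threshold)
}

#' Write ranked candidates to a TSV file
#'
#' Columns: `rank`, `drug_id`, `disease_id`, `edge_type`, `score`,
#' `tiebreak`, `referenced_keys` (`;`-separated canonical keys).
#'
#' @param ranked ranked candidates.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(ranked, path) {
  df <- data.frame(rank = ranked$rank,
                   drug_id = ranked$drug_id,
                   disease_id = ranked$disease_id,
                   edge_type = ranked$edge_type,
                   score = sprintf("%.10g", ranked$score),
                   tiebreak = ranked$tiebreak,
                   referenced_keys = vapply(ranked$referenced, paste, "",
                                            collapse = ";"),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
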