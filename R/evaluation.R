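# Evaluation: ABC-model baseline, labeled score universes, tie-aware
# ROC/AUC against a held-out answer set.

#' ABC-model baseline inference
#'
#' Swanson-style transitive inference: a drug is proposed for the target
#' disease if it connects to it through any intermediate gene or pathway,
#' and its score is the number of distinct such intermediates
#' (`|N(drug) & N(target)|` restricted to the intermediate types). The
#' model is type-blind: proposed edges carry no interaction type.
#'
#' @param graph training [typed_graph()] (holdout already applied).
#' @param target target disease id.
#' @param intermediate_types node types allowed as intermediates.
#' @param chemical_type entity type label identifying drugs.
#' @return Data frame `drug_id`, `score` for drugs with score > 0, sorted
#'   by score descending then id. Drugs it omits are treated as score 0 by
#'   [build_labeled_universe()].
#' @export
abc_inference <- function(graph, target, intermediate_types = c("gene", "pathway"),
                          chemical_type = "chemical") {
  stopifnot(inherits(graph, "typed_graph"))
  if (!target %in% graph$nodes$id)
    abort(sprintf("target disease %s is absent from the graph", target),
          "tnmca_config_error")
  e <- graph$edges
  nbr <- function(id) unique(c(e$to[e$from == id], e$from[e$to == id]))
  mid <- nbr(target)
  mid <- mid[graph$nodes$type[match(mid, graph$nodes$id)] %in% intermediate_types]
  drugs <- node_ids(graph, chemical_type)
  score <- vapply(drugs, function(d) length(intersect(nbr(d), mid)), numeric(1))
  out <- data.frame(drug_id = drugs, score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[out$score > 0, , drop = FALSE]
  out <- out[radix_order(-out$score, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the labeled score universe for ROC evaluation
#'
#' With typed matching the universe is every (drug, edge type) pair; an
#' item is positive exactly when it is a held-out typed answer edge, so a
#' prediction of the wrong interaction type for an answered drug counts
#' as a negative. Without typed matching (ABC baseline) the universe is
#' the drugs, and a drug is positive if any typed answer edge exists for
#' it. Items the model did not emit get score 0, so the AUC is defined
#' over the full candidate space.
#'
#' @param predictions data frame with `drug_id`, `score` and (for typed
#'   matching) `edge_type`.
#' @param answers answer-set data frame (`drug_id`, `disease_id`,
#'   `edge_type`), all for one target disease.
#' @param graph training [typed_graph()]; its chemical nodes define the
#'   drug universe.
#' @param typed_matching logical; see above.
#' @param edge_types extra edge types to include in the typed universe
#'   (normally the candidate vocabulary used during inference).
#' @param chemical_type entity type label identifying drugs.
#' @return Data frame `drug_id`, `edge_type` (`NA` when untyped), `score`,
#'   `label` (logical), each universe item exactly once.
#' @export
build_labeled_universe <- function(predictions, answers, graph,
                                   typed_matching = TRUE, edge_types = NULL,
                                   chemical_type = "chemical") {
  stopifnot(inherits(graph, "typed_graph"))
  drugs <- node_ids(graph, chemical_type)
  if (typed_matching) {
    tys <- sort(unique(c(as.character(edge_types),
                         as.character(predictions$edge_type),
                         as.character(answers$edge_type))), method = "radix")
    uni <- data.frame(drug_id = rep(drugs, each = length(tys)),
                      edge_type = rep(tys, times = length(drugs)),
                      stringsAsFactors = FALSE)
    pkey <- paste(predictions$drug_id, predictions$edge_type, sep = "\r")
    if (anyDuplicated(pkey))
      abort("predictions contain a duplicated (drug, edge type) item",
            "tnmca_input_error")
    ukey <- paste(uni$drug_id, uni$edge_type, sep = "\r")
    uni$score <- predictions$score[match(ukey, pkey)]
    uni$score[is.na(uni$score)] <- 0
    uni$label <- ukey %in% paste(answers$drug_id, answers$edge_type, sep = "\r")
  } else {
    if (anyDuplicated(predictions$drug_id))
      abort("predictions contain a duplicated drug item", "tnmca_input_error")
    uni <- data.frame(drug_id = drugs, edge_type = NA_character_,
                      stringsAsFactors = FALSE)
    uni$score <- predictions$score[match(uni$drug_id, predictions$drug_id)]
    uni$score[is.na(uni$score)] <- 0
    uni$label <- uni$drug_id %in% answers$drug_id
  }
  uni
}

#' Tie-aware AUC of a labeled score universe
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with ties counting one half. Equals the trapezoidal
#' area under the threshold-swept ROC curve of [roc_curve()], and is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param labeled output of [build_labeled_universe()] (needs at least one
#'   positive and one negative).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labeled) {
  lab <- as.logical(labeled$label)
  s <- as.numeric(labeled$score)
  P <- sum(lab)
  N <- sum(!lab)
  if (P == 0L || N == 0L)
    abort("AUC is undefined without both positive and negative items",
          "tnmca_metric_error")
  r <- rank(s)  # average ranks implement the half-credit tie convention
  (sum(r[lab]) - P * (P + 1) / 2) / (P * N)
}

#' Threshold-swept ROC curve
#'
#' One `(FPR, TPR)` point per distinct score threshold (items with score
#' at or above the threshold are called positive) plus the `(0, 0)`
#' origin; the staircase ends at `(1, 1)` and its trapezoidal area equals
#' [auc()].
#'
#' @inheritParams auc
#' @return Data frame `threshold`, `fpr`, `tpr`, monotone nondecreasing in
#'   both rate columns.
#' @export
roc_curve <- function(labeled) {
  lab <- as.logical(labeled$label)
  s <- as.numeric(labeled$score)
  P <- sum(lab)
  N <- sum(!lab)
  if (P == 0L || N == 0L)
    abort("ROC is undefined without both positive and negative items",
          "tnmca_metric_error")
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  lab <- lab[o]
  block_end <- cumsum(rle(s)$lengths)
  data.frame(threshold = c(Inf, s[block_end]),
             fpr = c(0, cumsum(!lab)[block_end] / N),
             tpr = c(0, cumsum(lab)[block_end] / P))
}

#' Evaluate model predictions against a held-out answer set
#'
#' Builds the labeled universe, the ROC curve and the tie-aware AUC.
#'
#' @inheritParams build_labeled_universe
#' @return Object of class `tnmca_evaluation`: `auc`, `roc`, `positives`,
#'   `universe_size`, `labeled`.
#' @export
evaluate_predictions <- function(predictions, answers, graph,
                                 typed_matching = TRUE, edge_types = NULL,
                                 chemical_type = "chemical") {
  labeled <- build_labeled_universe(predictions, answers, graph,
                                    typed_matching = typed_matching,
                                    edge_types = edge_types,
                                    chemical_type = chemical_type)
  structure(list(auc = auc(labeled), roc = roc_curve(labeled),
                 positives = sum(labeled$label),
                 universe_size = nrow(labeled), labeled = labeled),
            class = "tnmca_evaluation")
}

#' @export
print.tnmca_evaluation <- function(x, ...) {
  cat(sprintf("tnmca_evaluation: AUC = %.4f (%d positives / %d items)\n",
              x$auc, x$positives, x$universe_size))
  invisible(x)
}

#' Write evaluation outputs
#'
#' @param result a [evaluate_predictions()] object.
#' @param roc_path optional CSV path for the ROC points (`fpr,tpr`).
#' @param summary_path optional JSON path for
#'   `{model, k, auc, positives, universe_size}`.
#' @param model,k metadata recorded in the summary.
#' @return Invisibly, the written paths.
#' @export
write_evaluation <- function(result, roc_path = NULL, summary_path = NULL,
                             model = NA_character_, k = NA_integer_) {
  stopifnot(inherits(result, "tnmca_evaluation"))
  written <- character(0)
  if (!is.null(roc_path)) {
    write.table(result$roc[, c("fpr", "tpr")], roc_path, sep = ",",
                quote = FALSE, row.names = FALSE, col.names = TRUE, eol = "\n")
    written <- c(written, roc_path)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(model = model, k = k, auc = result$auc,
                              positives = result$positives,
                              universe_size = result$universe_size),
                         summary_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, summary_path)
  }
  invisible(written)
}
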