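abc_fixture <- function() {
  typed_graph(
    nodes = data.frame(id = c("drug1", "drug2", "gene1", "gene2", "path1",
                              "dis1"),
                       type = c("chemical", "chemical", "gene", "gene",
                                "pathway", "disease")),
    edges = data.frame(from = c("drug1", "drug1", "drug1", "gene1", "gene2",
                                "path1", "drug2"),
                       to = c("gene1", "gene2", "path1", "dis1", "dis1",
                              "dis1", "gene1"),
                       type = c("marker", "marker", "", "marker", "marker",
                                "", "marker")))
}

test_that("ABC scores count distinct gene/pathway intermediates", {
  g <- abc_fixture()
  abc <- abc_inference(g, "dis1")
  expect_equal(abc$score[abc$drug_id == "drug1"], 3)  # gene1, gene2, path1
  expect_equal(abc$score[abc$drug_id == "drug2"], 1)  # gene1 only

  # brute-force common-neighbour oracle
  A <- oracle_adj(g)
  mids <- g$nodes$id[g$nodes$type %in% c("gene", "pathway")]
  for (d in c("drug1", "drug2")) {
    common <- sum(A[d, mids] & A["dis1", mids])
    expect_equal(abc$score[abc$drug_id == d], common)
  }

  # drugs with no common intermediate are omitted from the inferred list
  g2 <- typed_graph(rbind(g$nodes,
                          data.frame(id = "drug3", type = "chemical")),
                    g$edges)
  abc2 <- abc_inference(g2, "dis1")
  expect_false("drug3" %in% abc2$drug_id)
  # ...but appear in the evaluation universe with score 0
  uni <- build_labeled_universe(abc2,
                               data.frame(drug_id = "drug3",
                                          disease_id = "dis1",
                                          edge_type = "therapeutic"),
                               g2, typed_matching = FALSE)
  expect_equal(uni$score[uni$drug_id == "drug3"], 0)
  expect_true(uni$label[uni$drug_id == "drug3"])

  expect_error(abc_inference(g, "zzz"), class = "tnmca_config_error")
})

test_that("labeled universes implement typed and type-blind matching", {
  g <- abc_fixture()
  answers <- data.frame(drug_id = c("drug1", "drug2"),
                        disease_id = "dis1",
                        edge_type = c("therapeutic", "marker"),
                        stringsAsFactors = FALSE)
  preds <- data.frame(drug_id = c("drug1", "drug2"),
                      edge_type = c("marker", "marker"),
                      score = c(0.9, 0.8), stringsAsFactors = FALSE)

  uni <- build_labeled_universe(preds, answers, g, typed_matching = TRUE,
                                edge_types = c("marker", "therapeutic"))
  expect_equal(nrow(uni), 2L * 2L)  # drugs x edge types
  # wrong-type prediction for an answered drug is a negative item
  expect_false(uni$label[uni$drug_id == "drug1" & uni$edge_type == "marker"])
  expect_true(uni$label[uni$drug_id == "drug1" &
                        uni$edge_type == "therapeutic"])
  expect_equal(uni$score[uni$drug_id == "drug1" &
                         uni$edge_type == "therapeutic"], 0)
  expect_equal(sum(uni$label), 2L)

  # type-blind: any answered drug is positive
  uni2 <- build_labeled_universe(preds[, c("drug_id", "score")], answers, g,
                                 typed_matching = FALSE)
  expect_equal(nrow(uni2), 2L)
  expect_true(all(uni2$label))

  # empty model output -> all scores zero
  uni3 <- build_labeled_universe(data.frame(drug_id = character(0),
                                            edge_type = character(0),
                                            score = numeric(0)),
                                 answers, g, typed_matching = TRUE)
  expect_true(all(uni3$score == 0))
})

test_that("tie-aware AUC matches brute-force pair counting", {
  perfect <- data.frame(score = c(1, 1, 0, 0),
                        label = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc(perfect), 1)
  tied <- data.frame(score = rep(0.5, 6),
                     label = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(auc(tied), 0.5)
  expect_error(auc(data.frame(score = 1, label = TRUE)),
               class = "tnmca_metric_error")

  set.seed(59)
  for (i in 1:20) {
    n <- 50L
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    lab <- data.frame(score = scores, label = labels)
    expect_equal(auc(lab), oracle_auc(scores, labels))
    # invariance under strictly monotone transforms
    expect_equal(auc(data.frame(score = exp(3 * scores), label = labels)),
                 auc(lab))
    # label swap maps AUC to its complement
    expect_equal(auc(data.frame(score = scores, label = !labels)),
                 1 - auc(lab))
  }
})

test_that("ROC staircases are consistent with the AUC", {
  perfect <- data.frame(score = c(0.9, 0.8, 0.2, 0.1),
                        label = c(TRUE, TRUE, FALSE, FALSE))
  roc <- roc_curve(perfect)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # passes through (0, 1)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(utils::tail(roc$fpr, 1), 1)
  expect_equal(utils::tail(roc$tpr, 1), 1)

  tied <- data.frame(score = rep(0.3, 5),
                     label = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(nrow(roc_curve(tied)), 2L)  # (0,0) and (1,1) only

  set.seed(61)
  for (i in 1:10) {
    scores <- sample(seq(0, 1, by = 0.2), 40, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (!any(labels) || all(labels)) next
    lab <- data.frame(score = scores, label = labels)
    roc <- roc_curve(lab)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    expect_equal(trapezoid_area(roc), auc(lab))
  }
})

test_that("evaluation objects summarize and export", {
  td <- withr::local_tempdir()
  g <- abc_fixture()
  answers <- data.frame(drug_id = "drug1", disease_id = "dis1",
                        edge_type = "therapeutic", stringsAsFactors = FALSE)
  ev <- evaluate_predictions(abc_inference(g, "dis1"), answers, g,
                             typed_matching = FALSE)
  expect_s3_class(ev, "tnmca_evaluation")
  expect_equal(ev$positives, 1L)
  expect_equal(ev$universe_size, 2L)
  expect_equal(trapezoid_area(ev$roc), ev$auc)

  paths <- file.path(td, c("roc.csv", "summary.json"))
  write_evaluation(ev, paths[1], paths[2], model = "abc")
  roc <- read.csv(paths[1])
  expect_equal(names(roc), c("fpr", "tpr"))
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$model, "abc")
  expect_equal(js$auc, ev$auc)
})
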