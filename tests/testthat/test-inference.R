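nearmatch_graph <- function() {
  typed_graph(
    nodes = data.frame(id = c("drug1", "drug2", "gene1", "gene2", "dis1"),
                       type = c("chemical", "chemical", "gene", "gene",
                                "disease")),
    edges = data.frame(from = c("drug1", "gene1", "drug1", "drug2", "gene2"),
                       to = c("gene1", "dis1", "dis1", "gene2", "dis1"),
                       type = c("marker", "marker", "therapeutic", "marker",
                                "marker")))
}

test_that("single-edge completion proposes exactly the near-match candidate", {
  g <- nearmatch_graph()
  cen <- build_census(g, 3)
  expect_length(cen$frequencies, 1L)  # the complete drug1 triangle
  cfg <- inference_config("dis1", k = 3)
  cands <- find_candidates(g, cen, cfg)

  expect_equal(nrow(cands), 1L)
  expect_equal(cands$drug_id, "drug2")
  expect_equal(cands$disease_id, "dis1")
  expect_equal(cands$edge_type, "therapeutic")
  expect_equal(cands$referenced[[1L]], names(cen$frequencies))

  # an edge present with the same type is never re-proposed, but another
  # type may be: drug1 already has the therapeutic indication edge
  expect_false(any(cands$drug_id == "drug1" &
                   cands$edge_type == "therapeutic"))

  scored <- score_candidates(cands, cen)
  expect_equal(scored$score, 1)  # single pattern with relative frequency 1

  expect_error(find_candidates(g, cen, inference_config("absent", k = 3)),
               class = "tnmca_config_error")
  expect_error(find_candidates(g, cen, inference_config("dis1", k = 4)),
               class = "tnmca_config_error")  # census k mismatch
})

test_that("graphs one edge short of no census pattern yield no candidates", {
  g <- typed_graph(
    nodes = data.frame(id = c("d1", "g1", "s1"),
                       type = c("chemical", "gene", "disease")),
    edges = data.frame(from = c("d1", "g1"), to = c("g1", "s1"),
                       type = c("marker", "marker")))
  cen <- structure(list(k = 3L, frequencies = c(`chemical,disease,gene|1-2:x|1-3:x|2-3:x` = 1),
                        total = 1),
                   class = "tnm_census")
  cands <- find_candidates(g, cen, inference_config("s1", k = 3))
  expect_equal(nrow(cands), 0L)  # path types don't match the census key
})

test_that("noisy-OR aggregation reproduces forced arithmetic", {
  expect_identical(score_indication(c(0.2, 0.5)), 0.6)
  expect_identical(score_indication(numeric(0)), 0)
  expect_equal(score_indication(0.37), 0.37)
  expect_equal(score_indication(c(0.5, 0.5, 0.5)), 0.875)
  expect_error(score_indication(c(0.5, 0)), class = "tnmca_contract_error")
  expect_error(score_indication(1.2), class = "tnmca_contract_error")
})

test_that("scores obey the noisy-OR laws", {
  set.seed(31)
  for (i in 1:50) {
    s <- runif(sample(1:6, 1), min = 1e-6, max = 1)
    sc <- score_indication(s)
    expect_gte(sc, 0)
    expect_lte(sc, 1)
    expect_gte(sc, max(s) - 1e-12)          # >= every referenced score
    extra <- runif(1, min = 1e-6, max = 1)
    expect_gte(score_indication(c(s, extra)), sc - 1e-12)  # monotone
    if (length(s) >= 2 && all(s < 1))       # strict with >= 2 patterns
      expect_gt(sc, max(s))
  }
})

test_that("ranking is score-desc, frequency tiebreak, then lexicographic", {
  cands <- data.frame(
    drug_id = c("b", "a", "c", "a"),
    disease_id = "s",
    edge_type = c("t", "t", "t", "u"),
    score = c(0.6, 0.9, 0.6, 0.1),
    tiebreak = c(7, 1, 10, 1),
    stringsAsFactors = FALSE)
  ranked <- rank_candidates(cands)
  expect_equal(ranked$score, c(0.9, 0.6, 0.6, 0.1))
  expect_equal(ranked$drug_id[2:3], c("c", "b"))  # 10 beats 7 at equal score
  expect_equal(ranked$rank, 1:4)

  # fully tied candidates order lexicographically and reproducibly
  tied <- data.frame(drug_id = c("b", "a", "a"), disease_id = "s",
                     edge_type = c("t", "u", "t"), score = 0.5, tiebreak = 3,
                     stringsAsFactors = FALSE)
  r1 <- rank_candidates(tied)
  r2 <- rank_candidates(tied[c(3, 1, 2), ])
  expect_equal(r1$drug_id, c("a", "a", "b"))
  expect_equal(r1$edge_type, c("t", "u", "t"))
  expect_equal(r1, r2)
})

test_that("thresholding keeps scores at or above the cut, order intact", {
  ranked <- rank_candidates(data.frame(
    drug_id = c("a", "b", "c"), disease_id = "s", edge_type = "t",
    score = c(0.9, 0.6, 0.59), tiebreak = 0, stringsAsFactors = FALSE))
  expect_equal(nrow(apply_threshold(ranked, 0)), 3L)
  expect_equal(apply_threshold(ranked, 0.6)$drug_id, c("a", "b"))
  expect_equal(nrow(apply_threshold(ranked, 1)), 0L)
  expect_error(apply_threshold(ranked, 1.5), class = "tnmca_parameter_error")
})

test_that("candidate search agrees with the tentative-edge oracle", {
  set.seed(47)
  for (i in 1:4) {
    g <- random_typed_graph(sample(9:12, 1), p = 0.3,
                            node_types = c("chemical", "gene", "disease",
                                           "pathway"))
    diseases <- node_ids(g, "disease")
    if (!length(diseases) || !length(node_ids(g, "chemical"))) next
    target <- diseases[1L]
    for (k in c(3L, 4L)) {
      cen <- build_census(g, k)
      cfg <- inference_config(target, k = k)
      got <- find_candidates(g, cen, cfg)
      want <- oracle_candidates(g, cen, target, k,
                                candidate_edge_types(g, cfg))
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        want_df <- do.call(rbind, lapply(want, function(w)
          data.frame(drug_id = w$drug_id, edge_type = w$edge_type,
                     stringsAsFactors = FALSE)))
        o1 <- order(got$drug_id, got$edge_type)
        o2 <- order(want_df$drug_id, want_df$edge_type)
        expect_equal(got$drug_id[o1], want_df$drug_id[o2])
        expect_equal(got$edge_type[o1], want_df$edge_type[o2])
        expect_equal(lapply(got$referenced[o1], sort, method = "radix"),
                     lapply(want[o2], `[[`, "referenced"))
      }
    }
  }
})

test_that("ranked candidates export round-trips through TSV", {
  td <- withr::local_tempdir()
  g <- nearmatch_graph()
  cen <- build_census(g, 3)
  ranked <- infer_indications(g, cen, inference_config("dis1", k = 3))
  path <- file.path(td, "candidates.tsv")
  write_candidates(ranked, path)
  df <- read.delim(path, colClasses = "character")
  expect_equal(names(df), c("rank", "drug_id", "disease_id", "edge_type",
                            "score", "tiebreak", "referenced_keys"))
  expect_equal(df$drug_id, ranked$drug_id)
  expect_equal(as.numeric(df$score), ranked$score)
})
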