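# Seeded generator of CTD-like synthetic networks: four node types, typed
# edges only on chemical-gene / chemical-disease / gene-disease pairs,
# planted 3- and 4-node motif instances around a target disease, a held-out
# answer set of indication edges, and background noise edges.

#' Configuration for the synthetic network generator
#'
#' The defaults describe the benchmark network used throughout the test
#' suite: 200 chemicals, 300 genes, 40 diseases, 50 pathways; 100 planted
#' 3-node and 100 planted 4-node motif instances around the target
#' disease; 20% of the planted indication edges held out; a low background
#' noise rate.
#'
#' The 3-node template is the chemical-gene-disease triangle (chemical-gene
#' and gene-disease association edges plus a typed indication edge); the
#' 4-node template is the chemical-pathway-gene-disease cycle, which has no
#' chemical-gene interaction -- the drug reaches the disease through a
#' disease-related pathway. Edge types on typed pairs come from a two-label
#' vocabulary; the last label (default `"therapeutic"`) is used for the
#' planted indication edges.
#'
#' @param n_chemical,n_gene,n_disease,n_pathway node counts per entity type.
#' @param n_motif3,n_motif4 planted instance counts for the two templates.
#' @param holdout_fraction fraction of the target's chemical-disease edges
#'   moved into the answer set.
#' @param noise_rate expected background edges per type pair as a fraction
#'   of all possible pairs of that type combination.
#' @param edge_types interaction-type vocabulary for typed pairs.
#' @param shared_drugs draw the 3-node and 4-node instances on the same
#'   drug pool (`TRUE`, default), so each indication drug carries both
#'   motif shapes and is recoverable at either k; `FALSE` draws the two
#'   pools independently.
#' @param seed RNG seed; the same config and seed give byte-identical
#'   output.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_chemical = 200L, n_gene = 300L, n_disease = 40L,
                             n_pathway = 50L, n_motif3 = 100L, n_motif4 = 100L,
                             holdout_fraction = 0.2, noise_rate = 0.002,
                             edge_types = c("marker", "therapeutic"),
                             shared_drugs = TRUE, seed = 1L) {
  cfg <- list(n_chemical = as.integer(n_chemical), n_gene = as.integer(n_gene),
              n_disease = as.integer(n_disease), n_pathway = as.integer(n_pathway),
              n_motif3 = as.integer(n_motif3), n_motif4 = as.integer(n_motif4),
              holdout_fraction = holdout_fraction, noise_rate = noise_rate,
              edge_types = as.character(edge_types),
              shared_drugs = isTRUE(shared_drugs), seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_chemical, n_gene, n_disease, n_pathway) < 1L))
      abort("node counts must be positive", "tnmca_config_error")
    if (any(c(n_motif3, n_motif4) < 0L))
      abort("motif instance counts must be non-negative", "tnmca_config_error")
    if (holdout_fraction < 0 || holdout_fraction > 1)
      abort("holdout_fraction must lie in [0, 1]", "tnmca_config_error")
    if (noise_rate < 0 || noise_rate > 1)
      abort("noise_rate must lie in [0, 1]", "tnmca_config_error")
    if (length(edge_types) < 1L)
      abort("edge_types must contain at least one label", "tnmca_config_error")
  })
  structure(cfg, class = "generator_config")
}

edge_df <- function(from, to, type) {
  data.frame(from = from, to = to, type = rep_len(type, length(from)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic typed network with planted motifs and hold-out
#'
#' Plants the configured motif instances around the target disease
#' (`dis001`), adds background noise edges (never duplicating a planted
#' `(pair, type)` combination), then moves the configured fraction of the
#' target's chemical-disease edges into the answer set. The manifest
#' records every planted instance and held-out edge.
#'
#' @param config a [generator_config()].
#' @param out_dir optional directory; when given, `nodes.tsv`,
#'   `edges.tsv`, `answers.tsv` and `manifest.json` are written there.
#' @return Object of class `synthetic_network`: `graph` (the training
#'   [typed_graph()]), `answers` (held-out indication edges), `manifest`,
#'   `config`.
#' @export
generate_network <- function(config = generator_config(), out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n3 <- config$n_motif3
  n4 <- config$n_motif4
  if (max(n3, n4) > config$n_chemical || n3 > config$n_gene || n4 > config$n_gene)
    abort("more motif instances requested than the node budget permits",
          "tnmca_generation_error")

  chems <- sprintf("chem%04d", seq_len(config$n_chemical))
  genes <- sprintf("gene%04d", seq_len(config$n_gene))
  diseases <- sprintf("dis%03d", seq_len(config$n_disease))
  paths <- sprintf("path%03d", seq_len(config$n_pathway))
  target <- diseases[1L]
  nodes <- data.frame(
    id = c(chems, genes, diseases, paths),
    type = rep(c("chemical", "gene", "disease", "pathway"),
               c(length(chems), length(genes), length(diseases), length(paths))),
    stringsAsFactors = FALSE)

  ety <- config$edge_types
  assoc <- ety[1L]
  indication <- ety[length(ety)]

  res <- with_seed(config$seed, {
    pool <- sample(chems, max(n3, n4))
    d3 <- if (config$shared_drugs) pool[seq_len(n3)] else sample(chems, n3)
    d4 <- if (config$shared_drugs) pool[seq_len(n4)] else sample(chems, n4)
    g3 <- sample(genes, n3)
    g4 <- sample(genes, n4)
    p4 <- if (n4 > 0L) sample(paths, n4, replace = TRUE) else character(0)

    planted <- rbind(
      edge_df(d3, g3, assoc),
      edge_df(g3, rep(target, n3), assoc),
      edge_df(d3, rep(target, n3), indication),
      edge_df(d4, p4, UNTYPED),
      edge_df(p4, g4, UNTYPED),
      edge_df(g4, rep(target, n4), assoc),
      edge_df(d4, rep(target, n4), indication))
    planted <- unique(normalize_edges(planted))

    typed_pairs <- c("chemical.gene", "chemical.disease", "gene.disease")
    pools <- list(chemical = chems, gene = genes, disease = diseases,
                  pathway = paths)
    pair_names <- utils::combn(names(pools), 2L, simplify = FALSE)
    noise <- do.call(rbind, lapply(pair_names, function(pr) {
      a <- pools[[pr[1L]]]
      b <- pools[[pr[2L]]]
      m <- round(config$noise_rate * length(a) * length(b))
      if (m == 0L) return(NULL)
      idx <- sample(length(a) * length(b), m)
      ty <- if (paste(pr, collapse = ".") %in% typed_pairs)
        sample(ety, m, replace = TRUE) else rep(UNTYPED, m)
      edge_df(a[(idx - 1L) %% length(a) + 1L],
              b[(idx - 1L) %/% length(a) + 1L], ty)
    }))
    if (!is.null(noise) && nrow(noise)) {
      noise <- normalize_edges(noise)
      pkey <- function(df) paste(df$from, df$to, df$type, sep = "\r")
      noise <- noise[!pkey(noise) %in% pkey(planted), , drop = FALSE]
    } else {
      noise <- edge_df(character(0), character(0), character(0))
    }
    all_edges <- rbind(planted, noise)

    ftype <- nodes$type[match(all_edges$from, nodes$id)]
    ttype <- nodes$type[match(all_edges$to, nodes$id)]
    at_target <- (all_edges$from == target & ttype == "chemical") |
                 (all_edges$to == target & ftype == "chemical")
    pool_idx <- which(at_target)
    n_hold <- round(config$holdout_fraction * length(pool_idx))
    hold_idx <- if (n_hold > 0L) sort(sample(pool_idx, n_hold)) else integer(0)
    list(d3 = d3, g3 = g3, d4 = d4, g4 = g4, p4 = p4,
         all_edges = all_edges, hold_idx = hold_idx, n_noise = nrow(noise))
  })

  held <- res$all_edges[res$hold_idx, , drop = FALSE]
  training <- res$all_edges[setdiff(seq_len(nrow(res$all_edges)), res$hold_idx), ,
                            drop = FALSE]
  drug <- ifelse(held$from == target, held$to, held$from)
  answers <- data.frame(drug_id = drug, disease_id = rep(target, nrow(held)),
                        edge_type = held$type, stringsAsFactors = FALSE)
  answers <- answers[radix_order(answers$drug_id, answers$edge_type), ,
                     drop = FALSE]
  rownames(answers) <- NULL

  graph <- typed_graph(nodes, training)
  manifest <- list(
    seed = config$seed, target = target,
    planted3 = data.frame(chemical = res$d3, gene = res$g3,
                          disease = rep(target, n3), stringsAsFactors = FALSE),
    planted4 = data.frame(chemical = res$d4, gene = res$g4, pathway = res$p4,
                          disease = rep(target, n4), stringsAsFactors = FALSE),
    n_noise_edges = res$n_noise,
    heldout = answers)
  out <- structure(list(graph = graph, answers = answers, manifest = manifest,
                        config = config),
                   class = "synthetic_network")
  if (!is.null(out_dir)) write_network_files(out, out_dir)
  out
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf("synthetic_network: target %s, %d held-out indication edge(s)\n",
              x$manifest$target, nrow(x$answers)))
  print(x$graph)
  invisible(x)
}

#' Write a generated network to disk
#'
#' Emits `nodes.tsv`, `edges.tsv` (the training graph), `answers.tsv` and
#' `manifest.json` into `out_dir`; repeated writes of the same object are
#' byte-identical.
#'
#' @param x a [generate_network()] result.
#' @param out_dir directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_network_files <- function(x, out_dir) {
  stopifnot(inherits(x, "synthetic_network"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(out_dir, c("nodes.tsv", "edges.tsv", "answers.tsv",
                            "manifest.json"))
  write_graph(x$graph, p[1L], p[2L])
  write_tsv(x$answers, p[3L])
  jsonlite::write_json(x$manifest, p[4L], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

#' Read an answer set written by [write_network_files()]
#'
#' @param path `answers.tsv` path.
#' @return Data frame `drug_id`, `disease_id`, `edge_type`.
#' @export
read_answers <- function(path) {
  if (!file.exists(path))
    abort(sprintf("input file not found: %s", path), "tnmca_input_error")
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "#", colClasses = "character",
                   check.names = FALSE, na.strings = character(0),
                   fileEncoding = "UTF-8")
  if (!all(c("drug_id", "disease_id", "edge_type") %in% names(df)))
    abort(sprintf("%s: expected columns 'drug_id', 'disease_id', 'edge_type'",
                  path), "tnmca_input_error")
  df
}

#' Write the canonical small fixture graphs
#'
#' Writes the deterministic fixtures shared across the test suite into
#' `out_dir`: a typed chemical-gene-disease triangle (`triangle_*`), the
#' chemical-pathway-gene-disease 4-cycle (`fourcycle_*`), a near-match
#' inference fixture with one complete and one incomplete triangle
#' (`nearmatch_*`), and an ABC fixture with a drug linked to the target
#' through two genes and a pathway (`abc_*`). Regenerated suites are
#' byte-identical.
#'
#' @param out_dir directory (created if needed).
#' @return Invisibly, a named list of `c(nodes, edges)` path pairs.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- list(
    triangle = typed_graph(
      nodes = data.frame(id = c("drug1", "gene1", "dis1"),
                         type = c("chemical", "gene", "disease")),
      edges = data.frame(from = c("drug1", "gene1", "drug1"),
                         to = c("gene1", "dis1", "dis1"),
                         type = c("marker", "marker", "therapeutic"))),
    fourcycle = typed_graph(
      nodes = data.frame(id = c("drugA", "geneA", "pathA", "disA"),
                         type = c("chemical", "gene", "pathway", "disease")),
      edges = data.frame(from = c("drugA", "pathA", "geneA", "drugA"),
                         to = c("pathA", "geneA", "disA", "disA"),
                         type = c("", "", "marker", "therapeutic"))),
    nearmatch = typed_graph(
      nodes = data.frame(id = c("drug1", "drug2", "gene1", "gene2", "dis1"),
                         type = c("chemical", "chemical", "gene", "gene",
                                  "disease")),
      edges = data.frame(from = c("drug1", "gene1", "drug1", "drug2", "gene2"),
                         to = c("gene1", "dis1", "dis1", "gene2", "dis1"),
                         type = c("marker", "marker", "therapeutic",
                                  "marker", "marker"))),
    abc = typed_graph(
      nodes = data.frame(id = c("drug1", "gene1", "gene2", "path1", "dis1"),
                         type = c("chemical", "gene", "gene", "pathway",
                                  "disease")),
      edges = data.frame(from = c("drug1", "drug1", "drug1", "gene1", "gene2",
                                  "path1"),
                         to = c("gene1", "gene2", "path1", "dis1", "dis1",
                                "dis1"),
                         type = c("marker", "marker", "", "marker", "marker",
                                  ""))))
  paths <- lapply(names(fixtures), function(nm) {
    p <- file.path(out_dir, paste0(nm, c("_nodes.tsv", "_edges.tsv")))
    write_graph(fixtures[[nm]], p[1L], p[2L])
    p
  })
  names(paths) <- names(fixtures)
  invisible(paths)
}
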