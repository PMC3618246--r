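# Independent brute-force oracles used to anchor the motif machinery:
# exhaustive subset enumeration with a BFS connectivity check, permutation
# search canonicalization with its own encoding, tentative-edge candidate
# recounting, and pairwise AUC counting. None of these share code with the
# package's enumeration/canonicalization path.

random_typed_graph <- function(n, p = 0.3,
                               node_types = c("chemical", "gene", "disease"),
                               edge_types = c("marker", "therapeutic"),
                               p_untyped = 0.3, p_parallel = 0.15) {
  ids <- sprintf("n%02d", seq_len(n))
  nodes <- data.frame(id = ids, type = sample(node_types, n, replace = TRUE),
                      stringsAsFactors = FALSE)
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  ed <- NULL
  if (any(keep)) {
    pr <- pairs[keep, , drop = FALSE]
    ty <- ifelse(stats::runif(nrow(pr)) < p_untyped, UNTYPED,
                 sample(edge_types, nrow(pr), replace = TRUE))
    ed <- data.frame(from = ids[pr[, 1L]], to = ids[pr[, 2L]], type = ty,
                     stringsAsFactors = FALSE)
    par <- which(stats::runif(nrow(pr)) < p_parallel & ty != UNTYPED)
    if (length(par)) {
      other <- ifelse(ed$type[par] == edge_types[1L], edge_types[2L],
                      edge_types[1L])
      ed <- rbind(ed, data.frame(from = ed$from[par], to = ed$to[par],
                                 type = other, stringsAsFactors = FALSE))
    }
  }
  typed_graph(nodes, ed)
}

oracle_adj <- function(g) {
  ids <- g$nodes$id
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      A[g$edges$from[i], g$edges$to[i]] <- TRUE
      A[g$edges$to[i], g$edges$from[i]] <- TRUE
    }
  }
  A
}

oracle_connected <- function(A, ids) {
  sub <- A[ids, ids, drop = FALSE]
  seen <- 1L
  frontier <- 1L
  while (length(frontier)) {
    nxt <- setdiff(which(colSums(sub[frontier, , drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(ids)
}

# every k-node subset whose induced subgraph is connected
oracle_ksets <- function(g, k) {
  ids <- g$nodes$id
  if (length(ids) < k) return(list())
  A <- oracle_adj(g)
  cmb <- utils::combn(ids, k, simplify = FALSE)
  Filter(function(s) oracle_connected(A, s), cmb)
}

oracle_valid <- function(g, ids, min_types = 3L) {
  A <- oracle_adj(g)
  sub <- A[ids, ids, drop = FALSE]
  length(ids) >= 3L && all(rowSums(sub) >= 2) &&
    length(unique(g$nodes$type[match(ids, g$nodes$id)])) >= min_types
}

all_perms <- function(k) {
  if (k == 1L) return(matrix(1L))
  p <- all_perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[p], nrow(p)))
  }))
}

# permutation-search canonical key over raw (types, edge list) structures;
# the encoding is deliberately different from the package's key format.
# P may be passed precomputed when calling in bulk.
oracle_key_raw <- function(types, ia, ib, etypes, P = all_perms(length(types))) {
  k <- length(types)
  n_p <- nrow(P)
  posM <- matrix(0L, n_p, k)  # posM[r, i] = position of original node i
  posM[cbind(rep(seq_len(n_p), k), as.vector(P))] <- rep(seq_len(k), each = n_p)
  tyM <- matrix(types[P], n_p, k)
  ty_str <- do.call(paste, c(lapply(seq_len(k), function(j) tyM[, j]),
                             list(sep = "/")))
  if (length(ia)) {
    A <- posM[, ia, drop = FALSE]
    B <- posM[, ib, drop = FALSE]
    a <- pmin(A, B)
    b <- pmax(A, B)
    esM <- matrix(paste(a, b, rep(etypes, each = n_p), sep = "_"), n_p)
    es_str <- vapply(seq_len(n_p), function(r)
      paste(sort(esM[r, ], method = "radix"), collapse = " "), "")
  } else {
    es_str <- rep("", n_p)
  }
  enc <- paste(ty_str, es_str, sep = " # ")
  enc[order(enc, method = "radix")][1L]
}

oracle_key <- function(g, ids) {
  e <- g$edges[g$edges$from %in% ids & g$edges$to %in% ids, , drop = FALSE]
  oracle_key_raw(g$nodes$type[match(ids, g$nodes$id)],
                 match(e$from, ids), match(e$to, ids), e$type)
}

# census by exhaustive subsets + oracle canonical grouping; keeps one
# representative node set per class so classes can be translated into the
# package's key space for comparison
oracle_census <- function(g, k, min_types = 3L) {
  sets <- Filter(function(s) oracle_valid(g, s, min_types), oracle_ksets(g, k))
  if (!length(sets)) return(list(keys = character(0), freq = numeric(0),
                                 reps = list()))
  keys <- vapply(sets, function(s) oracle_key(g, s), "")
  tab <- table(keys)
  first <- !duplicated(keys)
  reps <- sets[first]
  names(reps) <- keys[first]
  list(keys = names(tab), freq = as.numeric(tab), reps = reps[names(tab)])
}

# tentative-edge candidate recount: add each absent typed (drug, target)
# edge, enumerate all valid k-sets containing both endpoints, and keep the
# package-canonical keys found in the census
oracle_candidates <- function(g, census, target, k, vocab, min_types = 3L) {
  drugs <- node_ids(g, "chemical")
  out <- list()
  for (d in drugs) {
    for (t in vocab) {
      e <- g$edges
      present <- any(((e$from == d & e$to == target) |
                      (e$from == target & e$to == d)) & e$type == t)
      if (present) next
      g2 <- typed_graph(g$nodes, rbind(e, data.frame(from = d, to = target,
                                                     type = t,
                                                     stringsAsFactors = FALSE)))
      sets <- Filter(function(s) d %in% s && target %in% s &&
                       oracle_valid(g2, s, min_types),
                     oracle_ksets(g2, k))
      if (!length(sets)) next
      keys <- unique(vapply(sets, function(s)
        canonical_form(g2, s, min_types)$canonical_key, ""))
      keys <- keys[keys %in% names(census$frequencies)]
      if (length(keys))
        out[[length(out) + 1L]] <- list(drug_id = d, edge_type = t,
                                        referenced = sort(keys, method = "radix"))
    }
  }
  out
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# compare a package census against the oracle census on the same graph
expect_census_matches_oracle <- function(g, k, min_types = 3L) {
  cen <- build_census(g, k, min_distinct_types = min_types)
  orc <- oracle_census(g, k, min_types)
  expect_equal(length(cen$frequencies), length(orc$keys))
  expect_equal(cen$total, sum(orc$freq))
  if (length(orc$keys)) {
    impl_keys <- vapply(orc$reps, function(s)
      canonical_form(g, s, min_types)$canonical_key, "")
    expect_setequal(unname(impl_keys), names(cen$frequencies))
    expect_equal(unname(cen$frequencies[impl_keys]), orc$freq)
  }
}
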