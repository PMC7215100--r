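# Independent oracles used by the property tests. Deliberately naive:
# recursion/enumeration rather than dynamic programming or igraph, so a bug
# in the package cannot hide in the oracle.

AA20_TEST <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA20_TEST, n, replace = TRUE), collapse = "")
}

# Optimal global alignment score by recursion over the full alignment space
# (match/mismatch, gap in a, gap in b at every step), memoised on the
# suffix pair. Score only; independent of the package's iterative DP and
# traceback.
oracle_nw_score <- function(a, b, mat, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1))
    }
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1))
    memo[[key]] <- best
    best
  }
  rec(1, 1)
}

# Fully unmemoised variant for very short sequences: literally walks every
# monotone alignment path. Used to cross-check oracle_nw_score itself.
oracle_nw_score_exhaustive <- function(a, b, mat, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1))
    }
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# --- graph oracles -----------------------------------------------------

# Adjacency list from a triad_graph.
graph_adj <- function(g) {
  adj <- stats::setNames(vector("list", nrow(g$nodes)), g$nodes$id)
  for (k in seq_len(nrow(g$edges))) {
    f <- g$edges$from[k]; t <- g$edges$to[k]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  adj
}

# Local clustering by direct triangle counting over all neighbour pairs.
oracle_local_clustering <- function(g, node) {
  adj <- graph_adj(g)
  nb <- unique(adj[[node]])
  k <- length(nb)
  if (k < 2) return(0)
  closed <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) closed <- closed + 1L
    }
  }
  closed / (k * (k - 1) / 2)
}

# Transitivity by exhaustive triple/triangle counting.
oracle_transitivity <- function(g) {
  adj <- graph_adj(g)
  ids <- g$nodes$id
  triples <- 0L
  triangles3 <- 0L  # each triangle counted once per centre = 3 times total
  for (v in ids) {
    nb <- unique(adj[[v]])
    k <- length(nb)
    if (k < 2) next
    triples <- triples + k * (k - 1) / 2
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (nb[j] %in% adj[[nb[i]]]) triangles3 <- triangles3 + 1L
      }
    }
  }
  if (triples == 0) 0 else triangles3 / triples
}

# Single-source BFS distances (unit weights).
oracle_bfs <- function(adj, src) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in unique(adj[[v]])) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Effective diameter: BFS over the largest component, full unordered pair
# distance multiset, then the stated interpolation rule applied literally.
oracle_effective_diameter <- function(g, q = 90) {
  adj <- graph_adj(g)
  ids <- g$nodes$id
  # components by repeated BFS
  seen <- character(0); comps <- list()
  for (v in ids) {
    if (v %in% seen) next
    comp <- names(which(is.finite(oracle_bfs(adj, v))))
    comps[[length(comps) + 1]] <- comp
    seen <- c(seen, comp)
  }
  big <- comps[[which.max(vapply(comps, length, 0L))]]
  dists <- c()
  for (i in seq_along(big)) {
    d <- oracle_bfs(adj, big[i])
    for (j in seq_along(big)) {
      if (j > i) dists <- c(dists, d[[big[j]]])
    }
  }
  s <- sort(dists)
  m <- length(s)
  r <- q * (m - 1) / 100
  lo <- floor(r); hi <- ceiling(r)
  s[lo + 1] + (r - lo) * (s[hi + 1] - s[lo + 1])
}

# Random typed graph: node types sampled, edges only between distinct types
# (as in any drug/target/indication graph), each with probability p.
random_triad_graph <- function(n, p) {
  types <- sample(c("drug", "target", "indication"), n, replace = TRUE)
  nodes <- data.frame(id = sprintf("n%02d", seq_len(n)), node_type = types,
                      stringsAsFactors = FALSE)
  from <- character(0); to <- character(0); et <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (types[i] == types[j]) next
      if (stats::runif(1) < p) {
        from <- c(from, nodes$id[i]); to <- c(to, nodes$id[j])
        key <- paste(sort(c(types[i], types[j])), collapse = "-")
        et <- c(et, switch(key,
                           "drug-target" = "drug_target",
                           "indication-target" = "target_indication",
                           "drug-indication" = "drug_indication"))
      }
    }
  }
  triad_graph(nodes,
              data.frame(from = from, to = to, edge_type = et,
                         stringsAsFactors = FALSE))
}

# Convenience: one-row case table built in code.
make_case <- function(drug, om, sm, ot = character(), st = character(),
                      modality = "small_molecule", okind = "protein",
                      skind = "protein") {
  repo_cases(drug, modality,
             original_label = paste("indication", om), original_mesh = om,
             secondary_label = paste("indication", sm), secondary_mesh = sm,
             original_targets = list(target_set(ot, molecule_kind = okind)),
             secondary_targets = list(target_set(st, molecule_kind = skind)))
}

bind_cases <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  class(out) <- c("repo_cases", "data.frame")
  out
}
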