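NODE_TYPES <- c("drug", "target", "indication")

edge_type_for <- function(ta, tb) {
  key <- paste(sort(c(ta, tb)), collapse = "-")
  switch(key,
         "drug-target" = "drug_target",
         "indication-target" = "target_indication",
         "drug-indication" = "drug_indication",
         stop("unsupported edge between node types ", key, call. = FALSE))
}

#' Construct a typed drug-target-indication graph
#'
#' Low-level constructor enforcing the simple-graph invariants: no
#' self-loops, no duplicate edges, endpoints present in the node table, and
#' edge types consistent with endpoint node types.
#'
#' @param nodes data.frame with columns `id`, `node_type` (one of `drug`,
#'   `target`, `indication`).
#' @param edges data.frame with columns `from`, `to`, `edge_type`.
#' @param class_label Which repositioning class the graph represents.
#' @return An object of class `triad_graph`.
#' @export
triad_graph <- function(nodes, edges, class_label = NA_character_) {
  stopifnot(is.data.frame(nodes), all(c("id", "node_type") %in% names(nodes)),
            is.data.frame(edges),
            all(c("from", "to", "edge_type") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  bad <- setdiff(nodes$node_type, NODE_TYPES)
  if (length(bad)) stop("unknown node type: ", bad[1], call. = FALSE)
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loop edge", call. = FALSE)
    miss <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(miss)) {
      stop("edge endpoint(s) not in node set: ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
    key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                  paste(edges$to, edges$from))
    if (anyDuplicated(key)) stop("duplicate edge(s)", call. = FALSE)
    tt <- stats::setNames(nodes$node_type, nodes$id)
    want <- mapply(edge_type_for, tt[edges$from], tt[edges$to])
    if (!all(want == edges$edge_type)) {
      stop("edge_type inconsistent with endpoint node types", call. = FALSE)
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes[, c("id", "node_type")],
                 edges = edges[, c("from", "to", "edge_type")],
                 class_label = class_label),
            class = "triad_graph")
}

#' Build the drug-target-indication graph for one repositioning class
#'
#' Nodes are unique drugs, unique protein-target identifiers, and top-level
#' MeSH keys (indications are collapsed to their root key uniformly across
#' classes). For each case, edges connect the drug to every target in either
#' target set, each target to the indication it belongs to, and the drug to
#' both indications; duplicates are collapsed.
#'
#' @param cases A `repo_cases` table, all of one repositioning class (use
#'   [cases_by_label()]).
#' @param class_label Label recorded on the graph.
#' @param classification Optional [classify_all()] result covering `cases`;
#'   when supplied, the labels of `cases` are checked and an error is raised
#'   if they are mixed or differ from `class_label`.
#' @return A `triad_graph`.
#' @export
build_graph <- function(cases, class_label = NA_character_,
                        classification = NULL) {
  stopifnot(inherits(cases, "repo_cases"))
  if (!is.null(classification)) {
    stopifnot(inherits(classification, "repo_classification"))
    lab <- classification$per_case$label[
      match(cases$drug_name, classification$per_case$drug_name)]
    if (anyNA(lab)) stop("cases missing from classification", call. = FALSE)
    if (length(unique(lab)) > 1L) {
      stop("cases carry mixed class labels: ",
           paste(unique(lab), collapse = ", "), call. = FALSE)
    }
    if (is.na(class_label)) class_label <- unique(lab)
    if (length(lab) && unique(lab) != class_label) {
      stop("cases are labeled ", unique(lab), ", not ", class_label,
           call. = FALSE)
    }
  }
  # paste0 maps character(0) to "", so guard the possibly-empty target case
  drug_id <- function(x) paste0("drug:", x)
  targ_id <- function(x) if (length(x)) paste0("target:", x) else character(0)
  ind_id <- function(x) paste0("indication:", x)
  nodes <- data.frame(id = character(), node_type = character(),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      edge_type = character(), stringsAsFactors = FALSE)
  add_nodes <- function(ids, type) {
    if (!length(ids)) return(nodes)
    rbind(nodes, data.frame(id = ids, node_type = type,
                            stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(cases))) {
    d <- drug_id(cases$drug_name[i])
    io <- ind_id(cases$original_mesh[i])
    is_ <- ind_id(cases$secondary_mesh[i])
    to <- protein_ids(cases$original_targets[[i]])
    ts <- protein_ids(cases$secondary_targets[[i]])
    nodes <- add_nodes(d, "drug")
    nodes <- add_nodes(unique(c(io, is_)), "indication")
    nodes <- add_nodes(targ_id(unique(c(to, ts))), "target")
    e <- rbind(
      if (length(to)) data.frame(from = d, to = targ_id(to),
                                 edge_type = "drug_target"),
      if (length(ts)) data.frame(from = d, to = targ_id(ts),
                                 edge_type = "drug_target"),
      if (length(to)) data.frame(from = targ_id(to), to = io,
                                 edge_type = "target_indication"),
      if (length(ts)) data.frame(from = targ_id(ts), to = is_,
                                 edge_type = "target_indication"),
      data.frame(from = d, to = unique(c(io, is_)),
                 edge_type = "drug_indication")
    )
    edges <- rbind(edges, e)
  }
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  if (nrow(edges)) {
    key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                  paste(edges$to, edges$from))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  triad_graph(nodes, edges, class_label)
}

as_igraph <- function(g) {
  stopifnot(inherits(g, "triad_graph"))
  igraph::graph_from_data_frame(g$edges[, c("from", "to")], directed = FALSE,
                                vertices = g$nodes)
}

#' Local clustering coefficient of one node
#'
#' Triangle-based local clustering: the fraction of a node's neighbour pairs
#' that are themselves adjacent. Nodes of degree < 2 return 0.
#'
#' @param g A `triad_graph`.
#' @param node Node id (e.g. `"drug:Nilotinib"`).
#' @return A number in \[0, 1\].
#' @export
local_clustering <- function(g, node) {
  stopifnot(inherits(g, "triad_graph"))
  if (!node %in% g$nodes$id) stop("unknown node: ", node, call. = FALSE)
  ig <- as_igraph(g)
  unname(igraph::transitivity(ig, type = "localundirected", vids = node,
                              isolates = "zero"))
}

#' Mean local clustering of one node type
#'
#' Degree-<2 nodes contribute 0 to the average (they are not excluded).
#'
#' @param g A `triad_graph`.
#' @param node_type One of `"drug"`, `"target"`, `"indication"`.
#' @return The arithmetic mean of [local_clustering()] over nodes of that
#'   type; errors when the graph has no node of the type.
#' @export
avg_clustering_by_type <- function(g, node_type) {
  stopifnot(inherits(g, "triad_graph"), node_type %in% NODE_TYPES)
  ids <- g$nodes$id[g$nodes$node_type == node_type]
  if (!length(ids)) stop("no node of type ", node_type, call. = FALSE)
  ig <- as_igraph(g)
  vals <- igraph::transitivity(ig, type = "localundirected", vids = ids,
                               isolates = "zero")
  mean(unname(vals))
}

#' Graph transitivity
#'
#' Global clustering: 3 x triangles / connected triples; defined as 0 for a
#' graph with no connected triple.
#'
#' @param g A `triad_graph`.
#' @return A number in \[0, 1\].
#' @export
graph_transitivity <- function(g) {
  stopifnot(inherits(g, "triad_graph"))
  if (nrow(g$nodes) == 0L) stop("empty graph", call. = FALSE)
  val <- igraph::transitivity(as_igraph(g), type = "global")
  if (is.nan(val)) 0 else val
}

# q-th percentile at rank q*(m-1)/100 with linear interpolation, over a
# numeric vector (R's quantile type 7, restated so the rule is explicit).
interpolated_percentile <- function(x, q) {
  x <- sort(x)
  m <- length(x)
  r <- q * (m - 1) / 100
  lo <- floor(r)
  hi <- ceiling(r)
  x[lo + 1] + (r - lo) * (x[hi + 1] - x[lo + 1])
}

largest_component <- function(g) {
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(ig, keep)
}

#' Effective diameter
#'
#' The 90th percentile (linearly interpolated) of the exact shortest-path
#' distance distribution over unordered distinct node pairs of the largest
#' connected component. Fractional values are expected.
#'
#' @param g A `triad_graph`.
#' @param q Percentile; default 90.
#' @return A non-negative real number.
#' @export
effective_diameter <- function(g, q = 90) {
  stopifnot(inherits(g, "triad_graph"))
  sub <- largest_component(g)
  n <- igraph::vcount(sub)
  if (n < 2L) {
    stop("largest component has fewer than 2 nodes", call. = FALSE)
  }
  d <- igraph::distances(sub)
  dists <- d[upper.tri(d)]
  interpolated_percentile(dists, q)
}

#' Small-world score
#'
#' The scalar small-world statistic: transitivity times the number of nodes,
#' divided by the effective diameter. Higher values indicate more cliquish,
#' short-range connectivity; low values flag networks whose nodes engage in
#' distant connections.
#'
#' @param transitivity Graph transitivity in \[0, 1\].
#' @param n_nodes Total node count of the graph.
#' @param eff_diameter Effective diameter (> 0).
#' @return `transitivity * n_nodes / eff_diameter`.
#' @examples
#' small_world_score(0.27, 51, 3.43)  # 4.01
#' @export
small_world_score <- function(transitivity, n_nodes, eff_diameter) {
  stopifnot(is.numeric(transitivity), is.numeric(n_nodes),
            is.numeric(eff_diameter))
  if (eff_diameter <= 0) {
    stop("effective diameter must be positive", call. = FALSE)
  }
  transitivity * n_nodes / eff_diameter
}

#' Summarise a repositioning-class network
#'
#' Computes the full per-class network characterisation: size, largest
#' component shares, per-type mean clustering, transitivity, effective
#' diameter, and the small-world score (which always satisfies
#' `small_world * effective_diameter = transitivity * n_nodes`).
#'
#' @param g A non-empty `triad_graph` whose largest component has at least
#'   two nodes.
#' @return An object of class `network_summary`: list with `n_nodes`,
#'   `n_edges`, `pct_nodes_biggest`, `pct_edges_biggest`, `avg_clust_drug`,
#'   `avg_clust_disease`, `avg_clust_target` (NA when the graph has no node
#'   of the type, as in a class whose cases carry no examined targets),
#'   `transitivity`, `effective_diameter`, `small_world`.
#' @export
summarize_network <- function(g) {
  stopifnot(inherits(g, "triad_graph"))
  if (nrow(g$nodes) == 0L) stop("empty graph", call. = FALSE)
  sub <- largest_component(g)
  n_nodes <- nrow(g$nodes)
  n_edges <- nrow(g$edges)
  avg_or_na <- function(type) {
    if (any(g$nodes$node_type == type)) avg_clustering_by_type(g, type)
    else NA_real_
  }
  trans <- graph_transitivity(g)
  diam <- effective_diameter(g)
  structure(list(
    n_nodes = n_nodes,
    n_edges = n_edges,
    pct_nodes_biggest = 100 * igraph::vcount(sub) / n_nodes,
    pct_edges_biggest = if (n_edges) 100 * igraph::ecount(sub) / n_edges
                        else NA_real_,
    avg_clust_drug = avg_or_na("drug"),
    avg_clust_disease = avg_or_na("indication"),
    avg_clust_target = avg_or_na("target"),
    transitivity = trans,
    effective_diameter = diam,
    small_world = small_world_score(trans, n_nodes, diam),
    class_label = g$class_label
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary>%s\n",
              if (is.na(x$class_label)) "" else paste0(" ", x$class_label)))
  cat(sprintf("  nodes %d, edges %d (biggest component: %.2f%% nodes, %.2f%% edges)\n",
              x$n_nodes, x$n_edges, x$pct_nodes_biggest, x$pct_edges_biggest))
  cat(sprintf("  clustering  drug %.2f | disease %.2f | target %.2f\n",
              x$avg_clust_drug, x$avg_clust_disease, x$avg_clust_target))
  cat(sprintf("  transitivity %.4f, effective diameter %.4f, small-world %.4f\n",
              x$transitivity, x$effective_diameter, x$small_world))
  invisible(x)
}

#' @export
print.triad_graph <- function(x, ...) {
  cat(sprintf("<triad_graph>%s %d node(s), %d edge(s)\n",
              if (is.na(x$class_label)) "" else paste0(" ", x$class_label),
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a typed edge list
#'
#' @param g A `triad_graph`.
#' @param path Output TSV path (columns `source`, `target`, `edge_type`).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "triad_graph"))
  out <- data.frame(source = g$edges$from, target = g$edges$to,
                    edge_type = g$edges$edge_type, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
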