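test_that("build_graph enumerates nodes and edges of simple cases", {
  # 1 drug, 1 shared target, 2 indications: 4 nodes, 5 edges
  g <- build_graph(make_case("D1", "C04", "C10", ot = "T1", st = "T1"),
                   "target_centric")
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$edges), 5L)
  expect_setequal(g$edges$edge_type[g$edges$edge_type == "drug_indication"],
                  "drug_indication")
  # empty case set -> empty graph
  g0 <- build_graph(repo_cases(character(), character(), character(),
                               character(), character(), character()))
  expect_equal(nrow(g0$nodes), 0L)
  # disease-centric case without targets: drug + one indication, one edge
  g1 <- build_graph(make_case("D2", "C04", "C04"), "disease_centric")
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 1L)
})

test_that("build_graph counts match a flat set-construction oracle", {
  withr::with_seed(12, {
    cases <- bind_cases(
      make_case("D1", "C04", "C10", ot = c("T1", "T2"), st = "T1"),
      make_case("D2", "C04", "C16", ot = "T2", st = c("T3", "T4")),
      make_case("D3", "C01", "C10", ot = "T1", st = "T5")
    )
  })
  g <- build_graph(cases, "drug_centric")
  # oracle: scan rows, build node and edge sets independently
  nodes <- character(0); edges <- character(0)
  for (i in 1:3) {
    d <- paste0("drug:", cases$drug_name[i])
    io <- paste0("indication:", cases$original_mesh[i])
    is_ <- paste0("indication:", cases$secondary_mesh[i])
    to <- paste0("target:", cases$original_targets[[i]]$target_id)
    ts <- paste0("target:", cases$secondary_targets[[i]]$target_id)
    nodes <- union(nodes, c(d, io, is_, to, ts))
    ekey <- function(x, y) paste(pmin(x, y), pmax(x, y))
    edges <- union(edges, c(ekey(d, to), ekey(d, ts), ekey(to, io),
                            ekey(ts, is_), ekey(d, io), ekey(d, is_)))
  }
  expect_equal(nrow(g$nodes), length(nodes))
  expect_equal(nrow(g$edges), length(edges))
})

test_that("mixed class labels are rejected when a classification is supplied", {
  cases <- bind_cases(make_case("A", "C04", "C04"),
                      make_case("B", "C04", "C10", ot = "T1", st = "T1"))
  cl <- classify_all(cases)
  expect_error(build_graph(cases, classification = cl), "mixed")
  expect_silent(build_graph(cases_by_label(cases, cl, "disease_centric"),
                            classification = cl))
})

test_that("local clustering: clique centre 1, star centre 0, degree<2 is 0", {
  tri <- triad_graph(
    data.frame(id = c("d", "t", "i"),
               node_type = c("drug", "target", "indication")),
    data.frame(from = c("d", "t", "d"), to = c("t", "i", "i"),
               edge_type = c("drug_target", "target_indication",
                             "drug_indication")))
  expect_equal(local_clustering(tri, "d"), 1)
  expect_equal(graph_transitivity(tri), 1)
  star <- triad_graph(
    data.frame(id = c("d", "i1", "i2", "i3"),
               node_type = c("drug", rep("indication", 3))),
    data.frame(from = "d", to = c("i1", "i2", "i3"),
               edge_type = "drug_indication"))
  expect_equal(local_clustering(star, "d"), 0)
  expect_equal(local_clustering(star, "i1"), 0)  # degree 1
  expect_error(local_clustering(star, "nope"), "unknown node")
})

test_that("clustering, transitivity, diameter match brute-force oracles on random graphs", {
  withr::with_seed(77, {
    for (k in 1:12) {
      g <- random_triad_graph(sample(4:12, 1), stats::runif(1, 0.25, 0.7))
      if (nrow(g$edges) == 0) next
      for (v in g$nodes$id) {
        expect_equal(local_clustering(g, v), oracle_local_clustering(g, v),
                     info = v)
      }
      expect_equal(graph_transitivity(g), oracle_transitivity(g))
      big_ok <- tryCatch({
        expect_equal(effective_diameter(g), oracle_effective_diameter(g))
        TRUE
      }, error = function(e) grepl("fewer than 2", conditionMessage(e)))
      expect_true(big_ok)
      for (ty in unique(g$nodes$node_type)) {
        ids <- g$nodes$id[g$nodes$node_type == ty]
        expect_equal(avg_clustering_by_type(g, ty),
                     mean(vapply(ids, oracle_local_clustering, 0, g = g)))
      }
    }
  })
})

test_that("effective diameter uses interpolated percentiles of exact distances", {
  # path graph P5 via alternating types; distances {1,1,1,1,2,2,2,3,3,4}
  p5 <- triad_graph(
    data.frame(id = c("a", "b", "c", "d", "e"),
               node_type = c("drug", "target", "indication", "drug",
                             "target")),
    data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "e"),
               edge_type = c("drug_target", "target_indication",
                             "drug_indication", "drug_target")))
  # rank r = 90*(10-1)/100 = 8.1 -> between sorted d[9]=3 and d[10]=4 -> 3.1
  expect_equal(effective_diameter(p5), 3.1)
  # complete bipartite-ish: all distances 1 in a triangle
  tri <- triad_graph(
    data.frame(id = c("d", "t", "i"),
               node_type = c("drug", "target", "indication")),
    data.frame(from = c("d", "t", "d"), to = c("t", "i", "i"),
               edge_type = c("drug_target", "target_indication",
                             "drug_indication")))
  expect_equal(effective_diameter(tri), 1.0)
  single <- triad_graph(data.frame(id = "d", node_type = "drug"),
                        data.frame(from = character(), to = character(),
                                   edge_type = character()))
  expect_error(effective_diameter(single), "fewer than 2")
})

test_that("small_world_score is the stated ratio", {
  expect_equal(round(small_world_score(0.27, 51, 3.43), 2), 4.01)
  expect_equal(small_world_score(0, 100, 2.5), 0)
  expect_equal(small_world_score(1, 10, 2), 5)
  expect_error(small_world_score(0.5, 10, 0), "positive")
})

test_that("summarize_network is consistent with its constituents", {
  withr::with_seed(41, {
    for (k in 1:6) {
      g <- random_triad_graph(sample(6:12, 1), 0.5)
      s <- tryCatch(summarize_network(g), error = function(e) NULL)
      if (is.null(s)) next
      expect_equal(s$n_nodes, nrow(g$nodes))
      expect_equal(s$n_edges, nrow(g$edges))
      expect_equal(s$transitivity, graph_transitivity(g))
      expect_equal(s$effective_diameter, effective_diameter(g))
      # Eq-consistency: small_world * diameter == transitivity * n_nodes
      expect_equal(s$small_world * s$effective_diameter,
                   s$transitivity * s$n_nodes, tolerance = 1e-9)
      expect_true(s$pct_nodes_biggest >= 0 && s$pct_nodes_biggest <= 100)
    }
  })
})

test_that("component percentages and isolated nodes behave as stated", {
  # triangle plus pendant node: 4 nodes, 4 edges, one component
  g <- triad_graph(
    data.frame(id = c("d", "t", "i", "i2"),
               node_type = c("drug", "target", "indication", "indication")),
    data.frame(from = c("d", "t", "d", "d"), to = c("t", "i", "i", "i2"),
               edge_type = c("drug_target", "target_indication",
                             "drug_indication", "drug_indication")))
  s <- summarize_network(g)
  expect_equal(s$n_nodes, 4L)
  expect_equal(s$n_edges, 4L)
  expect_equal(s$pct_nodes_biggest, 100)
  # two disjoint triangles: 50% nodes, 50% edges in the biggest component
  two <- triad_graph(
    data.frame(id = c("d1", "t1", "i1", "d2", "t2", "i2"),
               node_type = rep(c("drug", "target", "indication"), 2)),
    data.frame(from = c("d1", "t1", "d1", "d2", "t2", "d2"),
               to = c("t1", "i1", "i1", "t2", "i2", "i2"),
               edge_type = rep(c("drug_target", "target_indication",
                                 "drug_indication"), 2)))
  s2 <- summarize_network(two)
  expect_equal(s2$pct_nodes_biggest, 50)
  expect_equal(s2$pct_edges_biggest, 50)
  # adding an isolated node: transitivity and diameter unchanged,
  # small_world scales with n_nodes
  g_iso <- triad_graph(rbind(g$nodes,
                             data.frame(id = "lonely", node_type = "drug")),
                       g$edges)
  s_iso <- summarize_network(g_iso)
  expect_equal(s_iso$transitivity, s$transitivity)
  expect_equal(s_iso$effective_diameter, s$effective_diameter)
  expect_equal(s_iso$small_world / s$small_world, 5 / 4)
})

test_that("metrics are invariant under node relabeling", {
  withr::with_seed(55, {
    g <- random_triad_graph(10, 0.5)
    perm <- sample(nrow(g$nodes))
    map <- stats::setNames(sprintf("relab%02d", perm), g$nodes$id)
    g2 <- triad_graph(
      data.frame(id = unname(map[g$nodes$id]), node_type = g$nodes$node_type),
      data.frame(from = unname(map[g$edges$from]),
                 to = unname(map[g$edges$to]),
                 edge_type = g$edges$edge_type))
    expect_equal(graph_transitivity(g2), graph_transitivity(g))
    expect_equal(effective_diameter(g2), effective_diameter(g))
    for (ty in unique(g$nodes$node_type)) {
      expect_equal(avg_clustering_by_type(g2, ty),
                   avg_clustering_by_type(g, ty))
    }
  })
})

test_that("triad_graph constructor enforces the simple-graph invariants", {
  nodes <- data.frame(id = c("d", "t"), node_type = c("drug", "target"))
  expect_error(triad_graph(nodes, data.frame(from = "d", to = "d",
                                             edge_type = "drug_target")),
               "self-loop")
  expect_error(triad_graph(nodes, data.frame(from = c("d", "t"),
                                             to = c("t", "d"),
                                             edge_type = "drug_target")),
               "duplicate edge")
  expect_error(triad_graph(nodes, data.frame(from = "d", to = "x",
                                             edge_type = "drug_target")),
               "endpoint")
  expect_error(triad_graph(nodes, data.frame(from = "d", to = "t",
                                             edge_type = "drug_indication")),
               "inconsistent")
})
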