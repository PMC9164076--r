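test_that("tripartite construction keeps layers separate and counts right", {
  g <- build_pta(data.frame(pathway = "p1", target = "t1"),
                 data.frame(target = "t1", drug = c("d1", "d2")))
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(unname(igraph::degree(g, "T1")), 3)
  # an identifier in two layers is a structure error
  expect_error(build_pta(data.frame(pathway = "X", target = "t1"),
                         data.frame(target = "t1", drug = "X")),
               "two layers")
  # empty mappings -> empty network
  g0 <- build_pta(data.frame(pathway = character(0), target = character(0)),
                  data.frame(target = character(0), drug = character(0)))
  expect_equal(igraph::vcount(g0), 0L)
})

test_that("unreferenced drugs and pathways never enter the network", {
  # a drug whose only target fell out of the final set has no pair, so the
  # builder receives nothing for it and it stays out
  td <- data.frame(target = c("t1", "t1"), drug = c("d1", "d2"))
  g <- build_pta(data.frame(pathway = "p1", target = "t1"), td)
  expect_false("d3" %in% igraph::V(g)$name)
})

test_that("degree tables are raw counts with the handshake identity", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("n", 1:5)
  dt <- degree_table(star)
  expect_equal(dt$dc[dt$node == "n1"], 4L)
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- paste0("r", 1:5)
  rt <- degree_table(ring)
  expect_true(all(rt$dc == 2L))
  expect_equal(sum(rt$dc), 2L * igraph::ecount(ring))
  expect_equal(nrow(degree_table(igraph::make_empty_graph(0))), 0L)
})

test_that("handshake identity holds on generated graphs", {
  set.seed(21)
  for (i in 1:20) {
    g <- igraph::sample_gnp(sample(3:15, 1), runif(1, 0.2, 0.8))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    expect_equal(sum(degree_table(g)$dc), 2L * igraph::ecount(g))
  }
})

test_that("tripartite degree tables include per-layer breakdowns", {
  g <- build_pta(data.frame(pathway = c("p1", "p2"), target = "t1"),
                 data.frame(target = "t1", drug = c("d1", "d2", "d3")))
  dt <- degree_table(g)
  t1 <- dt[dt$node == "T1", ]
  expect_equal(t1$dc, 5L)
  expect_equal(t1$dc_pathway, 2L)
  expect_equal(t1$dc_drug, 3L)
})

test_that("betweenness normalization puts a sole intermediary at exactly 1", {
  path <- igraph::make_graph(~ A - B, B - C)
  bt <- betweenness_table(path)
  expect_equal(bt$bc[bt$node == "B"], 1)
  expect_equal(bt$bc[bt$node == "A"], 0)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  expect_true(all(betweenness_table(k4)$bc == 0))
})

test_that("betweenness equals the exhaustive path-counting oracle on small graphs", {
  # all connected graphs on 3-4 nodes, plus sampled 6- and 7-node graphs
  for (n in 3:4) {
    for (adj in Filter(is_connected_adj, all_graphs(n))) {
      g <- adj_to_graph(adj)
      igraph::V(g)$name <- paste0("v", 1:n)
      got <- betweenness_table(g)
      expect_equal(got$bc[match(paste0("v", 1:n), got$node)],
                   oracle_betweenness(adj), tolerance = 1e-12)
    }
  }
  set.seed(66)
  for (i in 1:30) {
    n <- sample(6:7, 1)
    repeat {
      g <- igraph::sample_gnp(n, runif(1, 0.35, 0.8))
      if (igraph::is_connected(g)) break
    }
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    igraph::V(g)$name <- paste0("v", 1:n)
    got <- betweenness_table(g)
    expect_equal(got$bc[match(paste0("v", 1:n), got$node)],
                 oracle_betweenness(adj), tolerance = 1e-12)
  }
})

test_that("top-fraction filter drops zeros, takes ceil(f*n) of the original size, keeps boundary ties", {
  tab <- data.frame(node = paste0("n", 1:5), dc = c(5, 4, 3, 2, 1))
  out <- top_fraction_filter(tab, "dc", fraction = 0.3)
  expect_equal(out$cutoff, 2L)
  expect_equal(out$selected, c("n1", "n2"))
  # boundary ties are all-or-none
  tab2 <- data.frame(node = paste0("n", 1:6), dc = c(5, 4, 4, 4, 1, 0))
  out2 <- top_fraction_filter(tab2, "dc", fraction = 0.3)
  expect_equal(out2$cutoff, 2L)
  expect_setequal(out2$selected, c("n1", "n2", "n3", "n4"))
  out2x <- top_fraction_filter(tab2, "dc", fraction = 0.3,
                               tie_policy = "exclude")
  expect_equal(length(out2x$selected), 2L)
  # all-zero tables warn and select nothing
  tab0 <- data.frame(node = c("a", "b"), bc = c(0, 0))
  expect_warning(out0 <- top_fraction_filter(tab0, "bc"), "zero")
  expect_equal(out0$selected, character(0))
})

test_that("filter selection is downward-closed in rank", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    tab <- data.frame(node = paste0("n", 1:n),
                      dc = sample(0:6, n, replace = TRUE))
    if (all(tab$dc == 0)) next
    out <- top_fraction_filter(tab, "dc", fraction = runif(1, 0.1, 0.9))
    sel <- tab$dc[tab$node %in% out$selected]
    unsel <- tab$dc[!(tab$node %in% out$selected)]
    if (length(sel) > 0 && length(unsel) > 0) {
      expect_true(min(sel) >= max(unsel))
      # all-or-none at the boundary
      expect_false(out$boundary %in% unsel)
    }
  }
})

test_that("the single filter rule reproduces both published stages (13->5 then 5->1)", {
  stage1 <- top_fraction_filter(fixture_ppi_centrality(), "dc")
  expect_setequal(stage1$selected, c("GRIN2B", "NOS2", "APP", "NOS3", "FYN"))
  stage2 <- top_fraction_filter(fixture_core_centrality(), "bc")
  expect_equal(stage2$selected, "GRIN2B")
})

test_that("hub isolation recovers dominant nodes on canonical topologies", {
  # star: center dominates degree and betweenness
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:10)
  expect_equal(isolate_hub(star)$hub, "s1")
  # two 5-cliques joined through a bridge connected to every member
  g <- gen_hub_graph(synth_config(seed = 2))
  res <- isolate_hub(g$edges, nodes = g$nodes)
  expect_equal(res$hub, g$hub)
  # stage artifacts are returned and consistent
  expect_true(all(res$stage2$selected %in% res$stage1$selected))
  expect_equal(igraph::vcount(res$subgraph), length(res$stage1$selected))
  expect_true(all(c("dc", "bc") %in% names(res$centrality_full)))
})

test_that("isolated nodes carry zero centrality but stay representable", {
  g <- gen_hub_graph(synth_config(seed = 4, n_isolated = 4))
  graph <- ppi_graph(g$edges, nodes = g$nodes)
  dt <- degree_table(graph)
  iso <- setdiff(g$nodes, c(g$edges$from, g$edges$to))
  expect_equal(length(iso), 4L)
  expect_true(all(dt$dc[dt$node %in% iso] == 0L))
  bt <- betweenness_table(graph)
  expect_true(all(bt$bc[bt$node %in% iso] == 0))
})
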