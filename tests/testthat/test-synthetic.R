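test_that("infeasible configurations are rejected up front", {
  expect_error(synth_config(n_targets_a = 10, overlap_ab = 20), "config error")
  expect_error(synth_config(overlap_ab = 10, overlap_final = 11), "config error")
  expect_error(synth_config(pathways = data.frame(K = 5L, k = 6L)),
               "config error")
  expect_error(gen_hub_graph(synth_config(clique_sizes = c(2L, 5L))),
               "config error")
  expect_error(gen_docking_table(synth_config(energy_range = c(-5, -4))),
               "config error")
  cfg <- synth_config(seed = 1, overlap_ab = 5, overlap_final = 5,
                      n_targets_a = 10, n_targets_b = 10, n_disease = 8)
  stage1 <- target_set("s", c("A", "B"))
  expect_error(gen_disease_set(cfg, stage1), "config error")
})

test_that("generators are pure functions of seed and config", {
  cfg <- synth_config(seed = 99)
  expect_identical(gen_prediction_sources(cfg), gen_prediction_sources(cfg))
  s1 <- target_set("s", gen_prediction_sources(cfg)$shared)
  expect_identical(gen_disease_set(cfg, s1), gen_disease_set(cfg, s1))
  final <- target_set("f", s1$members[1:15])
  expect_identical(gen_pathway_db(cfg, final), gen_pathway_db(cfg, final))
  expect_identical(gen_hub_graph(cfg), gen_hub_graph(cfg))
  expect_identical(gen_docking_table(cfg), gen_docking_table(cfg))
  # a different seed changes the draw
  cfg2 <- synth_config(seed = 100)
  expect_false(identical(gen_prediction_sources(cfg)$source_a$pairs,
                         gen_prediction_sources(cfg2)$source_a$pairs))
})

test_that("study-default cardinalities are planted exactly", {
  cfg <- synth_config(seed = 12)
  preds <- gen_prediction_sources(cfg)
  sa <- target_set("a", preds$source_a$pairs$target)
  sb <- target_set("b", preds$source_b$pairs$target)
  expect_equal(length(sa$members), 332L)
  expect_equal(length(sb$members), 660L)
  v <- intersect_sets(sa, sb)
  expect_equal(v$both, 198L)
  expect_equal(length(union(sa$members, sb$members)), 794L)
  disease <- gen_disease_set(cfg, target_set("s1", v$members))
  expect_equal(length(disease$members), 622L)
  res <- two_stage_overlap(sa, sb, disease)
  expect_equal(res$stage2$both, 15L)
})

test_that("disjoint and fully-nested overlaps are constructible", {
  cfg <- synth_config(seed = 3, n_targets_a = 8, n_targets_b = 9,
                      overlap_ab = 0, n_disease = 5, overlap_final = 0)
  preds <- gen_prediction_sources(cfg)
  expect_equal(length(intersect(preds$source_a$pairs$target,
                                preds$source_b$pairs$target)), 0L)
  cfg2 <- synth_config(seed = 3, n_targets_a = 10, n_targets_b = 10,
                       overlap_ab = 6, n_disease = 6, overlap_final = 6)
  s1 <- target_set("s", gen_prediction_sources(cfg2)$shared)
  d <- gen_disease_set(cfg2, s1)
  expect_true(all(s1$members %in% d$members))
})

test_that("planted pathway hits give the planted rich factors", {
  cfg <- synth_config(seed = 8,
                      pathways = data.frame(K = c(21L, 64L, 330L, 12L),
                                            k = c(2L, 3L, 4L, 0L)))
  final <- target_set("f", sprintf("T%02d", 1:15))
  db <- gen_pathway_db(cfg, final)
  expect_equal(db$K, c(21L, 64L, 330L, 12L))
  tab <- enrich(final, db, N = 20000)
  expect_equal(round(tab$rich_factor[match(c("path0001", "path0002", "path0003"),
                                           tab$pathway_id)], 4),
               c(0.0952, 0.0469, 0.0121))
  # zero-hit pathway never appears
  expect_false("path0004" %in% tab$pathway_id)
  # saturated pathway
  cfg2 <- synth_config(seed = 8, pathways = data.frame(K = 5L, k = 5L))
  db2 <- gen_pathway_db(cfg2, final)
  tab2 <- enrich(final, db2, N = 20000)
  expect_equal(tab2$rich_factor, 1)
})

test_that("hub graphs plant a strictly dominant bridge", {
  g <- gen_hub_graph(synth_config(seed = 5))
  graph <- ppi_graph(g$edges, nodes = g$nodes)
  bt <- betweenness_table(graph)
  hub_bc <- bt$bc[bt$node == g$hub]
  expect_true(all(bt$bc[bt$node != g$hub] < hub_bc))
  # isolated nodes have zero degree and betweenness
  dt <- degree_table(graph)
  iso <- setdiff(g$nodes, c(g$edges$from, g$edges$to))
  expect_true(all(dt$dc[dt$node %in% iso] == 0L))
})

test_that("docking generator plants the active/inactive split", {
  cfg <- synth_config(seed = 31, n_active = 6L, n_inactive = 2L)
  rec <- gen_docking_table(cfg)
  expect_equal(classify_binders(rec)$n_active, 6L)
  rec0 <- gen_docking_table(synth_config(seed = 31, n_active = 0L,
                                         n_inactive = 5L))
  expect_equal(classify_binders(rec0)$n_active, 0L)
})

test_that("the emitted study directory is byte-stable and readable by the ingest layer", {
  cfg <- synth_config(seed = 77, n_targets_a = 30, n_targets_b = 40,
                      overlap_ab = 12, n_disease = 20, overlap_final = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_study(cfg, d1)
  write_synthetic_study(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
  # files parse back through the readers they were written for
  pa <- read_prediction_table(file.path(d1, "predictions_A.tsv"), "a")
  expect_equal(length(unique(pa$pairs$target)), 30L)
  db <- read_gmt(file.path(d1, "pathways.gmt"))
  expect_equal(nrow(db), 4L)
  el <- read_edge_list(file.path(d1, "ppi_edges.tsv"))
  expect_true(nrow(el) > 0L)
  rec <- parse_scores(file.path(d1, "docking_scores.tsv"))
  expect_equal(nrow(rec), 8L)
})
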