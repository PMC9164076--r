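test_that("rich factor is exact k/K with strict domain checks", {
  expect_equal(round(rich_factor(2, 21), 4), 0.0952)
  expect_equal(round(rich_factor(3, 64), 4), 0.0469)
  expect_equal(round(rich_factor(2, 48), 4), 0.0417)
  expect_equal(round(rich_factor(4, 330), 4), 0.0121)
  expect_equal(rich_factor(5, 5), 1)
  expect_error(rich_factor(3, 2), "invalid annotation")
  expect_error(rich_factor(1, 0), "invalid annotation")
  expect_error(rich_factor(0, 5), "invalid annotation")
})

test_that("rich factor is monotone in k and antitone in K", {
  for (K in c(5, 21, 100)) {
    rf <- vapply(1:K, rich_factor, numeric(1), K = K)
    expect_true(all(diff(rf) > 0))
  }
  for (k in c(1, 3)) {
    rf <- vapply(seq(k, 60), function(K) rich_factor(k, K), numeric(1))
    expect_true(all(diff(rf) < 0))
  }
})

test_that("hypergeometric upper tail matches literal draw enumeration", {
  # hand-checkable case: 40 of the C(10,3)=120 draws have >= 2 hits
  expect_equal(hypergeom_pvalue(2, 4, 3, 10), 40 / 120)
  expect_equal(hypergeom_pvalue(0, 4, 3, 10), 1)
  expect_equal(hypergeom_pvalue(3, 10, 3, 10), 1)
  set.seed(5)
  for (i in 1:20) {
    N <- sample(4:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N),
                 oracle_hyper_enum(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(5, 4, 6, 10), "inconsistent")
  expect_error(hypergeom_pvalue(1, 11, 3, 10), "inconsistent")
})

test_that("hypergeometric tail matches combinatorial summation for all N <= 25", {
  for (N in c(5, 10, 17, 25)) {
    for (K in seq(0, N, by = 3)) {
      for (n in seq(1, N, by = 3)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_pvalue(k, K, n, N),
                       oracle_hyper_sum(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment matches the hand step-up oracle and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.5, 0.5)), c(0.5, 0.5))
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # permutation invariance up to alignment
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(1.2), "\\(0, 1\\]")
})

test_that("enrich recovers a planted over-represented pathway", {
  # one pathway loaded with 8 of 10 genes from a 20-gene query vs N=1000
  query <- target_set("q", sprintf("Q%02d", 1:20))
  db <- data.frame(pathway_id = c("planted", "noise1", "noise2"),
                   name = c("planted", "noise1", "noise2"),
                   K = c(10L, 50L, 80L), stringsAsFactors = FALSE)
  db$genes <- list(c(sprintf("Q%02d", 1:8), "F01", "F02"),
                   c("Q09", sprintf("N%03d", 1:49)),
                   sprintf("M%03d", 1:80))
  class(db) <- c("pathway_db", "data.frame")
  tab <- enrich(query, db, N = 1000)
  expect_equal(tab$pathway_id[which.min(tab$p_value)], "planted")
  expect_equal(tab$k[tab$pathway_id == "planted"], 8L)
  # p-value verified by enumeration oracle at reduced N (planted pathway
  # only, so every K fits inside the small background)
  db25 <- db[db$pathway_id == "planted", , drop = FALSE]
  class(db25) <- c("pathway_db", "data.frame")
  expect_equal(enrich(query, db25, N = 25)$p_value,
               oracle_hyper_sum(8, 10, 20, 25), tolerance = 1e-12)
  # rows sorted ascending by rich factor, fdr >= p
  expect_true(!is.unsorted(tab$rich_factor))
  expect_true(all(tab$fdr >= tab$p_value - 1e-15))
  # no-hit pathway absent
  expect_false("noise2" %in% tab$pathway_id)
})

test_that("enrich on a disjoint query warns and returns an empty table", {
  db <- data.frame(pathway_id = "p", name = "p", K = 3L)
  db$genes <- list(c("A", "B", "C"))
  class(db) <- c("pathway_db", "data.frame")
  expect_warning(tab <- enrich(target_set("q", "Z"), db), "no pathway")
  expect_equal(nrow(tab), 0L)
  expect_error(key_pathway(tab), "no result")
})

test_that("key pathway takes minimum rich factor with FDR then id tie-breaks", {
  tab <- fixture_enrichment()
  expect_equal(key_pathway(tab), "hsa04080")
  expect_equal(tab$rich_factor[tab$pathway_id == "hsa04080"], 0.0121)
  # single row
  one <- enrichment_table(data.frame(pathway_id = "p", rich_factor = 0.5,
                                     fdr = 0.01))
  expect_equal(key_pathway(one), "p")
  # tie on rich factor -> smaller FDR wins
  tie <- enrichment_table(data.frame(pathway_id = c("b", "a"),
                                     rich_factor = c(0.1, 0.1),
                                     fdr = c(0.01, 0.04)))
  expect_equal(key_pathway(tie), "b")
  # full tie -> lexicographic id
  tie2 <- enrichment_table(data.frame(pathway_id = c("b", "a"),
                                      rich_factor = 0.1, fdr = 0.01))
  expect_equal(key_pathway(tie2), "a")
})

test_that("the published seven-pathway table all survives the FDR < 0.05 rule", {
  tab <- fixture_enrichment()
  expect_equal(nrow(tab), 7L)
  expect_true(all(tab$fdr < 0.05))
  expect_equal(max(tab$fdr), 0.0497)
})

test_that("bubble data passes values through", {
  tab <- fixture_enrichment()
  bd <- bubble_data(tab)
  expect_equal(nrow(bd), 7L)
  expect_equal(bd$rich_factor, tab$rich_factor)
  one <- enrichment_table(data.frame(pathway_id = "p", rich_factor = 0.5,
                                     fdr = 0.01))
  expect_equal(bubble_data(one)$neg_log10_fdr, 2)
  empty <- enrichment_table(data.frame(pathway_id = character(0),
                                       rich_factor = numeric(0),
                                       fdr = numeric(0)))
  expect_equal(nrow(bubble_data(empty)), 0L)
})
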