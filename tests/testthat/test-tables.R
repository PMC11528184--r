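test_that("cluster list summarizes annotations and enrichments", {
  fx <- planted_fixture()
  rec <- enrich_all_clusters(fx$g, fx$p, fx$a)
  cl <- cluster_list_table(rec, fx$p, fx$a)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_enriched[cl$cluster == 1], 1L)
  expect_equal(cl$enriched_terms[cl$cluster == 1], "TT")
  expect_equal(cl$n_annotated, c(20L, 20L))
  expect_equal(cl$n_terms[cl$cluster == 1], 2L)  # CA and TT
})

test_that("clusters with no annotated node still get a zero row", {
  g <- barbell_graph()
  p <- new_partition(list(c("A", "B", "C"), c("D", "E", "F")), g)
  a <- annotation_from_list(list(A = "t", B = "t"), g)
  rec <- enrich_all_clusters(g, p, a, min_cluster_size = 1)
  cl <- cluster_list_table(rec, p, a)
  empty_row <- cl[cl$cluster == 2, ]
  expect_equal(empty_row$n_annotated, 0L)
  expect_equal(empty_row$n_terms, 0L)
  expect_equal(empty_row$n_enriched, 0L)
  expect_equal(empty_row$enriched_terms, "")
})

test_that("cluster analysis sorts by adjusted p and errors on unknown IDs", {
  fx <- planted_fixture()
  rec <- enrich_all_clusters(fx$g, fx$p, fx$a)
  tab <- cluster_analysis_table(rec, 1)
  expect_equal(tab$term[1], "TT")
  expect_true(!is.unsorted(tab$p_adj))
  expect_error(cluster_analysis_table(rec, 99), "unknown cluster")

  # a retained cluster without annotations yields an empty table
  g <- barbell_graph()
  p <- new_partition(list(c("A", "B", "C"), c("D", "E", "F")), g)
  a <- annotation_from_list(list(A = "t"), g)
  rec2 <- enrich_all_clusters(g, p, a, min_cluster_size = 1)
  expect_equal(nrow(cluster_analysis_table(rec2, 2)), 0)
})

test_that("singleton-count terms rank by background frequency", {
  # with k = 1 everywhere, P(X >= 1) increases with K, so the p-value
  # ordering must equal the K ordering
  g <- random_connected_graph(12, 9)
  p <- new_partition(list(g$nodes), g)
  nt <- list()
  nt[[g$nodes[1]]] <- "rare"
  for (v in g$nodes[2:6]) nt[[v]] <- "common"
  nt[[g$nodes[7]]] <- c("mid")
  for (v in g$nodes[8:9]) nt[[v]] <- "mid"
  a <- annotation_from_list(nt, g)
  # test cluster = 3 annotated nodes carrying each term once
  sub <- new_partition(list(c(g$nodes[1], g$nodes[2], g$nodes[7]),
                            g$nodes[-c(1, 2, 7)]), g)
  rec <- enrich_all_clusters(g, sub, a, min_cluster_size = 1)
  sub_rec <- rec[rec$cluster == 2 & rec$k == 1, ]  # the 3-node cluster
  expect_gte(nrow(sub_rec), 3)
  ord <- order(sub_rec$K)
  expect_true(all(diff(sub_rec$p_raw[ord]) > 0))
  expect_true(all(diff(sub_rec$p_adj[ord]) >= 0))
})

test_that("term analysis lists the containing clusters", {
  fx <- planted_fixture()
  rec <- enrich_all_clusters(fx$g, fx$p, fx$a)
  tt <- term_analysis_table(rec, "TT")
  expect_equal(nrow(tt), 2)
  expect_equal(tt$enriched, c(TRUE, FALSE))
  expect_equal(nrow(term_analysis_table(rec, "CA")), 2)
  expect_equal(nrow(term_analysis_table(rec, "ABSENT")), 0)
})

test_that("the annotation matrix holds the carrier counts", {
  fx <- planted_fixture()
  rec <- enrich_all_clusters(fx$g, fx$p, fx$a)
  m <- annotation_matrix(rec, fx$p, fx$a)
  expect_equal(m["1", "TT"], 15L)
  expect_equal(m["2", "TT"], 1L)
  expect_equal(m["1", "CA"], 20L)
  expect_equal(unname(rowSums(m)),
               vapply(c(1L, 2L), function(cid) {
                 sum(rec$k[rec$cluster == cid])
               }, 0))
})

test_that("manual cluster annotations are idempotent and removable", {
  fx <- planted_fixture()
  rec <- enrich_all_clusters(fx$g, fx$p, fx$a)
  p <- add_custom_annotation(fx$p, 1, "endocytosis-related")
  p <- add_custom_annotation(p, 1, "endocytosis-related")  # no duplicate
  cl <- cluster_list_table(rec, p, fx$a)
  expect_equal(cl$custom_annotations[cl$cluster == 1],
               "endocytosis-related")
  p2 <- remove_custom_annotation(p, 1)
  cl2 <- cluster_list_table(rec, p2, fx$a)
  expect_identical(cl2, cluster_list_table(rec, fx$p, fx$a))
  expect_error(add_custom_annotation(fx$p, 42, "x"), "unknown cluster")
})

test_that("node list flags carriers of a highlighted term", {
  fx <- planted_fixture()
  nl <- node_list_table(fx$p, fx$a, highlight_term = "TT")
  expect_equal(sum(nl$carries_term), 16)
  expect_true(all(grepl("CA", nl$terms)))
  expect_setequal(unique(nl$clusters), c("1", "2"))
})

test_that("tables and matrices serialize to TSV", {
  fx <- planted_fixture()
  rec <- enrich_all_clusters(fx$g, fx$p, fx$a)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(cluster_list_table(rec, fx$p, fx$a), f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), 2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(annotation_matrix(rec, fx$p, fx$a), f2)
  m2 <- read.delim(f2, check.names = FALSE)
  expect_equal(m2$TT, c(15L, 1L))
})
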