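test_that("FT recovers planted structure on canonical instances", {
  g <- barbell_graph()
  p <- ft_partition(g)
  expect_equal(n_clusters(p), 2)
  expect_setequal(p$clusters[["1"]], c("A", "B", "C"))
  expect_setequal(p$clusters[["2"]], c("D", "E", "F"))
  expect_equal(attr(p, "Q"), 5 / 14, tolerance = 1e-12)

  e1 <- network_from_edges("A", "B", quiet = TRUE)
  expect_equal(n_clusters(ft_partition(e1)), 1)

  pairs <- network_from_edges(c("a1", "b1"), c("a2", "b2"), quiet = TRUE)
  pp <- ft_partition(pairs)
  expect_equal(n_clusters(pp), 2)
  expect_setequal(pp$clusters[["1"]], c("a1", "a2"))
})

test_that("TFiT matches FT on the barbell and keeps K4 whole", {
  g <- barbell_graph()
  p <- tfit_partition(g)
  expect_equal(attr(p, "Q"), 5 / 14, tolerance = 1e-12)
  expect_equal(lapply(p$clusters, sort),
               list(`1` = c("A", "B", "C"), `2` = c("D", "E", "F")))

  k4 <- network_from_edges(c("a", "a", "a", "b", "b", "c"),
                           c("b", "c", "d", "c", "d", "d"), quiet = TRUE)
  expect_equal(n_clusters(tfit_partition(k4)), 1)
})

test_that("FT and TFiT stay within 0.05 of the exhaustive optimum", {
  # small pre-screen; the full 100-graph sweep runs in the acceptance suite
  for (seed in 1:15) {
    g <- random_connected_graph(sample(5:8, 1), seed)
    opt <- max_modularity_exhaustive(g)
    for (p in list(ft_partition(g, seed = seed),
                   tfit_partition(g, seed = seed))) {
      expect_gte(attr(p, "Q"), opt$q - 0.05)
      expect_lte(attr(p, "Q"), opt$q + 1e-9)
    }
  }
})

test_that("accepted transfer moves increase modularity monotonically", {
  for (seed in 1:5) {
    g <- random_connected_graph(10, seed)
    wg <- modclust:::as_wgraph(g)
    comm <- withr::with_seed(seed, {
      modclust:::transfer_sweeps(wg, seq_len(wg$n), order = sample(wg$n))
    })
    trace <- attr(comm, "q_trace")
    expect_true(all(diff(trace) > 0))
    # maintained Q agrees with from-scratch recomputation at the end
    expect_equal(trace[length(trace)],
                 modclust:::wmodularity(wg, as.integer(comm)),
                 tolerance = 1e-9)
  }
})

test_that("clustering is deterministic given the seed", {
  g <- random_connected_graph(12, 3)
  expect_identical(ft_partition(g, seed = 9), ft_partition(g, seed = 9))
  expect_identical(tfit_partition(g, seed = 9), tfit_partition(g, seed = 9))
  expect_identical(ocg_partition(g, "centered_cliques"),
                   ocg_partition(g, "centered_cliques"))
})

test_that("disconnected inputs cluster each component separately", {
  g <- network_from_edges(c("A", "B", "C", "X"),
                          c("B", "C", "A", "Y"), quiet = TRUE)
  p <- tfit_partition(g)
  expect_equal(n_clusters(p), 2)
  expect_setequal(p$clusters[["2"]], c("X", "Y"))
})

test_that("OCG keeps cliques together and flags shared nodes", {
  g <- barbell_graph()
  p <- ocg_partition(g, initial_system = "edges")
  # every triangle ends up fully inside some final cluster
  for (tri in list(c("A", "B", "C"), c("D", "E", "F"))) {
    expect_true(any(vapply(p$clusters, function(cl) all(tri %in% cl), TRUE)))
  }

  tri_g <- triangle_graph()
  pt <- ocg_partition(tri_g, initial_system = "maximal_cliques")
  expect_equal(n_clusters(pt), 1)
  expect_setequal(pt$clusters[["1"]], c("A", "B", "C"))

  pc <- ocg_partition(g, initial_system = "centered_cliques")
  expect_true(n_clusters(pc) %in% 2:3)
  shared <- names(pc$membership)[lengths(pc$membership) > 1]
  expect_true(all(shared %in% c("C", "D")))   # only the bridge endpoints
})

test_that("OCG covers remain complete even after primary assignment", {
  for (seed in 1:3) {
    g <- random_connected_graph(10, seed)
    p <- ocg_partition(g, initial_system = "centered_cliques")
    expect_setequal(names(p$membership), g$nodes)
    prim <- primary_clusters(p)
    expect_false(prim$overlapping)
    expect_setequal(names(prim$membership), g$nodes)
  }
})

test_that("OCG fusion gains match disjoint fusion gains in the limit", {
  # when the class system is disjoint, overlap modularity is plain Q, so
  # fusing two disjoint singleton-block classes must change Q_ov by the
  # delta_q_merge value
  g <- barbell_graph()
  p <- new_partition(list(c("A", "B", "C"), c("D", "E"), "F"), g)
  st <- mod_state(g, p)
  merged <- new_partition(list(c("A", "B", "C"), c("D", "E", "F")), g)
  expect_equal(overlap_modularity(g, merged) - overlap_modularity(g, p),
               delta_q_merge(st, 2, 3), tolerance = 1e-12)
})

test_that("external partitions are validated on import", {
  tri <- triangle_graph()
  f <- withr::local_tempfile(lines = c("A\t1", "B\t1", "C\t2"))
  p <- import_partition(f, tri)
  expect_false(p$overlapping)
  expect_equal(lapply(p$clusters, sort), list(`1` = c("A", "B"), `2` = "C"))

  f2 <- withr::local_tempfile(lines = c("A\t1", "B\t1", "C\t2", "A\t2"))
  p2 <- import_partition(f2, tri)
  expect_true(p2$overlapping)
  expect_equal(sort(p2$membership[["A"]]), c(1L, 2L))

  f3 <- withr::local_tempfile(lines = c("A\t1", "B\t1"))
  expect_error(import_partition(f3, tri), "uncovered nodes: C")

  f4 <- withr::local_tempfile(lines = c("A\t1", "B\t1", "C\t1", "Z\t2"))
  expect_error(import_partition(f4, tri), "not in graph: Z")
})

test_that("partition files round-trip", {
  g <- random_connected_graph(9, 4)
  p <- ocg_partition(g, "centered_cliques")
  f <- withr::local_tempfile()
  write_partition(p, f)
  p2 <- import_partition(f, g)
  expect_equal(p2$clusters, p$clusters)
  expect_equal(p2$overlapping, p$overlapping)
})

test_that("planted SBM blocks are recovered by TFiT", {
  sbm <- make_sbm(c(20, 20, 20, 20), p_in = 0.3, p_out = 0.02, seed = 101)
  p <- tfit_partition(sbm$network, seed = 1)
  ari <- mclust::adjustedRandIndex(mem_of(sbm$network, p),
                                   mem_of(sbm$network, sbm$partition))
  expect_gte(ari, 0.9)
})
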