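test_that("degenerate SBM probabilities give exact graphs", {
  sbm <- make_sbm(c(3, 3), p_in = 1, p_out = 0, seed = 1)
  expect_equal(sbm$network$m, 6)   # two disjoint triangles
  comp <- igraph::components(as_igraph(sbm$network))
  expect_equal(comp$no, 2)
  expect_equal(unname(comp$csize), c(3, 3))
  expect_false(sbm$partition$overlapping)

  empty <- make_sbm(c(3, 3), p_in = 0, p_out = 0, seed = 1)
  expect_equal(empty$network$m, 0)
  expect_equal(length(empty$network$nodes), 6)  # isolated nodes retained
  expect_error(make_sbm(c(3, 3), p_in = 1.5, p_out = 0, seed = 1),
               "probabilities")
})

test_that("SBM output is reproducible bit-for-bit", {
  a <- make_sbm(c(10, 10), 0.3, 0.05, seed = 99)
  b <- make_sbm(c(10, 10), 0.3, 0.05, seed = 99)
  expect_identical(a, b)
  c <- make_sbm(c(10, 10), 0.3, 0.05, seed = 100)
  expect_false(identical(a$network$edges, c$network$edges))
})

test_that("SBM edge counts match the binomial expectation within 3 sigma", {
  sizes <- c(20, 20, 20, 20)
  n <- sum(sizes)
  within_pairs <- sum(choose(sizes, 2))
  between_pairs <- choose(n, 2) - within_pairs
  p_in <- 0.3; p_out <- 0.02
  mu <- within_pairs * p_in + between_pairs * p_out
  sigma <- sqrt(within_pairs * p_in * (1 - p_in) +
                between_pairs * p_out * (1 - p_out))
  m <- make_sbm(sizes, p_in, p_out, seed = 7)$network$m
  expect_lt(abs(m - mu), 3 * sigma)
})

test_that("empirical block densities track p_in and p_out", {
  sizes <- c(15, 15)
  p_in <- 0.4; p_out <- 0.05
  n_rep <- 20
  win <- between <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sbm <- make_sbm(sizes, p_in, p_out, seed = 1000 + r)
    g <- sbm$network
    blk <- mem_of(g, sbm$partition)
    same <- blk[g$edges[, 1]] == blk[g$edges[, 2]]
    win[r] <- sum(same) / sum(choose(sizes, 2))
    between[r] <- sum(!same) / (choose(sum(sizes), 2) - sum(choose(sizes, 2)))
  }
  n_within <- n_rep * sum(choose(sizes, 2))
  n_between <- n_rep * (choose(sum(sizes), 2) - sum(choose(sizes, 2)))
  expect_lt(abs(mean(win) - p_in), 3 * sqrt(p_in * (1 - p_in) / n_within))
  expect_lt(abs(mean(between) - p_out),
            3 * sqrt(p_out * (1 - p_out) / n_between))
})

test_that("planted annotations hit their cluster exactly in the limit", {
  sbm <- make_sbm(c(6, 6), 1, 0, seed = 2)
  a <- make_annotations(sbm$network, sbm$partition, n_terms = 3,
                        background_rate = 0,
                        planted = data.frame(cluster = 1, term = "T01",
                                             multiplier = Inf),
                        coverage = 1, seed = 3) |>
    suppressWarnings()
  expect_setequal(a$term_nodes[["T01"]], sbm$partition$clusters[["1"]])
  # coverage 1 guarantees every node carries >= 1 term via the catch-all
  expect_equal(coverage(a)$count, 12)
  expect_true("T00" %in% names(a$term_nodes))
})

test_that("planted multipliers raise carrier counts proportionally", {
  sbm <- make_sbm(c(20, 20, 20), 0.3, 0.02, seed = 4)
  n_rep <- 30
  k_planted <- k_bg <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    a <- make_annotations(sbm$network, sbm$partition, n_terms = 5,
                          background_rate = 0.1,
                          planted = data.frame(cluster = 1, term = "T01",
                                               multiplier = 3),
                          coverage = 1, seed = 5000 + r)
    c1 <- sbm$partition$clusters[["1"]]
    k_planted[r] <- length(intersect(a$term_nodes[["T01"]], c1))
    k_bg[r] <- length(intersect(a$term_nodes[["T02"]], c1))
  }
  # expectations 6 vs 2 per 20-node cluster
  expect_lt(abs(mean(k_planted) - 6),
            3 * sqrt(20 * 0.3 * 0.7 / n_rep))
  expect_lt(abs(mean(k_bg) - 2), 3 * sqrt(20 * 0.1 * 0.9 / n_rep))
})

test_that("coverage thinning hits the target and warns on capped rates", {
  sbm <- make_sbm(c(10, 10), 0.5, 0.1, seed = 6)
  a <- make_annotations(sbm$network, sbm$partition, n_terms = 10,
                        background_rate = 0.5, coverage = 0.6, seed = 7)
  expect_equal(coverage(a)$count, 12)
  expect_warning(
    make_annotations(sbm$network, sbm$partition, n_terms = 2,
                     background_rate = 0.6,
                     planted = data.frame(cluster = 1, term = "T01",
                                          multiplier = 2),
                     coverage = 1, seed = 8),
    "capped")
  expect_identical(
    make_annotations(sbm$network, sbm$partition, 5, 0.3, seed = 9),
    make_annotations(sbm$network, sbm$partition, 5, 0.3, seed = 9))
})
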