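# shared fixtures and independent oracles for the test suite

# two triangles {A,B,C} and {D,E,F} joined by the bridge C-D (6-node barbell)
barbell_graph <- function() {
  network_from_edges(c("A", "B", "C", "D", "E", "F", "C"),
                     c("B", "C", "A", "E", "F", "D", "D"), quiet = TRUE)
}

triangle_graph <- function() {
  network_from_edges(c("A", "B", "C"), c("B", "C", "A"), quiet = TRUE)
}

# seeded random connected graph on n nodes (igraph G(n,p), resampled until
# connected); names n01, n02, ... so ordering is deterministic
random_connected_graph <- function(n, seed, p = 0.45) {
  withr::with_seed(seed, {
    repeat {
      ig <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(ig) && igraph::ecount(ig) >= 1) break
    }
    el <- igraph::as_edgelist(ig)
    ids <- sprintf("n%02d", seq_len(n))
    network_from_edges(ids[el[, 1]], ids[el[, 2]], nodes = ids, quiet = TRUE)
  })
}

# all set partitions of 1..n as membership vectors (restricted growth
# strings); cached per n
.partition_cache <- new.env(parent = emptyenv())
all_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  out <- list()
  rec <- function(assign, next_label) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (lab in seq_len(next_label)) {
      rec(c(assign, lab), max(next_label, lab + 1))
    }
  }
  rec(integer(0), 1)
  .partition_cache[[key]] <- out
  out
}

# exhaustive maximum-modularity search; Q evaluated with igraph (independent
# of the package's own modularity code)
max_modularity_exhaustive <- function(g) {
  ig <- as_igraph(g)
  best_q <- -Inf
  best_mem <- NULL
  for (mem in all_set_partitions(length(g$nodes))) {
    q <- igraph::modularity(ig, mem)
    if (q > best_q) {
      best_q <- q
      best_mem <- mem
    }
  }
  list(q = best_q, membership = best_mem)
}

# independently coded Benjamini-Hochberg step-up (reference for bh_adjust)
bh_reference <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hypergeometric upper tail by enumeration of all C(N, n) draws:
# elements 1..K carry the term; returns P(#carriers in draw >= k)
hyper_enum <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  carriers <- colSums(draws <= K)
  mean(carriers >= k)
}

# membership vector of a disjoint partition aligned with g$nodes
mem_of <- function(g, p) {
  vapply(p$membership[g$nodes], `[[`, 0L, 1L)
}

# random disjoint partition of g's nodes into <= kmax parts
random_partition <- function(g, kmax, seed) {
  withr::with_seed(seed, {
    n <- length(g$nodes)
    k <- sample(1:min(kmax, n), 1)
    mem <- sample(1:k, n, replace = TRUE)
    mem <- match(mem, unique(mem))   # no empty parts
    new_partition(split(g$nodes, mem), g = g)
  })
}

# deterministic planted enrichment fixture: two clusters of 20 nodes; term
# TT on 15 nodes of cluster 1 and 1 node of cluster 2; a catch-all term CA
# keeps every node annotated
planted_fixture <- function() {
  sbm <- make_sbm(c(20, 20), p_in = 0.4, p_out = 0.05, seed = 33)
  g <- sbm$network
  p <- sbm$partition
  c1 <- p$clusters[["1"]]; c2 <- p$clusters[["2"]]
  node_terms <- setNames(rep(list("CA"), 40), c(c1, c2))
  for (v in c1[1:15]) node_terms[[v]] <- c("CA", "TT")
  node_terms[[c2[1]]] <- c("CA", "TT")
  a <- annotation_from_list(node_terms, g)
  list(g = g, p = p, a = a)
}

# build an annotation table directly from a node -> terms list
annotation_from_list <- function(node_terms, g) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  rows <- vapply(names(node_terms), function(v) {
    paste(v, paste(node_terms[[v]], collapse = ","), sep = "\t")
  }, "")
  writeLines(rows, tmp)
  read_annotations(tmp, parser_config(), g, quiet = TRUE)
}
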