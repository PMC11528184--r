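#' Stochastic block model generator with planted partition
#'
#' Every within-block node pair becomes an edge independently with
#' probability `p_in`, every between-block pair with probability `p_out`.
#' Nodes are named `b<block>n<index>` so the planted blocks are recoverable
#' by eye; isolated nodes are retained in the network.
#'
#' @param block_sizes integer vector of block sizes.
#' @param p_in,p_out within- and between-block edge probabilities in
#'   `[0, 1]`.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   output.
#' @return a list with `network` (an `mc_network`) and `partition` (the
#'   planted disjoint `mc_partition`).
#' @export
make_sbm <- function(block_sizes, p_in, p_out, seed) {
  mc_assert(all(block_sizes >= 1), "block sizes must be >= 1")
  mc_assert(p_in >= 0 && p_in <= 1 && p_out >= 0 && p_out <= 1,
            "probabilities must lie in [0, 1]")
  mc_assert(!missing(seed), "seed is required")
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  width <- max(2, nchar(as.character(max(block_sizes))))
  idx_in_block <- unlist(lapply(block_sizes, seq_len))
  nodes <- sprintf("b%02dn%0*d", block, width, idx_in_block)

  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  prob <- ifelse(block[pair_i] == block[pair_j], p_in, p_out)
  draw <- withr::with_seed(seed, stats::runif(length(prob)) < prob)

  g <- network_from_edges(nodes[pair_i[draw]], nodes[pair_j[draw]],
                          nodes = nodes, quiet = TRUE)
  p <- new_partition(split(nodes, block), g = g)
  list(network = g, partition = p)
}

#' Planted-annotation generator
#'
#' Every (node, term) pair is annotated independently at `background_rate`;
#' for planted (cluster, term, multiplier) triples the rate of that term is
#' multiplied for the nodes of that cluster (capped at 1 with a warning).
#' The annotated-node fraction is then adjusted to `coverage`: excess
#' annotated nodes are stripped at random, and missing ones receive a
#' catch-all term (`"T00"`) so the target is met exactly.
#'
#' @param g an `mc_network`.
#' @param p an `mc_partition` covering `g`.
#' @param n_terms number of terms (`"T01"`, `"T02"`, ...).
#' @param background_rate per-(node, term) annotation probability.
#' @param planted `NULL` or a data.frame with columns `cluster` (integer
#'   ID), `term` (e.g. `"T01"`) and `multiplier`.
#' @param coverage target fraction of annotated nodes in `(0, 1]`.
#' @param seed integer seed.
#' @return an `mc_annotation` over `g`.
#' @export
make_annotations <- function(g, p, n_terms, background_rate, planted = NULL,
                             coverage = 1, seed) {
  mc_assert(background_rate >= 0 && background_rate <= 1,
            "background_rate must lie in [0, 1]")
  mc_assert(coverage > 0 && coverage <= 1, "coverage must lie in (0, 1]")
  mc_assert(!missing(seed), "seed is required")
  terms <- sprintf("T%02d", seq_len(n_terms))
  n <- length(g$nodes)

  rate <- matrix(background_rate, nrow = n, ncol = n_terms,
                 dimnames = list(g$nodes, terms))
  if (!is.null(planted) && nrow(planted) > 0) {
    for (r in seq_len(nrow(planted))) {
      cid <- as.character(planted$cluster[r])
      mc_assert(cid %in% names(p$clusters), "unknown cluster: ", cid)
      tcol <- match(planted$term[r], terms)
      mc_assert(!is.na(tcol), "unknown term: ", planted$term[r])
      rate[p$clusters[[cid]], tcol] <-
        rate[p$clusters[[cid]], tcol] * planted$multiplier[r]
    }
    rate[is.nan(rate)] <- 1   # 0 * Inf: an infinite multiplier means rate 1
    if (any(rate > 1)) {
      warning("planted multiplier drove ", sum(rate > 1),
              " rate(s) above 1; capped")
      rate[rate > 1] <- 1
    }
  }

  withr::with_seed(seed, {
    hits <- matrix(stats::runif(n * n_terms), nrow = n) < rate
    node_terms <- lapply(seq_len(n), function(v) terms[hits[v, ]])
    names(node_terms) <- g$nodes

    target <- round(coverage * n)
    annotated <- which(lengths(node_terms) > 0)
    if (length(annotated) > target) {
      strip <- annotated[sample.int(length(annotated),
                                    length(annotated) - target)]
      node_terms[strip] <- replicate(length(strip), character(0),
                                     simplify = FALSE)
    } else if (length(annotated) < target) {
      bare <- setdiff(seq_len(n), annotated)
      fill <- bare[sample.int(length(bare), target - length(annotated))]
      node_terms[fill] <- lapply(fill, function(v) "T00")
    }
    node_terms <- node_terms[lengths(node_terms) > 0]
    new_annotation(lapply(node_terms, sort), g$nodes)
  })
}
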