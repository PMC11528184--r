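#' Iterated Transfer-Fusion (TFiT) partitioning
#'
#' Multi-level modularity optimization in the Louvain style.  Each level
#' starts from singleton clusters of the current (weighted) graph, sweeps the
#' vertices in a seeded-shuffled order moving each to its best adjacent
#' cluster while the weighted-modularity gain exceeds `tol`, and then
#' collapses the clusters into a weighted quotient graph (internal edges
#' become self-loop weights).  Levels repeat until a sweep makes no move;
#' assignments are composed back down to the original nodes.
#'
#' Because the sweep outcome depends on the vertex order, each level runs
#' `restarts` independent seeded shuffles and keeps the sweep with the best
#' modularity; this markedly reduces the chance of coarse local optima at
#' little cost.
#'
#' @inheritParams ft_partition
#' @param restarts sweep restarts per level (default 8).
#' @return a disjoint `mc_partition` with canonical cluster IDs; final
#'   modularity attached as attribute `Q`, number of levels as `levels`.
#' @export
tfit_partition <- function(g, seed = 42L, tol = 1e-12, allow_split = FALSE,
                           restarts = 8L) {
  mc_assert(length(g$nodes) > 0, "empty graph")
  mc_assert(g$m >= 1, "graph has no edges")
  mc_assert(restarts >= 1, "restarts must be >= 1")
  withr::with_seed(seed, {
    wg <- as_wgraph(g)
    mapping <- seq_len(wg$n)      # original node -> current meta-vertex
    levels <- 0L
    repeat {
      comm <- NULL
      best_q <- -Inf
      for (r in seq_len(restarts)) {
        cand <- transfer_sweeps(wg, seq_len(wg$n), order = sample(wg$n),
                                tol = tol, allow_split = allow_split)
        trace <- attr(cand, "q_trace")
        q_end <- trace[length(trace)]
        if (q_end > best_q + 1e-12) {
          best_q <- q_end
          comm <- cand
        }
      }
      if (attr(comm, "n_moves") == 0L) break
      levels <- levels + 1L
      comm <- compact_labels(as.integer(comm))
      mapping <- comm[mapping]
      if (max(comm) == wg$n) break   # no coarsening achieved
      wg <- collapse_wgraph(wg, comm)
    }
    p <- partition_from_membership(g$nodes, mapping)
    attr(p, "Q") <- modularity_q(g, p)
    attr(p, "levels") <- levels
    p
  })
}
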