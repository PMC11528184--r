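#' Fusion-Transfer (FT) partitioning
#'
#' Ascending hierarchical modularity optimization: starting from singleton
#' clusters, the cluster pair with the largest positive fusion gain is merged
#' (ties broken by the lexicographically smallest cluster-ID pair; the
#' merged cluster keeps the smaller ID), and after each fusion a
#' vertex-transfer refinement repeatedly moves each vertex to its best
#' adjacent cluster while the gain exceeds `tol`.  Fusions and transfers
#' alternate until neither changes the partition; interleaving the
#' refinement keeps the greedy agglomeration from locking in early
#' mis-merges.
#'
#' Because the refinement outcome depends on the sweep order, the whole
#' procedure is restarted `restarts` times from seeded shuffles and the
#' best-modularity result kept.
#'
#' @param g an `mc_network` with at least one edge.
#' @param seed integer seed controlling the vertex sweep order (results are
#'   deterministic for a given seed).
#' @param tol minimum gain for an accepted transfer.
#' @param allow_split also consider moving a vertex out into a new singleton
#'   cluster during refinement.
#' @param restarts seeded restarts of the fusion-transfer loop (default 5).
#' @return a disjoint `mc_partition` with canonical cluster IDs; the final
#'   modularity is attached as attribute `Q`.
#' @export
ft_partition <- function(g, seed = 42L, tol = 1e-12, allow_split = FALSE,
                         restarts = 5L) {
  mc_assert(restarts >= 1, "restarts must be >= 1")
  best <- NULL
  for (r in seq_len(restarts)) {
    p <- ft_once(g, seed = seed + 7919L * (r - 1L), tol = tol,
                 allow_split = allow_split)
    if (is.null(best) || attr(p, "Q") > attr(best, "Q") + 1e-12) best <- p
  }
  best
}

ft_once <- function(g, seed, tol, allow_split) {
  mc_assert(length(g$nodes) > 0, "empty graph")
  mc_assert(g$m >= 1, "graph has no edges")
  wg <- as_wgraph(g)
  comm <- seq_along(g$nodes)
  withr::with_seed(seed, {
    repeat {
      state <- mod_state(
        g, partition_from_membership(g$nodes, compact_labels(comm),
                                     relabel = FALSE))
      best <- find_best_merge(state)
      merged <- !is.null(best) && best$dq > 0
      if (merged) {
        state <- state_merge(state, best$a, best$b)
        comm <- compact_labels(state$comm)
      }
      comm2 <- transfer_sweeps(wg, comm, order = sample(wg$n), tol = tol,
                               allow_split = allow_split)
      transferred <- attr(comm2, "n_moves") > 0L
      comm <- compact_labels(as.integer(comm2))
      if (!merged && !transferred) break
    }
  })
  p <- partition_from_membership(g$nodes, comm)
  attr(p, "Q") <- modularity_q(g, p)
  p
}

# scan all linked cluster pairs for the maximum fusion gain;
# ties -> smallest (a, b) pair
find_best_merge <- function(state) {
  best <- NULL
  for (a in which(state$active)) {
    nbs <- as.integer(names(state$l[[a]]))
    nbs <- nbs[nbs > a]
    for (b in sort(nbs)) {
      dq <- delta_q_merge(state, a, b)
      if (is.null(best) || dq > best$dq + 1e-15) {
        best <- list(a = a, b = b, dq = dq)
      }
    }
  }
  best
}

compact_labels <- function(comm) {
  match(comm, sort(unique(comm)))
}
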