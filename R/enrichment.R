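#' One-sided hypergeometric upper tail
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' uniform draw of `n` nodes from a background of `N` nodes, `K` of which
#' carry the term, contains at least `k` carriers.  Computed with
#' [stats::phyper()].
#'
#' @param k observed carriers in the draw (cluster).
#' @param n draw size (cluster size within the background).
#' @param K carriers in the background.
#' @param N background size.
#' @return the upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  mc_assert(all(c(k, n, K, N) >= 0), "counts must be nonnegative")
  mc_assert(n <= N, "n must not exceed N")
  mc_assert(K <= N, "K must not exceed N")
  mc_assert(k <= min(n, K), "k must not exceed min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]); adjusted
#' values are capped at 1 and returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  mc_assert(all(p_values >= 0 & p_values <= 1, na.rm = FALSE),
            "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Majority rule on an enrichment record
#'
#' A term passes when it annotates at least `threshold_percent` percent of
#' the annotated nodes of the cluster (boundary inclusive).
#'
#' @param record a one-row data.frame (or list) with a `majority_percent`
#'   field.
#' @param threshold_percent threshold in `[0, 100]` (default 50).
#' @return logical.
#' @export
majority_pass <- function(record, threshold_percent = 50) {
  mc_assert(threshold_percent >= 0 && threshold_percent <= 100,
            "threshold must be in [0, 100]")
  record$majority_percent >= threshold_percent
}

#' Per-cluster annotation enrichment
#'
#' Tests every (cluster, term) pair with `k >= 1`, for clusters with at
#' least `min_cluster_size` nodes, using the one-sided hypergeometric test
#' against the whole-graph background, and applies a single
#' Benjamini-Hochberg correction across all emitted records (or one per
#' cluster with `bh_scope = "per-cluster"`).  With the default
#' `background = "annotated"` the background is the annotated nodes of the
#' graph (`N` = annotated nodes, `n` = annotated nodes of the cluster);
#' `background = "all-nodes"` uses every node instead.  For overlapping
#' partitions a shared node contributes to the counts of every cluster
#' containing it, while the background counts are computed once on the
#' graph.
#'
#' @param g an `mc_network`.
#' @param p a complete `mc_partition` of `g`.
#' @param a an `mc_annotation` matched to `g`.
#' @param alpha adjusted-p threshold for the `enriched` flag (strict `<`,
#'   default 0.05).
#' @param majority_threshold majority-rule threshold in percent (default
#'   50, boundary inclusive).
#' @param min_cluster_size smallest cluster tested (default 5; set 1 to
#'   test all).
#' @param background `"annotated"` (default) or `"all-nodes"`.
#' @param bh_scope `"global"` (default) or `"per-cluster"`.
#' @return a data.frame of class `mc_enrichment`, one row per tested
#'   (cluster, term): columns `cluster`, `term`, `k`, `n_annotated`,
#'   `n_nodes`, `K`, `N`, `p_raw`, `p_adj`, `cluster_percent`,
#'   `majority_percent`, `enriched`, `majority_pass`.  The analysis
#'   parameters and the retained cluster IDs are carried as attributes.
#' @export
enrich_all_clusters <- function(g, p, a, alpha = 0.05,
                                majority_threshold = 50,
                                min_cluster_size = 5L,
                                background = c("annotated", "all-nodes"),
                                bh_scope = c("global", "per-cluster")) {
  background <- match.arg(background)
  bh_scope <- match.arg(bh_scope)
  annotated <- names(a$node_terms)
  mc_assert(length(annotated) > 0, "no annotated nodes")

  N <- if (background == "annotated") length(annotated) else length(g$nodes)
  K_map <- lengths(a$term_nodes)

  retained <- names(p$clusters)[lengths(p$clusters) >= min_cluster_size]
  rows <- vector("list", length(retained))
  for (i in seq_along(retained)) {
    cid <- retained[[i]]
    members <- p$clusters[[cid]]
    ann_members <- intersect(members, annotated)
    if (length(ann_members) == 0) next
    terms <- sort(unique(unlist(a$node_terms[ann_members],
                                use.names = FALSE)))
    k <- vapply(terms, function(t) {
      sum(members %in% a$term_nodes[[t]])
    }, 0L)
    n_draw <- if (background == "annotated") length(ann_members)
              else length(members)
    rows[[i]] <- data.frame(
      cluster = as.integer(cid),
      term = terms,
      k = as.integer(k),
      n_annotated = length(ann_members),
      n_nodes = length(members),
      K = as.integer(K_map[terms]),
      N = N,
      p_raw = vapply(seq_along(terms), function(t) {
        hypergeom_upper_tail(k[t], n_draw, K_map[[terms[t]]], N)
      }, 0),
      row.names = NULL
    )
  }
  rec <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rec)) {
    rec <- data.frame(cluster = integer(0), term = character(0),
                      k = integer(0), n_annotated = integer(0),
                      n_nodes = integer(0), K = integer(0), N = integer(0),
                      p_raw = numeric(0))
  }
  rec$p_adj <- if (nrow(rec) == 0) numeric(0)
    else if (bh_scope == "global") bh_adjust(rec$p_raw)
    else stats::ave(rec$p_raw, rec$cluster, FUN = bh_adjust)
  rec$cluster_percent <- if (nrow(rec)) 100 * rec$k / rec$n_nodes else numeric(0)
  rec$majority_percent <- if (nrow(rec)) 100 * rec$k / rec$n_annotated
    else numeric(0)
  rec$enriched <- rec$p_adj < alpha
  rec$majority_pass <- rec$majority_percent >= majority_threshold
  rec <- rec[order(rec$cluster, rec$p_adj, rec$term), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec,
            class = c("mc_enrichment", "data.frame"),
            alpha = alpha,
            majority_threshold = majority_threshold,
            min_cluster_size = min_cluster_size,
            background = background,
            bh_scope = bh_scope,
            retained_clusters = as.integer(retained))
}
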