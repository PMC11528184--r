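#' Cluster list table
#'
#' One row per retained cluster (clusters meeting the analysis'
#' `min_cluster_size`): number of nodes, number of annotated nodes, number
#' of distinct terms appearing in the cluster, number of hypergeometric
#' enrichments, number of majority-rule passes, the enriched term IDs and
#' any manual annotations (see [add_custom_annotation()]).
#'
#' @param records an `mc_enrichment` from [enrich_all_clusters()].
#' @param p the `mc_partition` the records were computed on.
#' @param a the `mc_annotation` used.
#' @return a data.frame with columns `cluster`, `n_nodes`, `n_annotated`,
#'   `n_terms`, `n_enriched`, `n_majority`, `enriched_terms`,
#'   `custom_annotations`.
#' @export
cluster_list_table <- function(records, p, a) {
  retained <- attr(records, "retained_clusters")
  if (is.null(retained)) retained <- sort(unique(records$cluster))
  custom <- attr(p, "custom_annotations")
  annotated <- names(a$node_terms)
  rows <- lapply(retained, function(cid) {
    sub <- records[records$cluster == cid, , drop = FALSE]
    members <- p$clusters[[as.character(cid)]]
    enr <- sub$term[sub$enriched]
    data.frame(
      cluster = cid,
      n_nodes = length(members),
      n_annotated = length(intersect(members, annotated)),
      n_terms = nrow(sub),
      n_enriched = sum(sub$enriched),
      n_majority = sum(sub$majority_pass),
      enriched_terms = paste(sort(enr), collapse = ","),
      custom_annotations = paste(custom[[as.character(cid)]],
                                 collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster analysis table
#'
#' All terms annotating one cluster, sorted by ascending adjusted p-value
#' (ties by term ID): the carrier count `k`, the percentage of cluster
#' nodes carrying the term, the raw and adjusted hypergeometric p-values,
#' the percentage among annotated cluster nodes, and the enrichment /
#' majority flags.
#'
#' @inheritParams cluster_list_table
#' @param cluster_id integer cluster ID; must be a retained cluster.
#' @return a data.frame (possibly empty when the cluster has no annotated
#'   node).
#' @export
cluster_analysis_table <- function(records, cluster_id) {
  retained <- attr(records, "retained_clusters")
  known <- if (!is.null(retained)) cluster_id %in% retained
           else cluster_id %in% records$cluster
  mc_assert(known, "unknown cluster: ", cluster_id)
  sub <- records[records$cluster == cluster_id, , drop = FALSE]
  sub <- sub[order(sub$p_adj, sub$term), , drop = FALSE]
  rownames(sub) <- NULL
  cols <- c("cluster", "term", "k", "cluster_percent", "p_raw", "p_adj",
            "majority_percent", "enriched", "majority_pass")
  as.data.frame(sub)[, cols, drop = FALSE]
}

#' Annotation term analysis table
#'
#' One row per cluster containing the term, with the same columns as
#' [cluster_analysis_table()].  An unknown term yields an empty table.
#'
#' @inheritParams cluster_list_table
#' @param term term ID.
#' @return a data.frame.
#' @export
term_analysis_table <- function(records, term) {
  sub <- records[records$term == term, , drop = FALSE]
  sub <- sub[order(sub$p_adj, sub$cluster), , drop = FALSE]
  rownames(sub) <- NULL
  cols <- c("cluster", "term", "k", "cluster_percent", "p_raw", "p_adj",
            "majority_percent", "enriched", "majority_pass")
  as.data.frame(sub)[, cols, drop = FALSE]
}

#' Node list table
#'
#' Per-node detail: cluster membership(s) and annotation terms, with a
#' `carries_term` flag marking the nodes annotated to a term of interest.
#'
#' @param p an `mc_partition`.
#' @param a an `mc_annotation`.
#' @param highlight_term optional term ID to flag.
#' @return a data.frame with columns `node`, `clusters`, `terms`,
#'   `carries_term`.
#' @export
node_list_table <- function(p, a, highlight_term = NULL) {
  nodes <- sort(names(p$membership))
  terms <- vapply(nodes, function(v) {
    ts <- a$node_terms[[v]]
    if (is.null(ts)) "" else paste(ts, collapse = ",")
  }, "")
  carriers <- if (is.null(highlight_term)) rep(FALSE, length(nodes))
    else nodes %in% a$term_nodes[[highlight_term]]
  data.frame(
    node = nodes,
    clusters = vapply(nodes, function(v) {
      paste(sort(p$membership[[v]]), collapse = ",")
    }, ""),
    terms = terms,
    carries_term = carriers,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Cluster-by-term annotation count matrix
#'
#' Dense matrix of carrier counts `k`: rows are retained clusters, columns
#' the terms appearing in the records.
#'
#' @inheritParams cluster_list_table
#' @return an integer matrix with cluster IDs as row names and term IDs as
#'   column names.
#' @export
annotation_matrix <- function(records, p, a) {
  retained <- attr(records, "retained_clusters")
  if (is.null(retained)) retained <- sort(unique(records$cluster))
  terms <- sort(unique(records$term))
  mat <- matrix(0L, nrow = length(retained), ncol = length(terms),
                dimnames = list(as.character(retained), terms))
  if (nrow(records) > 0) {
    mat[cbind(match(records$cluster, retained),
              match(records$term, terms))] <- as.integer(records$k)
  }
  mat
}

#' Add a manual annotation label to a cluster
#'
#' Manual labels are bookkeeping only: they appear in the
#' `custom_annotations` column of [cluster_list_table()] and are excluded
#' from all statistics.  Adding the same label twice is a no-op.
#'
#' @param p an `mc_partition`.
#' @param cluster_id integer cluster ID present in `p`.
#' @param label character label.
#' @return the partition with the label attached.
#' @export
add_custom_annotation <- function(p, cluster_id, label) {
  key <- as.character(cluster_id)
  mc_assert(key %in% names(p$clusters), "unknown cluster: ", cluster_id)
  custom <- attr(p, "custom_annotations")
  if (is.null(custom)) custom <- list()
  custom[[key]] <- sort(unique(c(custom[[key]], label)))
  attr(p, "custom_annotations") <- custom
  p
}

#' Remove manual annotation labels from a cluster
#'
#' @param p an `mc_partition`.
#' @param cluster_id integer cluster ID present in `p`.
#' @param label specific label to remove; all of the cluster's labels when
#'   `NULL`.
#' @return the partition with the label(s) removed.
#' @export
remove_custom_annotation <- function(p, cluster_id, label = NULL) {
  key <- as.character(cluster_id)
  mc_assert(key %in% names(p$clusters), "unknown cluster: ", cluster_id)
  custom <- attr(p, "custom_annotations")
  if (is.null(custom)) return(p)
  if (is.null(label)) {
    custom[[key]] <- NULL
  } else {
    custom[[key]] <- setdiff(custom[[key]], label)
    if (length(custom[[key]]) == 0) custom[[key]] <- NULL
  }
  if (length(custom) == 0) custom <- NULL
  attr(p, "custom_annotations") <- custom
  p
}

#' Write a table (or matrix) as TSV
#'
#' @param x a data.frame or matrix.
#' @param path output path.
#' @param matrix_corner header for the row-name column when `x` is a
#'   matrix.
#' @export
write_tsv_table <- function(x, path, matrix_corner = "cluster") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- matrix_corner
    x <- df
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
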