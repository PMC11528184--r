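#' Construct a partition (cover) of a network's node set
#'
#' A partition maps integer cluster IDs to member node sets.  Clusters may
#' overlap (a node in several clusters); the cover must be complete when a
#' network is supplied.
#'
#' @param clusters list of character vectors of node IDs; names (if any) are
#'   ignored — IDs are reassigned canonically: consecutive integers from 1 by
#'   decreasing cluster size, ties by lexicographically smallest member.
#' @param g optional `mc_network`; when given, the cover is validated against
#'   its node set.
#' @param relabel reassign canonical cluster IDs (default `TRUE`).
#' @return an object of class `mc_partition`: list with `clusters` (named
#'   list `"1"`, `"2"`, ... of sorted member vectors), `membership` (named
#'   list node -> integer vector of cluster IDs) and `overlapping` (logical).
#' @export
new_partition <- function(clusters, g = NULL, relabel = TRUE) {
  clusters <- lapply(clusters, function(x) sort(unique(as.character(x))))
  mc_assert(all(lengths(clusters) > 0), "empty cluster in partition")
  if (relabel) {
    first_member <- vapply(clusters, `[[`, "", 1L)
    ord <- order(-lengths(clusters), first_member)
    clusters <- clusters[ord]
  }
  names(clusters) <- as.character(seq_along(clusters))

  all_nodes <- sort(unique(unlist(clusters, use.names = FALSE)))
  if (!is.null(g)) {
    stopifnot(inherits(g, "mc_network"))
    extra <- setdiff(all_nodes, g$nodes)
    if (length(extra) > 0) {
      mc_stop_input("partition node(s) not in graph: ",
                    paste(head(extra, 20), collapse = ", "))
    }
    missing <- setdiff(g$nodes, all_nodes)
    if (length(missing) > 0) {
      mc_stop_input("uncovered nodes: ",
                    paste(head(missing, 20), collapse = ", "),
                    if (length(missing) > 20) paste0(" (and ",
                      length(missing) - 20, " more)") else "")
    }
  }

  membership <- vector("list", length(all_nodes))
  names(membership) <- all_nodes
  for (cid in seq_along(clusters)) {
    for (v in clusters[[cid]]) membership[[v]] <- c(membership[[v]], cid)
  }
  structure(
    list(
      clusters = clusters,
      membership = membership,
      overlapping = any(lengths(membership) > 1)
    ),
    class = "mc_partition"
  )
}

#' @export
print.mc_partition <- function(x, ...) {
  cat("mc_partition: ", length(x$clusters), " cluster(s) over ",
      length(x$membership), " node(s)",
      if (x$overlapping) " (overlapping)" else "", "\n", sep = "")
  invisible(x)
}

#' Number of clusters in a partition
#' @param p an `mc_partition`.
#' @return integer count.
#' @export
n_clusters <- function(p) length(p$clusters)

# membership as an integer vector aligned with g$nodes (disjoint partitions)
membership_vector <- function(g, p) {
  stopifnot(!p$overlapping)
  mem <- vapply(p$membership[g$nodes], `[[`, 0L, 1L)
  unname(mem)
}

partition_from_membership <- function(nodes, mem, relabel = TRUE) {
  new_partition(split(nodes, mem), relabel = relabel)
}

#' Read a partition from a two-column node/cluster file
#'
#' Each line holds `node<TAB>cluster`; repeated node IDs express multiple
#' membership (overlap).  The file must cover every node of `g`.
#'
#' @param path path to the file.
#' @param g the `mc_network` the partition refers to.
#' @param column_separator field separator (default tab).
#' @return an `mc_partition` (cluster IDs relabelled canonically only if the
#'   file's labels are not already consecutive integers; file labels are kept
#'   as written otherwise).
#' @export
import_partition <- function(path, g, column_separator = "\t") {
  mc_assert(file.exists(path), "partition file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  mc_assert(length(lines) > 0, "no records in partition file ", path)
  parts <- strsplit(lines, column_separator, fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    mc_stop_input("line ", bad[1], " of ", path, " has fewer than 2 fields")
  }
  node <- trimws(vapply(parts, `[[`, "", 1L))
  clus <- trimws(vapply(parts, `[[`, "", 2L))

  unknown <- setdiff(unique(node), g$nodes)
  if (length(unknown) > 0) {
    mc_stop_input("partition node(s) not in graph: ",
                  paste(head(unknown, 20), collapse = ", "))
  }
  p <- new_partition(split(node, clus), g = g, relabel = TRUE)
  p
}

#' Write a partition as a two-column node/cluster TSV
#'
#' One membership per line; round-trips through [import_partition()].
#'
#' @param p an `mc_partition`.
#' @param path output path.
#' @export
write_partition <- function(p, path) {
  rows <- unlist(lapply(names(p$clusters), function(cid) {
    paste(p$clusters[[cid]], cid, sep = "\t")
  }))
  writeLines(rows, path)
  invisible(path)
}
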