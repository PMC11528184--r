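#' Build a normalized undirected network from endpoint vectors
#'
#' Nodes are opaque, case-sensitive strings (surrounding whitespace trimmed).
#' Normalization drops self-loops and collapses duplicate edges (including
#' reversed duplicates); the numbers dropped are kept in the `dropped`
#' attribute and reported via `message()`.
#'
#' @param from,to character vectors of equal length: edge endpoints.
#' @param nodes optional character vector of node IDs to force into the node
#'   set even when isolated (used e.g. by the SBM generator).
#' @param quiet suppress the dropped-record message.
#' @return an object of class `mc_network`: a list with elements `nodes`
#'   (sorted character vector), `adj` (adjacency list of integer indices into
#'   `nodes`), `degree` (integer vector), `m` (edge count) and `edges`
#'   (m x 2 integer matrix, each row i < j).
#' @export
network_from_edges <- function(from, to, nodes = NULL, quiet = FALSE) {
  stopifnot(length(from) == length(to))
  from <- trimws(as.character(from))
  to <- trimws(as.character(to))
  keep <- nzchar(from) & nzchar(to)
  from <- from[keep]; to <- to[keep]

  n_loops <- sum(from == to)
  ok <- from != to
  from <- from[ok]; to <- to[ok]

  node_ids <- sort(unique(c(from, to, as.character(nodes))))
  i <- match(from, node_ids)
  j <- match(to, node_ids)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * length(node_ids) + hi
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]

  ord <- order(lo, hi)
  edges <- cbind(lo[ord], hi[ord])
  g <- structure(
    list(
      nodes = node_ids,
      adj = build_adj(edges, length(node_ids)),
      degree = NULL,
      m = nrow(edges),
      edges = edges
    ),
    class = "mc_network"
  )
  g$degree <- lengths(g$adj)
  attr(g, "dropped") <- c(self_loops = n_loops, duplicates = n_dup)
  if (!quiet && (n_loops > 0 || n_dup > 0)) {
    message("network normalization dropped ", n_loops, " self-loop(s) and ",
            n_dup, " duplicate edge(s)")
  }
  g
}

build_adj <- function(edges, n) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    end1 <- split(edges[, 2], factor(edges[, 1], levels = seq_len(n)))
    end2 <- split(edges[, 1], factor(edges[, 2], levels = seq_len(n)))
    adj <- mapply(function(a, b) sort(c(a, b)), end1, end2, SIMPLIFY = FALSE)
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }
  unname(adj)
}

#' @export
print.mc_network <- function(x, ...) {
  cat("mc_network: ", length(x$nodes), " nodes, ", x$m, " edges\n", sep = "")
  invisible(x)
}

#' Read an undirected network from an edge-list text file
#'
#' The first two columns of each line are the edge endpoints; extra columns
#' are ignored.  With `format = "sif"` three-column lines are read as
#' `node1 <interaction-type> node2` and the middle column is ignored.
#' Lines starting with `#` are skipped.  The result is normalized as in
#' [network_from_edges()].
#'
#' @param path path to the file.
#' @param column_separator `"\t"` (default), `" "`, `","`, `";"`, or
#'   `"whitespace"` to split on any run of blanks/tabs.
#' @param skip_header number of leading lines to skip.
#' @param format `"edgelist"` (default) or `"sif"`.
#' @param quiet suppress the dropped-record message.
#' @return an `mc_network`.
#' @export
read_edge_list <- function(path, column_separator = "\t", skip_header = 0L,
                           format = c("edgelist", "sif"), quiet = FALSE) {
  format <- match.arg(format)
  mc_assert(file.exists(path), "network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (skip_header > 0) lines <- lines[-seq_len(min(skip_header, length(lines)))]
  lineno <- seq_along(lines) + skip_header
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  mc_assert(length(lines) > 0, "no edge records in ", path)

  parts <- if (identical(column_separator, "whitespace")) {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    strsplit(lines, column_separator, fixed = TRUE)
  }
  nf <- lengths(parts)
  bad <- which(nf < 2)
  if (length(bad) > 0) {
    mc_stop_input("line ", lineno[bad[1]], " of ", path,
                  " has fewer than 2 fields")
  }
  from <- vapply(parts, `[[`, "", 1L)
  to_col <- if (format == "sif") 3L else 2L
  if (format == "sif") {
    bad <- which(nf < 3)
    if (length(bad) > 0) {
      mc_stop_input("line ", lineno[bad[1]], " of ", path,
                    " has fewer than 3 fields (SIF)")
    }
  }
  to <- vapply(parts, `[[`, "", to_col)
  network_from_edges(from, to, quiet = quiet)
}

#' Extract the largest connected component
#'
#' Ties between equally sized components are broken by taking the component
#' containing the lexicographically smallest node ID.
#'
#' @param g an `mc_network`.
#' @return the induced `mc_network` on the largest component.
#' @export
largest_connected_component <- function(g) {
  stopifnot(inherits(g, "mc_network"))
  mc_assert(length(g$nodes) > 0, "empty graph")
  comp <- igraph::components(as_igraph(g))
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # tie-break: component whose smallest member ID sorts first
    first_member <- vapply(best, function(b) {
      min(g$nodes[comp$membership == b])
    }, "")
    best <- best[order(first_member)][1]
  }
  induced_network(g, g$nodes[comp$membership == best])
}

#' @keywords internal
induced_network <- function(g, members) {
  idx <- match(members, g$nodes)
  keep <- g$edges[, 1] %in% idx & g$edges[, 2] %in% idx
  e <- g$edges[keep, , drop = FALSE]
  network_from_edges(g$nodes[e[, 1]], g$nodes[e[, 2]],
                     nodes = members, quiet = TRUE)
}

#' Convert an mc_network to an igraph object
#'
#' Vertex order follows `g$nodes`; the vertex attribute `name` carries IDs.
#' @param g an `mc_network`.
#' @return an igraph graph.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (g$m > 0) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

#' Topological summary of a node subset
#'
#' @param g an `mc_network`.
#' @param members character vector of node IDs, all present in `g`.
#' @return a list with `n_nodes`, `n_edges` (edges with both endpoints in
#'   `members`) and `density` (`2 e / (n (n-1))`; 0 by convention for n <= 1).
#' @export
cluster_stats <- function(g, members) {
  idx <- match(members, g$nodes)
  if (anyNA(idx)) {
    mc_stop_input("node(s) not in graph: ",
                  paste(members[is.na(idx)], collapse = ", "))
  }
  idx <- unique(idx)
  n <- length(idx)
  e <- count_internal_edges(g, idx)
  list(
    n_nodes = n,
    n_edges = e,
    density = if (n >= 2) 2 * e / (n * (n - 1)) else 0
  )
}

count_internal_edges <- function(g, idx) {
  if (g$m == 0 || length(idx) < 2) return(0L)
  inset <- logical(length(g$nodes))
  inset[idx] <- TRUE
  sum(inset[g$edges[, 1]] & inset[g$edges[, 2]])
}
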