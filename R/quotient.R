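#' Build the quotient (metanode) graph of a partition
#'
#' Each cluster becomes a metanode whose `size` is its node count.  Two edge
#' semantics summarize the connectivity between clusters:
#' \itemize{
#'   \item inter-cluster edges, weighted by the number of graph edges whose
#'     one endpoint belongs to cluster A but not B and whose other endpoint
#'     belongs to B but not A;
#'   \item overlap edges (overlapping partitions only), weighted by the
#'     number of nodes shared by the two clusters.
#' }
#' An edge whose endpoints are both members of clusters A and B counts as
#' internal to both A and B and toward no inter-cluster weight, so the same
#' adjacency is never reported both as a shared node and as a link.
#'
#' @param g an `mc_network`.
#' @param p a complete `mc_partition` of `g`.
#' @return an object of class `mc_quotient`: list with `sizes` (named
#'   integer, metanode sizes), `internal` (named integer, within-cluster
#'   edge counts), `inter` (data.frame `a`, `b`, `weight`) and `overlap`
#'   (data.frame `a`, `b`, `weight`; empty for disjoint partitions).
#' @export
build_quotient <- function(g, p) {
  missing <- setdiff(g$nodes, names(p$membership))
  if (length(missing) > 0) {
    mc_stop_input("uncovered nodes: ", paste(head(missing, 20),
                                             collapse = ", "))
  }
  K <- length(p$clusters)
  sizes <- lengths(p$clusters)
  internal <- integer(K)
  names(internal) <- names(p$clusters)

  inter <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(g$m)) {
    mu <- p$membership[[g$nodes[g$edges[r, 1]]]]
    mv <- p$membership[[g$nodes[g$edges[r, 2]]]]
    both <- intersect(mu, mv)
    internal[both] <- internal[both] + 1L
    for (a in setdiff(mu, mv)) {
      for (b in setdiff(mv, mu)) {
        key <- paste0(min(a, b), ".", max(a, b))
        inter[[key]] <- (if (is.null(inter[[key]])) 0L else inter[[key]]) + 1L
      }
    }
  }
  inter_df <- env_to_pairs(inter)

  overlap_df <- data.frame(a = integer(0), b = integer(0),
                           weight = integer(0))
  if (p$overlapping) {
    ov <- new.env(hash = TRUE, parent = emptyenv())
    for (mem in p$membership) {
      if (length(mem) > 1) {
        cmb <- utils::combn(sort(mem), 2)
        for (t in seq_len(ncol(cmb))) {
          key <- paste0(cmb[1, t], ".", cmb[2, t])
          ov[[key]] <- (if (is.null(ov[[key]])) 0L else ov[[key]]) + 1L
        }
      }
    }
    overlap_df <- env_to_pairs(ov)
  }

  structure(
    list(sizes = sizes, internal = internal, inter = inter_df,
         overlap = overlap_df),
    class = "mc_quotient"
  )
}

env_to_pairs <- function(e) {
  keys <- ls(e)
  if (length(keys) == 0) {
    return(data.frame(a = integer(0), b = integer(0), weight = integer(0)))
  }
  ab <- do.call(rbind, strsplit(keys, ".", fixed = TRUE))
  df <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                   weight = vapply(keys, function(k) as.integer(e[[k]]), 0L))
  rownames(df) <- NULL
  df[order(df$a, df$b), , drop = FALSE]
}

#' @export
print.mc_quotient <- function(x, ...) {
  cat("mc_quotient: ", length(x$sizes), " metanode(s), ",
      nrow(x$inter), " inter edge(s), ", nrow(x$overlap),
      " overlap edge(s)\n", sep = "")
  invisible(x)
}

#' Export a quotient graph to GraphML or DOT
#'
#' Metanodes carry attributes `size` (node count) and `internal`
#' (within-cluster edge count); edges carry `weight` and
#' `type` (`"inter"` or `"overlap"`).  GraphML files written here round-trip
#' through [read_quotient_graphml()].
#'
#' @param q an `mc_quotient`.
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_quotient <- function(q, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  ids <- names(q$sizes)
  ig <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = ids)
  ig <- igraph::set_vertex_attr(ig, "size", value = as.numeric(q$sizes))
  ig <- igraph::set_vertex_attr(ig, "internal",
                                value = as.numeric(q$internal))
  edf <- rbind(
    if (nrow(q$inter) > 0) cbind(q$inter, type = "inter"),
    if (nrow(q$overlap) > 0) cbind(q$overlap, type = "overlap")
  )
  if (!is.null(edf) && nrow(edf) > 0) {
    ends <- rbind(match(as.character(edf$a), ids),
                  match(as.character(edf$b), ids))
    ig <- igraph::add_edges(ig, as.vector(ends))
    ig <- igraph::set_edge_attr(ig, "weight", value = as.numeric(edf$weight))
    ig <- igraph::set_edge_attr(ig, "type", value = edf$type)
  }
  ok <- tryCatch({
    igraph::write_graph(ig, path, format = format)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) mc_stop_input("cannot write ", path, ": ",
                                 conditionMessage(ok))
  invisible(path)
}

#' Read back a GraphML quotient export
#'
#' @param path a GraphML file written by [export_quotient()].
#' @return an `mc_quotient`.
#' @export
read_quotient_graphml <- function(path) {
  mc_assert(file.exists(path), "file not found: ", path)
  ig <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::vertex_attr(ig, "name")
  sizes <- as.integer(igraph::vertex_attr(ig, "size"))
  internal <- as.integer(igraph::vertex_attr(ig, "internal"))
  names(sizes) <- ids
  names(internal) <- ids
  ord <- order(as.integer(ids))
  sizes <- sizes[ord]; internal <- internal[ord]

  el <- igraph::as_edgelist(ig)
  empty <- data.frame(a = integer(0), b = integer(0), weight = integer(0))
  inter <- empty; overlap <- empty
  if (nrow(el) > 0) {
    w <- as.integer(igraph::edge_attr(ig, "weight"))
    ty <- igraph::edge_attr(ig, "type")
    a <- pmin(as.integer(el[, 1]), as.integer(el[, 2]))
    b <- pmax(as.integer(el[, 1]), as.integer(el[, 2]))
    df <- data.frame(a = a, b = b, weight = w)
    inter <- df[ty == "inter", , drop = FALSE]
    inter <- inter[order(inter$a, inter$b), , drop = FALSE]
    rownames(inter) <- NULL
    overlap <- df[ty == "overlap", , drop = FALSE]
    overlap <- overlap[order(overlap$a, overlap$b), , drop = FALSE]
    rownames(overlap) <- NULL
  }
  structure(
    list(sizes = sizes, internal = internal, inter = inter,
         overlap = overlap),
    class = "mc_quotient"
  )
}
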