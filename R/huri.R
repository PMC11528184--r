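#' End-to-end summary of a deposited interactome + annotation pair
#'
#' Convenience driver for reproducing a published workflow from its
#' deposited files: reads an edge-list network, takes the largest connected
#' component, partitions it with [tfit_partition()], and matches an
#' annotation file against it.
#'
#' @param network_path edge-list file (tab-separated by default).
#' @param annotation_path annotation file.
#' @param cfg [parser_config()] describing the annotation dialect (default:
#'   tab-separated columns, comma-separated terms).
#' @param seed seed passed to the clustering.
#' @param column_separator separator of the network file (`"whitespace"`
#'   splits on runs of blanks/tabs).
#' @return list with `n_nodes`, `n_edges`, `coverage_count`,
#'   `coverage_percent`, `n_clusters`, `n_clusters_gt4` and the `partition`.
#' @export
huri_reproduction <- function(network_path, annotation_path,
                              cfg = parser_config(),
                              seed = 42L, column_separator = "whitespace") {
  g <- read_edge_list(network_path, column_separator = column_separator,
                      quiet = TRUE)
  g <- largest_connected_component(g)
  p <- tfit_partition(g, seed = seed)
  a <- read_annotations(annotation_path, cfg, g, quiet = TRUE)
  cov <- coverage(a)
  list(
    n_nodes = length(g$nodes),
    n_edges = g$m,
    coverage_count = cov$count,
    coverage_percent = cov$percent,
    n_clusters = n_clusters(p),
    n_clusters_gt4 = sum(lengths(p$clusters) > 4),
    partition = p
  )
}
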