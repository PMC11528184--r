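#' Parser configuration for annotation files
#'
#' Annotation files are plain text with at least two columns: a node ID
#' column and a term-list column.  Column and term separators are each one
#' of comma, semicolon or tab and must differ.
#'
#' @param node_column,term_column 1-based column indices.
#' @param column_separator,term_separator `","`, `";"` or `"\t"`; must
#'   differ.
#' @param skip_lines number of leading header lines to skip.
#' @return an object of class `mc_parser_config`.
#' @export
parser_config <- function(node_column = 1L, term_column = 2L,
                          column_separator = "\t", term_separator = ",",
                          skip_lines = 0L) {
  seps <- c(",", ";", "\t")
  mc_assert(column_separator %in% seps,
            "column_separator must be comma, semicolon or tab")
  mc_assert(term_separator %in% seps,
            "term_separator must be comma, semicolon or tab")
  mc_assert(!identical(column_separator, term_separator),
            "column separator and term separator must differ")
  mc_assert(node_column >= 1 && term_column >= 1,
            "column indices are 1-based")
  mc_assert(skip_lines >= 0, "skip_lines must be >= 0")
  structure(
    list(node_column = as.integer(node_column),
         term_column = as.integer(term_column),
         column_separator = column_separator,
         term_separator = term_separator,
         skip_lines = as.integer(skip_lines)),
    class = "mc_parser_config"
  )
}

#' Read node annotations and match them to a network
#'
#' Terms are split on the term separator, whitespace-trimmed, and empty
#' strings dropped.  Multiple lines for the same node union their term
#' sets.  Annotations for IDs absent from the network are dropped (their
#' count is reported via `message()`).
#'
#' @param path path to the annotation file.
#' @param cfg an [parser_config()] object.
#' @param g the `mc_network` providing the node universe.
#' @param quiet suppress the unmatched-ID message.
#' @return an object of class `mc_annotation`: list with `node_terms`
#'   (named list node -> sorted character vector of terms; one entry per
#'   annotated network node), `term_nodes` (the inverse mapping) and
#'   `universe` (the network's node vector).
#' @export
read_annotations <- function(path, cfg, g, quiet = FALSE) {
  stopifnot(inherits(cfg, "mc_parser_config"))
  mc_assert(file.exists(path), "annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (cfg$skip_lines > 0) {
    lines <- lines[-seq_len(min(cfg$skip_lines, length(lines)))]
  }
  lineno <- seq_along(lines) + cfg$skip_lines
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]

  parts <- strsplit(lines, cfg$column_separator, fixed = TRUE)
  need <- max(cfg$node_column, cfg$term_column)
  bad <- which(lengths(parts) < need)
  if (length(bad) > 0) {
    mc_stop_input("line ", lineno[bad[1]], " of ", path, " has ",
                  lengths(parts)[bad[1]], " column(s); column ", need,
                  " requested")
  }
  nodes <- trimws(vapply(parts, `[[`, "", cfg$node_column))
  term_field <- vapply(parts, `[[`, "", cfg$term_column)
  term_sets <- lapply(strsplit(term_field, cfg$term_separator, fixed = TRUE),
                      function(x) {
                        x <- trimws(x)
                        x[nzchar(x)]
                      })

  matched <- nodes %in% g$nodes
  n_dropped <- length(unique(nodes[!matched]))
  if (!quiet && n_dropped > 0) {
    message(n_dropped, " annotated ID(s) not present in the network; dropped")
  }
  nodes <- nodes[matched]; term_sets <- term_sets[matched]

  node_terms <- lapply(split(term_sets, nodes), function(sets) {
    sort(unique(unlist(sets, use.names = FALSE)))
  })
  node_terms <- node_terms[lengths(node_terms) > 0]
  new_annotation(node_terms, g$nodes)
}

new_annotation <- function(node_terms, universe) {
  node_terms <- node_terms[order(names(node_terms))]
  structure(
    list(node_terms = node_terms,
         term_nodes = invert_annotation(node_terms),
         universe = universe),
    class = "mc_annotation"
  )
}

invert_annotation <- function(node_terms) {
  if (length(node_terms) == 0) return(list())
  pairs_term <- unlist(node_terms, use.names = FALSE)
  pairs_node <- rep(names(node_terms), lengths(node_terms))
  tn <- lapply(split(pairs_node, pairs_term), function(x) sort(unique(x)))
  tn[order(names(tn))]
}

#' @export
print.mc_annotation <- function(x, ...) {
  cov <- coverage(x)
  cat("mc_annotation: ", length(x$term_nodes), " term(s); ", cov$count,
      "/", length(x$universe), " node(s) annotated (", cov$percent,
      "%)\n", sep = "")
  invisible(x)
}

#' Annotation coverage of the network
#'
#' @param a an `mc_annotation`.
#' @return list with `count` (number of annotated nodes) and `percent`
#'   (100 * count / universe size, rounded to 2 decimals).
#' @export
coverage <- function(a) {
  mc_assert(length(a$universe) > 0, "empty node universe")
  count <- sum(lengths(a$node_terms) > 0)
  list(count = count, percent = round(100 * count / length(a$universe), 2))
}

#' Write an annotation table in the two-column dialect
#'
#' One line per annotated node: the node ID, then its terms joined by the
#' term separator.  Round-trips through [read_annotations()] for any valid
#' separator pair.
#'
#' @param a an `mc_annotation`.
#' @param path output path.
#' @param cfg an [parser_config()]; only the separators are used
#'   (node column 1, term column 2).
#' @export
write_annotations <- function(a, path, cfg = parser_config()) {
  stopifnot(inherits(cfg, "mc_parser_config"))
  rows <- vapply(names(a$node_terms), function(v) {
    paste(v, paste(a$node_terms[[v]], collapse = cfg$term_separator),
          sep = cfg$column_separator)
  }, "")
  writeLines(rows, path)
  invisible(path)
}
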