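#' Overlapping Cluster Generator (OCG)
#'
#' Ascending hierarchical fusion starting from an overlapping class system.
#' At each step the class pair with the largest positive overlap-modularity
#' gain (see [overlap_modularity()]) is fused; candidate pairs must share at
#' least one node or be connected by at least one edge.  Ties are broken by
#' the smaller combined class size, then by the smaller class-ID pair.
#' Fusion stops when no pair fusion increases the overlap modularity, so
#' nodes belonging to several surviving classes end up with multiple
#' cluster memberships.
#'
#' Initial class systems:
#' \describe{
#'   \item{`centered_cliques`}{(default) for each vertex `v` in ID order, a
#'     clique grown greedily from `v` through its neighbours in descending
#'     degree order (ties by ID); classes contained in another class are
#'     dropped.}
#'   \item{`maximal_cliques`}{all maximal cliques (Bron-Kerbosch, via
#'     igraph), including isolated vertices as singletons.}
#'   \item{`edges`}{every edge is a class; isolated vertices become
#'     singleton classes.}
#' }
#'
#' @param g an `mc_network` with at least one edge.
#' @param initial_system one of `"centered_cliques"`, `"maximal_cliques"`,
#'   `"edges"`.
#' @param seed integer, kept for interface uniformity; the procedure is
#'   deterministic and uses no randomness.
#' @return an `mc_partition`, possibly overlapping, with canonical cluster
#'   IDs; final overlap modularity attached as attribute `Q_ov`.
#' @export
ocg_partition <- function(g,
                          initial_system = c("centered_cliques",
                                             "maximal_cliques", "edges"),
                          seed = 42L) {
  initial_system <- match.arg(initial_system)
  mc_assert(length(g$nodes) > 0, "empty graph")
  mc_assert(g$m >= 1, "graph has no edges")

  classes <- switch(initial_system,
    centered_cliques = centered_clique_classes(g),
    maximal_cliques = maximal_clique_classes(g),
    edges = edge_classes(g)
  )
  classes <- canonical_class_order(g, classes)

  n <- length(g$nodes)
  f <- integer(n)
  for (cl in classes) f[cl] <- f[cl] + 1L
  stopifnot(all(f >= 1L))

  deg <- as.numeric(g$degree)
  m <- g$m
  contrib <- function(members, fvec) {
    inset <- logical(n); inset[members] <- TRUE
    internal <- g$edges[inset[g$edges[, 1]] & inset[g$edges[, 2]], ,
                        drop = FALSE]
    a_term <- if (nrow(internal) > 0) {
      sum(1 / (fvec[internal[, 1]] * fvec[internal[, 2]]))
    } else 0
    a_term / m - sum(deg[members] / fvec[members])^2 / (4 * m^2)
  }

  repeat {
    K <- length(classes)
    if (K <= 1) break
    inset_list <- lapply(classes, function(cl) {
      z <- logical(n); z[cl] <- TRUE; z
    })
    best <- NULL
    for (a in seq_len(K - 1)) {
      A <- classes[[a]]
      for (b in (a + 1):K) {
        B <- classes[[b]]
        shared <- A[inset_list[[b]][A]]
        linked <- length(shared) > 0 ||
          any(vapply(A, function(v) any(inset_list[[b]][g$adj[[v]]]), TRUE))
        if (!linked) next
        U <- sort(unique(c(A, B)))
        fnew <- f
        fnew[shared] <- fnew[shared] - 1L
        affected <- if (length(shared) > 0) {
          which(vapply(seq_len(K), function(cidx) {
            cidx != a && cidx != b && any(inset_list[[cidx]][shared])
          }, TRUE))
        } else integer(0)
        gain <- contrib(U, fnew) - contrib(A, f) - contrib(B, f)
        for (cidx in affected) {
          gain <- gain + contrib(classes[[cidx]], fnew) -
            contrib(classes[[cidx]], f)
        }
        better <- is.null(best) ||
          gain > best$gain + 1e-15 ||
          (abs(gain - best$gain) <= 1e-15 &&
             length(A) + length(B) < best$size)
        if (better) {
          best <- list(a = a, b = b, gain = gain,
                       size = length(A) + length(B),
                       U = U, fnew = fnew)
        }
      }
    }
    if (is.null(best) || best$gain <= 0) break
    classes[[best$a]] <- best$U
    classes[[best$b]] <- NULL
    f <- best$fnew
  }

  p <- new_partition(lapply(classes, function(cl) g$nodes[cl]), g = g)
  attr(p, "Q_ov") <- overlap_modularity(g, p)
  p
}

centered_clique_classes <- function(g) {
  n <- length(g$nodes)
  classes <- list()
  for (v in seq_len(n)) {
    clique <- v
    nb <- g$adj[[v]]
    nb <- nb[order(-g$degree[nb], g$nodes[nb])]
    for (u in nb) {
      if (all(vapply(clique, function(w) u %in% g$adj[[w]], TRUE))) {
        clique <- c(clique, u)
      }
    }
    classes[[length(classes) + 1]] <- sort(clique)
  }
  drop_contained(unique(classes))
}

maximal_clique_classes <- function(g) {
  cl <- igraph::max_cliques(as_igraph(g))
  lapply(cl, function(x) sort(as.integer(x)))
}

edge_classes <- function(g) {
  classes <- lapply(seq_len(g$m), function(r) g$edges[r, ])
  isolated <- which(g$degree == 0)
  c(classes, lapply(isolated, identity))
}

drop_contained <- function(classes) {
  ord <- order(-lengths(classes))
  classes <- classes[ord]
  keep <- rep(TRUE, length(classes))
  for (i in seq_along(classes)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (keep[j] && all(classes[[i]] %in% classes[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  classes[keep]
}

canonical_class_order <- function(g, classes) {
  keys <- vapply(classes, function(cl) paste(g$nodes[cl], collapse = "\r"), "")
  classes[order(keys)]
}

#' Primary (disjoint) cluster assignment of an overlapping partition
#'
#' Assigns every node to a single cluster: its only cluster when
#' unambiguous, otherwise deterministically the smallest containing cluster
#' ID.  The result is a disjoint complete cover.
#'
#' @param p an `mc_partition`.
#' @return a disjoint `mc_partition`.
#' @export
primary_clusters <- function(p) {
  prim <- vapply(p$membership, min, 0L)
  new_partition(split(names(p$membership), prim))
}
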