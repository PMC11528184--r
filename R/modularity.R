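#' Newman-Girvan modularity of a disjoint partition
#'
#' `Q = sum_c [ e_c/m - (d_c/(2m))^2 ]` where `e_c` is the number of edges
#' inside cluster `c`, `d_c` the summed degree of its members and `m` the
#' total edge count.
#'
#' @param g an `mc_network` with `m >= 1`.
#' @param p a disjoint complete `mc_partition` of `g`.
#' @return the modularity, a real number in `[-0.5, 1)`.
#' @export
modularity_q <- function(g, p) {
  mc_assert(g$m >= 1, "modularity undefined for a graph with no edges")
  if (p$overlapping) {
    mc_stop_input("overlapping partition: use overlap_modularity()")
  }
  mem <- membership_vector(g, p)
  K <- max(mem)
  e <- numeric(K)
  same <- mem[g$edges[, 1]] == mem[g$edges[, 2]]
  if (any(same)) {
    ec <- table(factor(mem[g$edges[same, 1]], levels = seq_len(K)))
    e <- as.numeric(ec)
  }
  d <- as.numeric(rowsum(as.numeric(g$degree), mem)[, 1])
  sum(e / g$m - (d / (2 * g$m))^2)
}

#' Overlap-aware modularity of a (possibly overlapping) cover
#'
#' Each node's contribution is split evenly across the `f_v` clusters that
#' contain it:
#' `Q_ov = (1/2m) sum_c sum_{i,j in c} [A_ij - k_i k_j/(2m)] / (f_i f_j)`
#' (ordered pairs, including `i = j`), equivalently
#' `sum_c [ (1/m) sum_{i<j in c} A_ij/(f_i f_j)
#'          - (sum_{i in c} k_i/f_i)^2 / (4 m^2) ]`.
#' For a disjoint cover (`f_v = 1` everywhere) this is exactly [modularity_q()].
#'
#' @param g an `mc_network` with `m >= 1`.
#' @param p an `mc_partition` (complete cover of `g`).
#' @return the overlap modularity.
#' @export
overlap_modularity <- function(g, p) {
  mc_assert(g$m >= 1, "modularity undefined for a graph with no edges")
  f <- lengths(p$membership)[g$nodes]
  m <- g$m
  q <- 0
  for (cid in seq_along(p$clusters)) {
    members <- p$clusters[[cid]]
    idx <- match(members, g$nodes)
    inset <- logical(length(g$nodes))
    inset[idx] <- TRUE
    internal <- g$edges[inset[g$edges[, 1]] & inset[g$edges[, 2]], ,
                        drop = FALSE]
    a_term <- if (nrow(internal) > 0) {
      sum(1 / (f[internal[, 1]] * f[internal[, 2]]))
    } else 0
    deg_term <- sum(g$degree[idx] / f[idx])
    q <- q + a_term / m - deg_term^2 / (4 * m^2)
  }
  q
}

#' Incremental modularity state for agglomerative fusion
#'
#' Tracks, for a disjoint partition, per-cluster internal edge counts `e`,
#' total degrees `d`, the sparse inter-cluster edge counts `l`, and the
#' current modularity `Q`, so that fusion gains can be evaluated in O(1).
#'
#' @param g an `mc_network` with `m >= 1`.
#' @param p a disjoint complete `mc_partition` of `g`.
#' @return an object of class `mc_modstate`.
#' @export
mod_state <- function(g, p) {
  mc_assert(g$m >= 1, "modularity undefined for a graph with no edges")
  if (p$overlapping) mc_stop_input("mod_state requires a disjoint partition")
  mem <- membership_vector(g, p)
  K <- max(mem)
  e <- numeric(K)
  d <- as.numeric(rowsum(as.numeric(g$degree), mem,
                         reorder = TRUE)[as.character(seq_len(K)), 1])
  l <- replicate(K, numeric(0), simplify = FALSE)
  for (r in seq_len(g$m)) {
    a <- mem[g$edges[r, 1]]; b <- mem[g$edges[r, 2]]
    if (a == b) {
      e[a] <- e[a] + 1
    } else {
      ka <- as.character(b); kb <- as.character(a)
      l[[a]][ka] <- (if (ka %in% names(l[[a]])) l[[a]][[ka]] else 0) + 1
      l[[b]][kb] <- (if (kb %in% names(l[[b]])) l[[b]][[kb]] else 0) + 1
    }
  }
  st <- structure(
    list(m = g$m, e = e, d = d, l = l, active = rep(TRUE, K), comm = mem),
    class = "mc_modstate"
  )
  st$Q <- sum(st$e / st$m - (st$d / (2 * st$m))^2)
  st
}

#' Modularity gain of fusing two clusters
#'
#' `dQ = l_ab/m - d_a d_b / (2 m^2)`; equals the from-scratch modularity
#' difference after vs before the fusion.
#'
#' @param state an `mc_modstate`.
#' @param a,b distinct cluster IDs present in the state.
#' @return the gain (a real number).
#' @export
delta_q_merge <- function(state, a, b) {
  mc_assert(a != b, "a and b must differ")
  ok <- a >= 1 && b >= 1 && a <= length(state$active) &&
    b <= length(state$active) && state$active[a] && state$active[b]
  mc_assert(ok, "unknown cluster ID: ", if (!isTRUE(ok)) paste(a, b) else "")
  kb <- as.character(b)
  lab <- if (kb %in% names(state$l[[a]])) state$l[[a]][[kb]] else 0
  lab / state$m - state$d[a] * state$d[b] / (2 * state$m^2)
}

# fuse cluster b into cluster a (a keeps its ID); returns the updated state
state_merge <- function(state, a, b) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  dq <- delta_q_merge(state, a, b)
  kb <- as.character(b); ka <- as.character(a)
  lab <- if (kb %in% names(state$l[[a]])) state$l[[a]][[kb]] else 0
  state$e[a] <- state$e[a] + state$e[b] + lab
  state$d[a] <- state$d[a] + state$d[b]
  # merge b's inter-cluster links into a's
  lb <- state$l[[b]]
  la <- state$l[[a]]
  la <- la[names(la) != kb]
  for (kx in names(lb)) {
    if (kx == ka) next
    la[kx] <- (if (kx %in% names(la)) la[[kx]] else 0) + lb[[kx]]
    # repoint x's entry for b to a
    lx <- state$l[[as.integer(kx)]]
    lx_b <- lx[[kb]]
    lx <- lx[names(lx) != kb]
    lx[ka] <- (if (ka %in% names(lx)) lx[[ka]] else 0) + lx_b
    state$l[[as.integer(kx)]] <- lx
  }
  state$l[[a]] <- la
  state$l[[b]] <- numeric(0)
  state$active[b] <- FALSE
  state$e[b] <- 0; state$d[b] <- 0
  state$comm[state$comm == b] <- a
  state$Q <- state$Q + dq
  state
}

# ---- weighted-graph internals (multi-level coarsening) ----------------------

# wgraph: nodes 1..n, adjacency + parallel weights, per-node loop weights.
# strength = sum of incident edge weights + 2 * loop; W = total weight.
as_wgraph <- function(g) {
  w <- lapply(g$adj, function(nb) rep(1, length(nb)))
  loop <- numeric(length(g$nodes))
  structure(
    list(n = length(g$nodes), adj = g$adj, w = w, loop = loop,
         strength = as.numeric(g$degree), W = g$m),
    class = "mc_wgraph"
  )
}

# weighted modularity from scratch, membership vector comm over 1..n
wmodularity <- function(wg, comm) {
  K <- max(comm)
  win <- numeric(K)
  S <- numeric(K)
  for (v in seq_len(wg$n)) {
    cv <- comm[v]
    S[cv] <- S[cv] + wg$strength[v]
    win[cv] <- win[cv] + wg$loop[v]
    nb <- wg$adj[[v]]
    same <- nb > v & comm[nb] == cv   # count each internal edge once
    win[cv] <- win[cv] + sum(wg$w[[v]][same])
  }
  sum(win / wg$W - (S / (2 * wg$W))^2)
}

# collapse wg under comm (values 1..K) into a K-node weighted quotient graph
collapse_wgraph <- function(wg, comm) {
  K <- max(comm)
  loop <- numeric(K)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  for (v in seq_len(wg$n)) {
    cv <- comm[v]
    loop[cv] <- loop[cv] + wg$loop[v]
    nb <- wg$adj[[v]]
    wts <- wg$w[[v]]
    keep <- nb > v
    nb <- nb[keep]; wts <- wts[keep]
    cn <- comm[nb]
    internal <- cn == cv
    loop[cv] <- loop[cv] + sum(wts[internal])
    if (any(!internal)) {
      ext_c <- cn[!internal]; ext_w <- wts[!internal]
      for (t in seq_along(ext_c)) {
        a <- min(cv, ext_c[t]); b <- max(cv, ext_c[t])
        key <- paste0(a, ".", b)
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + ext_w[t]
      }
    }
  }
  adj <- replicate(K, integer(0), simplify = FALSE)
  w <- replicate(K, numeric(0), simplify = FALSE)
  for (key in ls(acc)) {
    ab <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
    adj[[ab[1]]] <- c(adj[[ab[1]]], ab[2]); w[[ab[1]]] <- c(w[[ab[1]]], acc[[key]])
    adj[[ab[2]]] <- c(adj[[ab[2]]], ab[1]); w[[ab[2]]] <- c(w[[ab[2]]], acc[[key]])
  }
  strength <- vapply(seq_len(K), function(v) sum(w[[v]]) + 2 * loop[v], 0)
  structure(
    list(n = K, adj = adj, w = w, loop = loop, strength = strength, W = wg$W),
    class = "mc_wgraph"
  )
}

# Repeated vertex-transfer sweeps: move each vertex (in the given order) to
# its best adjacent cluster while the weighted-modularity gain exceeds tol.
# Returns comm with attributes n_moves and q_trace (maintained Q after each
# accepted move; q_trace[1] is the starting Q).
transfer_sweeps <- function(wg, comm, order, tol = 1e-12,
                            allow_split = FALSE) {
  W <- wg$W
  K <- max(comm)
  S <- numeric(K)
  size <- numeric(K)
  for (v in seq_len(wg$n)) {
    S[comm[v]] <- S[comm[v]] + wg$strength[v]
    size[comm[v]] <- size[comm[v]] + 1
  }
  q <- wmodularity(wg, comm)
  q_trace <- q
  n_moves <- 0L
  repeat {
    moved <- FALSE
    for (v in order) {
      a <- comm[v]
      nb <- wg$adj[[v]]
      if (length(nb) == 0) next
      wlink <- rowsum(wg$w[[v]], comm[nb])
      cand <- as.integer(rownames(wlink))
      wv <- wlink[, 1]
      w_va <- if (a %in% cand) wv[match(a, cand)] else 0
      s_v <- wg$strength[v]
      keep <- cand != a
      cand <- cand[keep]; wv <- wv[keep]
      if (allow_split && size[a] > 1) {
        cand <- c(cand, K + 1L)   # leave to a fresh singleton
        wv <- c(wv, 0)
        if (length(S) < K + 1L) { S <- c(S, 0); size <- c(size, 0) }
      }
      if (length(cand) == 0) next
      gains <- unname((wv - w_va) / W -
        s_v * (S[cand] - S[a] + s_v) / (2 * W^2))
      best <- which(gains == max(gains))
      best <- best[order(cand[best])][1]
      if (gains[best] > tol) {
        b <- cand[best]
        if (b > K) K <- b
        comm[v] <- b
        S[a] <- S[a] - s_v; S[b] <- S[b] + s_v
        size[a] <- size[a] - 1; size[b] <- size[b] + 1
        q <- q + gains[best]
        q_trace <- c(q_trace, q)
        n_moves <- n_moves + 1L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  attr(comm, "n_moves") <- n_moves
  attr(comm, "q_trace") <- q_trace
  comm
}
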