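prim_mst_cost <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  intree <- rep(FALSE, n)
  mind <- D[1L, ]
  intree[1L] <- TRUE
  mind[1L] <- Inf
  total <- 0
  for (step in seq_len(n - 1L)) {
    v <- which.min(mind)
    total <- total + mind[v]
    intree[v] <- TRUE
    mind[v] <- Inf
    upd <- !intree & D[v, ] < mind
    mind[upd] <- D[v, upd]
  }
  total
}

#' Maximum-parsimony (Steiner) pruning of a haplotype network
#'
#' Removes median vectors and links that lie on no minimum-cost spanning
#' subgraph connecting all observed haplotypes, the cleaning step applied
#' after median-joining when the maximum-parsimony option is on.  Observed
#' nodes are never deleted and the result stays connected.  With at most 14
#' median vectors all subsets are examined exactly; beyond that a greedy
#' cost-neutral removal is used.
#'
#' @param net an \code{mp_network}.
#' @return the pruned \code{mp_network}.
#' @export
mp_prune <- function(net) {
  X <- net$X
  W <- class_weight_matrix(net$cfg)
  D <- cond_pair_dist(X, W)
  obs <- which(net$nodes$observed)
  med <- which(!net$nodes$observed)
  k <- length(med)
  if (k <= 14L) {
    best <- Inf
    optimal_sets <- list()
    for (mask in 0:(2^k - 1L)) {
      sel <- med[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
      nodes <- c(obs, sel)
      cost <- prim_mst_cost(D[nodes, nodes, drop = FALSE])
      if (cost < best - 1e-9) {
        best <- cost
        optimal_sets <- list(nodes)
      } else if (cost <= best + 1e-9) {
        optimal_sets[[length(optimal_sets) + 1L]] <- nodes
      }
    }
    keep_nodes <- sort(unique(unlist(optimal_sets)))
    keep_edges <- new.env(hash = TRUE)
    for (nodes in optimal_sets) {
      sub <- msn_edges(D[nodes, nodes, drop = FALSE], 0L)
      if (nrow(sub)) {
        for (r in seq_len(nrow(sub))) {
          a <- nodes[sub[r, 1L]]; b <- nodes[sub[r, 2L]]
          assign(paste(min(a, b), max(a, b)), c(min(a, b), max(a, b), sub[r, 3L]),
                 envir = keep_edges)
        }
      }
    }
    ed <- do.call(rbind, mget(ls(keep_edges), envir = keep_edges))
  } else {
    nodes <- c(obs, med)
    cost <- prim_mst_cost(D[nodes, nodes, drop = FALSE])
    repeat {
      improved <- FALSE
      for (mnode in intersect(nodes, med)) {
        trial <- setdiff(nodes, mnode)
        tc <- prim_mst_cost(D[trial, trial, drop = FALSE])
        if (tc <= cost + 1e-9) {
          nodes <- trial
          cost <- tc
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    keep_nodes <- sort(nodes)
    sub <- msn_edges(D[keep_nodes, keep_nodes, drop = FALSE], 0L)
    ed <- if (nrow(sub)) cbind(keep_nodes[sub[, 1L]], keep_nodes[sub[, 2L]],
                               sub[, 3L]) else NULL
  }
  remap <- match(seq_len(nrow(X)), keep_nodes)
  labels <- net$nodes$id[keep_nodes]
  Xk <- X[keep_nodes, , drop = FALSE]
  cls <- if (!is.null(ed) && nrow(ed))
    edge_class_counts(X, ed[, 1L], ed[, 2L]) else list(ts = integer(0), tv = integer(0))
  nodes_df <- net$nodes[keep_nodes, , drop = FALSE]
  rownames(nodes_df) <- NULL
  edges_df <- if (!is.null(ed) && nrow(ed)) {
    data.frame(from = net$nodes$id[ed[, 1L]], to = net$nodes$id[ed[, 2L]],
               weight = ed[, 3L], ts = cls$ts, tv = cls$tv,
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               ts = integer(0), tv = integer(0))
  }
  out <- structure(list(nodes = nodes_df, edges = edges_df, X = Xk,
                        site_positions = net$site_positions,
                        counts = net$counts, cfg = net$cfg),
                   class = "mp_network")
  # minimum cost of a spanning subgraph connecting the observed haplotypes
  # (the Steiner cost realised by the pruned network; the network itself is
  # the union of all cost-optimal connections, so its edge sum can be larger)
  out$min_cost <- if (k <= 14L) best else cost
  out
}
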