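#' Median-joining network configuration
#'
#' Substitution classes are weighted separately: for a strongly
#' transition-biased mitochondrial locus the rarer transversions carry more
#' signal, so they default to weight 5 against 1 for transitions.
#' \code{epsilon} relaxes the minimum-spanning criterion (0 = strict),
#' \code{mp_prune} switches on the final maximum-parsimony (Steiner)
#' cleaning.
#'
#' @param weight_transversion,weight_transition positive integer weights.
#' @param epsilon non-negative integer tolerance for link feasibility and
#'   median acceptance.
#' @param mp_prune prune the converged network to edges/medians on a
#'   minimum-cost connection of the observed haplotypes.
#' @param max_medians_factor cap on inferred median vectors, as a multiple of
#'   the observed haplotype count.
#' @param max_iter iteration cap for the median-insertion loop.
#' @return list of class \code{mp_netconfig}.
#' @export
network_config <- function(weight_transversion = 5L, weight_transition = 1L,
                           epsilon = 0L, mp_prune = TRUE,
                           max_medians_factor = 10, max_iter = 50L) {
  stopifnot(weight_transversion >= 1, weight_transition >= 1, epsilon >= 0)
  structure(list(weight_transversion = as.integer(weight_transversion),
                 weight_transition = as.integer(weight_transition),
                 epsilon = as.integer(epsilon),
                 mp_prune = isTRUE(mp_prune),
                 max_medians_factor = max_medians_factor,
                 max_iter = as.integer(max_iter)),
            class = "mp_netconfig")
}

class_weight_matrix <- function(cfg) {
  # 4x4 per-site substitution cost: 0 on the diagonal, transition weight for
  # A<->G / C<->T, transversion weight otherwise
  W <- matrix(cfg$weight_transversion, 4L, 4L,
              dimnames = list(VALID_BASES, VALID_BASES))
  W["A", "G"] <- W["G", "A"] <- cfg$weight_transition
  W["C", "T"] <- W["T", "C"] <- cfg$weight_transition
  diag(W) <- 0L
  W
}

#' Weighted substitution distance between two sequences
#'
#' Sum over differing sites of the class weight (transition vs transversion).
#' Sites where either sequence is gap/ambiguous are excluded.
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @param cfg a \code{\link{network_config}}.
#' @return non-negative integer.
#' @export
weighted_distance <- function(seq_a, seq_b, cfg = network_config()) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  a <- encode_bases(strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]])
  b <- encode_bases(strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]])
  ok <- !is.na(a) & !is.na(b)
  W <- class_weight_matrix(cfg)
  sum(W[cbind(a[ok], b[ok])])
}

cond_pair_dist <- function(X, W) {
  n <- nrow(X)
  D <- matrix(0L, n, n)
  if (ncol(X) == 0L) return(D)
  for (i in seq_len(n - 1L)) {
    xi <- X[i, ]
    for (k in (i + 1L):n) {
      D[i, k] <- D[k, i] <- sum(W[cbind(xi, X[k, ])])
    }
  }
  D
}

cond_dist_to <- function(X, v, W) {
  if (ncol(X) == 0L) return(integer(nrow(X)))
  vapply(seq_len(nrow(X)), function(i) sum(W[cbind(X[i, ], v)]), numeric(1))
}

# epsilon-relaxed minimum spanning network over an integer distance matrix:
# link (u,v) is feasible iff u and v are not already connected using only
# links strictly shorter than d(u,v) - epsilon.  With epsilon = 0 this is the
# union of all minimum spanning trees.
msn_edges <- function(D, epsilon = 0L) {
  n <- nrow(D)
  if (n < 2L) return(matrix(integer(0), 0L, 3L,
                            dimnames = list(NULL, c("from", "to", "weight"))))
  pr <- which(upper.tri(D), arr.ind = TRUE)
  wt <- D[upper.tri(D)]
  o <- order(wt, pr[, 1L], pr[, 2L])
  pr <- pr[o, , drop = FALSE]
  wt <- wt[o]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(length(wt))
  lag <- 1L  # pointer into edges merged into the blocking union-find
  for (e in seq_along(wt)) {
    thr <- wt[e] - epsilon
    while (lag < e && wt[lag] < thr) {
      ra <- find(pr[lag, 1L]); rb <- find(pr[lag, 2L])
      if (ra != rb) parent[ra] <- rb
      lag <- lag + 1L
    }
    keep[e] <- find(pr[e, 1L]) != find(pr[e, 2L])
  }
  cbind(from = pr[keep, 1L], to = pr[keep, 2L], weight = wt[keep])
}

# quasi-medians of three condensed vectors: majority state per site; sites
# where all three differ contribute each observed state (cartesian product,
# capped)
quasi_medians <- function(a, b, c, max_combo = 27L) {
  S <- length(a)
  base <- integer(S)
  tie <- integer(0)
  for (j in seq_len(S)) {
    if (a[j] == b[j] || a[j] == c[j]) base[j] <- a[j]
    else if (b[j] == c[j]) base[j] <- b[j]
    else tie <- c(tie, j)
  }
  if (length(tie) == 0L) return(matrix(base, nrow = 1L))
  if (3L^length(tie) > max_combo) {
    # cap expansion: resolve surplus ties deterministically to the first
    # sequence's state
    k <- max(0L, floor(log(max_combo, 3)))
    fix <- tie[seq_len(length(tie) - k)]
    for (j in fix) base[j] <- a[j]
    tie <- setdiff(tie, fix)
    if (length(tie) == 0L) return(matrix(base, nrow = 1L))
  }
  states <- lapply(tie, function(j) c(a[j], b[j], c[j]))
  grid <- as.matrix(expand.grid(states))
  out <- matrix(rep(base, each = nrow(grid)), nrow = nrow(grid))
  out[, tie] <- grid
  out
}

#' Median-joining haplotype network
#'
#' Implements the median-joining iteration: build the epsilon-relaxed
#' minimum spanning network over the current node set; for triplets of nodes
#' joined through the network, generate quasi-median vectors (majority state
#' per site); insert those whose connection cost is within \code{epsilon} of
#' the round's minimum; drop unobserved nodes with fewer than three links;
#' repeat to a fixpoint.  Only variable, fully unambiguous sites enter the
#' computation (excluded columns are logged); edge weights are weighted
#' Hamming distances under the configured transition/transversion weights.
#' With \code{mp_prune = TRUE} the converged network is cleaned to
#' links/medians on a minimum-cost spanning subgraph of the observed
#' haplotypes (see \code{\link{mp_prune}}).
#'
#' @param haps an \code{mp_haplotypes} (at least 2 haplotypes).
#' @param cfg a \code{\link{network_config}}.
#' @return object of class \code{mp_network}: \code{nodes} data.frame (id,
#'   observed, freq), \code{edges} data.frame (from, to, weight, ts, tv),
#'   condensed site matrix \code{X}, \code{site_positions}, \code{counts}
#'   (observed haplotype x population), and \code{cfg}.
#' @export
median_joining <- function(haps, cfg = network_config()) {
  n_obs <- length(haps$seq)
  if (n_obs < 2L) stop("need at least 2 haplotypes")
  m <- do.call(rbind, strsplit(unname(haps$seq), "", fixed = TRUE))
  e <- encode_bases(m)
  clean <- colSums(is.na(e)) == 0L
  if (any(!clean))
    message(sum(!clean), " site(s) with gap/ambiguity excluded from network construction")
  varb <- clean & apply(e, 2L, function(col) length(unique(col)) > 1L)
  X <- e[, varb, drop = FALSE]
  site_positions <- which(varb)
  W <- class_weight_matrix(cfg)
  observed <- rep(TRUE, n_obs)
  labels <- names(haps$seq)
  max_medians <- ceiling(cfg$max_medians_factor * n_obs)
  D <- cond_pair_dist(X, W)

  drop_obsolete <- function() {
    repeat {
      if (nrow(X) < 2L) break
      ed <- msn_edges(D, cfg$epsilon)
      deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = nrow(X))
      kill <- which(!observed & deg < 3L)
      if (!length(kill)) break
      keep <- setdiff(seq_len(nrow(X)), kill)
      X <<- X[keep, , drop = FALSE]
      D <<- D[keep, keep, drop = FALSE]
      observed <<- observed[keep]
      labels <<- labels[keep]
    }
  }

  iter <- 0L
  med_counter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > cfg$max_iter)
      stop("median-joining did not converge within ", cfg$max_iter,
           " iterations (nodes: ", nrow(X), ")")
    drop_obsolete()
    ed <- msn_edges(D, cfg$epsilon)
    # linked triples: two links sharing a node
    adj <- lapply(seq_len(nrow(X)), function(i) integer(0))
    for (r in seq_len(nrow(ed))) {
      adj[[ed[r, 1L]]] <- c(adj[[ed[r, 1L]]], ed[r, 2L])
      adj[[ed[r, 2L]]] <- c(adj[[ed[r, 2L]]], ed[r, 1L])
    }
    cand <- list()
    cost <- numeric(0)
    seen <- new.env(hash = TRUE)
    key_of <- function(v) paste(v, collapse = ",")
    existing <- new.env(hash = TRUE)
    for (i in seq_len(nrow(X))) assign(key_of(X[i, ]), TRUE, envir = existing)
    for (u in seq_len(nrow(X))) {
      nb <- sort(unique(adj[[u]]))
      if (length(nb) < 2L) next
      prs <- combn(nb, 2L)
      for (pcol in seq_len(ncol(prs))) {
        v <- prs[1L, pcol]; w <- prs[2L, pcol]
        qm <- quasi_medians(X[u, ], X[v, ], X[w, ])
        for (r in seq_len(nrow(qm))) {
          mv <- qm[r, ]
          k <- key_of(mv)
          if (exists(k, envir = existing) || exists(k, envir = seen)) next
          assign(k, TRUE, envir = seen)
          cc <- sum(W[cbind(mv, X[u, ])]) + sum(W[cbind(mv, X[v, ])]) +
            sum(W[cbind(mv, X[w, ])])
          cand[[length(cand) + 1L]] <- mv
          cost <- c(cost, cc)
        }
      }
    }
    if (!length(cand)) break
    lambda <- min(cost)
    take <- which(cost <= lambda + cfg$epsilon)
    # deterministic order: by cost then lexicographic vector
    keys <- vapply(cand[take], paste, character(1), collapse = ",")
    take <- take[order(cost[take], keys)]
    room <- max_medians - med_counter
    if (room <= 0L) {
      warning("median-vector cap reached; stopping insertion")
      break
    }
    if (length(take) > room) take <- take[seq_len(room)]
    for (t in take) {
      mv <- cand[[t]]
      dnew <- cond_dist_to(X, mv, W)
      X <- rbind(X, mv)
      D <- rbind(cbind(D, dnew), c(dnew, 0))
      observed <- c(observed, FALSE)
      med_counter <- med_counter + 1L
      labels <- c(labels, paste0("MV", med_counter))
    }
  }
  drop_obsolete()
  net <- build_network(X, D, observed, labels, site_positions, haps, cfg)
  if (cfg$mp_prune) net <- mp_prune(net) else net
}

edge_class_counts <- function(X, from, to) {
  ts <- integer(length(from)); tv <- integer(length(from))
  for (r in seq_along(from)) {
    a <- X[from[r], ]; b <- X[to[r], ]
    dif <- which(a != b)
    same_class <- (a[dif] %% 2L) == (b[dif] %% 2L)
    ts[r] <- sum(same_class)
    tv[r] <- sum(!same_class)
  }
  list(ts = ts, tv = tv)
}

build_network <- function(X, D, observed, labels, site_positions, haps, cfg) {
  ed <- msn_edges(D, cfg$epsilon)
  freq <- ifelse(observed, rowSums(haps$counts)[labels], 0)
  freq[is.na(freq)] <- 0
  cls <- edge_class_counts(X, ed[, 1L], ed[, 2L])
  nodes <- data.frame(id = labels, observed = observed,
                      freq = as.integer(freq), stringsAsFactors = FALSE)
  edges <- data.frame(from = labels[ed[, 1L]], to = labels[ed[, 2L]],
                      weight = ed[, 3L], ts = cls$ts, tv = cls$tv,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, X = X,
                 site_positions = site_positions,
                 counts = haps$counts, cfg = cfg),
            class = "mp_network")
}

#' @export
print.mp_network <- function(x, ...) {
  cat("HaplotypeNetwork:", sum(x$nodes$observed), "observed +",
      sum(!x$nodes$observed), "median nodes,", nrow(x$edges), "edges, cost",
      sum(x$edges$weight), "\n")
  invisible(x)
}

#' Total edge cost of a network
#' @param net an \code{mp_network}.
#' @return sum of edge weights.
#' @export
network_cost <- function(net) sum(net$edges$weight)
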