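# Fast infinite-sites null engine for neutrality-test p-values.
#
# Simulates a constant-size coalescent genealogy and places mutations under
# the infinite-sites assumption (every mutation its own site), which is the
# convention of the published null distributions for Fu's Fs and R2.  Works
# directly on the edge/descendant structure, never building sequences, so a
# single replicate costs microseconds-to-milliseconds.

coal_edge_structure <- function(n) {
  ct <- coal_times_single(n, Inf, 1)
  parent <- integer(2L * n - 2L)
  child <- integer(2L * n - 2L)
  r <- 0L
  for (ev in seq_len(n - 1L)) {
    anc <- n + ev
    for (cnd in ct$merges[ev, ]) {
      r <- r + 1L
      parent[r] <- anc
      child[r] <- cnd
    }
  }
  len <- ct$times[parent] - ct$times[child]  # 2N units
  # descendant-tip count and membership per edge (indexed by child node)
  ndesc <- integer(2L * n - 1L)
  ndesc[seq_len(n)] <- 1L
  desc <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) desc[[i]] <- i
  ord <- order(child)  # children < their parents, so ascending child order
  for (r in ord) {
    p <- parent[r]; ch <- child[r]
    ndesc[p] <- ndesc[p] + ndesc[ch]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  list(n = n, parent = parent, child = child, len = len,
       ndesc = ndesc[child], desc = desc[child])
}

# summary statistics given mutation counts per edge
infinite_sites_stats <- function(es, m_e) {
  n <- es$n
  hit <- which(m_e > 0L)
  npairs <- n * (n - 1) / 2
  S <- sum(m_e)
  if (S == 0L) {
    return(list(S = 0L, k_bar = 0, K = 1L, U = integer(n)))
  }
  c_e <- es$ndesc[hit]
  k_bar <- sum(m_e[hit] * c_e * (n - c_e)) / npairs
  # haplotype identity: the set of mutation-bearing edges above each tip
  sig <- rep("", n)
  for (e in hit) {
    d <- es$desc[[e]]
    sig[d] <- paste(sig[d], e, sep = "|")
  }
  K <- length(unique(sig))
  # folded singletons: derived base carried by one tip (c_e = 1) or ancestral
  # base left in one tip (c_e = n - 1)
  U <- integer(n)
  for (j in seq_along(hit)) {
    e <- hit[j]
    if (c_e[j] == 1L) {
      U[es$desc[[e]]] <- U[es$desc[[e]]] + m_e[e]
    } else if (c_e[j] == n - 1L) {
      out <- setdiff(seq_len(n), es$desc[[e]])
      U[out] <- U[out] + m_e[e]
    }
  }
  list(S = S, k_bar = k_bar, K = K, U = U)
}

#' Simulate neutral constant-size summary statistics (infinite sites)
#'
#' Null/bootstrap engine: per replicate, a constant-size coalescent tree of
#' \code{n} tips with mutations either Poisson at rate \code{theta}/2 per
#' lineage per 2N generations, or conditioned on exactly \code{fixed_S}
#' events placed proportional to branch length.  Returns the statistics the
#' neutrality tests need.
#'
#' @param n sample size.
#' @param nsim replicates.
#' @param theta scaled mutation rate (ignored when \code{fixed_S} given).
#' @param fixed_S condition on this segregating-site count.
#' @param seed integer seed.
#' @return data.frame with columns \code{S}, \code{k_bar}, \code{K} and the
#'   per-replicate singleton vectors in attribute \code{"U"}.
#' @export
simulate_null_stats <- function(n, nsim, theta = NULL, fixed_S = NULL,
                                seed = NULL) {
  if (is.null(theta) && is.null(fixed_S))
    stop("need theta or fixed_S")
  with_seed(seed, {
    S <- integer(nsim); k_bar <- numeric(nsim); K <- integer(nsim)
    U <- vector("list", nsim)
    for (b in seq_len(nsim)) {
      es <- coal_edge_structure(n)
      m_e <- if (!is.null(fixed_S)) {
        as.integer(rmultinom(1L, fixed_S, es$len / sum(es$len)))
      } else {
        rpois(length(es$len), es$len * theta / 2)
      }
      st <- infinite_sites_stats(es, m_e)
      S[b] <- st$S; k_bar[b] <- st$k_bar; K[b] <- st$K; U[[b]] <- st$U
    }
    out <- data.frame(S = S, k_bar = k_bar, K = K)
    attr(out, "U") <- U
    out
  })
}
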