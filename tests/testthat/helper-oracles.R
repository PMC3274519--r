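# independent brute-force oracles, deliberately written from first principles
# rather than reusing package internals

# sums of squares by direct enumeration of all individual pairs
oracle_amova <- function(D, pop, grp) {
  N <- length(pop)
  pair_ss <- function(members) {
    s <- 0
    if (length(members) < 2) return(0)
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (a < b) s <- s + D[members[a], members[b]]
      }
    }
    s
  }
  SS_total <- pair_ss(seq_len(N)) / N
  SS_wg <- 0
  for (g in unique(grp)) {
    members <- which(grp == g)
    SS_wg <- SS_wg + pair_ss(members) / length(members)
  }
  SS_wp <- 0
  for (p in unique(pop)) {
    members <- which(pop == p)
    SS_wp <- SS_wp + pair_ss(members) / length(members)
  }
  SS_AG <- SS_total - SS_wg
  SS_AP <- SS_wg - SS_wp
  SS_WP <- SS_wp
  P <- length(unique(pop)); G <- length(unique(grp))
  df <- c(G - 1, P - G, N - P)
  # expected-mean-square coefficients, unequal sizes
  n_p <- sapply(unique(pop), function(p) sum(pop == p))
  names(n_p) <- unique(pop)
  sum_np2_g <- 0
  for (g in unique(grp)) {
    pops_in_g <- unique(pop[grp == g])
    sum_np2_g <- sum_np2_g + sum(n_p[as.character(pops_in_g)]^2) / sum(grp == g)
  }
  n_g <- sapply(unique(grp), function(g) sum(grp == g))
  n1 <- (N - sum_np2_g) / df[2]
  n2 <- (sum_np2_g - sum(n_p^2) / N) / df[1]
  n3 <- (N - sum(n_g^2) / N) / df[1]
  sc <- SS_WP / df[3]
  sb <- (SS_AP / df[2] - sc) / n1
  sa <- (SS_AG / df[1] - sc - n2 * sb) / n3
  tot <- sa + sb + sc
  list(SS = c(SS_AG, SS_AP, SS_WP), sigma2 = c(sa, sb, sc),
       phi = c(ST = (sa + sb) / tot, SC = sb / (sb + sc), CT = sa / tot))
}

# Kruskal minimum spanning tree on a symmetric distance matrix; deterministic
# lexicographic tie-break
oracle_kruskal <- function(D) {
  n <- nrow(D)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    edges <- rbind(edges, c(i, j, D[i, j]))
  edges <- edges[order(edges[, 3], edges[, 1], edges[, 2]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  picked <- NULL
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
    if (ra != rb) {
      parent[ra] <- rb
      picked <- rbind(picked, edges[r, ])
    }
  }
  list(edges = picked, cost = sum(picked[, 3]))
}

# exact minimum Steiner-tree cost over the weighted Hamming space spanned by
# the observed per-site states (Dreyfus-Wagner dynamic program)
oracle_steiner_cost <- function(seqs, w_ts = 1, w_tv = 5) {
  M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  varb <- apply(M, 2, function(col) length(unique(col)) > 1L)
  M <- M[, varb, drop = FALSE]
  if (ncol(M) == 0L) return(0)
  bases <- c("A", "C", "G", "T")
  W <- matrix(w_tv, 4, 4, dimnames = list(bases, bases))
  W["A", "G"] <- W["G", "A"] <- w_ts
  W["C", "T"] <- W["T", "C"] <- w_ts
  diag(W) <- 0
  states <- apply(M, 2, function(col) sort(unique(col)), simplify = FALSE)
  cand <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  V <- nrow(cand)
  D <- matrix(0, V, V)
  for (i in seq_len(V - 1)) for (j in (i + 1):V)
    D[i, j] <- D[j, i] <- sum(W[cbind(cand[i, ], cand[j, ])])
  key <- apply(cand, 1, paste, collapse = "")
  terms <- match(unique(apply(M, 1, paste, collapse = "")), key)
  k <- length(terms)
  if (k <= 1) return(0)
  if (k == 2) return(D[terms[1], terms[2]])
  q <- terms[1]; rest <- terms[-1]; m <- k - 1
  dp <- matrix(Inf, 2^m - 1, V)
  for (i in seq_len(m)) dp[2^(i - 1), ] <- D[rest[i], ]
  popcount <- vapply(1:(2^m - 1),
                     function(s) sum(bitwAnd(s, 2^(0:(m - 1))) > 0), 0L)
  for (S in order(popcount)) {
    if (popcount[S] < 2) next
    merge <- rep(Inf, V)
    sub <- S
    repeat {
      sub <- bitwAnd(sub - 1L, S)
      if (sub == 0L) break
      other <- S - sub
      if (sub < other) next
      merge <- pmin(merge, dp[sub, ] + dp[other, ])
    }
    dp[S, ] <- apply(D + merge, 2, min)
  }
  dp[2^m - 1, q]
}

# uncorrected proportion of differing comparable sites
oracle_p_distance <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  sum(va[ok] != vb[ok]) / sum(ok)
}
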