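#' Specify a demographic model for coalescent simulation
#'
#' Time is handled internally in units of 2N generations of the reference
#' (present-day) population; the exposed parameters are scaled mutation rates
#' (theta, per sequence) and expansion/split ages in mutational units (tau,
#' expected pairwise mutations), so no absolute population size is ever
#' needed.
#'
#' @param kind \code{"constant"}, \code{"sudden_expansion"} or
#'   \code{"two_deme_split"}.
#' @param theta scaled mutation rate (constant model; also the reference,
#'   post-expansion rate of the other models).
#' @param theta0 pre-expansion theta (sudden expansion).
#' @param theta1 post-expansion / present-day theta.
#' @param tau expansion age in mutational units.
#' @param split_tau split age in mutational units (two-deme model).
#' @param deme_sizes relative sizes of the two demes (reference units).
#' @param ancestral_size relative size of the ancestral deme.
#' @param migration scaled symmetric migration rate between the demes
#'   (per-lineage rate migration/2); 0 for complete isolation.
#' @return object of class \code{mp_demography}.
#' @export
demography_model <- function(kind = c("constant", "sudden_expansion", "two_deme_split"),
                             theta = NULL, theta0 = NULL, theta1 = NULL,
                             tau = NULL, split_tau = NULL,
                             deme_sizes = c(1, 1), ancestral_size = 1,
                             migration = 0) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(theta) || theta <= 0) stop("constant model needs theta > 0")
    theta0 <- theta1 <- theta
    tau <- 0
  } else if (kind == "sudden_expansion") {
    if (is.null(theta0) || is.null(theta1) || is.null(tau))
      stop("sudden_expansion needs theta0, theta1, tau")
    if (theta0 < 0 || theta1 <= 0 || tau < 0)
      stop("invalid sudden_expansion parameters")
  } else {
    if (is.null(split_tau) || split_tau < 0)
      stop("two_deme_split needs split_tau >= 0")
    if (is.null(theta1) && !is.null(theta)) theta1 <- theta
    if (is.null(theta1) || theta1 <= 0) stop("two_deme_split needs theta (> 0)")
    if (migration < 0) stop("migration must be >= 0")
    theta0 <- theta1
    tau <- 0
  }
  structure(list(kind = kind, theta0 = theta0, theta1 = theta1, tau = tau,
                 split_tau = split_tau, deme_sizes = deme_sizes,
                 ancestral_size = ancestral_size, migration = migration),
            class = "mp_demography")
}

#' Simulation configuration
#'
#' @param n sample size (scalar; for the two-deme model a length-2 vector of
#'   per-deme sizes).
#' @param L number of sites.
#' @param kappa transition:transversion odds of a mutation (each transversion
#'   target equiprobable); the default matches a strongly transition-biased
#'   mitochondrial locus.
#' @param seed integer seed (optional; the caller's RNG stream is restored).
#' @param fixed_S condition on exactly this many mutation events, placed on
#'   branches with probability proportional to length.
#' @return object of class \code{mp_simconfig}.
#' @export
sim_config <- function(n, L = 1140L, kappa = 5.33, seed = NULL, fixed_S = NULL) {
  if (any(n < 1L) || sum(n) < 2L) stop("need at least 2 samples")
  if (L < 1L) stop("L must be >= 1")
  structure(list(n = as.integer(n), L = as.integer(L), kappa = kappa,
                 seed = seed, fixed_S = fixed_S),
            class = "mp_simconfig")
}

# single-deme coalescent with piecewise-constant size; size = 1 for
# t < t_switch, size0 afterwards (times in 2N_ref units).  Returns per-node
# times and merge order.
coal_times_single <- function(n, t_switch = Inf, size0 = 1) {
  times <- numeric(2L * n - 1L)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  size <- if (t_switch > 0) 1 else size0
  merges <- matrix(0L, n - 1L, 2L)
  for (ev in seq_len(n - 1L)) {
    k <- length(active)
    repeat {
      rate <- k * (k - 1) / 2 / size
      w <- rexp(1L, rate)
      if (t < t_switch && t + w > t_switch) {
        t <- t_switch
        size <- size0
      } else {
        t <- t + w
        break
      }
    }
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    times[nxt] <- t
    merges[ev, ] <- c(a, b)
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(times = times, merges = merges, n = n)
}

# structured coalescent for two demes merging into one ancestral deme at
# t_split, with symmetric migration; returns the same (times, merges) shape
coal_times_split <- function(n1, n2, t_split, sizes, anc_size, migration) {
  n <- n1 + n2
  times <- numeric(2L * n - 1L)
  deme <- c(rep(1L, n1), rep(2L, n2))
  active <- seq_len(n)
  act_deme <- deme
  nxt <- n + 1L
  t <- 0
  merges <- matrix(0L, n - 1L, 2L)
  ev <- 0L
  merged <- FALSE
  while (length(active) > 1L) {
    if (!merged && t >= t_split) {
      act_deme[] <- 1L
      merged <- TRUE
    }
    k1 <- sum(act_deme == 1L); k2 <- sum(act_deme == 2L)
    s1 <- if (merged) anc_size else sizes[1L]
    s2 <- sizes[2L]
    r_c1 <- k1 * (k1 - 1) / 2 / s1
    r_c2 <- if (merged) 0 else k2 * (k2 - 1) / 2 / s2
    r_m <- if (merged) 0 else (k1 + k2) * migration / 2
    rate <- r_c1 + r_c2 + r_m
    if (rate == 0) {
      # isolated singleton lineages: jump to the split
      t <- t_split
      next
    }
    w <- rexp(1L, rate)
    if (!merged && t + w > t_split) {
      t <- t_split
      next
    }
    t <- t + w
    u <- runif(1L) * rate
    if (u < r_c1 + r_c2) {
      d <- if (u < r_c1) 1L else 2L
      idx <- which(act_deme == d)
      pick <- idx[sample.int(length(idx), 2L)]
      a <- active[pick[1L]]; b <- active[pick[2L]]
      ev <- ev + 1L
      times[nxt] <- t
      merges[ev, ] <- c(a, b)
      active <- c(active[-pick], nxt)
      act_deme <- c(act_deme[-pick], d)
      nxt <- nxt + 1L
    } else {
      idx <- sample.int(length(active), 1L)
      act_deme[idx] <- 3L - act_deme[idx]
    }
  }
  list(times = times, merges = merges, n = n)
}

#' Simulate a coalescent genealogy
#'
#' Branch lengths are returned in mutational units (expected mutations per
#' sequence), obtained by scaling coalescent time (2N units) by theta/2 of
#' the reference population; a sudden expansion of age tau mutational units
#' is a size change at scaled time tau/theta1.
#'
#' @param model an \code{\link{demography_model}}.
#' @param cfg an \code{\link{sim_config}}.
#' @return object of class \code{mp_tree}: \code{n}, \code{edge} (2-column
#'   parent/child matrix), \code{edge_length} (mutational units),
#'   \code{node_time} and, for the two-deme model, the tip \code{deme}.
#' @export
simulate_genealogy <- function(model, cfg) {
  with_seed(cfg$seed, {
    if (model$kind == "two_deme_split") {
      n1 <- cfg$n[1L]
      n2 <- if (length(cfg$n) >= 2L) cfg$n[2L] else cfg$n[1L]
      t_split <- model$split_tau / model$theta1
      ct <- coal_times_split(n1, n2, t_split, model$deme_sizes,
                             model$ancestral_size, model$migration)
      deme <- c(rep(1L, n1), rep(2L, n2))
    } else {
      n <- sum(cfg$n)
      t_switch <- if (model$kind == "sudden_expansion")
        model$tau / model$theta1 else Inf
      size0 <- if (model$kind == "sudden_expansion" && model$theta1 > 0)
        model$theta0 / model$theta1 else 1
      if (model$kind == "sudden_expansion" && size0 <= 0)
        size0 <- 1e-8  # vanishing ancestral size: near-instant coalescence
      ct <- coal_times_single(n, t_switch, size0)
      deme <- NULL
    }
    n <- ct$n
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
    scale <- model$theta1 / 2
    len <- (ct$times[parent] - ct$times[child]) * scale
    structure(list(n = n, edge = cbind(parent = parent, child = child),
                   edge_length = len, node_time = ct$times * scale,
                   deme = deme),
              class = "mp_tree")
  })
}

transition_partner <- c(A = "G", C = "T", G = "A", T = "C")
transversion_targets <- list(A = c("C", "T"), G = c("C", "T"),
                             C = c("A", "G"), T = c("A", "G"))

# apply n_mut kappa-biased mutations to a sequence (character vector)
mutate_lineage <- function(s, n_mut, kappa, L) {
  if (n_mut == 0L) return(s)
  p_ts <- kappa / (kappa + 1)
  for (mu in seq_len(n_mut)) {
    site <- sample.int(L, 1L)
    cur <- s[site]
    s[site] <- if (runif(1L) < p_ts) transition_partner[[cur]]
    else sample(transversion_targets[[cur]], 1L)
  }
  s
}

#' Drop mutations on a genealogy and build sequences
#'
#' Mutation counts per branch are Poisson with mean equal to the branch
#' length in mutational units (or, with \code{fixed_S}, exactly that many
#' events multinomially assigned proportional to branch length).  Each
#' mutation hits a uniformly chosen site; it is a transition with odds
#' \code{kappa}:1, otherwise one of the two transversion targets with equal
#' probability.  The ancestral sequence is uniform over A/C/G/T.
#'
#' @param tree an \code{mp_tree}.
#' @param cfg an \code{\link{sim_config}}.
#' @param root_seq optional ancestral sequence (character vector of length
#'   \code{cfg$L}); drawn uniformly when absent.
#' @return an \code{mp_alignment} with samples \code{s1..sn}; the realised
#'   number of mutation events is in attribute \code{n_mutations}.
#' @export
mutate_sequences <- function(tree, cfg, root_seq = NULL) {
  n <- tree$n
  L <- cfg$L
  nmut <- if (!is.null(cfg$fixed_S)) {
    tot <- sum(tree$edge_length)
    if (tot <= 0) stop("fixed_S requires a tree with positive total length")
    as.integer(rmultinom(1L, cfg$fixed_S, tree$edge_length / tot))
  } else {
    rpois(length(tree$edge_length), tree$edge_length)
  }
  root <- 2L * n - 1L
  seqs <- vector("list", 2L * n - 1L)
  seqs[[root]] <- if (is.null(root_seq))
    sample(VALID_BASES, L, replace = TRUE) else root_seq
  # preorder: edges sorted by decreasing parent id visit parents before kids
  ord <- order(tree$edge[, "parent"], decreasing = TRUE)
  for (r in ord) {
    p <- tree$edge[r, "parent"]; ch <- tree$edge[r, "child"]
    seqs[[ch]] <- mutate_lineage(seqs[[p]], nmut[r], cfg$kappa, L)
  }
  tips <- vapply(seqs[seq_len(n)], paste, character(1), collapse = "")
  aln <- alignment(setNames(tips, paste0("s", seq_len(n))))
  attr(aln, "n_mutations") <- sum(nmut)
  aln
}

#' Simulate an alignment under a demographic model
#'
#' Convenience wrapper chaining \code{\link{simulate_genealogy}} and
#' \code{\link{mutate_sequences}}; for the two-deme model a population map
#' assigning tips to demes is attached.
#'
#' @param model an \code{\link{demography_model}}.
#' @param cfg an \code{\link{sim_config}}.
#' @return list with \code{alignment}, \code{popmap} and \code{tree}.
#' @export
simulate_alignment <- function(model, cfg) {
  with_seed(cfg$seed, {
    cfg_inner <- cfg
    cfg_inner$seed <- NULL
    tree <- simulate_genealogy(model, cfg_inner)
    aln <- mutate_sequences(tree, cfg_inner)
    pop <- if (!is.null(tree$deme)) paste0("d", tree$deme)
    else rep("d1", tree$n)
    popmap <- data.frame(sample_id = aln$ids, population_id = pop,
                         group_id = pop, stringsAsFactors = FALSE)
    list(alignment = aln, popmap = popmap, tree = tree)
  })
}
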