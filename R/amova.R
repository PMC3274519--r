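#' Define a grouping scheme for hierarchical AMOVA
#'
#' @param name scheme label used in reports.
#' @param mapping named character vector: population_id -> group_id.
#' @return object of class \code{mp_scheme}.
#' @export
grouping_scheme <- function(name, mapping) {
  if (is.null(names(mapping)) || any(names(mapping) == ""))
    stop("mapping must be a named vector population_id -> group_id")
  if (length(unique(mapping)) < 2L)
    stop("a grouping scheme needs at least 2 groups")
  structure(list(name = name, mapping = mapping), class = "mp_scheme")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

half_sum <- function(D, idx) sum(D[idx, idx]) / 2

# three-level variance components from squared inter-individual distances
# (Excoffier-style sums of squares with unequal-size coefficients);
# pop / grp are integer codes per individual
amova_components <- function(D, pop, grp) {
  N <- length(pop)
  pops <- sort(unique(pop))
  grps <- sort(unique(grp))
  P <- length(pops); G <- length(grps)
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  grp_of_pop <- vapply(pops, function(p) grp[match(p, pop)], numeric(1))
  n_g <- vapply(grps, function(g) sum(grp == g), numeric(1))
  ss_all <- half_sum(D, seq_len(N)) / N
  ss_g <- vapply(grps, function(g) half_sum(D, which(grp == g)) / sum(grp == g),
                 numeric(1))
  ss_p <- vapply(pops, function(p) half_sum(D, which(pop == p)) / sum(pop == p),
                 numeric(1))
  SS_WP <- sum(ss_p)
  SS_AP <- sum(ss_g) - SS_WP
  SS_AG <- ss_all - sum(ss_g)
  df_a <- G - 1L; df_b <- P - G; df_c <- N - P
  sum_np2_by_g <- vapply(grps, function(g) {
    sum(n_p[grp_of_pop == g]^2) / n_g[match(g, grps)]
  }, numeric(1))
  n1 <- (N - sum(sum_np2_by_g)) / df_b
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_a
  n3 <- (N - sum(n_g^2) / N) / df_a
  MS_c <- if (df_c > 0) SS_WP / df_c else NA_real_
  MS_b <- if (df_b > 0) SS_AP / df_b else NA_real_
  MS_a <- SS_AG / df_a
  sigma_c <- MS_c
  if (df_b > 0) {
    sigma_b <- (MS_b - sigma_c) / n1
    sigma_a <- (MS_a - sigma_c - n2 * sigma_b) / n3
  } else {
    # one population per group: the among-populations stratum vanishes and
    # the analysis reduces to two levels with groups as the only partition
    sigma_b <- 0
    two <- fst_components(D, grp)
    sigma_a <- unname(two$sigma2["a"])
    sigma_c <- unname(two$sigma2["c"])
  }
  total <- sigma_a + sigma_b + sigma_c
  list(SS = c(among_groups = SS_AG, among_pops = SS_AP, within_pops = SS_WP),
       df = c(df_a, df_b, df_c),
       sigma2 = c(a = sigma_a, b = sigma_b, c = sigma_c),
       total = total,
       phi = c(
         ST = if (isTRUE(total != 0)) (sigma_a + sigma_b) / total else NA_real_,
         SC = if (isTRUE(sigma_b + sigma_c != 0)) sigma_b / (sigma_b + sigma_c) else NA_real_,
         CT = if (isTRUE(total != 0)) sigma_a / total else NA_real_))
}

# two-level (population) variance components; returns Phi_ST a.k.a. Fst
fst_components <- function(D, pop) {
  N <- length(pop)
  pops <- sort(unique(pop))
  P <- length(pops)
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  ss_all <- half_sum(D, seq_len(N)) / N
  ss_p <- vapply(pops, function(p) half_sum(D, which(pop == p)) / sum(pop == p),
                 numeric(1))
  SS_WP <- sum(ss_p)
  SS_AP <- ss_all - SS_WP
  df_a <- P - 1L; df_c <- N - P
  sigma_c <- if (df_c > 0) SS_WP / df_c else NA_real_
  nc <- (N - sum(n_p^2) / N) / df_a
  sigma_a <- (SS_AP / df_a - sigma_c) / nc
  total <- sigma_a + sigma_c
  list(sigma2 = c(a = sigma_a, c = sigma_c),
       fst = if (isTRUE(total != 0)) sigma_a / total else NA_real_)
}

#' Hierarchical AMOVA with permutation tests
#'
#' Partitions molecular variance into among-group, among-population-within-
#' group and within-population components from a matrix of inter-individual
#' raw pairwise difference counts (the conventional squared-distance choice
#' for haplotype data), with Excoffier-style sums of squares and
#' unequal-size coefficients.  Significance of each Phi-statistic is
#' assessed by its level-appropriate permutation scheme: individuals among
#' populations anywhere (Phi_ST), individuals among populations within their
#' group (Phi_SC), and whole populations among groups (Phi_CT); one-tailed
#' p-values use the (b+1)/(m+1) correction.  Negative variance components
#' are reported as computed, never clamped.
#'
#' @param dm square matrix of raw pairwise difference counts (from
#'   \code{\link{distance_matrix}} with \code{model = "raw"}), row/col names
#'   are sample ids.
#' @param popmap population map data.frame.
#' @param scheme an \code{\link{grouping_scheme}}, or NULL to use the
#'   \code{group_id} column of \code{popmap}.
#' @param n_perm permutations per statistic (0 skips testing).
#' @param seed integer seed for the permutation RNG.
#' @return object of class \code{mp_amova}: variance components, percentages,
#'   Phi-statistics, permutation p-values, degrees of freedom and flags.
#' @export
amova <- function(dm, popmap, scheme = NULL, n_perm = 1000L, seed = NULL) {
  ids <- rownames(dm)
  pm <- popmap[match(ids, popmap$sample_id), ]
  if (anyNA(pm$sample_id)) stop("distance matrix contains unmapped samples")
  pop_chr <- pm$population_id
  grp_map <- if (is.null(scheme)) {
    setNames(pm$group_id, pm$population_id)[!duplicated(pm$population_id)]
  } else scheme$mapping
  missing <- setdiff(unique(pop_chr), names(grp_map))
  if (length(missing))
    stop("populations not assigned to a group: ", paste(missing, collapse = ", "))
  grp_chr <- unname(grp_map[pop_chr])
  if (length(unique(grp_chr)) < 2L) stop("need at least 2 groups")
  pop <- as.integer(factor(pop_chr))
  grp <- as.integer(factor(grp_chr))
  obs <- amova_components(dm, pop, grp)
  flags <- character(0)
  if (obs$df[3] == 0L)
    flags <- c(flags, "within-population component undefined (one sequence per population)")
  if (isTRUE(all(dm == 0)))
    flags <- c(flags, "all sequences identical: variance components zero, Phi undefined")
  pvals <- c(ST = NA_real_, SC = NA_real_, CT = NA_real_)
  do_test <- !is.na(obs$phi)
  if (n_perm > 0L && any(do_test)) {
    pvals <- with_seed(seed, {
      hits <- c(ST = 0L, SC = 0L, CT = 0L)
      pops <- sort(unique(pop))
      grp_of_pop <- vapply(pops, function(p) grp[match(p, pop)], integer(1))
      for (b in seq_len(n_perm)) {
        if (do_test["ST"]) {
          # Phi_ST: individuals among populations anywhere
          p1 <- sample(pop)
          phi_st <- amova_components(dm, p1, grp[match(p1, pop)])$phi["ST"]
          if (!is.na(phi_st) && phi_st >= obs$phi["ST"])
            hits["ST"] <- hits["ST"] + 1L
        }
        if (do_test["SC"]) {
          # Phi_SC: individuals among populations within their group
          p2 <- pop
          for (g in unique(grp)) {
            i <- which(grp == g)
            p2[i] <- p2[i][sample(length(i))]
          }
          phi_sc <- amova_components(dm, p2, grp)$phi["SC"]
          if (!is.na(phi_sc) && phi_sc >= obs$phi["SC"])
            hits["SC"] <- hits["SC"] + 1L
        }
        if (do_test["CT"]) {
          # Phi_CT: whole populations among groups
          g3 <- grp_of_pop[sample(length(pops))]
          phi_ct <- amova_components(dm, pop, g3[pop])$phi["CT"]
          if (!is.na(phi_ct) && phi_ct >= obs$phi["CT"])
            hits["CT"] <- hits["CT"] + 1L
        }
      }
      p <- (hits + 1L) / (n_perm + 1L)
      p[!do_test] <- NA_real_
      p
    })
  }
  total <- obs$total
  structure(list(
    scheme = if (is.null(scheme)) "popmap groups" else scheme$name,
    SS = obs$SS, df = obs$df, sigma2 = obs$sigma2,
    pct = 100 * obs$sigma2 / total,
    phi = obs$phi, p = pvals, n_perm = n_perm, flags = flags),
    class = "mp_amova")
}

#' @export
print.mp_amova <- function(x, ...) {
  cat("AMOVA (", x$scheme, ")\n", sep = "")
  cat(sprintf("  sigma2: among groups %.4f (%.2f%%), among pops %.4f (%.2f%%), within pops %.4f (%.2f%%)\n",
              x$sigma2["a"], x$pct["a"], x$sigma2["b"], x$pct["b"],
              x$sigma2["c"], x$pct["c"]))
  cat(sprintf("  Phi_ST = %.4f (p = %.4g), Phi_SC = %.4f (p = %.4g), Phi_CT = %.4f (p = %.4g)\n",
              x$phi["ST"], x$p["ST"], x$phi["SC"], x$p["SC"],
              x$phi["CT"], x$p["CT"]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pairwise Fst between populations with permutation tests
#'
#' Distance-based Fst: the two-population Phi_ST from raw pairwise difference
#' counts; p-values from permuting individuals between the two populations
#' with the (b+1)/(m+1) correction.  Pairs where both populations have a
#' single sequence are skipped with a warning.
#'
#' @param dm raw difference-count matrix (sample ids as dimnames).
#' @param popmap population map data.frame.
#' @param n_perm permutations per pair.
#' @param seed integer seed.
#' @return object of class \code{mp_fst}: symmetric \code{fst} and \code{p}
#'   matrices over populations.
#' @export
pairwise_fst <- function(dm, popmap, n_perm = 1000L, seed = NULL) {
  ids <- rownames(dm)
  pm <- popmap[match(ids, popmap$sample_id), ]
  if (anyNA(pm$sample_id)) stop("distance matrix contains unmapped samples")
  pops <- unique(pm$population_id)
  np <- length(pops)
  fst <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  diag(fst) <- 0
  skipped <- 0L
  with_seed(seed, {
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        ia <- which(pm$population_id == pops[i])
        ib <- which(pm$population_id == pops[j])
        if (length(ia) == 1L && length(ib) == 1L) {
          skipped <- skipped + 1L
          next
        }
        idx <- c(ia, ib)
        sub <- dm[idx, idx, drop = FALSE]
        lab <- rep(1:2, c(length(ia), length(ib)))
        obs <- fst_components(sub, lab)$fst
        fst[i, j] <- fst[j, i] <- obs
        if (n_perm > 0L && !is.na(obs)) {
          hits <- 0L
          for (b in seq_len(n_perm)) {
            st <- fst_components(sub, sample(lab))$fst
            if (!is.na(st) && st >= obs) hits <- hits + 1L
          }
          pv[i, j] <- pv[j, i] <- (hits + 1L) / (n_perm + 1L)
        }
      }
    }
  })
  if (skipped > 0L)
    warning(skipped, " population pair(s) skipped: one sequence in each")
  structure(list(fst = fst, p = pv, n_perm = n_perm), class = "mp_fst")
}

#' @export
print.mp_fst <- function(x, ...) {
  cat("Pairwise Fst over", nrow(x$fst), "populations; range",
      sprintf("%.3f-%.3f\n", min(x$fst, na.rm = TRUE), max(x$fst, na.rm = TRUE)))
  invisible(x)
}

#' Write AMOVA and Fst reports as TSV
#'
#' The Fst table carries significance flags at the 0.05 level and marks
#' values at or above 0.25, the conventional threshold for strongly
#' restricted gene flow.
#'
#' @param x an \code{mp_amova} or \code{mp_fst}.
#' @param path output TSV path.
#' @export
write_structure_report <- function(x, path) {
  if (inherits(x, "mp_amova")) {
    df <- data.frame(
      scheme = x$scheme,
      level = c("among_groups", "among_pops_within_groups", "within_pops"),
      df = x$df, SS = x$SS, sigma2 = x$sigma2, pct = x$pct,
      phi = c(x$phi["CT"], x$phi["SC"], x$phi["ST"]),
      phi_label = c("Phi_CT", "Phi_SC", "Phi_ST"),
      p = c(x$p["CT"], x$p["SC"], x$p["ST"]),
      stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "mp_fst")) {
    long <- which(upper.tri(x$fst), arr.ind = TRUE)
    df <- data.frame(
      pop_a = rownames(x$fst)[long[, 1]],
      pop_b = colnames(x$fst)[long[, 2]],
      fst = x$fst[long], p = x$p[long],
      significant_0.05 = x$p[long] < 0.05,
      restricted_gene_flow_0.25 = x$fst[long] >= 0.25,
      stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
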