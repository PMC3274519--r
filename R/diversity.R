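# vectorised segregating-site count: a site is variable iff at least two
# distinct unambiguous bases occur (same rule as classify_sites)
count_segregating_sites <- function(aln) {
  m <- as.matrix(aln)
  present <- vapply(VALID_BASES, function(b) colSums(m == b) > 0,
                    logical(ncol(m)))
  present <- matrix(present, nrow = ncol(m))
  sum(rowSums(present) >= 2L)
}

#' Molecular diversity summary for a set of sequences
#'
#' Computes the standard single-locus summaries: number of haplotypes,
#' haplotype diversity with the small-sample correction
#' \eqn{Hd = \frac{n}{n-1}(1 - \sum p_i^2)}, nucleotide diversity per site
#' (mean over sequence pairs of raw differences divided by comparable sites,
#' i.e. pairwise deletion of gap/ambiguous positions), mean pairwise
#' difference count \eqn{\bar k}, and the number of segregating sites S.
#'
#' @param aln an \code{mp_alignment} (possibly a subset).
#' @return object of class \code{mp_diversity} with fields \code{n},
#'   \code{n_haplotypes}, \code{Hd}, \code{pi}, \code{S}, \code{k_bar}.
#' @export
diversity_summary <- function(aln) {
  n <- length(aln$ids)
  if (n < 2L) stop("diversity summary needs at least 2 sequences")
  haps <- collapse_haplotypes(aln)
  p <- rowSums(haps$counts) / n
  Hd <- (n / (n - 1)) * (1 - sum(p^2))
  pc <- pairwise_base_counts(aln)
  ut <- upper.tri(pc$comparable)
  if (any(pc$comparable[ut] == 0))
    stop("sequence pair with no comparable sites")
  pi <- mean(pc$diff[ut] / pc$comparable[ut])
  k_bar <- mean(pc$diff[ut])
  S <- count_segregating_sites(aln)
  structure(list(n = n, n_haplotypes = length(haps$seq), Hd = Hd,
                 pi = pi, S = S, k_bar = k_bar),
            class = "mp_diversity")
}

#' @export
print.mp_diversity <- function(x, ...) {
  cat(sprintf("n = %d | haplotypes = %d | Hd = %.4f | pi = %.5f | S = %d | k_bar = %.3f\n",
              x$n, x$n_haplotypes, x$Hd, x$pi, x$S, x$k_bar))
  invisible(x)
}

#' Diversity report by population, group and total
#'
#' One row per population (with n >= 2), per group, plus a "total" row; units
#' and estimators as in \code{\link{diversity_summary}}.
#'
#' @param aln an \code{mp_alignment}.
#' @param popmap population map data.frame.
#' @return data.frame with columns level, unit, n, n_haplotypes, Hd, pi, S,
#'   k_bar.
#' @export
diversity_report <- function(aln, popmap) {
  check_popmap(aln, popmap)
  pm <- popmap[match(aln$ids, popmap$sample_id), ]
  rows <- list()
  add <- function(level, unit, ids) {
    if (length(ids) < 2L) return()
    d <- diversity_summary(subset_alignment(aln, ids))
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, unit = unit, n = d$n, n_haplotypes = d$n_haplotypes,
      Hd = d$Hd, pi = d$pi, S = d$S, k_bar = d$k_bar,
      stringsAsFactors = FALSE)
  }
  for (p in unique(pm$population_id))
    add("population", p, pm$sample_id[pm$population_id == p])
  for (g in unique(pm$group_id))
    add("group", g, pm$sample_id[pm$group_id == g])
  add("total", "total", pm$sample_id)
  do.call(rbind, rows)
}
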