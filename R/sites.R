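seq_char_matrix <- function(x) {
  if (inherits(x, "mp_alignment")) {
    m <- as.matrix(x)
    w <- rep(1L, nrow(m))
  } else if (inherits(x, "mp_haplotypes")) {
    m <- do.call(rbind, strsplit(unname(x$seq), "", fixed = TRUE))
    rownames(m) <- names(x$seq)
    w <- as.integer(rowSums(x$counts))
  } else if (is.character(x)) {
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    w <- rep(1L, nrow(m))
  } else stop("unsupported input type")
  list(m = m, w = w)
}

#' Classify alignment sites and count substitution classes
#'
#' A site is variable iff at least two distinct unambiguous bases (A/C/G/T)
#' occur across the sequences; conserved otherwise.  Columns with no
#' unambiguous base at all (all gap/N) are excluded from both counts and
#' reported.  Substitution-class totals consider, per variable site, every
#' unordered pair of distinct observed bases: purine-purine or
#' pyrimidine-pyrimidine pairs count as transitions, the rest as
#' transversions.  Singleton and parsimony-informative classification weights
#' haplotypes by their sample counts, so results match what the uncollapsed
#' alignment would give.
#'
#' Both the transition/transversion ratio and its inverse are returned;
#' \code{ratio_reported} carries ts/tv, the conventional orientation for a
#' transition-biased mitochondrial locus.
#'
#' @param x an \code{mp_alignment}, \code{mp_haplotypes} or character vector
#'   of equal-length sequences.
#' @return object of class \code{mp_siteclass}; see fields in the source.
#' @export
classify_sites <- function(x) {
  sm <- seq_char_matrix(x)
  m <- sm$m
  w <- sm$w
  if (nrow(m) < 2L) stop("need at least 2 sequences/haplotypes")
  L <- ncol(m)
  n_states <- integer(L)
  ts <- 0L; tv <- 0L
  singleton <- 0L; pinf <- 0L
  excluded <- integer(0)
  variable_sites <- integer(0)
  for (j in seq_len(L)) {
    col <- m[, j]
    keep <- col %in% VALID_BASES
    if (!any(keep)) {
      excluded <- c(excluded, j)
      next
    }
    tab <- tapply(w[keep], col[keep], sum)
    states <- names(tab)
    n_states[j] <- length(states)
    if (length(states) >= 2L) {
      variable_sites <- c(variable_sites, j)
      prs <- combn(states, 2L)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1L, k]; b <- prs[2L, k]
        if ((a %in% PURINES) == (b %in% PURINES)) ts <- ts + 1L else tv <- tv + 1L
      }
      if (sum(tab >= 2L) >= 2L) pinf <- pinf + 1L else singleton <- singleton + 1L
    }
  }
  analyzed <- L - length(excluded)
  variable <- length(variable_sites)
  if (length(excluded))
    message(length(excluded), " all-gap/ambiguous site(s) excluded from site classification")
  structure(list(
    sites = L,
    analyzed = analyzed,
    conserved = analyzed - variable,
    variable = variable,
    singleton = singleton,
    parsimony_informative = pinf,
    transitions = ts,
    transversions = tv,
    ts_tv = if (tv > 0) ts / tv else NA_real_,
    tv_ts = if (ts > 0) tv / ts else NA_real_,
    ratio_reported = if (tv > 0) ts / tv else NA_real_,
    variable_sites = variable_sites,
    excluded_sites = excluded
  ), class = "mp_siteclass")
}

#' @export
print.mp_siteclass <- function(x, ...) {
  cat("Sites analyzed:", x$analyzed,
      "| conserved:", x$conserved,
      "| variable:", x$variable,
      sprintf("(singleton %d, parsimony-informative %d)\n",
              x$singleton, x$parsimony_informative))
  cat("Substitution classes: ts =", x$transitions, ", tv =", x$transversions,
      sprintf("; ts/tv = %.3f, tv/ts = %.3f\n", x$ts_tv, x$tv_ts))
  invisible(x)
}
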