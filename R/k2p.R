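encode_bases <- function(m) {
  # integer codes: A=1, C=2, G=3, T=4; anything else (gap, N, ambiguity) -> NA
  e <- match(m, VALID_BASES)
  dim(e) <- dim(m)
  dimnames(e) <- dimnames(m)
  e
}

pair_site_counts <- function(ea, eb) {
  ok <- !is.na(ea) & !is.na(eb)
  m <- sum(ok)
  if (m == 0L) return(list(m = 0L, ts = 0L, tv = 0L))
  diff <- ok & (ea != eb)
  # purines code 1,3 (odd); pyrimidines 2,4 (even): same parity => transition
  is_ts <- diff & ((ea %% 2L) == (eb %% 2L))
  ts <- sum(is_ts, na.rm = TRUE)
  tv <- sum(diff, na.rm = TRUE) - ts
  list(m = m, ts = ts, tv = tv)
}

k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    d <- NaN
    attr(d, "saturated") <- TRUE
    return(d)
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  attr(d, "saturated") <- FALSE
  d
}

#' Kimura 2-parameter distance between two sequences
#'
#' Gap/ambiguous positions are removed pairwise; over the remaining
#' comparable sites, with transition proportion P and transversion proportion
#' Q, the distance is \eqn{-\frac12\ln(1-2P-Q) - \frac14\ln(1-2Q)}
#' substitutions/site.  Saturated pairs (a logarithm argument at or below
#' zero) return \code{NaN} carrying attribute \code{saturated = TRUE}.
#'
#' @param seq_a,seq_b nucleotide strings of equal length.
#' @return numeric distance with a \code{saturated} attribute.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  ea <- encode_bases(strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]])
  eb <- encode_bases(strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]])
  cnt <- pair_site_counts(ea, eb)
  if (cnt$m == 0L) stop("no comparable sites between the two sequences")
  k2p_from_pq(cnt$ts / cnt$m, cnt$tv / cnt$m)
}

pairwise_base_counts <- function(x) {
  sm <- seq_char_matrix(x)
  m <- sm$m
  n <- nrow(m)
  L <- ncol(m)
  ind <- lapply(VALID_BASES, function(b) {
    M <- matrix(0, n, L)
    M[m == b] <- 1
    M
  })
  names(ind) <- VALID_BASES
  valid <- ind$A + ind$C + ind$G + ind$T
  comp <- valid %*% t(valid)
  same <- Reduce(`+`, lapply(ind, function(M) M %*% t(M)))
  ts <- ind$A %*% t(ind$G) + ind$G %*% t(ind$A) +
    ind$C %*% t(ind$T) + ind$T %*% t(ind$C)
  diffs <- comp - same
  tv <- diffs - ts
  ids <- rownames(m)
  dimnames(comp) <- dimnames(ts) <- dimnames(tv) <- dimnames(diffs) <-
    list(ids, ids)
  list(comparable = comp, ts = ts, tv = tv, diff = diffs)
}

#' Pairwise distance matrix under K2P or raw difference counts
#'
#' @param x an \code{mp_alignment}, \code{mp_haplotypes} or character vector.
#' @param model \code{"K2P"} (substitutions/site, corrected) or \code{"raw"}
#'   (integer count of differing comparable sites).
#' @return symmetric numeric matrix with zero diagonal; attributes
#'   \code{model}, \code{comparable} (per-pair comparable-site counts) and,
#'   for K2P, \code{saturated} (logical matrix).
#' @export
distance_matrix <- function(x, model = c("K2P", "raw")) {
  model <- match.arg(model)
  pc <- pairwise_base_counts(x)
  n <- nrow(pc$comparable)
  if (any(pc$comparable[upper.tri(pc$comparable)] == 0))
    stop("sequence pair with no comparable sites")
  if (model == "raw") {
    d <- pc$diff
    diag(d) <- 0
    attr(d, "model") <- "raw"
    attr(d, "comparable") <- pc$comparable
    return(d)
  }
  P <- pc$ts / pc$comparable
  Q <- pc$tv / pc$comparable
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  sat <- (w1 <= 0) | (w2 <= 0)
  d <- matrix(NaN, n, n, dimnames = dimnames(pc$comparable))
  ok <- !sat
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  diag(d) <- 0
  if (any(sat[upper.tri(sat)]))
    warning(sum(sat[upper.tri(sat)]), " saturated pair(s): distance set to NaN")
  attr(d, "model") <- "K2P"
  attr(d, "comparable") <- pc$comparable
  attr(d, "saturated") <- sat
  d
}

#' Mean K2P distance between two groups of samples
#'
#' Arithmetic mean of the pairwise distance over all between-group sequence
#' pairs, the conventional "net-free" between-clade divergence summary.
#'
#' @param dm distance matrix from \code{\link{distance_matrix}} whose
#'   row/column names are sample ids.
#' @param popmap population map data.frame.
#' @param group_a,group_b group ids present in \code{popmap$group_id}.
#' @return mean distance (substitutions/site for K2P).
#' @export
group_mean_k2p <- function(dm, popmap, group_a, group_b) {
  grp <- setNames(popmap$group_id, popmap$sample_id)
  ids <- rownames(dm)
  for (g in c(group_a, group_b))
    if (!g %in% grp[ids]) stop("unknown or empty group: ", g)
  ia <- ids[!is.na(grp[ids]) & grp[ids] == group_a]
  ib <- ids[!is.na(grp[ids]) & grp[ids] == group_b]
  mean(dm[ia, ib, drop = FALSE])
}

#' Export a distance matrix as TSV
#' @param dm matrix from \code{\link{distance_matrix}}.
#' @param path output path.
#' @param lower_triangle write a PHYLIP-style lower triangle instead of the
#'   full square matrix.
#' @export
write_distance_matrix <- function(dm, path, lower_triangle = FALSE) {
  if (lower_triangle) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(dm)), con)
    for (i in seq_len(nrow(dm))) {
      row <- if (i > 1) paste(formatC(dm[i, seq_len(i - 1)], format = "g"),
                              collapse = "\t") else ""
      writeLines(paste(rownames(dm)[i], row, sep = "\t"), con)
    }
  } else {
    write.table(as.data.frame(dm), path, sep = "\t", quote = FALSE,
                col.names = NA)
  }
  invisible(path)
}
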