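#' Substitution-rate calibration from a dated clade divergence
#'
#' The per-site per-lineage yearly rate is obtained from a between-clade
#' corrected distance and the age of the split: mu = d / (2 T), since the
#' two lineages accumulate divergence d over T years each.  The per-sequence
#' per-generation rate entering the expansion-dating equation is then
#' u = 2 mu L g (mutation rate per nucleotide per generation, 2 mu g, times
#' the number of nucleotides L).
#'
#' @param clade_divergence_k2p between-clade K2P distance (proportion, e.g.
#'   0.031).
#' @param divergence_time_years age of the calibrating split in years.
#' @param L number of nucleotides.
#' @param generation_years generation time in years.
#' @return object of class \code{mp_calibration} with \code{mu} (per site
#'   per lineage per year) and \code{u} (per sequence per generation).
#' @export
rate_calibration <- function(clade_divergence_k2p, divergence_time_years,
                             L = 1140L, generation_years = 1) {
  if (clade_divergence_k2p <= 0 || divergence_time_years <= 0 ||
      L <= 0 || generation_years <= 0)
    stop("all calibration inputs must be positive")
  mu <- clade_divergence_k2p / (2 * divergence_time_years)
  u <- 2 * mu * L * generation_years
  structure(list(clade_divergence_k2p = clade_divergence_k2p,
                 divergence_time_years = divergence_time_years,
                 L = as.integer(L), generation_years = generation_years,
                 mu = mu, u = u),
            class = "mp_calibration")
}

#' @export
print.mp_calibration <- function(x, ...) {
  cat(sprintf("Rate calibration: mu = %.3g /site/lineage/yr, u = %.3g /sequence/generation\n",
              x$mu, x$u))
  invisible(x)
}

#' Date a demographic expansion from tau
#'
#' Inverts tau = 2 u t: the expansion happened t = tau / (2u) generations
#' ago, converted to years by the generation time.  Confidence bounds on tau
#' transform identically (the map is linear in tau).
#'
#' @param tau expansion age in mutational units.
#' @param cal an \code{\link{rate_calibration}}.
#' @param tau_ci optional numeric length-2 (lower, upper) tau bounds.
#' @return object of class \code{mp_expansion_time}: \code{t_years},
#'   \code{t_mya}, \code{t_mya_3} (rounded to 3 decimals, the conventional
#'   reporting precision) and the transformed \code{ci_*} fields.
#' @export
date_expansion <- function(tau, cal, tau_ci = NULL) {
  if (!inherits(cal, "mp_calibration")) stop("cal must be a rate_calibration")
  if (tau < 0) stop("tau must be >= 0")
  to_years <- function(x) x / (2 * cal$u) * cal$generation_years
  t_years <- to_years(tau)
  ci_years <- if (!is.null(tau_ci)) to_years(tau_ci) else c(NA_real_, NA_real_)
  structure(list(tau = tau, t_years = t_years, t_mya = t_years / 1e6,
                 t_mya_3 = round(t_years / 1e6, 3),
                 ci_years = ci_years, ci_mya = ci_years / 1e6,
                 ci_mya_3 = round(ci_years / 1e6, 3)),
            class = "mp_expansion_time")
}

#' @export
print.mp_expansion_time <- function(x, ...) {
  cat(sprintf("Expansion time: %.3f Mya", x$t_mya_3))
  if (!anyNA(x$ci_mya_3))
    cat(sprintf(" (%.3f-%.3f)", min(x$ci_mya_3), max(x$ci_mya_3)))
  cat("\n")
  invisible(x)
}

#' Demographic summary table for a set of groups
#'
#' One row per group: Fu's Fs, R2, SSD, raggedness (each with p-values), the
#' fitted tau with its bootstrap CI, and the dated expansion time when a
#' calibration is supplied.
#'
#' @param aln an \code{mp_alignment}.
#' @param popmap population map data.frame.
#' @param cal optional \code{\link{rate_calibration}} for dating.
#' @param n_boot mismatch-bootstrap replicates.
#' @param n_sim neutrality-test simulation replicates.
#' @param seed integer seed.
#' @param min_n smallest group size analysed.
#' @return data.frame, one row per group.
#' @export
demography_report <- function(aln, popmap, cal = NULL, n_boot = 200L,
                              n_sim = 1000L, seed = NULL, min_n = 4L) {
  check_popmap(aln, popmap)
  pm <- popmap[match(aln$ids, popmap$sample_id), ]
  rows <- list()
  seeds <- with_seed(seed, sample.int(2^30, length(unique(pm$group_id)) * 3L))
  si <- 0L
  for (g in unique(pm$group_id)) {
    ids <- pm$sample_id[pm$group_id == g]
    si <- si + 3L
    if (length(ids) < min_n) next
    sub <- subset_alignment(aln, ids)
    fs <- fu_fs(sub, n_sim = n_sim, seed = seeds[si - 2L])
    r2 <- tryCatch(r2_test(sub, n_sim = n_sim, seed = seeds[si - 1L]),
                   error = function(e) NULL)
    h <- mismatch_histogram(sub)
    fit <- fit_sudden_expansion(h, n_boot = n_boot, seed = seeds[si],
                                L = aln$L)
    dt <- if (!is.null(cal) && !fit$degenerate)
      date_expansion(fit$tau, cal, fit$tau_CI) else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n = length(ids),
      Fs = fs$Fs, p_Fs = fs$p_Fs,
      R2 = if (is.null(r2)) NA_real_ else r2$R2,
      p_R2 = if (is.null(r2)) NA_real_ else r2$p_R2,
      SSD = fit$SSD, p_SSD = fit$p_SSD, rg = fit$rg, p_rg = fit$p_rg,
      tau = fit$tau, tau_lo = fit$tau_CI[1], tau_hi = fit$tau_CI[2],
      t_mya = if (is.null(dt)) NA_real_ else dt$t_mya_3,
      t_mya_lo = if (is.null(dt)) NA_real_ else min(dt$ci_mya_3),
      t_mya_hi = if (is.null(dt)) NA_real_ else max(dt$ci_mya_3),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
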