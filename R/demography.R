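#' Mismatch distribution (pairwise difference spectrum)
#'
#' Relative frequency of raw pairwise difference counts over all
#' \eqn{n(n-1)/2} sequence pairs.
#'
#' @param aln an \code{mp_alignment}.
#' @return object of class \code{mp_mismatch_hist}: integer \code{counts}
#'   (classes 0..max difference), relative \code{freq}, \code{n} and
#'   \code{k_bar}.
#' @export
mismatch_histogram <- function(aln) {
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  pc <- pairwise_base_counts(aln)
  diffs <- pc$diff[upper.tri(pc$diff)]
  dmax <- max(diffs)
  counts <- tabulate(diffs + 1L, nbins = dmax + 1L)
  structure(list(counts = counts, freq = counts / sum(counts),
                 classes = 0:dmax, n = n, k_bar = mean(diffs)),
            class = "mp_mismatch_hist")
}

#' Geometric equilibrium mismatch spectrum
#' @param theta scaled mutation rate.
#' @param i difference class (vectorised).
#' @return \eqn{\hat F_i(\theta) = \theta^i/(\theta+1)^{i+1}}.
#' @export
equilibrium_mismatch <- function(theta, i) theta^i / (theta + 1)^(i + 1)

#' Expected mismatch spectrum under the sudden-expansion model
#'
#' \deqn{F_i(\tau,\theta_0,\theta_1) = \hat F_i(\theta_1) + e^{-\tau}
#'   \sum_{j=0}^{i} \frac{\tau^j}{j!}\,[\hat F_{i-j}(\theta_0) -
#'   \hat F_{i-j}(\theta_1)]}
#' with \eqn{\hat F_i(\theta) = \theta^i/(\theta+1)^{i+1}}.  The mass beyond
#' the last class is folded into it so the returned vector sums to 1.
#'
#' @param tau expansion age in mutational units.
#' @param theta0,theta1 pre-/post-expansion theta.
#' @param d_max last difference class.
#' @param fold_tail fold the truncated tail mass into class \code{d_max}.
#' @return numeric vector over classes 0..\code{d_max}.
#' @export
expected_mismatch <- function(tau, theta0, theta1, d_max, fold_tail = TRUE) {
  i <- 0:d_max
  f0 <- equilibrium_mismatch(theta0, i)
  f1 <- equilibrium_mismatch(theta1, i)
  pois <- stats::dpois(i, tau)
  dlt <- f0 - f1
  conv <- if (d_max == 0L) pois * dlt
  else stats::convolve(pois, rev(dlt), type = "open")[seq_len(d_max + 1L)]
  Fi <- f1 + conv
  # the transient-phase formula can dip marginally below zero in extreme
  # parameter corners; clip so the spectrum is usable as a distribution
  Fi <- pmax(Fi, 0)
  if (fold_tail && d_max >= 1L) {
    Fi[d_max + 1L] <- max(0, 1 - sum(Fi[seq_len(d_max)]))
    Fi <- Fi / sum(Fi)
  }
  Fi
}

#' Harpending's raggedness index
#' @param freq relative mismatch frequencies over classes 0..d.
#' @return \eqn{rg = \sum_{i=1}^{d} (x_i - x_{i-1})^2}.
#' @export
raggedness <- function(freq) {
  if (length(freq) < 2L) return(0)
  sum(diff(freq)^2)
}

ssd_objective <- function(par, obs) {
  # clamp at the boundary: optim's finite-difference gradient may probe a
  # step below the box constraint
  tau <- max(par[1L], 0)
  theta0 <- max(par[2L], 0)
  theta1 <- theta0 + max(par[3L], 0)
  expv <- expected_mismatch(tau, theta0, theta1, length(obs) - 1L)
  sum((obs - expv)^2)
}

fit_expansion_point <- function(obs, theta1_max = 1e5, start = NULL) {
  d <- length(obs) - 1L
  kb <- sum((0:d) * obs)
  best <- NULL
  best_val <- Inf
  if (is.null(start)) {
    # cold start: seed over a (tau, theta0) grid with theta1 profiled
    tau_grid <- unique(pmax(0, c(0, kb * c(0.5, 0.75, 1, 1.25), 1, 5)))
    th0_grid <- unique(pmax(0, c(0, 0.5, 2, kb / 2)))
    for (tau in tau_grid) {
      for (th0 in th0_grid) {
        f <- function(lth1) ssd_objective(c(tau, th0, exp(lth1)), obs)
        opt <- optimize(f, c(log(1e-3), log(theta1_max)), tol = 0.01)
        if (opt$objective < best_val) {
          best_val <- opt$objective
          best <- c(tau, th0, exp(opt$minimum))
        }
      }
    }
  } else {
    # warm start (bootstrap refits): the parent estimate, rescaled to the
    # replicate's mean, plus a no-expansion fallback
    for (cand in list(
      c(start[1L], start[2L], max(start[3L] - start[2L], 1e-3)),
      c(max(kb - start[2L], 0), start[2L], max(start[3L] - start[2L], 1e-3)),
      c(0, kb, 1e-3))) {
      v <- ssd_objective(cand, obs)
      if (v < best_val) { best_val <- v; best <- cand }
    }
  }
  o <- optim(best, ssd_objective, obs = obs, method = "L-BFGS-B",
             lower = c(0, 0, 0), upper = c(Inf, theta1_max, theta1_max),
             control = list(maxit = 500))
  if (o$convergence != 0 && o$value > best_val)
    o <- list(par = best, value = best_val, convergence = 0)
  list(tau = o$par[1L], theta0 = o$par[2L], theta1 = o$par[2L] + o$par[3L],
       SSD = o$value)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of (tau, theta0, theta1) to the observed pairwise
#' difference spectrum (grid-seeded with theta1 profiled, refined by
#' box-constrained quasi-Newton search; theta1 capped at 1e5, the
#' conventional near-infinite post-expansion value).  Goodness of fit is the
#' sum of squared deviations (SSD) and Harpending's raggedness; their
#' p-values and the tau confidence interval come from a parametric bootstrap:
#' coalescent samples are simulated under the fitted expansion, each is
#' refitted, and p is the fraction of simulated statistics at or above the
#' observed one.
#'
#' @param hist an \code{\link{mismatch_histogram}}.
#' @param n sample size behind the histogram (defaults to \code{hist$n}).
#' @param n_boot parametric-bootstrap replicates (0 skips bootstrap).
#' @param seed integer seed.
#' @param L sequence length for bootstrap simulation.
#' @param kappa transition bias for bootstrap simulation.
#' @param ci_level percentile confidence level for tau.
#' @return object of class \code{mp_mismatch_fit} with fields \code{tau},
#'   \code{theta0}, \code{theta1}, \code{SSD}, \code{p_SSD}, \code{rg},
#'   \code{p_rg}, \code{tau_CI}, \code{observed}, \code{expected}.
#' @export
fit_sudden_expansion <- function(hist, n = hist$n, n_boot = 1000L,
                                 seed = NULL, L = 1140L, kappa = 5.33,
                                 ci_level = 0.95) {
  obs <- hist$freq
  if (length(obs) < 2L) {
    fit <- list(tau = 0, theta0 = 0, theta1 = 0, SSD = 0)
    out <- c(fit, list(rg = 0, p_SSD = NA_real_, p_rg = NA_real_,
                       tau_CI = c(NA_real_, NA_real_),
                       observed = obs, expected = 1,
                       degenerate = TRUE, n_boot = 0L))
    return(structure(out, class = "mp_mismatch_fit"))
  }
  fit <- fit_expansion_point(obs)
  rg_obs <- raggedness(obs)
  p_SSD <- p_rg <- NA_real_
  tau_CI <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    model <- demography_model("sudden_expansion", theta0 = fit$theta0,
                              theta1 = max(fit$theta1, 1e-3), tau = fit$tau)
    res <- with_seed(seed, {
      ssd_b <- numeric(n_boot); rg_b <- numeric(n_boot); tau_b <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        sim <- simulate_alignment(model, sim_config(n = n, L = L, kappa = kappa))
        h <- mismatch_histogram(sim$alignment)
        if (length(h$freq) < 2L) {
          f <- list(tau = 0, SSD = sum((h$freq - 1)^2))
          rg_b[b] <- 0
        } else {
          f <- fit_expansion_point(h$freq,
                                   start = c(fit$tau, fit$theta0,
                                             fit$theta1 - fit$theta0))
          rg_b[b] <- raggedness(h$freq)
        }
        ssd_b[b] <- f$SSD
        tau_b[b] <- f$tau
      }
      list(ssd = ssd_b, rg = rg_b, tau = tau_b)
    })
    p_SSD <- (sum(res$ssd >= fit$SSD) + 1L) / (n_boot + 1L)
    p_rg <- (sum(res$rg >= rg_obs) + 1L) / (n_boot + 1L)
    a <- (1 - ci_level) / 2
    tau_CI <- unname(stats::quantile(res$tau, c(a, 1 - a)))
  }
  structure(list(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 SSD = fit$SSD, p_SSD = p_SSD, rg = rg_obs, p_rg = p_rg,
                 tau_CI = tau_CI, observed = obs,
                 expected = expected_mismatch(fit$tau, fit$theta0, fit$theta1,
                                              length(obs) - 1L),
                 degenerate = FALSE, n_boot = n_boot),
            class = "mp_mismatch_fit")
}

#' @export
print.mp_mismatch_fit <- function(x, ...) {
  cat(sprintf("Sudden-expansion fit: tau = %.3f (CI %.3f-%.3f), theta0 = %.3f, theta1 = %.3g\n",
              x$tau, x$tau_CI[1], x$tau_CI[2], x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f (p = %.3f), rg = %.5f (p = %.3f)\n",
              x$SSD, x$p_SSD, x$rg, x$p_rg))
  invisible(x)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n), via the
# recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| computed in log space;
# rows are memoized (the null simulations request the same n repeatedly)
.stirling_cache <- new.env(parent = emptyenv())
log_stirling1_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  row <- 0  # n = 1: |s(1,1)| = 1
  if (n > 1L) {
    for (m in seq_len(n - 1L)) {
      prev <- c(row, -Inf)          # k = 1..m+1, |s(m, m+1)| = 0
      shift <- c(-Inf, row)         # |s(m, k-1)|
      grown <- prev + log(m)
      row <- pmax(grown, shift) +
        log1p(exp(pmin(grown, shift) - pmax(grown, shift)))
      row[is.nan(row)] <- -Inf
    }
  }
  .stirling_cache[[key]] <- row
  row
}

#' Ewens distribution of the number of haplotypes
#'
#' \eqn{\Pr(K=k \mid \theta, n) = |s(n,k)|\,\theta^k / (\theta (\theta+1)
#' \cdots (\theta+n-1))} with unsigned Stirling numbers of the first kind,
#' computed in log space.
#'
#' @param n sample size.
#' @param theta scaled mutation rate.
#' @return probability vector over k = 1..n.
#' @export
ewens_haplotype_pmf <- function(n, theta) {
  if (theta <= 0) stop("theta must be > 0")
  ls <- log_stirling1_row(n)
  k <- seq_len(n)
  logp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1L)))
  exp(logp)
}

#' Fu's Fs neutrality test
#'
#' With \eqn{\hat\theta = \bar k} (mean pairwise differences), let
#' \eqn{S' = \Pr(K \ge k_{obs} \mid \hat\theta, n)} under the Ewens
#' distribution; then \eqn{F_s = \ln(S'/(1-S'))}.  Large negative values
#' indicate an excess of haplotypes, the signature of expansion (or
#' selection).  The p-value is the fraction of neutral constant-size
#' coalescent simulations (infinite sites, rate parameterised by
#' \eqn{\hat\theta}) whose simulated Fs is at or below the observed one.
#'
#' @param aln an \code{mp_alignment}.
#' @param n_sim simulation replicates for the p-value (0 skips).
#' @param seed integer seed.
#' @return object of class \code{mp_fufs}: \code{Fs}, \code{p_Fs},
#'   \code{k_obs}, \code{theta_hat}, \code{S_prime}, \code{saturated} flag.
#' @export
fu_fs <- function(aln, n_sim = 1000L, seed = NULL) {
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  pc <- pairwise_base_counts(aln)
  k_bar <- mean(pc$diff[upper.tri(pc$diff)])
  k_obs <- length(unique(unname(aln$seq)))
  if (k_bar == 0)
    return(structure(list(Fs = NA_real_, p_Fs = NA_real_, k_obs = k_obs,
                          theta_hat = 0, S_prime = NA_real_,
                          saturated = FALSE,
                          flag = "k_bar = 0: Fs undefined"),
                     class = "mp_fufs"))
  fs_of <- function(theta, k, n) {
    pmf <- ewens_haplotype_pmf(n, theta)
    sp <- sum(pmf[k:n])
    sp <- min(max(sp, 0), 1)
    if (sp <= 0 || sp >= 1) {
      # saturated in double precision: log-space fallback on the tail
      lsp <- log(sum(pmf[k:n]))
      fs <- if (sp >= 1) Inf else lsp - log1p(-exp(lsp))
      attr(fs, "saturated") <- TRUE
      attr(fs, "S_prime") <- sp
      return(fs)
    }
    fs <- log(sp / (1 - sp))
    attr(fs, "saturated") <- FALSE
    attr(fs, "S_prime") <- sp
    fs
  }
  fs <- fs_of(k_bar, k_obs, n)
  p_Fs <- NA_real_
  if (n_sim > 0L && is.finite(fs)) {
    sims <- simulate_null_stats(n, n_sim, theta = k_bar, seed = seed)
    hits <- 0L
    for (b in seq_len(n_sim)) {
      if (sims$k_bar[b] == 0) next  # Fs undefined, cannot beat the observed
      fb <- fs_of(sims$k_bar[b], sims$K[b], n)
      if (fb <= fs) hits <- hits + 1L
    }
    p_Fs <- (hits + 1L) / (n_sim + 1L)
  }
  structure(list(Fs = as.numeric(fs), p_Fs = p_Fs, k_obs = k_obs,
                 theta_hat = k_bar, S_prime = attr(fs, "S_prime"),
                 saturated = isTRUE(attr(fs, "saturated")), flag = NULL),
            class = "mp_fufs")
}

#' @export
print.mp_fufs <- function(x, ...) {
  cat(sprintf("Fu's Fs = %.3f (p = %.4g); k_obs = %d, theta_hat = %.3f\n",
              x$Fs, x$p_Fs, x$k_obs, x$theta_hat))
  invisible(x)
}

singletons_per_sequence <- function(aln) {
  m <- as.matrix(aln)
  n <- nrow(m)
  U <- integer(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    keep <- col %in% VALID_BASES
    if (sum(keep) < 2L) next
    tab <- table(col[keep])
    if (length(tab) < 2L) next
    for (b in names(tab)[tab == 1L]) {
      carrier <- which(keep & col == b)
      U[carrier] <- U[carrier] + 1L
    }
  }
  U
}

#' Ramos-Onsins and Rozas's R2 test
#'
#' \eqn{R_2 = \sqrt{\frac1n \sum_i (U_i - \bar k/2)^2} / S}, where
#' \eqn{U_i} counts singleton bases carried by sequence i (site patterns
#' whose minority base has frequency exactly 1; ambiguous bases ignored per
#' site).  Low values indicate expansion.  The p-value is the fraction of
#' neutral coalescent simulations conditioned on the observed S (fixed-S,
#' infinite sites) with simulated R2 at or below the observed one.
#'
#' @param aln an \code{mp_alignment}.
#' @param n_sim simulation replicates (0 skips).
#' @param seed integer seed.
#' @return object of class \code{mp_r2}: \code{R2}, \code{p_R2}, \code{U},
#'   \code{S}, \code{k_bar}.
#' @export
r2_test <- function(aln, n_sim = 1000L, seed = NULL) {
  n <- length(aln$ids)
  if (n < 2L) stop("need at least 2 sequences")
  S <- suppressMessages(classify_sites(aln))$variable
  if (S < 1L) stop("R2 undefined: no segregating sites")
  pc <- pairwise_base_counts(aln)
  k_bar <- mean(pc$diff[upper.tri(pc$diff)])
  U <- singletons_per_sequence(aln)
  r2_of <- function(U, k_bar, S, n) sqrt(mean((U - k_bar / 2)^2)) / S
  R2 <- r2_of(U, k_bar, S, n)
  p_R2 <- NA_real_
  if (n_sim > 0L) {
    sims <- simulate_null_stats(n, n_sim, fixed_S = S, seed = seed)
    Us <- attr(sims, "U")
    hits <- 0L
    for (b in seq_len(n_sim)) {
      rb <- r2_of(Us[[b]], sims$k_bar[b], S, n)
      if (rb <= R2) hits <- hits + 1L
    }
    p_R2 <- (hits + 1L) / (n_sim + 1L)
  }
  structure(list(R2 = R2, p_R2 = p_R2, U = U, S = S, k_bar = k_bar),
            class = "mp_r2")
}

#' @export
print.mp_r2 <- function(x, ...) {
  cat(sprintf("R2 = %.4f (p = %.4g); S = %d, k_bar = %.3f\n",
              x$R2, x$p_R2, x$S, x$k_bar))
  invisible(x)
}
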