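test_that("mismatch histograms count pairwise differences", {
  h <- mismatch_histogram(mk_aln(c("AAAA", "TTTA")))
  expect_equal(h$counts, c(0, 0, 0, 1))
  expect_equal(sum(h$freq), 1)

  h2 <- mismatch_histogram(mk_aln(c("AAAA", "GAAA", "GGAA")))
  # pairwise distances {1, 2, 1}
  expect_equal(h2$freq, c(0, 2 / 3, 1 / 3))
  expect_equal(h2$k_bar, 4 / 3)
})

test_that("the expansion spectrum reduces to the equilibrium form at tau = 0", {
  i <- 0:10
  for (th in c(0.5, 1, 3, 8)) {
    expect_equal(expected_mismatch(0, th, 999, 10, fold_tail = FALSE),
                 equilibrium_mismatch(th, i), tolerance = 1e-12)
  }
  # theta0 = 1, tau = 0: 1/2, 1/4, 1/8
  F0 <- expected_mismatch(0, 1, 1, 5, fold_tail = FALSE)
  expect_equal(F0[1:3], c(1 / 2, 1 / 4, 1 / 8), tolerance = 1e-12)
})

test_that("the expansion spectrum is a probability distribution for fuzzed parameters", {
  set.seed(19)
  for (rep in 1:60) {
    tau <- runif(1, 0, 20)
    th0 <- runif(1, 0, 10)
    th1 <- th0 + runif(1, 0, 1000)
    Fi <- expected_mismatch(tau, th0, th1, sample(5:40, 1))
    expect_true(all(Fi >= -1e-12))
    expect_equal(sum(Fi), 1, tolerance = 1e-9)
  }
})

test_that("raggedness follows its quadratic definition", {
  x <- c(0.5, 0.3, 0.2)
  expect_equal(raggedness(x), (0.3 - 0.5)^2 + (0.2 - 0.3)^2)
  expect_equal(raggedness(1), 0)
})

test_that("sudden-expansion fitting recovers a clean model spectrum", {
  # noiseless input generated from the model itself
  truth <- expected_mismatch(6, 0.5, 200, 30)
  fit <- fit_sudden_expansion(structure(list(freq = truth, n = 50,
                                             counts = truth * 1000,
                                             classes = 0:30, k_bar = sum((0:30) * truth)),
                                        class = "mp_mismatch_hist"),
                              n_boot = 0)
  expect_lt(fit$SSD, 1e-5)
  expect_equal(fit$tau, 6, tolerance = 0.25)
})

test_that("Fu's Fs matches hand-computed Ewens probabilities", {
  # n = 2, one difference: theta-hat = 1, k = 2, S' = 1/2, Fs = 0
  fs2 <- fu_fs(mk_aln(c("AAAA", "AAAG")), n_sim = 0)
  expect_equal(fs2$theta_hat, 1)
  expect_equal(fs2$S_prime, 0.5)
  expect_equal(fs2$Fs, 0)

  # n = 3, theta-hat = 1, k = 3: Pr(K) = {2/6, 3/6, 1/6}, S' = 1/6
  aln3 <- mk_aln(c("AA", "AG", "AC"))
  fs3 <- fu_fs(aln3, n_sim = 0)
  expect_equal(fs3$theta_hat, 1)
  expect_equal(fs3$k_obs, 3)
  expect_equal(fs3$S_prime, 1 / 6, tolerance = 1e-12)
  expect_equal(fs3$Fs, log(1 / 5), tolerance = 1e-12)

  # k_bar = 0 flagged
  fs0 <- fu_fs(mk_aln(c("AAAA", "AAAA")), n_sim = 0)
  expect_true(is.na(fs0$Fs))
})

test_that("the Ewens haplotype-count pmf is normalised", {
  for (n in c(2, 5, 20, 100, 200)) {
    for (th in c(0.1, 1, 10, 50)) {
      expect_equal(sum(ewens_haplotype_pmf(n, th)), 1, tolerance = 1e-9)
    }
  }
  expect_equal(exp(mitopop:::log_stirling1_row(4)), c(6, 11, 6, 1),
               tolerance = 1e-12)
})

test_that("R2 matches its definition on hand cases", {
  # n = 2, S = 1, k_bar = 1: |U_i - 1/2| = 1/2 either way -> R2 = 0.5
  r2 <- r2_test(mk_aln(c("AAAA", "AAAG")), n_sim = 0)
  expect_equal(r2$R2, 0.5)
  # star: each of 4 sequences carries exactly one private mutation
  star <- mk_aln(c("GAAAC", "AGAAC", "AAGAC", "AAATC"))
  r2s <- r2_test(star, n_sim = 0)
  expect_equal(r2s$U, rep(1L, 4))
  expect_equal(r2s$S, 4)
  expect_equal(r2s$k_bar, 2)
  expect_equal(r2s$R2, sqrt(mean((1 - 1)^2)) / 4)
  expect_error(r2_test(mk_aln(c("AA", "AA")), n_sim = 0), "undefined")
})

test_that("expansion dating is linear in tau and validates inputs", {
  cal <- rate_calibration(0.031, 620000, 1140, 1)
  expect_equal(cal$mu, 0.031 / (2 * 620000))
  expect_equal(cal$u, 2 * cal$mu * 1140)
  t1 <- date_expansion(2, cal)
  t2 <- date_expansion(4, cal)
  expect_equal(t2$t_years, 2 * t1$t_years)
  expect_equal(date_expansion(0, cal)$t_years, 0)
  ci <- date_expansion(4.389, cal, tau_ci = c(3.172, 5.389))
  expect_equal(ci$ci_mya_3, c(0.028, 0.047))
  expect_error(rate_calibration(-0.1, 620000), "positive")
  expect_error(date_expansion(-1, cal), "tau")
})
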