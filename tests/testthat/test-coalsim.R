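test_that("simulation is deterministic under a seed", {
  m <- demography_model("constant", theta = 4)
  a1 <- simulate_alignment(m, sim_config(n = 12, L = 200, seed = 77))
  a2 <- simulate_alignment(m, sim_config(n = 12, L = 200, seed = 77))
  expect_identical(a1$alignment$seq, a2$alignment$seq)
  a3 <- simulate_alignment(m, sim_config(n = 12, L = 200, seed = 78))
  expect_false(identical(a1$alignment$seq, a3$alignment$seq))
})

test_that("fixed_S places exactly S mutation events", {
  m <- demography_model("constant", theta = 4)
  for (s in c(0L, 3L, 7L)) {
    sim <- simulate_alignment(m, sim_config(n = 6, L = 100, seed = 100 + s,
                                            fixed_S = s))
    expect_equal(attr(sim$alignment, "n_mutations"), s)
  }
  # zero-length tree: identical sequences
  m0 <- demography_model("sudden_expansion", theta0 = 1e-8, theta1 = 1e8,
                         tau = 0)
  sim0 <- simulate_alignment(m0, sim_config(n = 5, L = 50, seed = 3))
  expect_equal(length(unique(unname(sim0$alignment$seq))), 1)
})

test_that("realised transition bias matches kappa", {
  set.seed(55)
  kappa <- 5.33
  L <- 1000000L  # large so multiple hits barely scramble the site classes
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mut <- mitopop:::mutate_lineage(s, 30000L, kappa, L)
  changed <- which(s != mut)
  purine <- function(x) x %in% c("A", "G")
  is_ts <- purine(s[changed]) == purine(mut[changed])
  ratio <- sum(is_ts) / sum(!is_ts)
  # 30k draws at p_ts = kappa/(kappa+1): 3 binomial SEs on the ratio is
  # about +-0.25, plus a small downward multi-hit bias
  expect_gt(ratio, 4.95)
  expect_lt(ratio, 5.75)
})

test_that("pairwise coalescent expectation holds for n = 2", {
  m <- demography_model("constant", theta = 3)
  set.seed(21)
  diffs <- replicate(800, {
    tree <- simulate_genealogy(m, sim_config(n = 2, L = 1000))
    sum(tree$edge_length)  # total tree length = 2 * T * theta/2
  })
  # E[pairwise mutational distance] = theta; SE = theta/sqrt(n)
  expect_lt(abs(mean(diffs) - 3), 3 * 3 / sqrt(800))
})

test_that("deep isolated splits separate demes far beyond within-deme variation", {
  m <- demography_model("two_deme_split", theta = 2, split_tau = 40,
                        migration = 0)
  sim <- simulate_alignment(m, sim_config(n = c(6, 6), L = 2000, seed = 31))
  pc <- mitopop:::pairwise_base_counts(sim$alignment)
  within <- c(pc$diff[1:6, 1:6][upper.tri(diag(6))],
              pc$diff[7:12, 7:12][upper.tri(diag(6))])
  across <- pc$diff[1:6, 7:12]
  expect_gt(mean(across), mean(within) + 20)
  expect_setequal(unique(sim$popmap$population_id), c("d1", "d2"))
})

test_that("the infinite-sites null engine matches Watterson's expectation", {
  sims <- simulate_null_stats(n = 10, nsim = 1500, theta = 5, seed = 41)
  ES <- 5 * sum(1 / (1:9))
  sdS <- sqrt(5 * sum(1 / (1:9)) + 25 * sum(1 / (1:9)^2))
  expect_lt(abs(mean(sims$S) - ES), 3 * sdS / sqrt(1500))
  expect_lt(abs(mean(sims$k_bar) - 5), 3 * 5 / sqrt(1500))
  # fixed-S conditioning pins S exactly
  fx <- simulate_null_stats(n = 8, nsim = 50, fixed_S = 9, seed = 5)
  expect_true(all(fx$S == 9))
})

test_that("the study-like fixture is reproducible and carries real structure", {
  f1 <- make_study_like_dataset(seed = 11)
  f2 <- make_study_like_dataset(seed = 11)
  expect_identical(f1$alignment$seq, f2$alignment$seq)
  expect_identical(f1$popmap, f2$popmap)
  expect_setequal(unique(f1$popmap$group_id), c("E1", "E2", "W1", "W2"))
  expect_true(all(table(f1$popmap$population_id) <= 15))

  dir <- withr::local_tempdir()
  f3 <- make_study_like_dataset(seed = 11, dir = dir)
  expect_true(all(file.exists(f3$files)))
  back <- read_alignment(f3$files[["fasta"]], f3$files[["popmap"]])
  expect_identical(back$alignment$seq, f1$alignment$seq)

  # built-in hierarchical structure must be detectable
  dm <- distance_matrix(f1$alignment, "raw")
  res <- amova(dm, f1$popmap, n_perm = 200, seed = 4)
  expect_gt(unname(res$phi["CT"]), 0)
  expect_lt(unname(res$p["CT"]), 0.05)

  # negative control: no-structure variant shows near-zero differentiation
  f0 <- make_study_like_dataset(seed = 11, structured = FALSE)
  dm0 <- distance_matrix(f0$alignment, "raw")
  res0 <- amova(dm0, f0$popmap, n_perm = 0)
  expect_lt(abs(unname(res0$phi["ST"])), 0.12)
})
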