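test_that("fixed differences between groups put all variance among groups", {
  aln <- mk_aln(c("AAAA", "AAAA", "AAAT", "AAAT"))
  pm <- mk_popmap(aln$ids, c("p1", "p1", "p2", "p2"), c("g1", "g1", "g2", "g2"))
  dm <- distance_matrix(aln, "raw")
  res <- amova(dm, pm, n_perm = 0)
  expect_equal(unname(res$phi["ST"]), 1)
  expect_equal(unname(res$pct["a"]), 100)
})

test_that("identical sequences are flagged as degenerate, not silently zeroed", {
  aln <- mk_aln(rep("AAAA", 6))
  pm <- mk_popmap(aln$ids, rep(c("p1", "p2"), each = 3), rep(c("g1", "g2"), each = 3))
  dm <- distance_matrix(aln, "raw")
  res <- amova(dm, pm, n_perm = 10, seed = 1)
  expect_true(any(grepl("identical", res$flags)))
  expect_true(is.na(res$phi["ST"]))
})

test_that("variance components match the brute-force enumeration oracle", {
  set.seed(13)
  for (rep in 1:10) {
    # 3 populations x 4 sequences in 2 groups, random raw distances
    n <- 12
    ids <- paste0("s", 1:n)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    vals <- sample(0:8, n * (n - 1) / 2, replace = TRUE)
    D[upper.tri(D)] <- vals
    D <- D + t(D)
    pop <- rep(c("p1", "p2", "p3"), each = 4)
    grp <- c(rep("g1", 8), rep("g2", 4))
    pm <- mk_popmap(ids, pop, grp)
    res <- amova(D, pm, n_perm = 0)
    orc <- oracle_amova(D, as.integer(factor(pop)), as.integer(factor(grp)))
    expect_equal(unname(res$sigma2), unname(orc$sigma2), tolerance = 1e-10)
    expect_equal(unname(res$SS), unname(orc$SS), tolerance = 1e-10)
    expect_equal(unname(res$phi), unname(orc$phi), tolerance = 1e-10)
    expect_equal(sum(res$pct), 100, tolerance = 1e-9)
  }
})

test_that("one population per group reduces to a two-level analysis", {
  set.seed(29)
  aln <- rand_aln(9, 40)
  pm <- mk_popmap(aln$ids, rep(c("p1", "p2", "p3"), each = 3),
                  rep(c("g1", "g2", "g3"), each = 3))
  dm <- distance_matrix(aln, "raw")
  res <- amova(dm, pm, n_perm = 0)
  expect_equal(unname(res$phi["ST"]), unname(res$phi["CT"]), tolerance = 1e-12)
  expect_equal(unname(res$sigma2["b"]), 0)
})

test_that("grouping schemes are validated and drive the hierarchy", {
  aln <- mk_aln(c("AAAA", "AAAT", "AATT", "TTTT", "TTTA", "TTAA"))
  pm <- mk_popmap(aln$ids, rep(c("p1", "p2", "p3"), each = 2),
                  rep("g1", 6))
  dm <- distance_matrix(aln, "raw")
  sch <- grouping_scheme("byhand", c(p1 = "A", p2 = "A", p3 = "B"))
  res <- amova(dm, pm, scheme = sch, n_perm = 50, seed = 2)
  expect_equal(res$scheme, "byhand")
  expect_true(all(res$p[!is.na(res$p)] > 0 & res$p[!is.na(res$p)] <= 1))
  expect_error(amova(dm, pm, scheme = grouping_scheme("bad", c(p1 = "A", p2 = "B")),
                     n_perm = 0), "not assigned")
  expect_error(grouping_scheme("one", c(p1 = "A", p2 = "A")), "at least 2")
})

test_that("permutation p-values are reproducible under a seed", {
  set.seed(51)
  aln <- rand_aln(12, 30)
  pm <- mk_popmap(aln$ids, rep(c("p1", "p2", "p3", "p4"), each = 3),
                  rep(c("g1", "g2"), each = 6))
  dm <- distance_matrix(aln, "raw")
  r1 <- amova(dm, pm, n_perm = 100, seed = 7)
  r2 <- amova(dm, pm, n_perm = 100, seed = 7)
  expect_identical(r1$p, r2$p)
})

test_that("pairwise Fst is 1 for fixed differences and matches the oracle", {
  aln <- mk_aln(c("AAAA", "AAAA", "AAAA", "AAAT", "AAAT", "AAAT"))
  pm <- mk_popmap(aln$ids, rep(c("p1", "p2"), each = 3))
  dm <- distance_matrix(aln, "raw")
  fst <- pairwise_fst(dm, pm, n_perm = 50, seed = 3)
  expect_equal(fst$fst["p1", "p2"], 1)
  expect_true(fst$p["p1", "p2"] > 0 && fst$p["p1", "p2"] <= 1)

  # hand 2-deme example against the enumeration oracle (two-level AMOVA)
  set.seed(9)
  aln2 <- rand_aln(10, 25)
  pm2 <- mk_popmap(aln2$ids, rep(c("p1", "p2"), each = 5))
  dm2 <- distance_matrix(aln2, "raw")
  got <- pairwise_fst(dm2, pm2, n_perm = 0)$fst["p1", "p2"]
  # independent two-level variance components by direct pair enumeration
  pair_ss <- function(members) {
    s <- 0
    for (a in members) for (b in members) if (a < b) s <- s + dm2[a, b]
    s
  }
  SS_total <- pair_ss(1:10) / 10
  SS_WP <- pair_ss(1:5) / 5 + pair_ss(6:10) / 5
  sigma_c <- SS_WP / 8
  nc <- (10 - (25 + 25) / 10) / 1
  sigma_a <- ((SS_total - SS_WP) / 1 - sigma_c) / nc
  expect_equal(unname(got), sigma_a / (sigma_a + sigma_c), tolerance = 1e-10)
})

test_that("singleton-singleton pairs are skipped with a warning", {
  aln <- mk_aln(c("AAAA", "AAAT", "AATT", "ATTT"))
  pm <- mk_popmap(aln$ids, c("p1", "p2", "p3", "p3"))
  dm <- distance_matrix(aln, "raw")
  expect_warning(fst <- pairwise_fst(dm, pm, n_perm = 10, seed = 1), "skipped")
  expect_true(is.na(fst$fst["p1", "p2"]))
  expect_false(is.na(fst$fst["p1", "p3"]))
})
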