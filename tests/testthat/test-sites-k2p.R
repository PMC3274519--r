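test_that("site classification separates conserved/variable and ts/tv", {
  sc <- classify_sites(c("ACGT", "ACGA"))
  expect_equal(sc$conserved, 3)
  expect_equal(sc$variable, 1)
  expect_equal(sc$transitions, 0)
  expect_equal(sc$transversions, 1)  # T<->A

  sc2 <- classify_sites(c("AAAA", "GAAA", "GAAC"))
  expect_equal(sc2$variable, 2)
  expect_equal(sc2$transitions, 1)   # A<->G
  expect_equal(sc2$transversions, 1) # A<->C
  expect_equal(sc2$ts_tv, 1)
  expect_equal(sc2$ratio_reported, sc2$ts_tv)
})

test_that("all-gap/all-N columns are excluded and logged", {
  expect_message(sc <- classify_sites(c("A-GN", "A-CN")), "excluded")
  expect_equal(sc$excluded_sites, c(2L, 4L))
  expect_equal(sc$analyzed, 2)
  expect_equal(sc$conserved + sc$variable, sc$analyzed)
})

test_that("variability is invariant under haplotype collapsing", {
  set.seed(17)
  for (rep in 1:15) {
    pool <- replicate(4, paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                               collapse = ""))
    aln <- mk_aln(sample(pool, 10, replace = TRUE))
    haps <- collapse_haplotypes(aln)
    if (length(haps$seq) < 2) next
    expect_equal(classify_sites(haps)$variable, classify_sites(aln)$variable)
    expect_equal(classify_sites(haps)$conserved, classify_sites(aln)$conserved)
  }
})

test_that("singleton vs parsimony-informative classification weights haplotype counts", {
  # site 1: G occurs once among 4 samples -> singleton; site 2: 2 vs 2 -> informative
  aln <- mk_aln(c("AA", "AA", "AT", "GT"))
  sc <- classify_sites(collapse_haplotypes(aln))
  expect_equal(sc$singleton, 1)
  expect_equal(sc$parsimony_informative, 1)
})

test_that("K2P distance matches the closed form and flags saturation", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0, ignore_attr = TRUE)
  # one transition among 10 sites: P = 0.1
  a10 <- strrep1("A", 10)
  ts1 <- paste0("G", strrep1("A", 9))
  tv1 <- paste0("C", strrep1("A", 9))
  expect_equal(k2p_distance(a10, ts1), -0.5 * log(0.8), ignore_attr = TRUE)
  expect_equal(k2p_distance(a10, tv1), -0.5 * log(0.9) - 0.25 * log(0.8),
               ignore_attr = TRUE)
  # P = 0.5 saturates the first logarithm
  sat <- k2p_distance(strrep1("AG", 10), strrep1("GA", 10))
  expect_true(is.nan(sat))
  expect_true(attr(sat, "saturated"))
  # no comparable sites
  expect_error(k2p_distance("NN", "AA"), "comparable")
})

test_that("K2P is symmetric, zero on identity, and dominates the p-distance", {
  set.seed(23)
  for (rep in 1:300) {
    L <- 40
    a <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    b <- strsplit(a, "")[[1]]
    flip <- sample(L, sample(1:4, 1))
    for (i in flip) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    b <- paste(b, collapse = "")
    d_ab <- k2p_distance(a, b)
    expect_equal(d_ab, k2p_distance(b, a))
    expect_gte(d_ab, oracle_p_distance(a, b) - 1e-12)
  }
})

test_that("changing a matching site to a transition strictly increases K2P", {
  a <- strrep1("A", 30)
  b <- paste0("G", strrep1("A", 29))       # 1 transition
  b2 <- paste0("GG", strrep1("A", 28))     # 2 transitions
  expect_gt(k2p_distance(a, b2), k2p_distance(a, b))
})

test_that("distance_matrix agrees with an established K2P implementation", {
  # related sequences at realistic divergence (saturation-free)
  m <- demography_model("constant", theta = 8)
  aln <- simulate_alignment(m, sim_config(n = 12, L = 300, seed = 5))$alignment
  dm <- distance_matrix(aln, model = "K2P")
  bin <- ape::as.DNAbin(lapply(aln$seq, function(s)
    strsplit(tolower(s), "")[[1]]))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(dm), unname(ref[rownames(dm), colnames(dm)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # raw model counts differing sites
  raw <- distance_matrix(aln, model = "raw")
  expect_true(all(raw == t(raw)))
  expect_true(all(diag(raw) == 0))
})

test_that("group_mean_k2p averages over all between-group pairs", {
  dm <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  dm["x", "z"] <- dm["z", "x"] <- 0.02
  dm["y", "z"] <- dm["z", "y"] <- 0.04
  dm["x", "y"] <- dm["y", "x"] <- 0.5
  pm <- mk_popmap(c("x", "y", "z"), c("p1", "p1", "p2"), c("E", "E", "W"))
  expect_equal(group_mean_k2p(dm, pm, "E", "W"), 0.03)
  expect_error(group_mean_k2p(dm, pm, "E", "Q"), "unknown")
})

test_that("distance matrices export as square TSV and PHYLIP lower triangle", {
  dm <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dir <- withr::local_tempdir()
  sq <- file.path(dir, "sq.tsv")
  write_distance_matrix(dm, sq)
  back <- as.matrix(read.delim(sq, row.names = 1))
  expect_equal(unname(back), unname(dm))
  lt <- file.path(dir, "lt.tsv")
  write_distance_matrix(dm, lt, lower_triangle = TRUE)
  lines <- readLines(lt)
  expect_equal(lines[1], "3")
  expect_match(lines[3], "^b\t1")
})
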