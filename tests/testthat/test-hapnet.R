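test_that("weighted distance applies per-class weights", {
  cfg <- network_config()
  expect_equal(weighted_distance("AAA", "AAA", cfg), 0)
  expect_equal(weighted_distance("AAA", "GAA", cfg), 1)   # one transition
  expect_equal(weighted_distance("AAA", "TAC", cfg), 10)  # two transversions
  expect_equal(weighted_distance("AN-A", "GNTA", cfg), 1) # ambiguous excluded
  cfg2 <- network_config(weight_transversion = 3, weight_transition = 2)
  expect_equal(weighted_distance("AAA", "TGA", cfg2), 5)
})

test_that("two haplotypes one step apart give a single weight-1 edge", {
  haps <- collapse_haplotypes(mk_aln(c("AAAA", "GAAA")))
  net <- median_joining(haps)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 1)
  expect_equal(net$edges$ts, 1)
  expect_true(all(net$nodes$observed))
})

test_that("the three-haplotype star gains its central median vector", {
  # binary-recoded 000/110/011 over three transition sites
  haps <- collapse_haplotypes(mk_aln(c("AAA", "GGA", "AGG")))
  net <- median_joining(haps)
  expect_equal(sum(!net$nodes$observed), 1)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  expect_equal(net$min_cost, 3)  # star beats any spanning tree (cost 4)
  expect_equal(net$min_cost, oracle_steiner_cost(c("AAA", "GGA", "AGG")))
})

test_that("epsilon-0 pre-median network equals the unique MST when distances are distinct", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    D <- matrix(0, n, n)
    vals <- sample(1:60, n * (n - 1) / 2)  # all distinct
    D[upper.tri(D)] <- vals
    D <- D + t(D)
    got <- mitopop:::msn_edges(D, 0L)
    mst <- oracle_kruskal(D)
    expect_equal(nrow(got), n - 1)
    expect_equal(sum(got[, "weight"]), mst$cost)
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_setequal(key(got), key(mst$edges))
  }
})

test_that("pruning keeps every observed haplotype and a connected graph", {
  set.seed(71)
  for (rep in 1:20) {
    m <- demography_model("constant", theta = 3)
    sim <- simulate_alignment(m, sim_config(n = 8, L = 60))
    haps <- collapse_haplotypes(sim$alignment)
    if (length(haps$seq) < 2) next
    net <- suppressMessages(median_joining(haps))
    expect_setequal(net$nodes$id[net$nodes$observed], names(haps$seq))
    g <- as_igraph(net)
    expect_true(igraph::is_connected(g))
    # a tree passes through pruning unchanged
    if (nrow(net$edges) == nrow(net$nodes) - 1 && all(net$nodes$observed)) {
      again <- mp_prune(net)
      expect_equal(nrow(again$edges), nrow(net$edges))
    }
  }
})

test_that("network construction is deterministic", {
  m <- demography_model("sudden_expansion", theta0 = 0.5, theta1 = 50, tau = 4)
  sim <- simulate_alignment(m, sim_config(n = 20, L = 200, seed = 99))
  haps <- collapse_haplotypes(sim$alignment)
  n1 <- suppressMessages(median_joining(haps))
  n2 <- suppressMessages(median_joining(haps))
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("pruned cost never exceeds the observed-haplotype MST cost", {
  set.seed(83)
  cfg <- network_config()
  for (rep in 1:25) {
    m <- demography_model("constant", theta = 2.5)
    sim <- simulate_alignment(m, sim_config(n = 7, L = 50))
    haps <- collapse_haplotypes(sim$alignment)
    if (length(haps$seq) < 3) next
    net <- suppressMessages(median_joining(haps, cfg))
    k <- length(haps$seq)
    D <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      D[i, j] <- D[j, i] <- weighted_distance(haps$seq[[i]], haps$seq[[j]], cfg)
    expect_lte(net$min_cost, oracle_kruskal(D)$cost + 1e-9)
  }
})

test_that("GraphML export round-trips topology, frequencies and attributes", {
  aln <- mk_aln(c("AAAA", "AAAA", "GAAA"))
  pm <- mk_popmap(aln$ids, c("p1", "p2", "p2"))
  haps <- collapse_haplotypes(aln, pm)
  net <- median_joining(haps)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "net.graphml")
  export_network(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(sort(igraph::V(g)$freq, decreasing = TRUE), c(2, 1))
  # conservation: node frequencies sum to the sample count
  expect_equal(sum(igraph::V(g)$freq), 3)
  expect_equal(igraph::E(g)$weight, 1)
  # population composition annotation survives
  expect_true(any(grepl("p1:1", igraph::V(g)$pops)))
  # DOT and TSV variants write without error
  expect_silent(export_network(net, file.path(dir, "net.dot")))
  expect_silent(export_network(net, file.path(dir, "net.tsv")))
  expect_error(export_network(net, file.path(dir, "missing_dir", "x.graphml")))
})

test_that("a star genealogy yields a star network with the ancestor central", {
  anc <- strrep1("A", 8)
  sing <- vapply(1:5, function(i) {
    v <- strsplit(anc, "")[[1]]; v[i] <- "G"; paste(v, collapse = "")
  }, character(1))
  aln <- mk_aln(c(rep(anc, 4), sing))
  haps <- collapse_haplotypes(aln)
  net <- median_joining(haps)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  hub <- names(which.max(deg))
  expect_equal(unname(deg[hub]), 5)
  # the hub is the observed ancestral haplotype, not an inferred median
  expect_equal(unname(haps$seq[hub]), anc)
  expect_equal(nrow(net$edges), 5)
  expect_true(all(net$edges$weight == 1))
})
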