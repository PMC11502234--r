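test_that("channel score combination follows the prior-corrected product rule", {
  # single channel passes through unchanged
  expect_equal(combineChannelScores(matrix(0.95, 1, 1)), 0.95,
               tolerance = 1e-12)
  # no evidence collapses to the prior
  expect_equal(combineChannelScores(matrix(0, 1, 3)), 0.041)
  # two channels: hand-computed combination
  p0 <- 0.041
  s <- c(0.8, 0.6)
  sp <- (s - p0) / (1 - p0)
  expect_equal(combineChannelScores(matrix(s, 1, 2)),
               (1 - prod(1 - sp)) * (1 - p0) + p0, tolerance = 1e-12)
  expect_error(combineChannelScores(matrix(1.2, 1, 1)), "\\[0, 1\\]")
})

test_that("STRING-dialect loading filters channels, thresholds, and orphan nodes", {
  path <- stringToyFile()
  g <- loadInteractions(path)          # experiments + databases + fusion, 0.9
  el <- igraph::as_data_frame(g)
  # the textmining-only edge is excluded, so C disappears; B-D falls below
  # 0.9, so D disappears and only A-B survives
  expect_equal(nrow(el), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(el$combined_score, 950)

  # admitting textmining brings A-C back
  g2 <- loadInteractions(path, channels = c("experiments", "databases",
                                            "fusion", "textmining"))
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))

  # lowering the threshold keeps the weak edge
  g3 <- loadInteractions(path, minCombined = 0.4)
  expect_setequal(igraph::V(g3)$name, c("A", "B", "D"))

  expect_error(loadInteractions(path, channels = "speculation"),
               "unknown channel")
  bad <- read.table(path, header = TRUE)
  bad$experimental[1] <- 1500
  expect_error(loadInteractions(bad), "malformed")
})

test_that("MCC matches its closed forms and stays local under pendant additions", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  expect_equal(mccScores(k3)$mcc, rep(2, 3))

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  mc <- mccScores(star)
  expect_equal(mc$mcc[mc$node == "hub"], 3)      # edgeless neighborhood: degree
  expect_equal(mc$mcc[mc$node == "l1"], 1)

  for (n in 4:7) {
    kn <- igraph::make_full_graph(n)
    igraph::V(kn)$name <- paste0("v", seq_len(n))
    expect_equal(mccScores(kn)$mcc, rep(factorial(n - 1), n))
  }

  set.seed(3)
  g <- igraph::sample_pa(30, m = 2, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:30)
  before <- mccScores(g)
  g2 <- igraph::add_vertices(g, 1, name = "leaf")
  g2 <- igraph::add_edges(g2, c("v5", "leaf"))
  after <- mccScores(g2)
  others <- setdiff(igraph::V(g)$name, "v5")
  expect_equal(after$mcc[match(others, after$node)],
               before$mcc[match(others, before$node)])
  expect_equal(after$mcc[after$node == "v5"],
               before$mcc[before$node == "v5"] + 1)

  directed <- igraph::make_ring(4, directed = TRUE)
  expect_error(mccScores(directed), "undirected")
  two <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_error(mccScores(two, maxCliques = 1), "guard")
})

test_that("MCC agrees with the exhaustive subset oracle on random graphs", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.15, 0.5))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    mc <- mccScores(g)
    o <- oracleMCC(g)
    expect_equal(mc$mcc[match(names(o), mc$node)], unname(o))
  }
})

test_that("topological coefficients follow the shared-neighbor formula", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(unname(topologicalCoefficients(tri)), rep(1, 3))

  path <- igraph::make_graph(~ a - b, b - c)
  tc <- topologicalCoefficients(path)
  expect_equal(unname(tc[c("a", "c")]), c(1, 1))   # share neighbor b, J=1, k=1
  expect_equal(unname(tc["b"]), 0)                 # nothing shares b's neighbors

  set.seed(2)
  pa <- igraph::sample_pa(300, m = 2, directed = FALSE)
  igraph::V(pa)$name <- paste0("v", 1:300)
  tcv <- topologicalCoefficients(pa)
  deg <- igraph::degree(pa)
  expect_lt(cor(deg, tcv, method = "spearman"), 0)
})

test_that("node deletion prunes disconnected remainders and keeps stats consistent", {
  # two triangles joined through one bridge node
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d,
                          a - x, x - d)
  res <- deleteNodesStats(g, "x")
  expect_equal(res$after$n_components, 2)
  expect_equal(res$after$n_edges, 6)
  expect_length(res$removedDisconnected, 0)
  expect_equal(res$before$n_edges,
               sum(igraph::degree(g)) / 2)
  expect_equal(res$after$avg_degree, 2 * res$after$n_edges / res$after$n_nodes)

  none <- deleteNodesStats(g, character())
  expect_equal(none$after, none$before)
  expect_error(deleteNodesStats(g, "zz"), "unknown node")

  # a node isolated by the deletion is itself removed
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  pruned <- deleteNodesStats(star, "hub")
  expect_equal(pruned$after$n_nodes, 0)
  expect_setequal(pruned$removedDisconnected, c("l1", "l2", "l3"))
})

test_that("seeded growth admits candidates only through direct contact with the network", {
  g <- igraph::make_graph(~ A - B, A - C, C - D, D - E, F - G)
  grown <- growSeededNetwork(c("A", "B"), c("C", "D", "E", "F", "G"), g)
  # C touches A, D touches C, E touches D; F-G never touch the network
  expect_setequal(igraph::V(grown)$name, c("A", "B", "C", "D", "E"))
  expect_equal(igraph::ecount(grown), 4)

  onlyChain <- growSeededNetwork("A", c("F", "G"), g)
  expect_setequal(igraph::V(onlyChain)$name, "A")

  # 8-node toy: hand-derived closure
  toy <- igraph::make_graph(~ s1 - s2, s2 - s3, s1 - c1, c1 - c2, c2 - c3,
                            c4 - c5, s3 - n1)
  grown2 <- growSeededNetwork(c("s1", "s2", "s3"),
                              c("c1", "c2", "c3", "c4", "c5"), toy)
  expect_setequal(igraph::V(grown2)$name,
                  c("s1", "s2", "s3", "c1", "c2", "c3"))

  # monotone in candidates
  less <- growSeededNetwork(c("s1", "s2", "s3"), c("c1", "c2"), toy)
  expect_true(all(igraph::V(less)$name %in% igraph::V(grown2)$name))

  expect_warning(empty <- growSeededNetwork("nope", "c1", toy), "no seed")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("hypergeometric enrichment reproduces closed-form worked examples", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5))
  res <- hypergeomEnrichment(paste0("g", 1:5), sets, universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  # 2x2 table (3,2,2,13) -> odds ratio 9.75
  sets2 <- list(s = paste0("g", c(1, 2, 3, 6, 7)))
  res2 <- hypergeomEnrichment(paste0("g", 1:5), sets2, universe)
  expect_equal(res2$overlap, 3)
  expect_equal(res2$oddsRatio, (3 * 13) / (2 * 2))

  # overlap at expectation sits in the upper tail's lower half
  universe3 <- paste0("g", 1:100)
  sets3 <- list(s = paste0("g", 1:50))
  res3 <- hypergeomEnrichment(paste0("g", seq(1, 100, by = 10)), sets3,
                              universe3)
  expect_equal(res3$overlap, 5)
  expect_gt(res3$p, 0.5)

  expect_error(hypergeomEnrichment("g1", sets, character()), "empty universe")
  expect_error(hypergeomEnrichment("zz", sets, universe), "missing")
})

test_that("enrichment p-values are near-uniform for random queries", {
  universe <- paste0("g", 1:1000)
  set.seed(21)
  sets <- lapply(1:4, function(i) sample(universe, 200))
  names(sets) <- paste0("s", 1:4)
  ps <- replicate(50, {
    q <- sample(universe, 200)
    hypergeomEnrichment(q, sets, universe)$p
  })
  expect_gt(suppressWarnings(ks.test(as.numeric(ps), "punif"))$p.value, 0.01)
})
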