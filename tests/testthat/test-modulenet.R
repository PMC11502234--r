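test_that("topological overlap matches the double-loop oracle and its closed forms", {
  # hand-set correlations 0.9 / 0.6 / 0.3 at beta = 2, via data constructed
  # with exactly those sample correlations
  R <- matrix(c(1, 0.9, 0.6,
                0.9, 1, 0.3,
                0.6, 0.3, 1), 3, 3)
  x <- exactCorData(R, n = 12, seed = 2)
  rownames(x) <- paste0("g", 1:3)
  net <- buildTOM(x, power = 2)
  a <- abs(R)^2; diag(a) <- 1
  dimnames(a) <- dimnames(adjacencyMatrix(net))
  expect_equal(adjacencyMatrix(net), a, tolerance = 1e-12)
  expect_equal(tomMatrix(net), oracleTOM(a), tolerance = 1e-12)

  # random instances against the same oracle
  set.seed(5)
  for (i in 1:10) {
    y <- matrix(rnorm(15 * 10), 15, 10)
    rownames(y) <- paste0("g", 1:15)
    nt <- buildTOM(y, power = 3)
    expect_equal(tomMatrix(nt), oracleTOM(adjacencyMatrix(nt)),
                 tolerance = 1e-10)
    expect_true(all(tomMatrix(nt) >= 0 & tomMatrix(nt) <= 1))
    expect_equal(tomMatrix(nt), t(tomMatrix(nt)))
  }

  # two identical genes: unit adjacency and unit overlap
  z <- rbind(g1 = rnorm(10), g2 = 0)
  z["g2", ] <- z["g1", ]
  n2 <- buildTOM(z, power = 6)
  expect_equal(unname(adjacencyMatrix(n2)["g1", "g2"]), 1)
  expect_equal(unname(tomMatrix(n2)["g1", "g2"]), 1)

  zz <- rbind(z, g3 = rep(1, 10))
  expect_warning(buildTOM(zz, power = 2), "zero-variance")
})

test_that("soft power selection follows the scale-free criterion with a plateau fallback", {
  mods <- list(list(size = 100, rho = 0.6, loading = c(0.5, 1.5)),
               list(size = 100, rho = -0.6, loading = c(0.5, 1.5)))
  sim <- simulateBulkCounts(simConfig(nGenes = 600, modules = mods, seed = 2))
  ne <- normChain(sim$counts)
  sp <- pickSoftPower(ne)
  expect_true(sp$fits$r2[sp$fits$power == sp$power] >= 0.8)
  # mean connectivity strictly decreases with the power
  expect_true(all(diff(sp$fits$meanK) < 0))

  white <- matrix(rnorm(120 * 10), 120, 10)
  rownames(white) <- paste0("g", seq_len(nrow(white)))
  expect_warning(pickSoftPower(white, candidates = 1:8), "plateau")
  expect_error(pickSoftPower(white[, 1:3]), "4 samples")
})

test_that("planted modules are recovered and pure noise stays unassigned", {
  sim <- simulateBulkCounts(simConfig(nGenes = 2000,
                                      modules = canonicalModules(), seed = 1))
  ne <- normChain(sim$counts)
  sp <- suppressWarnings(pickSoftPower(ne))
  ms <- detectModules(buildTOM(ne, sp$power), ne)
  truth <- sim$truth$module_map[names(moduleLabels(ms))]
  sel <- truth %in% c("M1", "M2")
  expect_gte(mclust::adjustedRandIndex(moduleLabels(ms)[sel], truth[sel]), 0.7)

  for (s in 1:2) {
    noise <- simulateBulkCounts(simConfig(nGenes = 800, seed = 400 + s))
    neN <- normChain(noise$counts)
    spN <- suppressWarnings(pickSoftPower(neN))
    msN <- detectModules(buildTOM(neN, spN$power), neN)
    expect_gte(mean(moduleLabels(msN) == "unassigned"), 0.8)
  }

  # minSize above the largest planted module: the planted module cannot
  # appear as a detected module (at most diluted inside a larger cluster)
  small <- simulateBulkCounts(simConfig(
    nGenes = 400, modules = list(list(size = 60, rho = 0.8,
                                      loading = c(0.5, 1.5))), seed = 5))
  neS <- normChain(small$counts)
  planted <- names(small$truth$module_map)[small$truth$module_map == "M1"]
  msOK <- detectModules(buildTOM(neS, 6), neS)
  okLab <- moduleLabels(msOK)
  expect_true(any(vapply(names(moduleSizes(msOK)), function(m)
    mean(names(okLab)[okLab == m] %in% planted) >= 0.5, logical(1))))
  msS <- detectModules(buildTOM(neS, 6), neS, minSize = 100)
  lab <- moduleLabels(msS)
  expect_true(all(moduleSizes(msS) >= 100))
  for (m in names(moduleSizes(msS)))
    expect_lt(mean(names(lab)[lab == m] %in% planted), 0.8)
})

test_that("eigengene orientation is stable under global sign flips", {
  sim <- simulateBulkCounts(simConfig(
    nGenes = 400, modules = list(list(size = 80, rho = 0.8,
                                      loading = c(0.5, 1.5))), seed = 8))
  ne <- normChain(sim$counts)
  v <- exprValues(ne)
  assignment <- sim$truth$module_map[rownames(v)]
  names(assignment) <- rownames(v)
  assignment[assignment == "none"] <- "unassigned"
  eg <- computeEigengenes(v, assignment)
  expect_equal(unname(sqrt(rowSums(eg^2))), rep(1, nrow(eg)))

  vFlip <- v
  mem <- names(assignment)[assignment == "M1"]
  vFlip[mem, ] <- -vFlip[mem, ]
  egFlip <- computeEigengenes(vFlip, assignment)
  expect_equal(abs(cor(eg["M1", ], egFlip["M1", ])), 1, tolerance = 1e-8)
  mm <- abs(cor(t(v[mem, ]), eg["M1", ]))
  mmFlip <- abs(cor(t(vFlip[mem, ]), egFlip["M1", ]))
  expect_equal(mm, mmFlip, tolerance = 1e-8)
})

test_that("module-trait statistics use the exact t-transform of r", {
  eg <- matrix(rnorm(24), 2, 12,
               dimnames = list(c("M1", "M2"), paste0("s", 1:12)))
  trait <- rep(c("WT", "MUT"), each = 6)
  traitNum <- as.numeric(trait == "MUT")
  eg["M1", ] <- scale(traitNum)[, 1] / sqrt(11)   # unit-norm copy of trait
  ms <- new("ModuleSet",
            assignment = setNames(rep(c("M1", "M2"), 5), paste0("g", 1:10)),
            eigengenes = eg / sqrt(rowSums(eg^2)))
  st <- moduleTraitStats(ms, data.frame(trait = trait), covariates = "trait")
  expect_equal(st$r[st$module == "M1"], 1, tolerance = 1e-10)
  r2 <- st$r[st$module == "M2"]
  oracle <- cor.test(eigengenes(ms)["M2", ], traitNum)
  expect_equal(r2, unname(oracle$estimate), tolerance = 1e-10)
  expect_equal(st$p[st$module == "M2"], oracle$p.value, tolerance = 1e-10)
  expect_error(moduleTraitStats(ms, data.frame(trait = rep("WT", 12))),
               "zero-variance")
})

test_that("gene significance and module membership hit their degenerate identities", {
  sim <- simulateBulkCounts(simConfig(
    nGenes = 300, modules = list(list(size = 80, rho = 0.9,
                                      loading = c(0.5, 1.5))), seed = 12))
  ne <- normChain(sim$counts)
  v <- exprValues(ne)
  assignment <- setNames(sim$truth$module_map[rownames(v)], rownames(v))
  assignment[assignment == "none"] <- "unassigned"
  eg <- computeEigengenes(v, assignment)
  ms <- new("ModuleSet", assignment = assignment, eigengenes = eg)
  sd0 <- as.data.frame(SummarizedExperiment::colData(ne))

  # a gene equal to its eigengene has MM = 1; one equal to the trait, |GS| = 1
  mem <- names(assignment)[assignment == "M1"]
  v[mem[1], ] <- eg["M1", ]
  v[mem[2], ] <- as.numeric(sd0$trait != levels(sd0$trait)[1])
  gms <- geneModuleStats(v, ms, sd0)
  expect_equal(gms$geneStats$MM[gms$geneStats$gene == mem[1]], 1,
               tolerance = 1e-10)
  expect_equal(abs(gms$geneStats$GS[gms$geneStats$gene == mem[2]]), 1,
               tolerance = 1e-10)
  # trait-linked planted module: GS and MM rise together
  row <- gms$gsMM[gms$gsMM$module == "M1", ]
  expect_gt(row$r, 0.4)
  expect_lt(row$p, 0.01)
})

test_that("permutation ranks are exchangeable for a trait-independent module", {
  # 200 small replicates, 9 permutations each: the observed |r|'s rank among
  # the permuted values must be uniform on 1..10
  nPerm <- 9
  ranks <- integer(200)
  for (b in seq_len(200)) {
    sim <- simulateBulkCounts(simConfig(
      nGenes = 150, modules = list(list(size = 40, rho = 0,
                                        loading = c(0.5, 1.5))),
      seed = 5000 + b))
    ne <- cpmLogPedestal(sim$counts)
    v <- exprValues(ne)
    assignment <- setNames(sim$truth$module_map[rownames(v)], rownames(v))
    assignment[assignment == "none"] <- "unassigned"
    ms <- new("ModuleSet", assignment = assignment,
              eigengenes = computeEigengenes(v, assignment))
    sd0 <- as.data.frame(SummarizedExperiment::colData(ne))
    pv <- permuteModuleValidation(v, ms, sd0, nPerm = nPerm, seed = b)
    ranks[b] <- 1L + sum(abs(pv$permuted$r) >= abs(pv$observed$r[1]))
  }
  tab <- tabulate(ranks, nbins = nPerm + 1)
  expect_gt(chisq.test(tab)$p.value, 0.01)
  expect_error(permuteModuleValidation(matrix(1, 2, 2),
                                       new("ModuleSet",
                                           assignment = c(g1 = "unassigned"),
                                           eigengenes = matrix(numeric(), 0, 2)),
                                       data.frame(trait = c("a", "b")),
                                       nPerm = 0), "nPerm")
})

test_that("driver selection takes the MM percentile with ties included", {
  gs <- data.frame(gene = sprintf("g%03d", 1:100), module = "M1",
                   MM = seq(0.01, 1, length.out = 100), GS = 0)
  dr <- selectDrivers(gs, 95)
  expect_setequal(dr$M1, sprintf("g%03d", 96:100))
  expect_setequal(selectDrivers(gs, 0)$M1, gs$gene)

  tied <- gs
  tied$MM[90:100] <- 0.9
  drT <- selectDrivers(tied, 95)
  expect_setequal(drT$M1, sprintf("g%03d", 90:100))   # all tied at the cutoff

  small <- data.frame(gene = paste0("g", 1:10), module = "M1",
                      MM = runif(10), GS = 0)
  expect_warning(selectDrivers(small, 95), "fewer than 20")
})

test_that("deleting drivers shifts module weights left, beyond matched random deletion", {
  sim <- simulateBulkCounts(simConfig(
    nGenes = 600, modules = list(list(size = 150, rho = 0.9,
                                      loading = c(0.5, 1.5))), seed = 17))
  ne <- normChain(sim$counts)
  v <- exprValues(ne)
  assignment <- setNames(sim$truth$module_map[rownames(v)], rownames(v))
  assignment[assignment == "none"] <- "unassigned"
  ms <- new("ModuleSet", assignment = assignment,
            eigengenes = computeEigengenes(v, assignment))
  sd0 <- as.data.frame(SummarizedExperiment::colData(ne))
  net <- buildTOM(ne, 6)
  gms <- geneModuleStats(ne, ms, sd0)
  drivers <- selectDrivers(gms$geneStats, 95)$M1

  res <- driverDeletionShift(net, ms, "M1", drivers)
  expect_gt(res$D, 0.1)
  expect_lt(res$p, 0.01)
  expect_identical(res$direction, "left")

  set.seed(1)
  mem <- names(assignment)[assignment == "M1"]
  rnd <- sample(setdiff(mem, drivers), length(drivers))
  resRnd <- driverDeletionShift(net, ms, "M1", rnd)
  expect_lt(resRnd$D, res$D)

  none <- driverDeletionShift(net, ms, "M1", character())
  expect_equal(none$D, 0)
  expect_match(none$note, "no drivers")
})
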