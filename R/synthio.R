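#' @importFrom stats rnorm runif rnbinom rpois resid lm sd cor quantile
#' @importFrom igraph sample_pa V E make_empty_graph vcount ecount
NULL

#' Assemble a count SummarizedExperiment from a matrix and sample table
#'
#' @param counts nonnegative integer gene x sample matrix with unique row and
#'   column names.
#' @param sampleData data.frame with one row per sample (same order as the
#'   matrix columns) holding at least `trait`, `batch` and `sex`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`.
#' @export
countExperiment <- function(counts, sampleData) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (max(abs(counts - round(counts))) > 0)
    stop("counts must be integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts need unique gene row names")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts need unique sample column names")
  if (nrow(sampleData) != ncol(counts))
    stop("sampleData must have one row per sample")
  if (!is.null(rownames(sampleData)) &&
      !identical(rownames(sampleData), colnames(counts)) &&
      !identical(rownames(sampleData), as.character(seq_len(nrow(sampleData)))))
    stop("sampleData rows do not match count columns")
  rownames(sampleData) <- colnames(counts)
  SummarizedExperiment(assays = list(counts = counts),
                       colData = S4Vectors::DataFrame(sampleData))
}

# balanced, crossed sample design: sex in blocks, batch interleaved, so that
# trait, batch and sex are mutually non-confounded
.designTable <- function(config) {
  n <- config@nPerGroup
  groups <- config@groups
  trait <- factor(rep(groups, each = n), levels = groups)
  sex <- factor(rep(rep(c("M", "F"), times = c(ceiling(n / 2), floor(n / 2))),
                    length(groups)), levels = c("M", "F"))
  batch <- factor(rep(rep(seq_len(config@nBatches), length.out = n),
                      length(groups)))
  ids <- paste0(rep(groups, each = n), "_", rep(seq_len(n), length(groups)))
  data.frame(sample = ids, trait = trait, batch = batch, sex = sex,
             stringsAsFactors = FALSE)
}

#' Simulate a bulk RNA-seq count experiment with known ground truth
#'
#' Draws negative-binomial counts around log-normal gene baselines scaled by
#' log-normal library sizes, in a balanced two-batch, mixed-sex design of
#' `nPerGroup` samples per trait group (the deposited design this emulates
#' used 6 mice per genotype, 3 of each sex, across two sequencing batches).
#' Planted differential expression shifts the test-group mean by
#' `2^deLog2FC`; planted coexpression modules share a latent per-sample
#' factor built as `rho * trait_z + sqrt(1 - rho^2) * noise_z` with the noise
#' component orthonormalized against the trait, so the factor's sample
#' correlation with the numeric trait equals `rho`; batches add gene-wise
#' additive log2-scale offsets.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `counts` (a `SummarizedExperiment`, assay
#'   `"counts"`, colData `trait`/`batch`/`sex`) and `truth` (list with
#'   `de_genes` data.frame of gene and signed log2FC, `module_map` named
#'   character vector gene -> module, `factor_scores` module x sample
#'   matrix).
#' @examples
#' sim <- simulateBulkCounts(simConfig(nGenes = 200, seed = 1))
#' dim(SummarizedExperiment::assay(sim$counts))
#' @export
simulateBulkCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)

  des <- .designTable(config)
  nS <- nrow(des)
  nG <- config@nGenes
  genes <- sprintf("gene%05d", seq_len(nG))

  baseline <- rnorm(nG, config@baselineLog2Mean, config@baselineLog2SD)

  # planted modules claim disjoint gene blocks; DE genes drawn from the rest
  # when possible so truth records stay unambiguous
  moduleMap <- setNames(rep("none", nG), genes)
  pool <- seq_len(nG)
  modNames <- if (length(config@modules))
    paste0("M", seq_along(config@modules)) else character()
  loadings <- numeric(nG)
  traitNum <- as.numeric(des$trait != levels(des$trait)[1])
  traitZ <- as.numeric(scale(traitNum))
  factorScores <- matrix(0, length(config@modules), nS,
                         dimnames = list(modNames, des$sample))
  for (i in seq_along(config@modules)) {
    m <- config@modules[[i]]
    idx <- sample(pool, m$size)
    pool <- setdiff(pool, idx)
    moduleMap[idx] <- modNames[i]
    eps <- rnorm(nS)
    eps <- resid(lm(eps ~ traitZ))          # exact orthogonality to trait
    eps <- eps / sqrt(sum(eps^2) / (nS - 1))
    f <- m$rho * traitZ + sqrt(1 - m$rho^2) * eps
    factorScores[i, ] <- f
    loadings[idx] <- runif(m$size, m$loading[1], m$loading[2])
  }

  nDE <- round(config@deFraction * nG)
  deIdx <- if (nDE > 0) {
    cand <- if (length(pool) >= nDE) pool else seq_len(nG)
    sort(sample(cand, nDE))
  } else integer()
  deSign <- rep(c(1, -1), length.out = nDE)
  deEffect <- numeric(nG)
  deEffect[deIdx] <- deSign * config@deLog2FC

  isTest <- as.numeric(des$trait != levels(des$trait)[1])
  batchShift <- matrix(0, nG, nS)
  if (config@nBatches > 1L) {
    delta <- matrix(rnorm(nG * (config@nBatches - 1L), 0, config@batchSD),
                    nG, config@nBatches - 1L)
    for (k in 2:config@nBatches)
      batchShift[, des$batch == k] <- delta[, k - 1L]
  }

  log2mu <- matrix(baseline, nG, nS) +
    outer(deEffect, isTest) + batchShift
  for (i in seq_along(config@modules)) {
    idx <- which(moduleMap == modNames[i])
    log2mu[idx, ] <- log2mu[idx, ] + outer(loadings[idx], factorScores[i, ])
  }

  rel <- 2^log2mu
  prop <- sweep(rel, 2L, colSums(rel), "/")
  libs <- exp(rnorm(nS, config@libSizeLogMean, config@libSizeLogSD))
  mu <- sweep(prop, 2L, libs, "*")

  counts <- if (config@nbDispersion < 1e-10) {
    matrix(rpois(nG * nS, lambda = mu), nG, nS)
  } else {
    matrix(rnbinom(nG * nS, mu = mu, size = 1 / config@nbDispersion), nG, nS)
  }
  dimnames(counts) <- list(genes, des$sample)

  se <- countExperiment(counts, des[, c("trait", "batch", "sex")])
  truth <- list(
    de_genes = data.frame(gene = genes[deIdx],
                          log2fc = deEffect[deIdx],
                          stringsAsFactors = FALSE),
    module_map = moduleMap,
    factor_scores = factorScores)
  list(counts = se, truth = truth)
}

#' Simulate a scale-free interactome with an optional planted clique
#'
#' Grows a preferential-attachment backbone (heavy-tailed degree
#' distribution), then plants a clique among the lowest-degree background
#' nodes. Each edge carries STRING-style evidence-channel scores in
#' [0, 1000] plus a combined score recomputed with the standard
#' prior-corrected product rule.
#'
#' @param nNodes number of nodes.
#' @param attachM edges added per step of preferential attachment (must be
#'   `< nNodes`).
#' @param plantedClique clique size (0 for none; otherwise >= 2 and
#'   `<= nNodes`).
#' @param seed integer seed.
#' @return list with `graph` (an [igraph::igraph] with edge attributes
#'   `experiments`, `databases`, `fusion`, `coexpression`, `textmining`,
#'   `neighborhood`, `combined_score`) and `truth` (list with `hub_nodes`,
#'   the planted clique member ids).
#' @export
simulateInteractome <- function(nNodes, attachM = 1, plantedClique = 0,
                                seed = 1) {
  if (attachM >= nNodes) stop("attachM must be smaller than nNodes")
  if (plantedClique > nNodes) stop("plantedClique must be <= nNodes")
  if (plantedClique == 1) stop("plantedClique must be 0 or >= 2")
  set.seed(seed)
  g <- igraph::sample_pa(nNodes, m = attachM, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("node%04d", seq_len(nNodes))

  hubs <- character()
  if (plantedClique >= 2) {
    deg <- igraph::degree(g)
    members <- order(deg, sample(nNodes))[seq_len(plantedClique)]
    hubs <- igraph::V(g)$name[members]
    pairs <- utils::combn(members, 2L)
    for (j in seq_len(ncol(pairs))) {
      if (!igraph::are_adjacent(g, pairs[1, j], pairs[2, j]))
        g <- igraph::add_edges(g, pairs[, j])
    }
  }

  m <- igraph::ecount(g)
  scores <- data.frame(
    experiments = sample(600:999, m, replace = TRUE),
    databases = ifelse(runif(m) < 0.5, sample(400:999, m, replace = TRUE), 0L),
    fusion = ifelse(runif(m) < 0.05, sample(300:900, m, replace = TRUE), 0L),
    coexpression = sample(0:800, m, replace = TRUE),
    textmining = sample(0:999, m, replace = TRUE),
    neighborhood = 0L)
  for (ch in names(scores)) g <- igraph::set_edge_attr(g, ch, value = scores[[ch]])
  comb <- combineChannelScores(as.matrix(scores) / 1000)
  g <- igraph::set_edge_attr(g, "combined_score", value = round(comb * 1000))
  list(graph = g, truth = list(hub_nodes = hubs))
}

#' Simulate a gene-set collection with one optionally planted enriched set
#'
#' Non-planted sets are drawn uniformly from the universe; the planted set is
#' forced to contain a specified number of genes from a query list.
#'
#' @param universe character vector of gene ids.
#' @param nSets number of background sets.
#' @param setSizeRange integer range of set sizes.
#' @param plantedQuery character vector of query genes (subset of universe),
#'   or NULL for no planted set.
#' @param plantedOverlap number of query genes forced into the planted set.
#' @param plantedSize size of the planted set (defaults to `plantedOverlap`).
#' @param seed integer seed.
#' @return list with `sets` (named list of character vectors) and `truth`
#'   (list with `enriched_sets`).
#' @export
simulateGeneSets <- function(universe, nSets, setSizeRange = c(10, 50),
                             plantedQuery = NULL, plantedOverlap = 0,
                             plantedSize = plantedOverlap, seed = 1) {
  set.seed(seed)
  sets <- list()
  if (nSets > 0) {
    sizes <- sample(setSizeRange[1]:setSizeRange[2], nSets, replace = TRUE)
    sizes <- pmin(sizes, length(universe))
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("set%03d", seq_len(nSets))
  }
  enriched <- character()
  if (!is.null(plantedQuery) && plantedOverlap > 0) {
    if (plantedOverlap > length(plantedQuery))
      stop("plantedOverlap exceeds the query size")
    if (plantedSize < plantedOverlap || plantedSize > length(universe))
      stop("plantedOverlap must be <= plantedSize <= universe size")
    core <- sample(plantedQuery, plantedOverlap)
    filler <- sample(setdiff(universe, plantedQuery),
                     plantedSize - plantedOverlap)
    sets[["planted"]] <- c(core, filler)
    enriched <- "planted"
  }
  if (anyDuplicated(names(sets))) stop("duplicate set ids")
  list(sets = sets, truth = list(enriched_sets = enriched))
}

#' Simulate an acoustic startle session
#'
#' Startle-alone trial amplitudes are Normal(`baselineMean`, `noiseSD`);
#' each prepulse trial type draws Normal(`baselineMean * (1 - effect)`,
#' `noiseSD`); all amplitudes are truncated at 0 (startle boxes report
#' nonnegative maximal voltage deflections).
#'
#' @param baselineMean mean startle-alone amplitude (arbitrary units).
#' @param ppiEffect named numeric vector of fractional inhibition per
#'   prepulse trial type, each in [0, 1].
#' @param noiseSD trial-to-trial amplitude standard deviation.
#' @param nTrials trials per trial type (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `trial_type` and `amplitude`; the
#'   startle-alone type is labelled `"startle_alone"`.
#' @export
simulateStartleSession <- function(baselineMean, ppiEffect, noiseSD,
                                   nTrials = 20, seed = 1) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (any(ppiEffect < 0 | ppiEffect > 1))
    stop("ppiEffect values must lie in [0, 1]")
  if (is.null(names(ppiEffect)) || anyDuplicated(names(ppiEffect)))
    stop("ppiEffect must be uniquely named by trial type")
  set.seed(seed)
  types <- c("startle_alone", names(ppiEffect))
  means <- c(baselineMean, baselineMean * (1 - ppiEffect))
  amps <- unlist(lapply(means, function(m)
    pmax(0, rnorm(nTrials, m, noiseSD))))
  data.frame(trial_type = rep(types, each = nTrials),
             amplitude = amps, stringsAsFactors = FALSE)
}
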