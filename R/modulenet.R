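#' @importFrom stats hclust cutree as.dist ks.test var lm coef
NULL

.scaleFreeFit <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2 = 0, slope = 0))
  cuts <- cut(k, breaks = nBins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(list(r2 = 0, slope = 0))
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  list(r2 = summary(fit)$r.squared, slope = coef(fit)[2])
}

.softAdjacency <- function(r, power, mode) {
  a <- if (mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Choose a soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power the soft adjacency is computed, connectivities
#' are binned, and log10 p(k) is regressed on log10 k. The smallest power
#' whose model fit reaches `fitTarget` with a negative slope is selected;
#' if none qualifies, the power at which the fit index plateaus (successive
#' change below 0.01) is returned with a warning.
#'
#' @param expr a [NormalizedExpr-class] or genes x samples matrix.
#' @param candidates integer powers to scan.
#' @param fitTarget scale-free fit R^2 target (default 0.8).
#' @param mode `"unsigned"` or `"signed"`.
#' @return list with `power`, and a data.frame `fits` (power, r2, slope,
#'   meanK).
#' @export
pickSoftPower <- function(expr, candidates = 1:20, fitTarget = 0.8,
                          mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  v <- if (is(expr, "NormalizedExpr")) exprValues(expr) else as.matrix(expr)
  if (ncol(v) < 4) stop("need at least 4 samples")
  if (ncol(v) < 8) warning("fewer than 8 samples: correlations are unstable")
  v <- v[apply(v, 1L, var) > 0, , drop = FALSE]
  r <- cor(t(v))
  fits <- data.frame(power = candidates, r2 = NA_real_, slope = NA_real_,
                     meanK = NA_real_)
  for (i in seq_along(candidates)) {
    a <- .softAdjacency(r, candidates[i], mode)
    k <- rowSums(a) - 1
    sf <- .scaleFreeFit(k)
    fits$r2[i] <- sf$r2
    fits$slope[i] <- sf$slope
    fits$meanK[i] <- mean(k)
  }
  ok <- which(fits$r2 >= fitTarget & fits$slope < 0)
  if (length(ok)) {
    power <- candidates[ok[1]]
  } else {
    # plateau: the smallest power from which the fit index stays flat
    # (every later successive change < 0.01); else the largest candidate
    d <- abs(diff(fits$r2))
    flat <- rev(cumprod(rev(d < 0.01))) == 1
    power <- candidates[if (any(flat)) which(flat)[1] else length(candidates)]
    warning("no candidate reached the scale-free fit target ",
            fitTarget, "; using plateau power ", power)
  }
  list(power = as.integer(power), fits = fits)
}

#' Build the soft-thresholded adjacency and topological overlap matrices
#'
#' Adjacency is `|cor|^power` (unsigned) or `((1 + cor)/2)^power` (signed);
#' the topological overlap between genes i and j is
#' `(sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the sum over
#' u distinct from i and j and k the connectivity (row sum minus the
#' diagonal). Genes with zero variance are dropped with a warning.
#'
#' @param expr a [NormalizedExpr-class] or genes x samples matrix.
#' @param power soft-thresholding exponent.
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return a [CoexpressionNetwork-class].
#' @export
buildTOM <- function(expr, power, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  v <- if (is(expr, "NormalizedExpr")) exprValues(expr) else as.matrix(expr)
  keep <- apply(v, 1L, var) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance gene(s) dropped")
    v <- v[keep, , drop = FALSE]
  }
  r <- cor(t(v))
  if (anyNA(r) || any(!is.finite(r))) stop("non-finite correlations")
  a <- .softAdjacency(r, power, mode)
  tom <- .tomFromAdjacency(a)
  new("CoexpressionNetwork", adjacency = a, tom = tom,
      power = as.integer(power), mode = mode)
}

.tomFromAdjacency <- function(a) {
  k <- rowSums(a) - 1
  numer <- a %*% a - a            # sum_{u != i,j} a_iu a_uj + a_ij
  denom <- outer(k, k, pmin) + 1 - a
  tom <- numer / denom
  diag(tom) <- 1
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1)
  dimnames(tom) <- dimnames(a)
  tom
}

# deep split of a dendrogram branch (iterative; branches can be large and
# twig-shedding would otherwise recurse once per shed twig)
# a branch stops splitting when its two sub-branches' eigengenes agree
# (dissimilarity < mergeCutHeight: one coherent module); sub-branches too
# small to stand alone are shed — peripheral genes are readopted later by
# the kME-adoption pass in detectModules()
.splitBranch <- function(members, tom, v, minSize, mergeCutHeight) {
  out <- list()
  queue <- list(members)
  while (length(queue)) {
    mem <- queue[[1]]
    queue <- queue[-1]
    repeat {
      if (length(mem) < 2 * minSize) {
        out[[length(out) + 1L]] <- mem
        break
      }
      d <- 1 - tom[mem, mem]
      hc <- hclust(as.dist(d), method = "average")
      parts <- cutree(hc, k = 2)
      m1 <- mem[parts == 1]
      m2 <- mem[parts == 2]
      small <- if (length(m1) <= length(m2)) m1 else m2
      if (length(small) < minSize) {    # shed the twig, keep splitting
        mem <- setdiff(mem, small)
        next
      }
      e1 <- .moduleEigengene(v[m1, , drop = FALSE])
      e2 <- .moduleEigengene(v[m2, , drop = FALSE])
      if (1 - cor(e1, e2) < mergeCutHeight) {   # one coherent module
        out[[length(out) + 1L]] <- mem
        break
      }
      queue <- c(queue, list(m1), list(m2))
      break
    }
  }
  out
}

.standardizeRows <- function(v) {
  v <- v - rowMeans(v)
  s <- sqrt(rowSums(v^2) / (ncol(v) - 1))
  s[s == 0] <- 1
  v / s
}

.moduleEigengene <- function(v) {
  # first right singular vector of the standardized module expression,
  # unit norm, oriented toward the member genes
  z <- .standardizeRows(v)
  e <- svd(z, nu = 0, nv = 1)$v[, 1]
  if (mean(cor(t(v), e)) < 0) e <- -e
  e
}

#' Compute module eigengenes for a given assignment
#'
#' @param expr a [NormalizedExpr-class] or genes x samples matrix.
#' @param assignment named character vector gene -> module label
#'   (`"unassigned"` entries are skipped).
#' @return module x sample matrix of unit-norm eigengenes.
#' @export
computeEigengenes <- function(expr, assignment) {
  v <- if (is(expr, "NormalizedExpr")) exprValues(expr) else as.matrix(expr)
  mods <- setdiff(unique(assignment), "unassigned")
  eg <- t(vapply(mods, function(m) {
    genes <- names(assignment)[assignment == m]
    .moduleEigengene(v[genes, , drop = FALSE])
  }, numeric(ncol(v))))
  rownames(eg) <- mods
  colnames(eg) <- colnames(v)
  eg
}

#' Detect coexpression modules by recursive branch-cutting of the TOM
#' dendrogram
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM` is
#' cut at `cutHeight` times the top merge height to obtain branches. Each
#' branch is then split recursively: its two sub-branches are accepted as
#' separate clusters when both are large enough and their eigengenes are
#' dissimilar (at least `mergeCutHeight` on the `1 - cor` scale); a
#' sub-branch too small to stand alone is shed to background when its
#' eigengene diverges from the main branch (a noise twig) or ends the
#' recursion when it does not (module periphery). This deep-split step
#' separates distinct modules that an unsigned metric glues together (e.g.
#' trait-up and trait-down modules, which are strongly |cor|-linked) and
#' fragments structureless branches, which lack a shared latent factor, down
#' to background. Clusters smaller than `minSize` fall into `"unassigned"`;
#' surviving clusters must also be cohesive (mean intra-cluster TOM at least
#' `cohesion` times the mean off-diagonal TOM of the whole network). Modules
#' whose eigengenes are closer than `mergeCutHeight` are merged. Final
#' modules are labelled `"M1"`, `"M2"`, ... in decreasing size order.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param expr the expression the network was built from (for eigengenes).
#' @param minSize minimum module size (default 30).
#' @param cutHeight branch cut as a fraction of the top merge height
#'   (default 0.99).
#' @param mergeCutHeight eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param cohesion intra-module TOM enrichment required over background
#'   (default 1.5).
#' @param kmeAdopt minimum absolute eigengene correlation for a background
#'   gene to be adopted into a module (default `1 - mergeCutHeight`: a gene
#'   is adopted when it is as close to the eigengene as merged modules are
#'   to each other).
#' @return a [ModuleSet-class].
#' @export
detectModules <- function(network, expr, minSize = 30, cutHeight = 0.99,
                          mergeCutHeight = 0.25, cohesion = 1.5,
                          kmeAdopt = 1 - mergeCutHeight) {
  stopifnot(is(network, "CoexpressionNetwork"))
  tom <- tomMatrix(network)
  genes <- rownames(tom)
  if (length(genes) < minSize) stop("fewer genes than minSize")
  d <- 1 - tom
  if (max(d) - min(d[upper.tri(d)]) < 1e-12)
    stop("degenerate dissimilarity: all gene pairs equally distant")
  hc <- hclust(as.dist(d), method = "average")
  labs <- cutree(hc, h = cutHeight * max(hc$height))

  vAll <- exprAsMatrix(expr)[genes, , drop = FALSE]
  background <- mean(tom[upper.tri(tom)])
  assignment <- setNames(rep("unassigned", length(genes)), genes)
  kept <- list()
  for (cl in unique(labs)) {
    members <- genes[labs == cl]
    if (length(members) < minSize) next
    for (part in .splitBranch(members, tom, vAll, minSize, mergeCutHeight)) {
      if (length(part) < minSize) next
      sub <- tom[part, part]
      within <- mean(sub[upper.tri(sub)])
      if (within >= cohesion * background) kept[[length(kept) + 1L]] <- part
    }
  }
  if (!length(kept)) {
    v <- exprAsMatrix(expr)
    return(new("ModuleSet", assignment = assignment,
               eigengenes = matrix(numeric(), 0, ncol(v),
                                   dimnames = list(NULL, colnames(v)))))
  }
  for (i in seq_along(kept)) assignment[kept[[i]]] <- paste0("tmp", i)

  # merge modules with near-identical eigengenes
  v <- exprAsMatrix(expr)[genes, , drop = FALSE]
  repeat {
    eg <- computeEigengenes(v, assignment)
    if (nrow(eg) < 2) break
    dis <- 1 - cor(t(eg))
    diag(dis) <- Inf
    idx <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    if (dis[idx[1], idx[2]] >= mergeCutHeight) break
    from <- rownames(eg)[idx[2]]; to <- rownames(eg)[idx[1]]
    assignment[assignment == from] <- to
  }

  # kME adoption: background genes as close to a module eigengene as merged
  # modules would be to each other are adopted as module periphery (twigs
  # shed during deep splitting come back here)
  eg <- computeEigengenes(v, assignment)
  un <- names(assignment)[assignment == "unassigned"]
  if (length(un) && nrow(eg)) {
    kme <- abs(cor(t(v[un, , drop = FALSE]), t(eg)))
    best <- max.col(kme, ties.method = "first")
    ok <- kme[cbind(seq_along(un), best)] >= kmeAdopt
    assignment[un[ok]] <- rownames(eg)[best[ok]]
  }

  sizes <- sort(table(assignment[assignment != "unassigned"]),
                decreasing = TRUE)
  relabel <- setNames(paste0("M", seq_along(sizes)), names(sizes))
  assignment[assignment != "unassigned"] <-
    relabel[assignment[assignment != "unassigned"]]
  eg <- computeEigengenes(v, assignment)
  new("ModuleSet", assignment = assignment, eigengenes = eg)
}

exprAsMatrix <- function(expr) {
  if (is(expr, "NormalizedExpr")) exprValues(expr) else as.matrix(expr)
}

.corTestP <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t), n - 2, lower.tail = FALSE)
}

# reference level = first factor level (or first appearance) -> 0
.numericCovariate <- function(x) {
  f <- if (is.factor(x)) x else factor(x, levels = unique(x))
  if (nlevels(f) < 2) stop("zero-variance covariate")
  as.numeric(f) - 1
}

#' Module-trait correlation statistics
#'
#' Pearson correlation of each module eigengene with numerically encoded
#' sample covariates (reference level = 0, test level = 1; sex and batch
#' likewise), with two-sided p-values from the exact t-transform of r with
#' n - 2 degrees of freedom.
#'
#' @param moduleSet a [ModuleSet-class].
#' @param sampleData data.frame (or DataFrame) with one row per sample;
#'   factor-like columns are encoded 0/1 in level order.
#' @param covariates which columns to correlate (default all).
#' @return data.frame with columns `module`, `covariate`, `r`, `p`.
#' @export
moduleTraitStats <- function(moduleSet, sampleData,
                             covariates = colnames(sampleData)) {
  eg <- eigengenes(moduleSet)
  sampleData <- as.data.frame(sampleData)
  n <- ncol(eg)
  stopifnot(nrow(sampleData) == n)
  out <- expand.grid(module = rownames(eg), covariate = covariates,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- .numericCovariate(sampleData[[out$covariate[i]]])
    r <- cor(eg[out$module[i], ], x)
    out$r[i] <- r
    out$p[i] <- .corTestP(r, n)
  }
  out
}

#' Gene significance and module membership
#'
#' MM is the Pearson correlation of each gene's expression with its own
#' module eigengene; GS is the (signed, by default) correlation with the
#' numerically encoded trait. The per-module association between the two
#' (computed on absolute values, as in driver-gene plots of MM versus GS) is
#' reported alongside.
#'
#' @param expr a [NormalizedExpr-class] or genes x samples matrix.
#' @param moduleSet a [ModuleSet-class].
#' @param sampleData data.frame with a `trait` column.
#' @param gsSigned keep the sign of GS (default TRUE).
#' @return list with `geneStats` (data.frame gene, module, MM, GS) and
#'   `gsMM` (data.frame module, r, p, n: the GS~MM correlation per module).
#' @export
geneModuleStats <- function(expr, moduleSet, sampleData, gsSigned = TRUE) {
  v <- exprAsMatrix(expr)
  assignment <- moduleLabels(moduleSet)
  v <- v[names(assignment), , drop = FALSE]
  eg <- eigengenes(moduleSet)
  trait <- .numericCovariate(as.data.frame(sampleData)$trait)
  gs <- as.numeric(cor(t(v), trait))
  if (!gsSigned) gs <- abs(gs)
  mm <- rep(NA_real_, length(assignment))
  for (m in rownames(eg)) {
    idx <- which(assignment == m)
    mm[idx] <- as.numeric(cor(t(v[idx, , drop = FALSE]), eg[m, ]))
  }
  geneStats <- data.frame(gene = names(assignment), module = assignment,
                          MM = mm, GS = gs, stringsAsFactors = FALSE,
                          row.names = NULL)
  mods <- rownames(eg)
  gsMM <- data.frame(module = mods, r = NA_real_, p = NA_real_,
                     n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(mods)) {
    sel <- geneStats$module == mods[i]
    ng <- sum(sel)
    r <- cor(abs(geneStats$MM[sel]), abs(geneStats$GS[sel]))
    gsMM$r[i] <- r
    gsMM$p[i] <- .corTestP(r, ng)
    gsMM$n[i] <- ng
  }
  list(geneStats = geneStats, gsMM = gsMM)
}

#' Permutation validation of module-trait correlations
#'
#' Gene-to-module labels are permuted (module sizes preserved), eigengenes
#' and module-trait correlations recomputed per permutation, and each
#' observed module is compared against its own permutation cloud. A module
#' is validated when no permuted replicate reaches its observed |r| (an
#' envelope criterion: with 40 permutations, none of the permuted modules
#' may show an equivalent correlation).
#'
#' @param expr a [NormalizedExpr-class] or genes x samples matrix.
#' @param moduleSet a [ModuleSet-class].
#' @param sampleData data.frame with a `trait` column.
#' @param nPerm number of permutations (default 40).
#' @param seed integer seed.
#' @return list with `observed` (module, r, p), `permuted` (perm, module,
#'   r, p) and `exceeds` (named logical: observed |r| beyond all permuted).
#' @export
permuteModuleValidation <- function(expr, moduleSet, sampleData, nPerm = 40,
                                    seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  set.seed(seed)
  v <- exprAsMatrix(expr)
  assignment <- moduleLabels(moduleSet)
  obs <- moduleTraitStats(moduleSet, sampleData, covariates = "trait")
  obs <- data.frame(module = obs$module, r = obs$r, p = obs$p,
                    stringsAsFactors = FALSE)
  perms <- vector("list", nPerm)
  for (b in seq_len(nPerm)) {
    permAssign <- setNames(sample(assignment), names(assignment))
    eg <- computeEigengenes(v, permAssign)
    ms <- new("ModuleSet", assignment = permAssign, eigengenes = eg)
    st <- moduleTraitStats(ms, sampleData, covariates = "trait")
    perms[[b]] <- data.frame(perm = b, module = st$module, r = st$r,
                             p = st$p, stringsAsFactors = FALSE)
  }
  permuted <- do.call(rbind, perms)
  exceeds <- vapply(obs$module, function(m) {
    cloud <- abs(permuted$r[permuted$module == m])
    abs(obs$r[obs$module == m]) > max(cloud)
  }, logical(1))
  list(observed = obs, permuted = permuted, exceeds = exceeds)
}

#' Select putative driver genes by module-membership percentile
#'
#' Within each module, genes whose MM reaches the module's `percentile`
#' cutoff are flagged as drivers; ties at the cutoff are all included.
#'
#' @param geneStats the `geneStats` data.frame from [geneModuleStats()].
#' @param percentile MM percentile cutoff (default 95).
#' @return named list of character vectors, module -> driver genes.
#' @export
selectDrivers <- function(geneStats, percentile = 95) {
  mods <- setdiff(unique(geneStats$module), "unassigned")
  out <- list()
  for (m in mods) {
    sel <- geneStats[geneStats$module == m, ]
    if (!nrow(sel)) stop("empty module: ", m)
    if (nrow(sel) < 20)
      warning("module ", m, " has fewer than 20 genes; the ", percentile,
              "th percentile is poorly determined")
    cutoff <- quantile(sel$MM, percentile / 100, names = FALSE)
    out[[m]] <- sel$gene[sel$MM >= cutoff]
  }
  out
}

#' Driver-deletion shift of the intra-module weight distribution
#'
#' Compares intra-module edge weights of the intact module network against
#' the module with driver rows/columns deleted, by a two-sample
#' Kolmogorov-Smirnov test, and reports whether the deletion shifted weights
#' leftward (deleted median below intact median). With `weights = "tom"`
#' (default) the topological overlap is recomputed from the module's
#' adjacency block before and after deleting the driver rows/columns, so the
#' loss of high-membership genes depresses the overlap of every remaining
#' pair — in a weighted network, removing the drivers biases the module
#' toward lower-weighted edges. With `weights = "adjacency"` the raw
#' adjacency entries are compared instead (deletion then only subsets the
#' weight list).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param moduleSet a [ModuleSet-class].
#' @param module module label to test.
#' @param drivers character vector of driver genes to delete.
#' @param weights `"tom"` (default) or `"adjacency"`.
#' @return list with `D`, `p`, `direction` (`"left"`, `"right"` or
#'   `"none"`), `nIntact`, `nDeleted`, and a `note` when no drivers were
#'   supplied.
#' @export
driverDeletionShift <- function(network, moduleSet, module, drivers,
                                weights = c("tom", "adjacency")) {
  weights <- match.arg(weights)
  assignment <- moduleLabels(moduleSet)
  genes <- names(assignment)[assignment == module]
  if (!length(genes)) stop("unknown or empty module: ", module)
  drivers <- intersect(drivers, genes)
  keep <- setdiff(genes, drivers)
  if (length(keep) < 2) stop("module needs >= 2 non-driver genes")
  if (!length(drivers))
    return(list(D = 0, p = NA_real_, direction = "none",
                nIntact = length(genes), nDeleted = length(keep),
                note = "no drivers supplied"))
  a <- adjacencyMatrix(network)
  if (weights == "tom") {
    wIntact <- .tomFromAdjacency(a[genes, genes])
    wDeleted <- .tomFromAdjacency(a[keep, keep])
  } else {
    wIntact <- a[genes, genes]
    wDeleted <- a[keep, keep]
  }
  intact <- wIntact[upper.tri(wIntact)]
  deleted <- wDeleted[upper.tri(wDeleted)]
  ks <- suppressWarnings(ks.test(deleted, intact))
  list(D = unname(ks$statistic), p = ks$p.value,
       direction = if (median(deleted) < median(intact)) "left"
                   else if (median(deleted) > median(intact)) "right"
                   else "none",
       nIntact = length(genes), nDeleted = length(keep))
}
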