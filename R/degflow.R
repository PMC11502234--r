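#' @importFrom stats model.matrix prcomp mad median pt p.adjust setNames
#' @importFrom limma normalizeCyclicLoess removeBatchEffect
NULL

.sampleData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' CPM normalization with a log2 pedestal
#'
#' Converts raw counts to counts per million within each sample, adds a
#' pedestal of 2 and takes log2: `value = log2(1e6 * count / total + 2)`.
#' The attainable minimum is `log2(2) = 1` at count zero; the pedestal keeps
#' zeros finite and compresses shot noise at low counts.
#'
#' @param counts a `SummarizedExperiment` with assay `"counts"` (see
#'   [countExperiment()]).
#' @param pedestal the additive pedestal on the CPM scale (default 2).
#' @return a [NormalizedExpr-class] carrying the sample table.
#' @examples
#' sim <- simulateBulkCounts(simConfig(nGenes = 100, seed = 1))
#' ne <- cpmLogPedestal(sim$counts)
#' @export
cpmLogPedestal <- function(counts, pedestal = 2) {
  m <- SummarizedExperiment::assay(counts, "counts")
  totals <- colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[totals <= 0]
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "))
  }
  cpm <- sweep(m, 2L, totals / 1e6, "/")
  newNormalizedExpr(log2(cpm + pedestal),
                    SummarizedExperiment::colData(counts),
                    stages = "cpm_log_pedestal")
}

#' Cyclic loess cross-sample normalization
#'
#' Equalizes spread and location across samples by repeatedly loess-smoothing
#' M (pairwise difference) against A (pairwise average) for every sample pair
#' and subtracting half the fit from each member of the pair.
#'
#' @param expr a [NormalizedExpr-class].
#' @param span loess span in (0, 1].
#' @param iterations full cycles over all sample pairs; 0 returns the input
#'   unchanged.
#' @return the normalized [NormalizedExpr-class].
#' @export
cyclicLowess <- function(expr, span = 0.3, iterations = 3) {
  stopifnot(is(expr, "NormalizedExpr"))
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (ncol(expr) < 2) stop("need at least 2 samples")
  v <- exprValues(expr)
  if (iterations >= 1)
    v <- limma::normalizeCyclicLoess(v, span = span,
                                     iterations = iterations,
                                     method = "pairs")
  newNormalizedExpr(v, SummarizedExperiment::colData(expr),
                    stages = c(stages(expr), "cyclic_lowess"),
                    floorThreshold = floorThreshold(expr))
}

#' Flag outlier samples on a covariance-based PCA scatter
#'
#' Runs PCA on centered (not scaled) expression, measures each sample's
#' Euclidean distance from the centroid in the PC1-PC2 plane, and flags
#' samples whose distance exceeds `sdMultiplier` times the robust standard
#' deviation of all distances. Distances are themselves deviations from the
#' centroid, so the robust SD is the normal-consistency-scaled median
#' absolute distance (MAD about zero). A reproducible surrogate for the
#' visual outlier inspection such scatterplots usually get.
#'
#' @param expr a [NormalizedExpr-class] with at least 4 samples.
#' @param sdMultiplier robust-SD multiplier (default 3).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flagOutlierSamples <- function(expr, sdMultiplier = 3) {
  stopifnot(is(expr, "NormalizedExpr"))
  if (ncol(expr) < 4) stop("need at least 4 samples to call outliers")
  v <- exprValues(expr)
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  d <- sqrt(rowSums(scale(sc, center = TRUE, scale = FALSE)^2))
  s <- mad(d, center = 0)
  if (s == 0) return(character())
  colnames(expr)[d > sdMultiplier * s]
}

.checkConfounding <- function(trait, batch) {
  tab <- table(trait, batch)
  if (nlevels(factor(batch)) > 1 &&
      all(rowSums(tab > 0) == 1))
    stop("batch is perfectly confounded with trait: factors 'trait' and ",
         "'batch' are aliased")
}

#' Remove additive batch effects while preserving trait effects
#'
#' Fits, per gene, a linear model containing the trait and batch factors and
#' subtracts the estimated batch coefficients, so that with noise-free
#' additive shifts the between-batch means agree to machine precision while
#' trait differences are untouched. With a single batch the input is
#' returned unchanged.
#'
#' @param expr a [NormalizedExpr-class] whose colData has `trait` and
#'   `batch`.
#' @return the corrected [NormalizedExpr-class].
#' @export
correctBatch <- function(expr) {
  stopifnot(is(expr, "NormalizedExpr"))
  des <- .sampleData(expr)
  batch <- factor(des$batch)
  if (nlevels(batch) < 2) {
    out <- expr
    out@stages <- c(stages(expr), "batch_corrected")
    return(out)
  }
  .checkConfounding(des$trait, batch)
  design <- model.matrix(~ factor(des$trait))
  v <- limma::removeBatchEffect(exprValues(expr), batch = batch,
                                design = design)
  newNormalizedExpr(v, SummarizedExperiment::colData(expr),
                    stages = c(stages(expr), "batch_corrected"),
                    floorThreshold = floorThreshold(expr))
}

#' Noise-floor filtering and flooring
#'
#' Removes genes with no sample above the threshold, then raises surviving
#' values below the threshold to the threshold. The default 2.25 is the mean
#' batch-corrected normalized expression value this pipeline treats as the
#' noise floor. Gene order is preserved; applying the filter twice equals
#' applying it once.
#'
#' @param expr a [NormalizedExpr-class].
#' @param threshold finite noise floor (default 2.25).
#' @return the filtered, floored [NormalizedExpr-class].
#' @export
floorFilter <- function(expr, threshold = 2.25) {
  stopifnot(is(expr, "NormalizedExpr"), is.finite(threshold))
  v <- exprValues(expr)
  keep <- apply(v, 1L, max) > threshold
  v <- v[keep, , drop = FALSE]
  v[v < threshold] <- threshold
  newNormalizedExpr(v, SummarizedExperiment::colData(expr),
                    stages = unique(c(stages(expr), "floor_filtered")),
                    floorThreshold = threshold)
}

# least-squares fit of all genes on a common design; returns trait t-test
# and covariate-adjusted group means
.fitAncova <- function(v, des) {
  trait <- factor(des$trait)
  if (nlevels(trait) != 2) stop("ANCOVA expects exactly two trait levels")
  if (min(table(trait)) < 2) stop("each trait level needs >= 2 samples")
  terms <- list(trait = trait)
  for (cv in c("batch", "sex")) {
    f <- factor(des[[cv]])
    if (nlevels(f) > 1) terms[[cv]] <- f
  }
  X <- model.matrix(~ ., data = as.data.frame(terms))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    alias <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(alias, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  coefs <- t(qr.coef(qx, t(v)))            # genes x p
  res <- v - coefs %*% t(X)
  df <- n - p
  sigma2 <- rowSums(res^2) / df
  xtxInv <- solve(crossprod(X))
  traitCol <- grep("^trait", colnames(X))
  se <- sqrt(sigma2 * xtxInv[traitCol, traitCol])
  beta <- coefs[, traitCol]
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0] <- 1                          # constant genes carry no evidence
  # covariate-adjusted means: prediction averaged over the observed design
  X0 <- X; X0[, traitCol] <- 0
  adjRef <- drop(coefs %*% colMeans(X0))
  list(log2FC = beta, p = p, meanRef = adjRef, meanTest = adjRef + beta,
       df = df)
}

#' Per-gene ANCOVA differential expression with fold-change calls
#'
#' Fits, for every gene, an ordinary least-squares model
#' `expression ~ trait + batch + sex` (covariates with a single level are
#' dropped), tests the trait term with a partial t-test, and reports
#' covariate-adjusted group means, `log2FC` (test minus reference, so
#' `linearFC = 2^log2FC` is test/reference), and threshold calls. A gene is
#' called when its p-value passes the cut AND `linearFC >= fcCut` or
#' `<= 1/fcCut` ("a minimum fold change in either direction").
#'
#' @param expr a [NormalizedExpr-class]; colData must have `trait` (first
#'   factor level = reference), `batch`, `sex`.
#' @param pCuts two p-value cuts, strict and relaxed (default 0.05, 0.1).
#' @param fcCut minimum linear fold change (default 1.25).
#' @param pAdjust `"none"` for raw ANCOVA p-values (default) or `"BH"` for
#'   Benjamini-Hochberg adjustment before thresholding.
#' @return a [S4Vectors::DataFrame] with one row per gene: `meanRef`,
#'   `meanTest`, `log2FC`, `linearFC`, `p`, `pUsed`, `called05`, `called10`.
#' @export
ancovaDEG <- function(expr, pCuts = c(0.05, 0.1), fcCut = 1.25,
                      pAdjust = c("none", "BH")) {
  stopifnot(is(expr, "NormalizedExpr"))
  pAdjust <- match.arg(pAdjust)
  stopifnot(length(pCuts) == 2, pCuts[1] <= pCuts[2], fcCut >= 1)
  des <- .sampleData(expr)
  fit <- .fitAncova(exprValues(expr), des)
  pUsed <- if (pAdjust == "BH") p.adjust(fit$p, "BH") else fit$p
  linearFC <- 2^fit$log2FC
  fcPass <- linearFC >= fcCut | linearFC <= 1 / fcCut
  out <- S4Vectors::DataFrame(
    meanRef = fit$meanRef, meanTest = fit$meanTest,
    log2FC = fit$log2FC, linearFC = linearFC,
    p = fit$p, pUsed = pUsed,
    called05 = pUsed < pCuts[1] & fcPass,
    called10 = pUsed < pCuts[2] & fcPass,
    row.names = rownames(expr))
  S4Vectors::metadata(out) <- list(pCuts = pCuts, fcCut = fcCut,
                                   pAdjust = pAdjust, df = fit$df)
  out
}

#' Run the full differential-expression chain
#'
#' Convenience wrapper: CPM + log2 pedestal, cyclic loess, outlier flagging
#' and removal, renormalization, batch correction, floor filtering, ANCOVA.
#'
#' @param counts a count `SummarizedExperiment` (see [countExperiment()]).
#' @param floor noise floor for [floorFilter()].
#' @param span,iterations cyclic loess settings.
#' @param sdMultiplier outlier threshold for [flagOutlierSamples()].
#' @param ... passed to [ancovaDEG()].
#' @return list with `deg` (the result DataFrame), `expr` (the final
#'   [NormalizedExpr-class]) and `outliers` (flagged sample ids).
#' @export
runDEGChain <- function(counts, floor = 2.25, span = 0.3, iterations = 3,
                        sdMultiplier = 3, ...) {
  ne <- cpmLogPedestal(counts)
  ne <- cyclicLowess(ne, span = span, iterations = iterations)
  out <- flagOutlierSamples(ne, sdMultiplier = sdMultiplier)
  if (length(out)) {
    keep <- setdiff(colnames(counts), out)
    ne <- cpmLogPedestal(counts[, keep])
    ne <- cyclicLowess(ne, span = span, iterations = iterations)
  }
  ne <- correctBatch(ne)
  ne <- floorFilter(ne, threshold = floor)
  list(deg = ancovaDEG(ne, ...), expr = ne, outliers = out)
}
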