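#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' @import methods
NULL

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @export
setGeneric("floorThreshold", function(x) standardGeneric("floorThreshold"))

#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))

#' @export
setGeneric("networkMode", function(x) standardGeneric("networkMode"))

#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Simulation configuration for bulk RNA-seq count generation
#'
#' Holds the full generative design for [simulateBulkCounts()]: group sizes,
#' batch and sex assignment, library-size and dispersion parameters, planted
#' differential expression, and latent-factor coexpression modules.
#'
#' @slot nGenes number of genes simulated.
#' @slot nPerGroup samples per trait group.
#' @slot groups two or more trait labels; the first is the reference level.
#' @slot nBatches number of sequencing batches; samples are assigned in a
#'   balanced, interleaved fashion.
#' @slot batchSD standard deviation of the gene-wise additive log2-scale
#'   batch offset.
#' @slot libSizeLogMean,libSizeLogSD natural-log parameters of the log-normal
#'   library-size distribution.
#' @slot baselineLog2Mean,baselineLog2SD log2-scale location/spread of the
#'   per-gene baseline expression level.
#' @slot nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @slot deFraction fraction of genes with a planted trait effect.
#' @slot deLog2FC magnitude of the planted effect; signs alternate up/down.
#' @slot modules list of planted coexpression modules, each a list with
#'   elements `size`, `rho` (Pearson correlation of the module latent factor
#'   with the numeric trait) and `loading` (range of per-gene factor
#'   loadings, log2 scale).
#' @slot seed integer root seed; identical seeds give identical output.
#'
#' @seealso [simConfig()], [simulateBulkCounts()]
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer",
    nPerGroup = "integer",
    groups = "character",
    nBatches = "integer",
    batchSD = "numeric",
    libSizeLogMean = "numeric",
    libSizeLogSD = "numeric",
    baselineLog2Mean = "numeric",
    baselineLog2SD = "numeric",
    nbDispersion = "numeric",
    deFraction = "numeric",
    deLog2FC = "numeric",
    modules = "list",
    seed = "integer"
  ),
  prototype(
    nGenes = 2000L,
    nPerGroup = 6L,
    groups = c("WT", "MUT"),
    nBatches = 2L,
    batchSD = 0.2,
    libSizeLogMean = log(5e5),
    libSizeLogSD = 0.2,
    baselineLog2Mean = log2(100),
    baselineLog2SD = 1.5,
    nbDispersion = 0.1,
    deFraction = 0,
    deLog2FC = 1,
    modules = list(),
    seed = 1L
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be positive")
  if (length(object@groups) < 2L) msg <- c(msg, "need at least 2 groups")
  if (anyDuplicated(object@groups)) msg <- c(msg, "group labels must be unique")
  if (object@nBatches < 1L) msg <- c(msg, "nBatches must be positive")
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must lie in [0, 1]")
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (object@libSizeLogSD < 0) msg <- c(msg, "libSizeLogSD must be >= 0")
  for (m in object@modules) {
    if (!all(c("size", "rho", "loading") %in% names(m)))
      msg <- c(msg, "each module needs 'size', 'rho' and 'loading'")
    else if (abs(m$rho) > 1)
      msg <- c(msg, "module |rho| must be <= 1")
  }
  msizes <- vapply(object@modules, function(m) as.numeric(m$size), 0)
  if (length(msizes) && sum(msizes) > object@nGenes)
    msg <- c(msg, "module sizes sum above nGenes")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nGenes,nPerGroup,groups,nBatches,batchSD,libSizeLogMean,libSizeLogSD,baselineLog2Mean,baselineLog2SD,nbDispersion,deFraction,deLog2FC,modules,seed
#'   see the slot documentation in [SimConfig-class].
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 500, deFraction = 0.1, seed = 7)
#' @export
simConfig <- function(nGenes = 2000, nPerGroup = 6, groups = c("WT", "MUT"),
                      nBatches = 2, batchSD = 0.2,
                      libSizeLogMean = log(5e5), libSizeLogSD = 0.2,
                      baselineLog2Mean = log2(100), baselineLog2SD = 1.5,
                      nbDispersion = 0.1, deFraction = 0, deLog2FC = 1,
                      modules = list(), seed = 1) {
  new("SimConfig",
    nGenes = as.integer(nGenes), nPerGroup = as.integer(nPerGroup),
    groups = as.character(groups), nBatches = as.integer(nBatches),
    batchSD = batchSD, libSizeLogMean = libSizeLogMean,
    libSizeLogSD = libSizeLogSD, baselineLog2Mean = baselineLog2Mean,
    baselineLog2SD = baselineLog2SD, nbDispersion = nbDispersion,
    deFraction = deFraction, deLog2FC = deLog2FC,
    modules = modules, seed = as.integer(seed))
}

#' @describeIn SimConfig-class compact display
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,",
      length(object@groups), "groups x", object@nPerGroup, "samples,",
      object@nBatches, "batch(es)\n")
  cat("  DE:", format(object@deFraction), "of genes at |log2FC| =",
      format(object@deLog2FC), "; dispersion", format(object@nbDispersion), "\n")
  cat("  modules:", length(object@modules), "; seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# NormalizedExpr
# ---------------------------------------------------------------------------

#' Log2-scale expression matrix with pipeline provenance
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `"expr"`
#' holds log2-scale expression, annotated with the normalization stages it
#' has passed through and, once floor-filtered, the noise-floor threshold.
#'
#' @slot stages character vector of stage tags applied so far, in order
#'   (e.g. `"cpm_log_pedestal"`, `"cyclic_lowess"`, `"batch_corrected"`,
#'   `"floor_filtered"`).
#' @slot floorThreshold the noise floor applied by [floorFilter()]; `NA`
#'   before filtering.
#' @export
setClass("NormalizedExpr",
  contains = "SummarizedExperiment",
  representation(stages = "character", floorThreshold = "numeric"),
  prototype(stages = character(), floorThreshold = NA_real_))

setValidity("NormalizedExpr", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  else {
    v <- SummarizedExperiment::assay(object, "expr")
    if (!is.numeric(v)) msg <- c(msg, "assay 'expr' must be numeric")
    if (anyNA(v)) msg <- c(msg, "assay 'expr' contains NA")
    thr <- object@floorThreshold
    if ("floor_filtered" %in% object@stages && !is.na(thr) && nrow(v)) {
      if (min(v) < thr - 1e-12)
        msg <- c(msg, "floor-filtered values below floorThreshold")
      if (any(apply(v, 1L, max) <= thr) && ncol(v))
        msg <- c(msg, "retained gene without any value above floorThreshold")
    }
  }
  if (length(msg)) msg else TRUE
})

newNormalizedExpr <- function(values, sampleData, stages,
                              floorThreshold = NA_real_) {
  se <- SummarizedExperiment(
    assays = list(expr = as.matrix(values)),
    colData = sampleData)
  new("NormalizedExpr", se, stages = stages, floorThreshold = floorThreshold)
}

#' @describeIn NormalizedExpr-class the expression matrix (genes x samples)
#' @param x a `NormalizedExpr`
#' @export
setMethod("exprValues", "NormalizedExpr",
          function(x) SummarizedExperiment::assay(x, "expr"))

#' @describeIn NormalizedExpr-class stage tags applied so far
#' @export
setMethod("stages", "NormalizedExpr", function(x) x@stages)

#' @describeIn NormalizedExpr-class the applied noise floor (NA before
#'   filtering)
#' @export
setMethod("floorThreshold", "NormalizedExpr", function(x) x@floorThreshold)

#' @describeIn NormalizedExpr-class compact display
#' @param object a `NormalizedExpr`
#' @export
setMethod("show", "NormalizedExpr", function(object) {
  cat("NormalizedExpr:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  stages:", if (length(object@stages))
    paste(object@stages, collapse = " -> ") else "(none)", "\n")
  if (!is.na(object@floorThreshold))
    cat("  noise floor:", format(object@floorThreshold), "\n")
})

# ---------------------------------------------------------------------------
# CoexpressionNetwork
# ---------------------------------------------------------------------------

#' Weighted gene-coexpression network
#'
#' Soft-thresholded adjacency and topological overlap (TOM) matrices over a
#' fixed gene set, as built by [buildTOM()].
#'
#' @slot adjacency gene x gene soft-thresholded adjacency, entries in [0, 1],
#'   unit diagonal.
#' @slot tom gene x gene topological overlap, entries in [0, 1], unit
#'   diagonal.
#' @slot power the soft-thresholding exponent.
#' @slot mode `"unsigned"` (|r|^power) or `"signed"` (((1 + r)/2)^power).
#' @export
setClass("CoexpressionNetwork",
  representation(adjacency = "matrix", tom = "matrix",
                 power = "integer", mode = "character"))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  a <- object@adjacency; t <- object@tom
  if (!identical(dim(a), dim(t))) msg <- c(msg, "adjacency/TOM dims differ")
  if (nrow(a) != ncol(a)) msg <- c(msg, "matrices must be square")
  if (is.null(rownames(a))) msg <- c(msg, "gene names required")
  if (nrow(a)) {
    if (max(abs(a - base::t(a))) > 1e-8) msg <- c(msg, "adjacency not symmetric")
    if (max(abs(t - base::t(t))) > 1e-8) msg <- c(msg, "TOM not symmetric")
    if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
      msg <- c(msg, "adjacency outside [0,1]")
    if (min(t) < -1e-12 || max(t) > 1 + 1e-12)
      msg <- c(msg, "TOM outside [0,1]")
    if (max(abs(diag(a) - 1)) > 1e-12)
      msg <- c(msg, "adjacency diagonal must be 1")
  }
  if (!object@mode %in% c("unsigned", "signed"))
    msg <- c(msg, "mode must be 'unsigned' or 'signed'")
  if (object@power < 1L) msg <- c(msg, "power must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoexpressionNetwork-class soft-thresholded adjacency matrix
#' @param x a `CoexpressionNetwork`
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)

#' @describeIn CoexpressionNetwork-class topological overlap matrix
#' @export
setMethod("tomMatrix", "CoexpressionNetwork", function(x) x@tom)

#' @describeIn CoexpressionNetwork-class soft-thresholding power
#' @export
setMethod("softPower", "CoexpressionNetwork", function(x) x@power)

#' @describeIn CoexpressionNetwork-class network mode
#' @export
setMethod("networkMode", "CoexpressionNetwork", function(x) x@mode)

#' @describeIn CoexpressionNetwork-class compact display
#' @param object a `CoexpressionNetwork`
#' @export
setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", nrow(object@adjacency), "genes,",
      object@mode, "mode, power", object@power, "\n")
})

# ---------------------------------------------------------------------------
# ModuleSet
# ---------------------------------------------------------------------------

#' Coexpression module assignment with eigengenes
#'
#' Gene-to-module labels from [detectModules()] together with per-module
#' eigengenes (first principal component of the standardized module
#' expression, unit norm, oriented so the mean correlation with member genes
#' is nonnegative). Background genes carry the label `"unassigned"`.
#'
#' @slot assignment named character vector, gene -> module label.
#' @slot eigengenes module x sample matrix of eigengene scores.
#' @export
setClass("ModuleSet",
  representation(assignment = "character", eigengenes = "matrix"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by gene")
  mods <- setdiff(unique(object@assignment), "unassigned")
  if (length(mods) && !all(mods %in% rownames(object@eigengenes)))
    msg <- c(msg, "every module needs an eigengene row")
  if (nrow(object@eigengenes)) {
    nrm <- sqrt(rowSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "eigengenes must have unit norm")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ModuleSet-class gene -> module labels (named character vector)
#' @param x a `ModuleSet`
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) x@assignment)

#' @describeIn ModuleSet-class module sizes, excluding `"unassigned"`
#' @export
setMethod("moduleSizes", "ModuleSet", function(x) {
  tab <- table(x@assignment)
  tab <- tab[names(tab) != "unassigned"]
  sizes <- as.integer(tab)
  names(sizes) <- names(tab)
  sizes[order(-sizes)]
})

#' @describeIn ModuleSet-class module x sample eigengene matrix
#' @export
setMethod("eigengenes", "ModuleSet", function(x) x@eigengenes)

#' @describeIn ModuleSet-class compact display
#' @param object a `ModuleSet`
#' @export
setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat("ModuleSet:", length(sz), "modules over",
      length(object@assignment), "genes (",
      sum(object@assignment == "unassigned"), "unassigned )\n")
  if (length(sz))
    cat("  sizes:", paste(names(sz), sz, sep = "=", collapse = ", "), "\n")
})
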