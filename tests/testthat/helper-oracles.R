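# Independent oracles and small fixture builders shared across test files.

# brute-force MCC: enumerate every vertex subset, keep cliques that no
# outside vertex extends, and sum (|C|-1)! per member
oracleMCC <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  score <- stats::setNames(numeric(n), nodes)
  for (sz in 2:n) {
    cmb <- utils::combn(n, sz)
    for (j in seq_len(ncol(cmb))) {
      s <- cmb[, j]
      if (all(A[s, s][upper.tri(diag(sz))] == 1)) {
        extendable <- any(vapply(setdiff(seq_len(n), s),
                                 function(u) all(A[u, s] == 1), logical(1)))
        if (!extendable)
          score[s] <- score[s] + factorial(sz - 1)
      }
    }
  }
  score
}

# double-loop topological overlap from an adjacency matrix
oracleTOM <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# data whose sample correlation matrix equals R exactly (orthonormalize iid
# draws, then mix with the Cholesky factor)
exactCorData <- function(R, n, seed = 1) {
  set.seed(seed)
  p <- nrow(R)
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z))[, seq_len(p)]
  x <- q %*% chol(R)
  t(x)                                   # genes x samples
}

# NormalizedExpr from a bare matrix plus a default two-group design
makeNE <- function(m, trait = NULL, batch = NULL, sex = NULL,
                   stages = "cpm_log_pedestal") {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  n <- ncol(m)
  if (is.null(trait)) trait <- rep(c("WT", "MUT"), each = ceiling(n / 2))[seq_len(n)]
  if (is.null(batch)) batch <- rep_len(c(1, 2), n)
  if (is.null(sex)) sex <- rep_len(c("M", "M", "F", "F"), n)
  dysnet:::newNormalizedExpr(
    m, S4Vectors::DataFrame(trait = factor(trait, levels = unique(trait)),
                            batch = factor(batch), sex = factor(sex),
                            row.names = colnames(m)),
    stages = stages)
}

# the standard normalization chain up to the floor filter
normChain <- function(counts, ...) {
  floorFilter(correctBatch(cyclicLowess(cpmLogPedestal(counts))), ...)
}

# canonical planted-module study conditions: trait-up and trait-down modules
# plus a dominant trait-independent background module
canonicalModules <- function() {
  list(list(size = 150, rho = 0.9,  loading = c(0.5, 1.5)),
       list(size = 150, rho = -0.75, loading = c(0.5, 1.5)),
       list(size = 600, rho = 0,    loading = c(0.5, 1.5)))
}

# map each true module to the detected label holding most of its genes
mapDetected <- function(detected, truth) {
  ov <- table(detected, truth)
  vapply(setdiff(colnames(ov), "none"),
         function(tm) rownames(ov)[which.max(ov[, tm])], character(1))
}

stringToyFile <- function() {
  # three edges: A-B carried by experiments only (950), A-C by textmining
  # only (900), B-D weak experiments (500)
  tab <- data.frame(
    protein1 = c("A", "A", "B"),
    protein2 = c("B", "C", "D"),
    neighborhood = 0L, fusion = 0L, cooccurence = 0L, coexpression = 0L,
    experimental = c(950L, 0L, 500L),
    database = 0L,
    textmining = c(0L, 900L, 0L),
    combined_score = c(950L, 900L, 500L))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
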