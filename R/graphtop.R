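#' @importFrom stats phyper
#' @importFrom utils read.table write.table combn
NULL

# channel aliases: spec-facing name -> column names accepted in STRING files
.channelAliases <- list(
  neighborhood = c("neighborhood", "neighborhood_transferred"),
  fusion = "fusion",
  cooccurrence = c("cooccurrence", "cooccurence"),
  coexpression = c("coexpression", "coexpression_transferred"),
  experiments = c("experiments", "experimental", "experiments_transferred"),
  databases = c("databases", "database", "databases_transferred"),
  textmining = c("textmining", "textmining_transferred"))

#' Combine evidence-channel scores with the prior-corrected product rule
#'
#' Each channel score (probability scale) is stripped of the random-expectation
#' prior `p0`, the corrected scores are combined as one minus the product of
#' their complements, and the prior is added back:
#' `s = (1 - prod(1 - s_i')) * (1 - p0) + p0` with
#' `s_i' = max((s_i - p0) / (1 - p0), 0)`.
#'
#' @param scores numeric matrix in [0, 1], one row per edge, one column per
#'   channel.
#' @param p0 prior probability of a random interaction (default 0.041).
#' @return numeric vector of combined scores in [p0, 1).
#' @export
combineChannelScores <- function(scores, p0 = 0.041) {
  scores <- as.matrix(scores)
  if (any(scores < 0 | scores > 1)) stop("channel scores must lie in [0, 1]")
  corr <- pmax((scores - p0) / (1 - p0), 0)
  tot <- 1 - apply(1 - corr, 1L, prod)
  tot * (1 - p0) + p0
}

.asEdgeTable <- function(path) {
  if (is.data.frame(path)) return(path)
  read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Load and filter a STRING-format interaction edge list
#'
#' Reads a STRING-dialect table (`protein1`, `protein2`, per-channel integer
#' scores in [0, 1000]), recomputes the combined score from the selected
#' evidence channels only (so excluded channels cannot credit an edge),
#' drops edges below the minimum combined score, and removes nodes left
#' without edges.
#'
#' @param path file path or data.frame in the STRING column dialect.
#' @param channels evidence channels to keep (default the high-confidence
#'   trio `experiments`, `databases`, `fusion`).
#' @param minCombined minimum combined score, probability scale in [0, 1]
#'   (values > 1 are interpreted on the 0-1000 scale); default 0.9.
#' @param p0 prior passed to [combineChannelScores()].
#' @return an undirected [igraph::igraph]; edges carry the per-channel
#'   scores and the recomputed `combined_score` (0-1000 integer scale).
#' @export
loadInteractions <- function(path,
                             channels = c("experiments", "databases",
                                          "fusion"),
                             minCombined = 0.9, p0 = 0.041) {
  tab <- .asEdgeTable(path)
  if (!all(c("protein1", "protein2") %in% colnames(tab)))
    stop("need 'protein1' and 'protein2' columns")
  unknown <- setdiff(channels, names(.channelAliases))
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  if (minCombined > 1) minCombined <- minCombined / 1000

  scoreCols <- intersect(unlist(.channelAliases), colnames(tab))
  for (cl in scoreCols) {
    s <- tab[[cl]]
    if (!is.numeric(s) || anyNA(s) || any(s < 0 | s > 1000))
      stop("malformed score column: ", cl)
  }
  sel <- matrix(0, nrow(tab), length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    col <- intersect(.channelAliases[[ch]], colnames(tab))
    if (length(col)) sel[, ch] <- tab[[col[1]]] / 1000
  }
  combined <- combineChannelScores(sel, p0 = p0)

  keep <- combined >= minCombined &
    tab$protein1 != tab$protein2
  tab <- tab[keep, , drop = FALSE]
  combined <- combined[keep]
  key <- paste(pmin(tab$protein1, tab$protein2),
               pmax(tab$protein1, tab$protein2))
  first <- !duplicated(key)
  tab <- tab[first, , drop = FALSE]
  combined <- combined[first]

  g <- igraph::graph_from_data_frame(
    data.frame(from = tab$protein1, to = tab$protein2,
               stringsAsFactors = FALSE),
    directed = FALSE)
  for (cl in scoreCols)
    g <- igraph::set_edge_attr(g, cl, value = tab[[cl]])
  g <- igraph::set_edge_attr(g, "combined_score",
                             value = as.integer(round(combined * 1000)))
  g
}

.checkSimple <- function(graph) {
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (any(igraph::which_multiple(graph)) || any(igraph::which_loop(graph)))
    stop("graph must be simple (no multi-edges or self-loops)")
}

#' Maximal clique centrality (MCC) hub ranking
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques `C`
#' containing `v`. When no two neighbors of `v` are adjacent every maximal
#' clique through `v` is a single edge, so the score reduces to the degree;
#' isolated nodes score 0. Maximal cliques are enumerated exactly
#' (pivoting branch-and-bound); enumeration aborts if the clique count
#' exceeds `maxCliques`.
#'
#' @param graph a simple undirected [igraph::igraph].
#' @param maxCliques guard on the number of maximal cliques (default 1e6).
#' @return data.frame with `node`, `mcc`, `degree` and dense `rank`
#'   (ties share a rank), ordered by rank.
#' @export
mccScores <- function(graph, maxCliques = 1e6) {
  .checkSimple(graph)
  nCl <- igraph::count_max_cliques(graph, min = 2)
  if (nCl > maxCliques)
    stop("clique enumeration guard tripped: ", nCl, " maximal cliques ",
         "exceed maxCliques = ", maxCliques)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  score <- setNames(numeric(length(nodes)), nodes)
  cliques <- igraph::max_cliques(graph, min = 2)
  for (cl in cliques) {
    idx <- as.integer(cl)
    score[idx] <- score[idx] + factorial(length(idx) - 1)
  }
  deg <- igraph::degree(graph)
  rank <- match(score, sort(unique(score), decreasing = TRUE))
  out <- data.frame(node = nodes, mcc = unname(score),
                    degree = unname(deg), rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$rank, out$node), ]
}

#' Select top hub nodes by MCC dense rank
#'
#' @param hubTable output of [mccScores()].
#' @param top number of dense ranks to keep (default 10); co-ranked ties are
#'   all retained, so more than `top` nodes may be returned.
#' @return character vector of hub node ids.
#' @export
topHubs <- function(hubTable, top = 10) {
  hubTable$node[hubTable$rank <= top & hubTable$mcc > 0]
}

#' Topological coefficients
#'
#' For a node `v` with degree `k(v)`, over all nodes `u != v` sharing at
#' least one neighbor with `v`, `J(v, u)` counts the shared neighbors plus 1
#' if `u` and `v` are adjacent; `TC(v)` is the mean of `J(v, u) / k(v)`.
#' Nodes with no qualifying partner (including isolated nodes) score 0. In
#' hub-and-spoke networks TC falls with degree.
#'
#' @param graph a simple undirected [igraph::igraph].
#' @return named numeric vector of TC values.
#' @export
topologicalCoefficients <- function(graph) {
  .checkSimple(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  S <- A %*% A                       # shared-neighbor counts
  k <- igraph::degree(graph)
  n <- nrow(A)
  tc <- setNames(numeric(n), rownames(A))
  for (v in seq_len(n)) {
    if (k[v] < 1) next
    sv <- S[v, ]
    partners <- which(sv > 0)
    partners <- partners[partners != v]
    if (!length(partners)) next
    J <- sv[partners] + A[v, partners]
    tc[v] <- mean(J) / k[v]
  }
  tc
}

.graphStats <- function(graph) {
  n <- igraph::vcount(graph)
  e <- igraph::ecount(graph)
  list(n_nodes = n, n_edges = e,
       n_components = if (n) igraph::components(graph)$no else 0L,
       avg_degree = if (n) 2 * e / n else 0)
}

#' Delete nodes and report fragmentation statistics
#'
#' Removes the listed nodes, then also removes any node left without edges
#' (disconnected nodes are dropped from the network), and reports node,
#' edge, component and mean-degree counts before and after.
#'
#' @param graph a simple undirected [igraph::igraph].
#' @param nodes node ids to delete (must exist; may be empty).
#' @return list with `graph` (the pruned graph), `before`, `after` (stats
#'   lists) and `removedDisconnected` (ids dropped because the deletion
#'   isolated them).
#' @export
deleteNodesStats <- function(graph, nodes) {
  .checkSimple(graph)
  vn <- igraph::V(graph)$name
  missing <- setdiff(nodes, vn)
  if (length(missing))
    stop("unknown node id(s): ", paste(missing, collapse = ", "))
  before <- .graphStats(graph)
  g2 <- igraph::delete_vertices(graph, nodes)
  isolated <- igraph::V(g2)$name[igraph::degree(g2) == 0]
  if (length(nodes)) g2 <- igraph::delete_vertices(g2, isolated)
  else isolated <- character()
  list(graph = g2, before = before, after = .graphStats(g2),
       removedDisconnected = isolated)
}

#' Grow a network from seed genes by direct interactions only
#'
#' Starting from the seed genes, candidates are admitted if and only if
#' they have a direct edge to a node already in the network; admission
#' repeats to a fixpoint, so candidate chains reach in only through the
#' seeds, and candidate-only components stay excluded. The result is the
#' interactome subgraph induced by the included nodes.
#'
#' @param seeds nonempty character vector of seed ids.
#' @param candidates character vector of candidate ids (e.g. a DEG list).
#' @param interactome a simple undirected [igraph::igraph].
#' @return the grown [igraph::igraph] (empty, with a warning, when no seed
#'   is present in the interactome).
#' @export
growSeededNetwork <- function(seeds, candidates, interactome) {
  if (!length(seeds)) stop("seeds must be nonempty")
  .checkSimple(interactome)
  vn <- igraph::V(interactome)$name
  included <- intersect(seeds, vn)
  if (!length(included)) {
    warning("no seed present in the interactome; returning an empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  pool <- setdiff(intersect(candidates, vn), included)
  repeat {
    if (!length(pool)) break
    reach <- vapply(pool, function(u)
      any(igraph::neighbors(interactome, u)$name %in% included), logical(1))
    if (!any(reach)) break
    included <- c(included, pool[reach])
    pool <- pool[!reach]
  }
  igraph::induced_subgraph(interactome, included)
}

#' Hypergeometric gene-set overrepresentation
#'
#' One-sided hypergeometric upper-tail p-value per set, odds ratio from the
#' 2x2 overlap table (Haldane 0.5 correction when any cell is zero), and
#' Benjamini-Hochberg adjustment across the collection. Sets are first
#' intersected with the universe.
#'
#' @param query character vector of query genes (subset of `universe`).
#' @param collection named list of character vectors (gene sets).
#' @param universe character vector of background genes.
#' @return data.frame with `set`, `setSize`, `overlap`, `expected`,
#'   `oddsRatio`, `p`, `q`.
#' @export
hypergeomEnrichment <- function(query, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes missing from the universe")
  N <- length(universe); q <- length(query)
  res <- lapply(names(collection), function(id) {
    set <- intersect(unique(collection[[id]]), universe)
    m <- length(set)
    k <- length(intersect(query, set))
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    a <- k; b <- q - k; cc <- m - k; d <- N - m - q + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
                                 cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(set = id, setSize = m, overlap = k,
               expected = q * m / N, oddsRatio = (a * d) / (b * cc),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
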