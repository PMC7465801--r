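# Neighbor-graph construction and pluggable community detection.

# exact k nearest neighbors by brute-force distances; ties broken by index
.knn_exact <- function(X, k) {
  n <- nrow(X)
  .assert(k < n, "k must be smaller than the number of cells")
  D <- as.matrix(dist(X))
  idx <- matrix(0L, n, k)
  dmat <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, -i], seq_len(n)[-i])[seq_len(k)]
    nb <- seq_len(n)[-i][o]
    idx[i, ] <- nb
    dmat[i, ] <- D[i, nb]
  }
  list(idx = idx, dist = dmat)
}

#' Build a nearest-neighbor graph of an embedding
#'
#' Supported graph types: `knn` (union-symmetrized k-nearest-neighbor edges
#' with similarity weights `1/(1 + distance)`); `snn_jaccard`
#' (shared-nearest-neighbor graph with Jaccard overlap of the
#' self-inclusive neighborhoods); `snn_rank` (shared-neighbor graph with
#' weight `k - r/2`, `r` being the smallest sum of within-neighborhood ranks
#' of any shared neighbor). Neighbor search is exact (brute force); the
#' `exact` flag is accepted for interface compatibility and an approximate
#' backend can be plugged in by registering one.
#'
#' @param embedding A `pg_embedding` or a cells x dims coordinate matrix.
#' @param k Number of neighbors.
#' @param graph_type One of `"knn"`, `"snn_rank"`, `"snn_jaccard"`.
#' @param exact Logical; only exact search is bundled.
#' @return An undirected weighted [igraph::graph] with one vertex per cell.
#' @export
build_neighbor_graph <- function(embedding, k = 10,
                                 graph_type = c("snn_jaccard", "snn_rank", "knn"),
                                 exact = TRUE) {
  graph_type <- match.arg(graph_type)
  X <- if (inherits(embedding, "pg_embedding")) embedding$coords
       else as.matrix(embedding)
  n <- nrow(X)
  nn <- .knn_exact(X, k)
  if (graph_type == "knn") {
    ii <- rep(seq_len(n), each = k)
    jj <- as.vector(t(nn$idx))
    ww <- 1 / (1 + as.vector(t(nn$dist)))
    a <- pmin(ii, jj); b <- pmax(ii, jj)
    keep <- !duplicated(cbind(a, b))
    g <- igraph::graph_from_edgelist(cbind(a, b)[keep, , drop = FALSE],
                                     directed = FALSE)
    igraph::E(g)$weight <- ww[keep]
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    return(g)
  }
  # neighborhoods including self (rank 0 for self)
  hood <- cbind(seq_len(n), nn$idx)
  if (graph_type == "snn_jaccard") {
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                              j = as.vector(hood), x = 1, dims = c(n, n))
    S <- Matrix::tcrossprod(A)            # shared-neighbor counts
    S <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
    sel <- S@i < S@j & S@x > 0
    ii <- S@i[sel] + 1L; jj <- S@j[sel] + 1L
    shared <- S@x[sel]
    w <- shared / (2 * (k + 1L) - shared)  # Jaccard of neighborhoods
    g <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
    igraph::E(g)$weight <- w
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    return(g)
  }
  # snn_rank: for each shared neighbor v of (i, j), rank sum = rank_i(v) +
  # rank_j(v); weight = k - min_v(ranksum)/2, floored at a small positive value
  rank_of <- matrix(NA_integer_, n, n)    # dense is fine at bundled scale
  for (i in seq_len(n)) rank_of[i, hood[i, ]] <- 0:(k)
  # accumulate minimal rank sums via each potential shared neighbor
  members <- vector("list", n)
  for (i in seq_len(n)) for (v in hood[i, ])
    members[[v]] <- c(members[[v]], i)
  emap <- new.env(parent = emptyenv())
  for (v in seq_len(n)) {
    ms <- members[[v]]
    if (length(ms) < 2) next
    for (a in seq_along(ms)[-length(ms)]) for (b in (a + 1L):length(ms)) {
      i <- ms[a]; j <- ms[b]
      if (i == j) next
      key <- paste(min(i, j), max(i, j))
      rs <- rank_of[i, v] + rank_of[j, v]
      old <- emap[[key]]
      if (is.null(old) || rs < old) emap[[key]] <- rs
    }
  }
  keys <- ls(emap)
  if (length(keys)) {
    prs <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
    w <- pmax(vapply(keys, function(kk) k - emap[[kk]] / 2, numeric(1)), 1e-8)
    g <- igraph::graph_from_edgelist(prs, directed = FALSE)
    igraph::E(g)$weight <- as.numeric(w)
  } else g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  g
}

#' Cluster a cell graph
#'
#' Pluggable community detection. `modularity_resolution` optimizes
#' modularity with a resolution parameter (multilevel/Louvain);
#' `walk_based` uses random-walk communities (walktrap);
#' `greedy_modularity` uses greedy modularity agglomeration. Runs are seeded
#' for determinism.
#'
#' @param graph An [igraph::graph] (weighted edges used when present).
#' @param method One of `"modularity_resolution"`, `"walk_based"`,
#'   `"greedy_modularity"`.
#' @param resolution Resolution parameter (only `modularity_resolution`
#'   honors it; larger values give more clusters).
#' @param seed RNG seed.
#' @return Integer cluster labels (1-based), one per vertex.
#' @export
cluster_graph <- function(graph, method = c("modularity_resolution",
                                            "walk_based", "greedy_modularity"),
                          resolution = 1, seed = 0L) {
  method <- match.arg(method)
  .assert(igraph::vcount(graph) >= 1, "empty graph")
  set.seed(as.integer(seed))
  cm <- switch(method,
    modularity_resolution = igraph::cluster_louvain(graph,
                                                    resolution = resolution),
    walk_based = igraph::cluster_walktrap(graph),
    greedy_modularity = igraph::cluster_fast_greedy(
      igraph::simplify(graph, edge.attr.comb = "max")))
  as.integer(igraph::membership(cm))
}
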