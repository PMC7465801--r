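# Cluster-informed artificial-doublet detection: artificial doublets are
# sums of real cells from different clusters; each real cell is scored by the
# artificial-doublet enrichment of its neighborhood in PCA space, and calls
# are thresholded around an expected doublet rate with uncertainty.

#' Doublet-caller parameters
#'
#' @param n_artificial Number of artificial doublets (default: one per real
#'   cell; must be at least `n_cells / 10`).
#' @param k_neighbors Neighbors used for scoring.
#' @param expected_rate Expected doublet fraction, in (0, 0.5).
#' @param rate_uncertainty Half-width of the accepted rate interval (calls
#'   are placed within `expected_rate` +/- `rate_uncertainty`).
#' @param include_metacell_triplets Add composite artificials made of a
#'   cluster meta-cell profile plus a sampled cell, emulating triplets.
#' @param n_pcs Principal components for the joint embedding.
#' @param n_hvg Variable genes kept for the joint embedding.
#' @param seed RNG seed.
#' @return A `doublet_params` list.
#' @export
doublet_params <- function(n_artificial = NULL, k_neighbors = 10,
                           expected_rate = 0.05, rate_uncertainty = 0.02,
                           include_metacell_triplets = FALSE, n_pcs = 10,
                           n_hvg = 1000, seed = 0L) {
  .assert(expected_rate > 0 && expected_rate < 0.5,
          "expected_rate must be in (0, 0.5)")
  .assert(k_neighbors >= 1, "k_neighbors must be >= 1")
  .assert(rate_uncertainty >= 0, "rate_uncertainty must be >= 0")
  structure(list(n_artificial = n_artificial, k_neighbors = as.integer(k_neighbors),
                 expected_rate = expected_rate,
                 rate_uncertainty = rate_uncertainty,
                 include_metacell_triplets = isTRUE(include_metacell_triplets),
                 n_pcs = as.integer(n_pcs), n_hvg = as.integer(n_hvg),
                 seed = as.integer(seed)), class = "doublet_params")
}

#' Generate artificial doublets
#'
#' Each artificial doublet is the entrywise sum of the raw counts of two
#' cells sampled from different clusters (cluster pairs drawn uniformly over
#' distinct pairs); counts are summed raw, since a real doublet is the union
#' of two transcript pools. With `include_metacell_triplets`, additional
#' artificials combine a cluster meta-cell profile (rounded per-gene mean)
#' with a sampled cell from another cluster. With a single cluster the
#' generator falls back to uniform random pairs (with a warning).
#'
#' @param counts Gene-by-cell raw counts (matrix or `pg_dataset`).
#' @param clusters Integer/factor cluster labels per cell.
#' @param params A [doublet_params()] object.
#' @return List with `counts` (genes x artificials), `parents` (2-column
#'   matrix of parent cell indices; meta-cell parents are `NA`) and
#'   `parent_clusters`.
#' @export
generate_artificial_doublets <- function(counts, clusters,
                                         params = doublet_params()) {
  if (inherits(counts, "pg_dataset")) counts <- counts$counts
  n <- ncol(counts)
  clusters <- as.integer(factor(clusters))
  .assert(length(clusters) == n, "cluster labels must match cells")
  n_art <- params$n_artificial %||% n
  .assert(n_art >= n / 10, "n_artificial must be at least n_cells / 10")
  set.seed(params$seed)
  ncl <- max(clusters)
  if (ncl < 2) {
    warning("single cluster: falling back to uniform random pairs")
    p1 <- sample.int(n, n_art, replace = TRUE)
    p2 <- vapply(p1, function(i) sample(seq_len(n)[-i], 1L), integer(1))
  } else {
    pairs <- combn(ncl, 2)
    pick <- sample.int(ncol(pairs), n_art, replace = TRUE)
    p1 <- vapply(pairs[1, pick], function(cl)
      sample(which(clusters == cl), 1L), integer(1))
    p2 <- vapply(pairs[2, pick], function(cl)
      sample(which(clusters == cl), 1L), integer(1))
  }
  art <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  parents <- cbind(p1, p2)
  pcl <- cbind(clusters[p1], clusters[p2])
  if (params$include_metacell_triplets && ncl >= 2) {
    n_tri <- max(1L, round(n_art / 4))
    meta <- vapply(seq_len(ncl), function(cl)
      round(Matrix::rowMeans(counts[, clusters == cl, drop = FALSE])),
      numeric(nrow(counts)))
    mcl <- sample.int(ncl, n_tri, replace = TRUE)
    other <- vapply(mcl, function(cl)
      sample(which(clusters != cl), 1L), integer(1))
    tri <- meta[, mcl, drop = FALSE] + as.matrix(counts[, other, drop = FALSE])
    art <- cbind(as.matrix(art), tri)
    parents <- rbind(parents, cbind(NA_integer_, other))
    pcl <- rbind(pcl, cbind(mcl, clusters[other]))
  }
  art <- .as_dgc(art)
  colnames(art) <- paste0("art", seq_len(ncol(art)))
  list(counts = art, parents = parents, parent_clusters = pcl)
}

#' Score cells for doublet likelihood
#'
#' Embeds real cells and artificial doublets jointly (log-normalization, top
#' variable genes, PCA) and scores each real cell by the fraction of
#' artificial doublets among its k nearest neighbors, normalized for the
#' artificial:real ratio so that a score of 0.5 means the neighborhood
#' matches the global composition. Scores lie in [0, 1] and increase with
#' neighborhood artificial-doublet enrichment.
#'
#' @param counts Real gene-by-cell counts (matrix or `pg_dataset`).
#' @param artificial Output of [generate_artificial_doublets()] (or a counts
#'   matrix).
#' @param params A [doublet_params()].
#' @return A `pg_doublet_scores` data.frame with `barcode` and `score`.
#' @export
score_doublets <- function(counts, artificial, params = doublet_params()) {
  if (inherits(counts, "pg_dataset")) counts <- counts$counts
  art <- if (is.list(artificial) && !is.null(artificial$counts))
    artificial$counts else artificial
  n_real <- ncol(counts); n_art <- ncol(art)
  set.seed(params$seed + 1L)
  comb <- cbind(.as_dgc(counts), .as_dgc(art))
  tot <- Matrix::colSums(comb)
  tot[tot == 0] <- 1
  nm <- lognormalize(comb, size_factors = tot / mean(tot))
  v <- .row_vars(nm$mat)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(params$n_hvg, nrow(comb)))]
  X <- as.matrix(nm$mat[hvg, , drop = FALSE])
  emb <- pca_embed(X, n_components = min(params$n_pcs, min(dim(X)) - 1L))
  k <- params$k_neighbors
  if (k >= n_real + n_art) {
    warning("k_neighbors larger than population; clipping")
    k <- n_real + n_art - 1L
  }
  nn <- .knn_exact(emb$coords, k)
  is_art <- c(rep(FALSE, n_real), rep(TRUE, n_art))
  p_art <- rowMeans(matrix(is_art[nn$idx[seq_len(n_real), ]], n_real, k))
  w <- n_real / n_art   # ratio correction
  score <- (p_art * w) / (p_art * w + (1 - p_art))
  structure(data.frame(barcode = colnames(counts) %||% seq_len(n_real),
                       score = score, stringsAsFactors = FALSE),
            class = c("pg_doublet_scores", "data.frame"),
            n_real = n_real, n_art = n_art)
}

#' Call doublets from scores
#'
#' Chooses the number of calls within the expected-rate band
#' `(expected_rate +/- rate_uncertainty) * n`: within the band, the call
#' count is placed at the steepest drop of the sorted score distribution
#' (the biggest score gap), trading an expected-count prior against the
#' separation of the score distribution. With `rate_uncertainty = 0` this
#' reduces to calling exactly `round(expected_rate * n)` cells. Degenerate
#' constant scores call exactly `round(expected_rate * n)` cells in index
#' order (with a warning).
#'
#' @param scores A `pg_doublet_scores` from [score_doublets()].
#' @param params A [doublet_params()].
#' @return The scores data.frame with added logical `call` column; the chosen
#'   threshold is in `attr(, "threshold")`.
#' @export
call_doublets <- function(scores, params = doublet_params()) {
  s <- scores$score
  n <- length(s)
  lo <- max(0L, floor((params$expected_rate - params$rate_uncertainty) * n))
  hi <- min(n, ceiling((params$expected_rate + params$rate_uncertainty) * n))
  target <- round(params$expected_rate * n)
  ord <- order(-s, seq_len(n))
  if (max(s) - min(s) < .Machine$double.eps^0.5) {
    warning("constant scores; calling the expected number of cells by index")
    n_call <- target
    thr <- s[1]
  } else if (params$rate_uncertainty == 0 || lo >= hi) {
    n_call <- target
    sorted <- s[ord]
    thr <- if (n_call == 0) Inf else if (n_call >= n) -Inf
           else (sorted[n_call] + sorted[n_call + 1]) / 2
  } else {
    sorted <- s[ord]
    cand <- seq(max(1L, lo), min(hi, n - 1L))
    gaps <- sorted[cand] - sorted[cand + 1L]
    n_call <- cand[which.max(gaps)]
    thr <- (sorted[n_call] + sorted[n_call + 1L]) / 2
  }
  call <- rep(FALSE, n)
  if (n_call > 0) call[ord[seq_len(n_call)]] <- TRUE
  scores$call <- call
  attr(scores, "threshold") <- thr
  scores
}

#' ROC curve and AUROC of doublet scores
#'
#' Standard ROC over score thresholds; the area is computed by the
#' trapezoidal rule.
#'
#' @param scores Numeric scores (or a `pg_doublet_scores`).
#' @param truth Logical truth flags (TRUE = doublet).
#' @return List with `fpr`, `tpr` (ROC points) and `auroc`.
#' @export
doublet_roc <- function(scores, truth) {
  if (is.data.frame(scores)) scores <- scores$score
  truth <- as.logical(truth)
  .assert(length(scores) == length(truth), "length mismatch")
  .assert(any(truth) && any(!truth), "need both classes in truth")
  ord <- order(-scores, seq_along(scores))
  s <- scores[ord]; y <- truth[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  # one ROC point per distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last] / sum(truth))
  fpr <- c(0, fp[last] / sum(!truth))
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, auroc = auroc)
}
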