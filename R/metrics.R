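# Clustering-evaluation metrics: contingency tables, ARI, mutual
# information, Hungarian-matched per-class precision/recall/F1, ARI at the
# true number of clusters, per-subpopulation silhouette, and cross-pipeline
# misclassification rates.

#' Cross-tabulate truth and predicted labels
#'
#' @param truth,pred Label vectors of equal length.
#' @return Integer matrix: true classes (rows) x predicted clusters (columns).
#' @export
contingency <- function(truth, pred) {
  .assert(length(truth) == length(pred), "label vectors differ in length")
  .assert(length(truth) >= 1, "need at least one cell")
  unclass(table(truth = as.character(truth), pred = as.character(pred)))
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie form) computed
#' from a contingency table.
#'
#' @param tab Contingency table from [contingency()] (or two label vectors
#'   via `ari(truth, pred)`).
#' @param pred Optional second label vector.
#' @return ARI in (-1, 1]; 1 for identical partitions.
#' @export
ari <- function(tab, pred = NULL) {
  if (!is.null(pred)) tab <- contingency(tab, pred)
  n <- sum(tab)
  .assert(n >= 2, "need at least 2 cells")
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maxi <- (a + b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' Mutual information of two partitions
#'
#' MI of the empirical joint distribution, in natural-log units (nats).
#' The normalized variant (NMI, by the mean of the two entropies) is
#' available via `normalized = TRUE`.
#'
#' @inheritParams ari
#' @param normalized Return NMI instead of raw MI.
#' @return MI >= 0 (equals the truth entropy for identical partitions).
#' @export
mutual_information <- function(tab, pred = NULL, normalized = FALSE) {
  if (!is.null(pred)) tab <- contingency(tab, pred)
  n <- sum(tab)
  .assert(n >= 2, "need at least 2 cells")
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / e[nz]))
  if (!normalized) return(max(mi, 0))
  hr <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  hc <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  if (hr + hc == 0) return(0)
  max(mi, 0) / ((hr + hc) / 2)
}

# Hungarian algorithm (augmenting-path formulation with potentials, O(n^3));
# returns, for a square cost matrix, the column assigned to each row of the
# minimum-cost perfect matching
.hungarian_min <- function(a) {
  n <- nrow(a)
  .assert(ncol(a) == n, "cost matrix must be square")
  if (n == 1L) return(1L)
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, n); used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) if (!used[j + 1]) {
        cur <- a[i0, j] - u[i0] - v[j + 1]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

# optimal one-to-one class->cluster matching maximizing total matched cells;
# rectangular tables are padded with zero-overlap dummies
.match_classes <- function(tab) {
  nr <- nrow(tab); nc <- ncol(tab)
  m <- max(nr, nc)
  full <- matrix(0, m, m)
  full[seq_len(nr), seq_len(nc)] <- tab
  asg <- .hungarian_min(max(full) - full)
  cl_of_class <- asg[seq_len(nr)]
  cl_of_class[cl_of_class > nc] <- NA_integer_   # matched to a dummy
  cl_of_class
}

#' Hungarian-matched per-class precision, recall and F1
#'
#' Clusters are assigned one-to-one to true classes so as to maximize the
#' total number of matched cells (rectangular tables are padded with
#' zero-overlap dummies). Per class: precision = overlap / cluster size,
#' recall = overlap / class size, F1 their harmonic mean (0 for an unmatched
#' class); `mean_F1` is the unweighted mean over true classes.
#'
#' @inheritParams ari
#' @return List with per-class `precision`, `recall`, `F1` (named by class),
#'   `mean_F1`, and the `matching` (cluster index per class, `NA` if
#'   unmatched).
#' @export
match_and_score <- function(tab, pred = NULL) {
  if (!is.null(pred)) tab <- contingency(tab, pred)
  .assert(nrow(tab) >= 1 && ncol(tab) >= 1, "need >= 1 class and cluster")
  cl <- .match_classes(tab)
  csize <- colSums(tab); rsize <- rowSums(tab)
  prec <- rec <- f1 <- setNames(numeric(nrow(tab)),
                                rownames(tab) %||% seq_len(nrow(tab)))
  for (r in seq_len(nrow(tab))) {
    if (is.na(cl[r]) || csize[cl[r]] == 0) next
    ov <- tab[r, cl[r]]
    prec[r] <- ov / csize[cl[r]]
    rec[r] <- ov / rsize[r]
    f1[r] <- if (prec[r] + rec[r] > 0) 2 * prec[r] * rec[r] / (prec[r] + rec[r]) else 0
  }
  list(precision = prec, recall = rec, F1 = f1, mean_F1 = mean(f1),
       matching = cl)
}

#' ARI at the true number of clusters
#'
#' Given evaluations from a resolution sweep (each carrying `n_clusters` and
#' `ari`), returns the maximum ARI among sweep members whose cluster count
#' equals the true number of subpopulations, or `NA` when that number was
#' never reached (rendered as a gray square in heatmaps).
#'
#' @param evals Data frame (or list of lists) with `n_clusters` and `ari`.
#' @param true_k True number of subpopulations.
#' @return ARI, or `NA_real_` when `true_k` is never reached.
#' @export
ari_at_true_k <- function(evals, true_k) {
  if (!is.data.frame(evals)) {
    evals <- data.frame(
      n_clusters = vapply(evals, function(e) as.numeric(e$n_clusters), numeric(1)),
      ari = vapply(evals, function(e) as.numeric(e$ari), numeric(1)))
  }
  .assert(nrow(evals) >= 1, "empty sweep")
  hit <- !is.na(evals$n_clusters) & evals$n_clusters == true_k
  if (!any(hit)) return(NA_real_)
  max(evals$ari[hit], na.rm = TRUE)
}

#' Mean silhouette width per true subpopulation
#'
#' Standard silhouette of each cell against the truth labels in an embedding
#' (Euclidean distances), averaged within each true class; cells of a
#' singleton class get silhouette 0.
#'
#' @param embedding A `pg_embedding` or a cells x dims coordinate matrix.
#' @param truth Truth labels (>= 2 classes).
#' @return Named numeric vector of per-class mean silhouette widths.
#' @export
silhouette_per_subpop <- function(embedding, truth) {
  X <- if (inherits(embedding, "pg_embedding")) embedding$coords
       else as.matrix(embedding)
  truth <- as.character(truth)
  .assert(length(truth) == nrow(X), "labels must match embedding rows")
  .assert(length(unique(truth)) >= 2, "need >= 2 classes")
  D <- as.matrix(dist(X))
  classes <- sort(unique(truth))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- truth == truth[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(classes[classes != truth[i]], function(cl)
      mean(D[i, truth == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  vapply(classes, function(cl) mean(s[truth == cl]),
         numeric(1))
}

#' Per-cell misclassification rates across many clusterings
#'
#' For each clustering outcome, a cell is misclassified when the
#' Hungarian-matched class of its cluster differs from its true class (cells
#' in unmatched clusters count as misclassified). The per-cell rate is the
#' fraction of outcomes misclassifying it; the adjusted rate subtracts the
#' median rate of the cell's true subpopulation, so systematic
#' subpopulation-level difficulty is removed.
#'
#' @param outcomes List of predicted label vectors over the same cells.
#' @param truth Truth labels.
#' @return Data frame with `rate` and `adjusted_rate` per cell.
#' @export
misclassification_rates <- function(outcomes, truth) {
  .assert(length(outcomes) >= 2, "need >= 2 clustering outcomes")
  truth <- as.character(truth)
  n <- length(truth)
  mis <- matrix(FALSE, n, length(outcomes))
  for (o in seq_along(outcomes)) {
    pred <- outcomes[[o]]
    .assert(length(pred) == n, "outcome has a mismatched cell set")
    tab <- contingency(truth, pred)
    cl <- .match_classes(tab)
    class_of_cluster <- rep(NA_character_, ncol(tab))
    class_of_cluster[cl[!is.na(cl)]] <- rownames(tab)[!is.na(cl)]
    pred_class <- class_of_cluster[match(as.character(pred), colnames(tab))]
    mis[, o] <- is.na(pred_class) | pred_class != truth
  }
  rate <- rowMeans(mis)
  med <- tapply(rate, truth, median)
  data.frame(rate = rate, adjusted_rate = rate - as.numeric(med[truth]))
}
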