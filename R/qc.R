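# Per-cell QC metrics and MAD-based cell-filtering strategies.
#
# All percentage-type metrics are stored as fractions in [0, 1]; the absolute
# mitochondrial threshold of 0.08 is read on that scale (8%).

#' Compute per-cell QC metrics
#'
#' Returns the five per-cell metrics consumed by the filter sets:
#' `log10_total_counts`, `log10_total_features` (detected = count > 0),
#' `pct_counts_in_top_20_features` (fraction of a cell's counts held by its 20
#' highest-count genes), `featcount_dist` (the cell's residual from an
#' ordinary least-squares fit of `log10_total_features` on
#' `log10_total_counts` across all cells) and `pct_counts_Mt` (fraction of
#' counts in mitochondria-flagged genes). Cells with zero total counts get
#' `-Inf` log metrics and are flagged via the `zero_total` column so they are
#' always filterable.
#'
#' @param ds A `pg_dataset` (or a counts matrix).
#' @param is_mito Logical per-gene mitochondrial flag; defaults to the
#'   dataset's `gene_meta$is_mito`.
#' @param robust_trend If `TRUE`, the features~counts trend is fitted by
#'   robust regression ([MASS::rlm()]) instead of OLS.
#' @return A `data.frame` (class `pg_qc`) with one row per cell.
#' @export
compute_cell_qc <- function(ds, is_mito = NULL, robust_trend = FALSE) {
  if (inherits(ds, "pg_dataset")) {
    counts <- ds$counts
    if (is.null(is_mito)) is_mito <- ds$gene_meta$is_mito
  } else counts <- .as_dgc(ds)
  if (is.null(is_mito)) is_mito <- rep(FALSE, nrow(counts))
  .assert(length(is_mito) == nrow(counts), "is_mito length must match genes")
  total <- Matrix::colSums(counts)
  nfeat <- Matrix::colSums(counts > 0)
  top20 <- vapply(seq_len(ncol(counts)), function(i) {
    v <- counts[, i]
    if (total[i] == 0) return(1)
    sum(sort(v[v > 0], decreasing = TRUE)[seq_len(min(20L, sum(v > 0)))]) / total[i]
  }, numeric(1))
  mt <- if (any(is_mito)) Matrix::colSums(counts[is_mito, , drop = FALSE])
  else rep(0, ncol(counts))
  pct_mt <- ifelse(total > 0, mt / total, 1)
  lc <- ifelse(total > 0, log10(total), -Inf)
  lf <- ifelse(nfeat > 0, log10(nfeat), -Inf)
  ok <- is.finite(lc) & is.finite(lf)
  fcd <- rep(-Inf, ncol(counts))
  if (sum(ok) >= 2 && sd(lc[ok]) > 0) {
    fit <- if (robust_trend) MASS::rlm(lf[ok] ~ lc[ok], maxit = 100)
    else lm(lf[ok] ~ lc[ok])
    fcd[ok] <- lf[ok] - (coef(fit)[1] + coef(fit)[2] * lc[ok])
  } else if (sum(ok) >= 1) fcd[ok] <- 0
  structure(data.frame(
    log10_total_counts = lc, log10_total_features = lf,
    pct_counts_in_top_20_features = top20, featcount_dist = fcd,
    pct_counts_Mt = pct_mt, zero_total = total == 0,
    row.names = colnames(counts) %||% seq_len(ncol(counts))),
    class = c("pg_qc", "data.frame"),
    has_mito = any(is_mito))
}

#' Flag MAD outliers in a numeric vector
#'
#' A value is an outlier when it lies below `median - nmads_lower * MAD` or
#' above `median + nmads_upper * MAD`, with the MAD scaled by the usual
#' consistency constant 1.4826. Either side can be disabled with an infinite
#' threshold. Non-finite values are always flagged. When the MAD is zero the
#' scale falls back to a small epsilon (`1e-8 * max(1, |median|)`), so values
#' truly distinct from the median are still flagged while constant vectors
#' yield no outliers.
#'
#' @param values Numeric vector (at least 2 finite values).
#' @param nmads_lower,nmads_upper Number of MADs for each side (`Inf`
#'   disables the side).
#' @param log If `TRUE`, values are log10-transformed first (non-positive
#'   values map to `-Inf` and are flagged).
#' @param constant MAD consistency constant.
#' @return Logical mask of outliers.
#' @export
mad_outlier <- function(values, nmads_lower = Inf, nmads_upper = Inf,
                        log = FALSE, constant = 1.4826) {
  if (log) values <- ifelse(values > 0, log10(values), -Inf)
  fin <- is.finite(values)
  .assert(sum(fin) >= 2, "need at least 2 finite values")
  med <- median(values[fin])
  s <- mad(values[fin], constant = constant)
  if (s == 0) s <- 1e-8 * max(1, abs(med))
  out <- !fin
  out[fin] <- (values[fin] < med - nmads_lower * s) |
    (values[fin] > med + nmads_upper * s)
  out
}

# per-metric outlier calls at the thresholds of a given filter set; returns a
# logical matrix cells x criteria
.filter_calls <- function(qc, set_name) {
  has_mt <- isTRUE(attr(qc, "has_mito")) || any(qc$pct_counts_Mt > 0)
  mt_call <- function(nmads, floor_val) {
    if (!has_mt) {
      warning("no mitochondrial annotation; Mt criterion skipped")
      return(rep(FALSE, nrow(qc)))
    }
    mad_outlier(qc$pct_counts_Mt, Inf, nmads) & qc$pct_counts_Mt > floor_val
  }
  switch(set_name,
    default = ,
    stringent = cbind(
      lc  = mad_outlier(qc$log10_total_counts, 5, 2.5),
      lf  = mad_outlier(qc$log10_total_features, 5, 2.5),
      t20 = mad_outlier(qc$pct_counts_in_top_20_features, 5, 5),
      fcd = mad_outlier(qc$featcount_dist, 5, 5),
      mt  = mt_call(2.5, 0.08)),
    lenient = cbind(
      lc  = mad_outlier(qc$log10_total_counts, 5, 5),
      lf  = mad_outlier(qc$log10_total_features, 5, 5),
      t20 = mad_outlier(qc$pct_counts_in_top_20_features, 5, 5),
      fcd = mad_outlier(qc$featcount_dist, 5, 5),
      mt  = mt_call(3, 0.08)),
    veryStringent = cbind(
      lc  = mad_outlier(qc$log10_total_counts, 2, 2),
      lf  = mad_outlier(qc$log10_total_features, 2, 2),
      mt  = if (has_mt) mad_outlier(qc$pct_counts_Mt, 2, 2)
            else rep(FALSE, nrow(qc)),
      t20 = mad_outlier(qc$pct_counts_in_top_20_features, 2, 2)),
    stop("unknown filter set: ", set_name, call. = FALSE))
}

#' Apply a named cell-filter set
#'
#' Implements the four shipped filter sets. `default` excludes cells that are
#' outliers on at least two of: `log10_total_counts` (>2.5 MADs or <5 MADs),
#' `log10_total_features` (>2.5 or <5), `pct_counts_in_top_20_features`
#' (two-sided 5), `featcount_dist` (two-sided 5), `pct_counts_Mt` (>2.5 MADs
#' and absolute value > 0.08). `stringent` uses the same thresholds but
#' excludes on any single criterion. `lenient` requires at least two
#' criteria at 5 MADs (Mt: >3 MADs and > 0.08). `veryStringent` excludes on
#' any single two-sided 2-MAD outlier among `log10_total_counts`,
#' `log10_total_features`, `pct_counts_Mt`, `pct_counts_in_top_20_features`
#' (no absolute Mt floor). Zero-count cells are always excluded.
#'
#' @param qc A `pg_qc` table from [compute_cell_qc()].
#' @param set_name One of `"default"`, `"lenient"`, `"stringent"`,
#'   `"veryStringent"`.
#' @return Logical keep mask (TRUE = cell kept). Purely deterministic in `qc`.
#' @export
apply_filter_set <- function(qc, set_name = c("default", "lenient",
                                              "stringent", "veryStringent")) {
  set_name <- match.arg(set_name)
  calls <- .filter_calls(qc, set_name)
  n_crit <- rowSums(calls)
  excl <- switch(set_name,
                 default = n_crit >= 2,
                 lenient = n_crit >= 2,
                 stringent = n_crit >= 1,
                 veryStringent = n_crit >= 1)
  if (!is.null(qc$zero_total)) excl <- excl | qc$zero_total
  !excl
}

#' Cluster-wise cell filtering
#'
#' Cells are first grouped by a quick graph-based clustering of the
#' log-normalized counts ([quick_cluster()]); the chosen filter set is then
#' applied independently within each cluster and the per-cluster exclusions
#' are combined. Clusters smaller than 3 cells are left unfiltered (the MAD
#' is not meaningful there). This protects genuine subpopulations with, for
#' example, systematically smaller libraries from being removed wholesale by
#' dataset-wide thresholds.
#'
#' @param ds A `pg_dataset`.
#' @param set_name Filter set name, as in [apply_filter_set()].
#' @param clusters Optional precomputed cluster labels; defaults to
#'   [quick_cluster()] output.
#' @param ... Passed to [quick_cluster()].
#' @return Logical keep mask over cells.
#' @export
clusterwise_filter <- function(ds, set_name = "default", clusters = NULL, ...) {
  .assert(inherits(ds, "pg_dataset"), "'ds' must be a pg_dataset")
  if (is.null(clusters)) clusters <- quick_cluster(ds$counts, ...)
  .assert(length(clusters) == ncol(ds$counts),
          "cluster labels must match cells")
  qc <- compute_cell_qc(ds)
  keep <- rep(TRUE, nrow(qc))
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    if (length(idx) < 3) next
    sub <- qc[idx, , drop = FALSE]
    attr(sub, "has_mito") <- attr(qc, "has_mito")
    class(sub) <- class(qc)
    keep[idx] <- apply_filter_set(sub, set_name)
  }
  keep
}

#' Multivariate PCA-based QC outlier filter
#'
#' Computes a robust Mahalanobis distance (minimum covariance determinant
#' estimate) on standardized QC covariates and excludes cells beyond the
#' chi-squared 0.999 quantile. `covariates = "all"` uses every numeric QC
#' metric; `"selected"` uses log counts, log features, mitochondrial fraction
#' and the top-features fraction. A singular covariance triggers a fallback
#' to the union of per-axis two-sided 3-MAD outliers (with a warning).
#'
#' @param qc A `pg_qc` table (>= 10 cells).
#' @param covariates `"all"` or `"selected"`.
#' @param quantile Chi-squared exclusion quantile.
#' @return Logical keep mask.
#' @export
pca_outlier_filter <- function(qc, covariates = c("all", "selected"),
                               quantile = 0.999) {
  covariates <- match.arg(covariates)
  cols <- if (covariates == "selected")
    c("log10_total_counts", "log10_total_features", "pct_counts_Mt",
      "pct_counts_in_top_20_features")
  else c("log10_total_counts", "log10_total_features",
         "pct_counts_in_top_20_features", "featcount_dist", "pct_counts_Mt")
  X <- as.matrix(qc[, cols, drop = FALSE])
  .assert(nrow(X) >= 10, "need at least 10 cells")
  bad <- !apply(X, 1, function(r) all(is.finite(r)))
  Xf <- X[!bad, , drop = FALSE]
  keep_cols <- apply(Xf, 2, sd) > 0
  Xs <- scale(Xf[, keep_cols, drop = FALSE])
  res <- tryCatch({
    mcd <- MASS::cov.mcd(Xs)
    d2 <- mahalanobis(Xs, mcd$center, mcd$cov)
    d2 > qchisq(quantile, df = ncol(Xs))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    warning("robust covariance failed (", conditionMessage(res),
            "); falling back to per-axis MAD union")
    res <- rowSums(vapply(seq_len(ncol(Xs)), function(j)
      mad_outlier(Xs[, j], 3, 3), logical(nrow(Xs)))) > 0
  }
  keep <- rep(TRUE, nrow(X))
  keep[bad] <- FALSE
  keep[which(!bad)[res]] <- FALSE
  keep
}

#' Quick graph-based pre-clustering
#'
#' Self-contained stand-in for a quick-clustering step: log-normalize, take
#' the most variable genes, embed with PCA and cluster a shared-nearest-
#' neighbor graph by modularity optimization. Used by [clusterwise_filter()]
#' and by the doublet generator.
#'
#' @param counts Gene-by-cell counts.
#' @param n_hvg Number of variable genes (default 1000).
#' @param n_pcs Number of principal components (default 10).
#' @param k Neighbors for the SNN graph (default 10).
#' @param min_size Clusters smaller than this are merged into the nearest
#'   (by centroid) larger cluster.
#' @param seed RNG seed.
#' @return Integer cluster labels per cell.
#' @export
quick_cluster <- function(counts, n_hvg = 1000, n_pcs = 10, k = 10,
                          min_size = 10, seed = 0L) {
  counts <- .as_dgc(counts)
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  nm <- lognormalize(counts, size_factors = tot / mean(tot))
  v <- .row_vars(nm$mat)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(counts)))]
  X <- as.matrix(nm$mat[hvg, , drop = FALSE])
  X <- X - rowMeans(X)
  emb <- pca_embed(X, n_components = min(n_pcs, dim(X) - 1L),
                   weight_by_variance = TRUE, center = FALSE)
  g <- build_neighbor_graph(emb, k = min(k, ncol(counts) - 1L),
                            graph_type = "snn_jaccard")
  cl <- cluster_graph(g, method = "modularity_resolution", resolution = 1,
                      seed = seed)
  # merge tiny clusters into the nearest larger one (centroid distance)
  tab <- table(cl)
  small <- as.integer(names(tab)[tab < min_size])
  big <- as.integer(names(tab)[tab >= min_size])
  if (length(small) && length(big)) {
    cent <- vapply(big, function(b)
      colMeans(emb$coords[cl == b, , drop = FALSE]), numeric(ncol(emb$coords)))
    for (s in small) {
      cs <- colMeans(emb$coords[cl == s, , drop = FALSE])
      d <- colSums((cent - cs)^2)
      cl[cl == s] <- big[which.min(d)]
    }
  }
  as.integer(factor(cl))
}
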