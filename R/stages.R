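# Reference implementations of the pipeline's processing stages:
# log-normalization, covariate regression + unit-variance scaling, feature
# ranking (mean / variance / standardized variance / binomial deviance),
# feature-type exclusion and PCA embedding.

# per-row means/vars that work for dense and dgCMatrix input
.row_means <- function(m) if (is(m, "Matrix")) Matrix::rowMeans(m) else rowMeans(m)
.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(0, nrow(m)))
  mu <- .row_means(m)
  if (is(m, "Matrix")) (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
  else (rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Log-normalize counts
#'
#' Divides each cell's counts by its total, multiplies by `scale_target`
#' (default 10,000) and applies `log1p` — the standard log-normalization of
#' scRNA-seq toolkits.
#'
#' @param counts Non-negative gene-by-cell matrix.
#' @param scale_target Library-size target after rescaling.
#' @param size_factors Optional per-cell size factors (default: totals divided
#'   by `scale_target`, i.e. counts-per-`scale_target`).
#' @return A `pg_norm` object: `mat` (normalized matrix, same shape),
#'   `size_factors`, `transform = "lognorm"`.
#' @export
lognormalize <- function(counts, scale_target = 1e4, size_factors = NULL) {
  if (!is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- .as_dgc(counts)
  tot <- Matrix::colSums(counts)
  if (is.null(size_factors)) {
    .assert(all(tot > 0), "cells with zero total counts must be filtered first")
    size_factors <- tot / scale_target
  }
  .assert(all(size_factors > 0), "size factors must be positive")
  mat <- counts %*% Matrix::Diagonal(x = 1 / size_factors)
  mat@x <- log1p(mat@x)
  dimnames(mat) <- dimnames(counts)
  structure(list(mat = mat, size_factors = size_factors,
                 transform = "lognorm"), class = "pg_norm")
}

#' Regress out covariates and scale genes to unit variance
#'
#' If `covariates` is given, each gene is first replaced by the residuals of
#' an ordinary least-squares regression on the covariates; genes are then
#' centered and scaled to unit variance (zero-variance genes are set to 0).
#' Optionally clips absolute values.
#'
#' @param norm A `pg_norm` object or a numeric matrix (genes x cells).
#' @param covariates Optional per-cell data.frame/matrix of covariates to
#'   regress out.
#' @param clip Optional positive clip value for the scaled matrix.
#' @return Dense scaled matrix (genes x cells).
#' @export
scale_features <- function(norm, covariates = NULL, clip = NULL) {
  X <- if (inherits(norm, "pg_norm")) as.matrix(norm$mat) else as.matrix(norm)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    .assert(nrow(covariates) == ncol(X),
            "covariate rows must match the number of cells")
    mm <- model.matrix(~ ., data = covariates)
    # residuals of every gene on the covariates in one shot
    Q <- qr(mm)
    X <- t(qr.resid(Q, t(X)))
  }
  mu <- rowMeans(X)
  s <- sqrt(.row_vars(X))
  zero <- s <= 1e-10 * (max(abs(X)) + 1)   # numerically zero variance
  X <- (X - mu) / ifelse(zero, 1, s)
  X[zero, ] <- 0
  if (!is.null(clip)) X <- pmin(pmax(X, -clip), clip)
  X
}

#' Rank features for selection
#'
#' Supported criteria: `mean_expression` (per-gene mean of normalized
#' values), `variance` (per-gene variance of normalized values),
#' `standardized_variance` (variance of values standardized by a fitted
#' mean-variance trend, clipped at `sqrt(n)`, in the spirit of Seurat's vst)
#' and `deviance` (per-gene binomial deviance under a constant-proportion
#' null, computed on raw counts):
#' \deqn{D_g = 2 \sum_i [ y_{gi} \ln(y_{gi}/(n_i \hat\pi_g)) +
#'   (n_i - y_{gi}) \ln((n_i - y_{gi})/(n_i (1-\hat\pi_g))) ]}
#' with \eqn{\hat\pi_g = \sum_i y_{gi} / \sum_i n_i} and \eqn{0 \ln 0 = 0}.
#'
#' @param x Counts matrix for `deviance`; a `pg_norm` (or normalized matrix)
#'   otherwise.
#' @param method Ranking criterion.
#' @return A `pg_ranking`: data.frame of `gene`, `value`, ordered by
#'   decreasing criterion (ties broken by original gene order).
#' @export
rank_features <- function(x, method = c("variance", "mean_expression",
                                        "standardized_variance", "deviance")) {
  method <- match.arg(method)
  if (method == "deviance") {
    if (inherits(x, "pg_norm"))
      stop("deviance ranking needs raw counts, not normalized values")
    X <- x
    value <- binomial_deviance(as.matrix(X))
  } else {
    X <- if (inherits(x, "pg_norm")) x$mat else x
    value <- switch(method,
      mean_expression = .row_means(X),
      variance = .row_vars(X),
      standardized_variance = .standardized_variance(X))
  }
  genes <- rownames(X) %||% paste0("G", seq_along(value))
  ord <- order(-value, seq_along(value))
  structure(data.frame(gene = genes[ord], value = value[ord],
                       stringsAsFactors = FALSE),
            class = c("pg_ranking", "data.frame"), method = method)
}

# Seurat-vst-style criterion: local regression of log10 variance on log10
# mean, then variance of values standardized by the fitted sd, clipped
.standardized_variance <- function(X) {
  mu <- .row_means(X)
  v <- .row_vars(X)
  out <- numeric(length(mu))
  use <- mu > 0 & v > 0
  if (sum(use) >= 10) {
    fit <- loess(log10(v[use]) ~ log10(mu[use]), span = 0.3, degree = 2)
    sd_fit <- sqrt(10^fitted(fit))
    Xu <- as.matrix(X[use, , drop = FALSE])
    n <- ncol(Xu)
    Z <- (Xu - mu[use]) / sd_fit
    clipmax <- sqrt(n)
    Z <- pmin(pmax(Z, -clipmax), clipmax)
    out[use] <- apply(Z, 1, var)
  } else out[use] <- v[use]
  out
}

#' Per-gene binomial deviance
#'
#' Deviance of each gene's counts against a constant-proportion null (each
#' cell's count a binomial draw from its total), the criterion suggested for
#' feature selection on raw counts.
#'
#' @param counts Gene-by-cell count matrix.
#' @return Numeric vector of deviances (one per gene).
#' @export
binomial_deviance <- function(counts) {
  counts <- as.matrix(counts)
  n <- colSums(counts)
  N <- sum(n)
  vapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    pi_hat <- sum(y) / N
    if (pi_hat <= 0 || pi_hat >= 1) return(0)
    xlogx <- function(a, b) ifelse(a > 0, a * log(a / b), 0)
    2 * sum(xlogx(y, n * pi_hat) + xlogx(n - y, n * (1 - pi_hat)))
  }, numeric(1))
}

#' Remove flagged feature types
#'
#' Drops genes flagged mitochondrial, ribosomal and/or non-protein-coding
#' from a dataset.
#'
#' @param ds A `pg_dataset` with `is_mito`/`is_ribo`/`is_coding` gene flags.
#' @param exclude Subset of `c("mito", "ribo", "noncoding")`.
#' @return The filtered `pg_dataset`.
#' @export
filter_features_by_type <- function(ds, exclude = character()) {
  .assert(inherits(ds, "pg_dataset"), "'ds' must be a pg_dataset")
  .assert(all(exclude %in% c("mito", "ribo", "noncoding")),
          "exclude must be a subset of {mito, ribo, noncoding}")
  drop <- rep(FALSE, nrow(ds$counts))
  if ("mito" %in% exclude) drop <- drop | ds$gene_meta$is_mito
  if ("ribo" %in% exclude) drop <- drop | ds$gene_meta$is_ribo
  if ("noncoding" %in% exclude) drop <- drop | !ds$gene_meta$is_coding
  .assert(!all(drop), "feature-type exclusion would empty the matrix")
  subset_dataset(ds, genes = !drop)
}

#' PCA embedding of a scaled matrix
#'
#' Truncated SVD of the gene-centered matrix. The weighted embedding (the
#' common default) scales cell scores by the singular values, so component
#' variances differ; the unweighted variant returns unit-normalized component
#' scores. The sign of each component is fixed so its largest-magnitude gene
#' loading is positive.
#'
#' @param X Scaled matrix, genes x cells.
#' @param n_components Number of components (`<= min(dim) - 1`).
#' @param weight_by_variance Weight cell scores by component standard
#'   deviations (`TRUE`, default) or return unit-variance scores.
#' @param center Center genes first (default `TRUE`).
#' @return A `pg_embedding`: `coords` (cells x components), `variance`
#'   (per-component, non-increasing), `weighted`.
#' @export
pca_embed <- function(X, n_components = 10, weight_by_variance = TRUE,
                      center = TRUE) {
  X <- as.matrix(X)
  .assert(n_components >= 1 &&
            n_components <= min(dim(X)) - 1L,
          "n_components must be <= min(genes, cells) - 1")
  if (center) X <- X - rowMeans(X)
  sv <- svd(X, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  # sign convention: largest-magnitude loading positive
  for (i in seq_len(n_components)) {
    j <- which.max(abs(sv$u[, i]))
    if (sv$u[j, i] < 0) { sv$u[, i] <- -sv$u[, i]; sv$v[, i] <- -sv$v[, i] }
  }
  n <- ncol(X)
  variance <- d^2 / (n - 1)
  coords <- if (weight_by_variance) sweep(sv$v, 2, d, "*") else sv$v
  rownames(coords) <- colnames(X)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  structure(list(coords = coords, variance = variance, loadings = sv$u,
                 weighted = isTRUE(weight_by_variance)),
            class = "pg_embedding")
}

#' @export
print.pg_embedding <- function(x, ...) {
  cat("A", if (x$weighted) "variance-weighted" else "unit-variance",
      "embedding:", nrow(x$coords), "cells x", ncol(x$coords), "components\n")
  invisible(x)
}
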