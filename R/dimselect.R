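# Dimensionality selection: elbow via farthest point from the scree chord,
# jackstraw-style permutation p-values, and molecular cross-validation on
# binomially split counts.

#' Farthest point from the scree chord
#'
#' Index of the curve point with the largest perpendicular distance to the
#' straight line from the first to the last point — an automatic reading of
#' the scree "elbow". Ties (e.g. an exactly linear curve) return the smallest
#' index. The result is invariant to jointly rescaling both axes.
#'
#' @param curve Numeric vector (ordered per-component values).
#' @return Integer index of the farthest point.
#' @export
farthest_point <- function(curve) {
  m <- length(curve)
  .assert(m >= 2 && all(is.finite(curve)), "need >= 2 finite values")
  if (m == 2L) {
    warning("curve of length 2: returning 1")
    return(1L)
  }
  x <- seq_len(m)
  dx <- m - 1; dy <- curve[m] - curve[1]
  # perpendicular distance of (x_i, y_i) to the chord
  d <- abs(dy * (x - 1) - dx * (curve - curve[1])) / sqrt(dx^2 + dy^2)
  which.max(d)   # first maximum = smallest index on ties
}

#' Elbow dimensionality of an embedding
#'
#' Applies [farthest_point()] to the per-component variance-explained curve,
#' using the first 50 components (or all, if fewer).
#'
#' @param embedding A `pg_embedding` (or a numeric variance vector).
#' @return Integer number of dimensions.
#' @export
elbow_dims <- function(embedding) {
  v <- if (inherits(embedding, "pg_embedding")) embedding$variance
       else as.numeric(embedding)
  .assert(length(v) >= 3, "need >= 3 components")
  farthest_point(v[seq_len(min(50L, length(v)))])
}

#' Jackstraw-style permutation p-values per component
#'
#' For each permutation round, a random fraction of genes is permuted across
#' cells and the PCA recomputed; the permuted genes' component-association
#' statistics (squared correlation between the permuted gene and each
#' component's scores) are pooled into a per-component null. Every observed
#' gene then gets an empirical p-value against that null, and each
#' component's p-value is a one-sided Kolmogorov-Smirnov test of those
#' per-gene p-values against the uniform distribution: components whose gene
#' associations are enriched beyond chance get small p-values even when only
#' a minority of genes carries the signal. [jackstraw_dims()] applies
#' [farthest_point()] to the log10 p-values, mirroring the practice of
#' looking for a drop in significance rather than thresholding.
#'
#' @param X Scaled matrix, genes x cells.
#' @param n_pcs Components to assess.
#' @param n_perm Number of permutations (>= 20).
#' @param perm_fraction Fraction of genes permuted per round.
#' @param seed RNG seed.
#' @return Numeric vector of per-component p-values.
#' @export
jackstraw_pvalues <- function(X, n_pcs = 10, n_perm = 100,
                              perm_fraction = 0.01, seed = 0L) {
  X <- as.matrix(X)
  .assert(n_perm >= 20, "n_perm must be >= 20")
  n_pcs <- min(n_pcs, min(dim(X)) - 1L)
  set.seed(as.integer(seed))
  obs <- pca_embed(X, n_components = n_pcs)
  S_obs <- suppressWarnings(cor(t(X), obs$coords))^2
  S_obs[!is.finite(S_obs)] <- 0
  n_genes <- nrow(X)
  n_sub <- max(1L, round(perm_fraction * n_genes))
  null_stats <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_genes, n_sub)
    Xp <- X
    for (g in idx) Xp[g, ] <- Xp[g, sample.int(ncol(X))]
    pe <- pca_embed(Xp, n_components = n_pcs)
    ns <- suppressWarnings(cor(t(Xp[idx, , drop = FALSE]), pe$coords))^2
    ns[!is.finite(ns)] <- 0
    null_stats[[b]] <- matrix(ns, nrow = n_sub)
  }
  null_mat <- do.call(rbind, null_stats)
  .assert(nrow(null_mat) >= 20, "degenerate null (too few permuted stats)")
  vapply(seq_len(n_pcs), function(j) {
    # per-gene empirical p-values, then one-sided KS against uniform
    pg <- (1 + colSums(outer(null_mat[, j], S_obs[, j], ">="))) /
      (1 + nrow(null_mat))
    pg <- sort(pg)
    n <- length(pg)
    dplus <- max(seq_len(n) / n - pg)
    min(1, exp(-2 * n * dplus^2))
  }, numeric(1))
}

#' @rdname jackstraw_pvalues
#' @export
jackstraw_dims <- function(X, n_pcs = 10, n_perm = 100, perm_fraction = 0.01,
                           seed = 0L) {
  p <- jackstraw_pvalues(X, n_pcs, n_perm, perm_fraction, seed)
  farthest_point(log10(pmax(p, 1e-300)))
}

#' Binomial 50-50 split of a count matrix
#'
#' Splits every count y into A ~ Binomial(y, p) and B = y - A, independently
#' per entry, so A + B reproduces the input exactly — the molecular
#' cross-validation construction. Non-integer counts are rounded up first.
#'
#' @param counts Gene-by-cell counts.
#' @param proportion Split probability (default 0.5).
#' @param seed RNG seed.
#' @return List of two matrices `A` and `B` of the input shape.
#' @export
mcv_split <- function(counts, proportion = 0.5, seed = 0L) {
  sparse <- is(counts, "Matrix")
  if (sparse)
    counts <- .as_dgc(counts)
  set.seed(as.integer(seed))
  if (sparse) {
    x <- counts@x
    if (any(x != round(x))) x <- ceiling(x)
    a <- rbinom(length(x), x, proportion)
    A <- counts; A@x <- as.numeric(a)
    B <- counts; B@x <- as.numeric(x - a)
    A <- Matrix::drop0(A); B <- Matrix::drop0(B)
  } else {
    counts <- as.matrix(counts)
    if (any(counts != round(counts))) counts <- ceiling(counts)
    a <- rbinom(length(counts), as.vector(counts), proportion)
    A <- matrix(a, nrow(counts), ncol(counts), dimnames = dimnames(counts))
    B <- counts - A
  }
  list(A = A, B = B)
}

#' Molecular cross-validation dimensionality
#'
#' Splits the counts 50-50 ([mcv_split()]), log-normalizes both halves
#' identically, fits a PCA basis on half A (genes centered on A's means) and,
#' for each candidate k, compares half A's rank-k reconstruction against half
#' B's normalized matrix; the selected dimensionality minimizes that mean
#' squared error. Since the two halves carry independent noise, components
#' fitted to A's noise worsen the agreement with B, giving the error curve a
#' minimum at the underlying dimensionality. `k = 0` (mean-only
#' reconstruction) is always included as a baseline. Because of the 50%
#' split, the dimensionality may be slightly underestimated.
#'
#' @param counts Gene-by-cell raw counts.
#' @param k_grid Candidate dimensionalities.
#' @param seed RNG seed.
#' @param scale_target Library-size target of the normalization.
#' @param n_splits Number of independent splits averaged (default 1).
#' @return List with `dims` (argmin k), `k` and `mse` (the curve, including
#'   k = 0).
#' @export
mcv_dims <- function(counts, k_grid = 1:20, seed = 0L, scale_target = 1e4,
                     n_splits = 1L) {
  k_grid <- sort(unique(as.integer(k_grid)))
  .assert(all(k_grid >= 1), "k_grid must be positive")
  mse_acc <- NULL
  for (r in seq_len(n_splits)) {
    halves <- mcv_split(counts, 0.5, seed = .mix_seed(seed, paste0("split", r)))
    totA <- Matrix::colSums(halves$A); totB <- Matrix::colSums(halves$B)
    totA[totA == 0] <- 1; totB[totB == 0] <- 1
    An <- as.matrix(lognormalize(halves$A, size_factors = totA / scale_target)$mat)
    Bn <- as.matrix(lognormalize(halves$B, size_factors = totB / scale_target)$mat)
    kmax <- min(max(k_grid), min(dim(An)) - 1L)
    ks <- k_grid[k_grid <= kmax]
    .assert(length(ks) >= 1, "k_grid exceeds the rank of half A")
    mA <- rowMeans(An)
    Ac <- An - mA
    sv <- svd(Ac, nu = kmax, nv = kmax)
    Bc <- Bn - mA                       # centered on A's means (prediction)
    mse <- numeric(length(ks) + 1L)
    mse[1] <- mean(Bc^2)                # k = 0: mean-only reconstruction
    acc <- matrix(0, nrow(Bn), ncol(Bn))
    ki <- 1L
    for (k in seq_len(kmax)) {
      # rank-k reconstruction of half A, scored against half B
      acc <- acc + sv$d[k] * sv$u[, k, drop = FALSE] %*% t(sv$v[, k, drop = FALSE])
      if (k == ks[ki]) {
        mse[ki + 1L] <- mean((Bc - acc)^2)
        ki <- ki + 1L
        if (ki > length(ks)) break
      }
    }
    mse_acc <- if (is.null(mse_acc)) mse else mse_acc + mse
  }
  mse <- mse_acc / n_splits
  kk <- c(0L, ks)
  list(dims = kk[which.min(mse)], k = kk, mse = mse)
}
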