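# Ground-truth-based intermediate metrics: variance and deviance explained by
# the known subpopulations, covariate-association diagnostics, and the
# truth-based dimensionality of an embedding.

#' Variance explained by subpopulations
#'
#' Per row of a matrix (genes, or transposed principal components), the
#' R-squared of a one-way fit on the subpopulation labels: between-group sum
#' of squares over total sum of squares. Zero-variance rows get 0.
#'
#' @param X Numeric matrix, variables x cells (pass `t(embedding$coords)` for
#'   components).
#' @param truth Subpopulation labels (>= 2 classes, each non-empty).
#' @return Numeric vector of R-squared values in [0, 1], one per row.
#' @export
variance_explained <- function(X, truth) {
  X <- as.matrix(X)
  truth <- as.character(truth)
  .assert(ncol(X) == length(truth), "labels must match columns")
  .assert(length(unique(truth)) >= 2, "need >= 2 classes")
  f <- factor(truth)
  n_k <- as.numeric(table(f))
  mu <- rowMeans(X)
  # per-class row means
  M <- vapply(levels(f), function(l) rowMeans(X[, f == l, drop = FALSE]),
              numeric(nrow(X)))
  if (nrow(X) == 1L) M <- matrix(M, nrow = 1L)
  ss_between <- as.numeric((M - mu)^2 %*% n_k)
  ss_total <- rowSums((X - mu)^2)
  r2 <- ifelse(ss_total > 0, ss_between / ss_total, 0)
  pmin(pmax(r2, 0), 1)
}

# negative-binomial deviance of counts y with fitted means mu and size theta
.nb_deviance <- function(y, mu, theta) {
  term1 <- ifelse(y > 0, y * log(y / mu), 0)
  term2 <- (y + theta) * log((y + theta) / (mu + theta))
  2 * sum(term1 - term2)
}

#' Deviance explained by subpopulations
#'
#' Per gene, two negative binomial log-link models are fitted: a full model
#' (intercept + log-library-size offset + subpopulation factor) and a reduced
#' one (intercept + offset only). The NB dispersion is estimated once, by
#' maximum likelihood under the full design (the usual GLM convention for the
#' error model), and held fixed for both fits so the models are strictly
#' nested. The deviance explained is
#' `(dev_reduced - dev_full) / dev_reduced`, clipped at 0. Genes whose NB fit
#' fails fall back to Poisson (with a message in `attr(, "fallback")`).
#' Setting `library_size = "covariate"` instead estimates a free coefficient
#' for log library size.
#'
#' @param counts Gene-by-cell raw counts.
#' @param truth Subpopulation labels (>= 2 classes).
#' @param library_size `"offset"` (default) or `"covariate"`.
#' @return Numeric vector of deviance-explained fractions in [0, 1].
#' @export
deviance_explained <- function(counts, truth,
                               library_size = c("offset", "covariate")) {
  library_size <- match.arg(library_size)
  counts <- as.matrix(counts)
  truth <- factor(as.character(truth))
  .assert(ncol(counts) == length(truth), "labels must match cells")
  .assert(nlevels(truth) >= 2, "need >= 2 classes")
  ls <- colSums(counts)
  .assert(all(ls > 0), "library sizes must be positive")
  o <- log(ls)
  out <- numeric(nrow(counts))
  fallback <- character(0)
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    de <- tryCatch({
      if (library_size == "offset") {
        full0 <- glm(y ~ truth + offset(o), family = poisson())
        theta <- suppressWarnings(MASS::theta.ml(y, fitted(full0), limit = 50))
        fam <- MASS::negative.binomial(theta)
        red <- glm(y ~ 1 + offset(o), family = fam)
        full <- glm(y ~ truth + offset(o), family = fam)
      } else {
        full0 <- glm(y ~ o + truth, family = poisson())
        theta <- suppressWarnings(MASS::theta.ml(y, fitted(full0), limit = 50))
        fam <- MASS::negative.binomial(theta)
        red <- glm(y ~ o, family = fam)
        full <- glm(y ~ o + truth, family = fam)
      }
      dr <- .nb_deviance(y, fitted(red), theta)
      df <- .nb_deviance(y, fitted(full), theta)
      if (dr <= 0) 0 else (dr - df) / dr
    }, error = function(e) e)
    if (inherits(de, "error")) {
      fallback <- c(fallback, rownames(counts)[g] %||% as.character(g))
      de <- tryCatch({
        if (library_size == "offset") {
          red <- glm(y ~ 1 + offset(o), family = poisson())
          full <- glm(y ~ truth + offset(o), family = poisson())
        } else {
          red <- glm(y ~ o, family = poisson())
          full <- glm(y ~ o + truth, family = poisson())
        }
        if (red$deviance <= 0) 0
        else (red$deviance - full$deviance) / red$deviance
      }, error = function(e) 0)
    }
    out[g] <- de
  }
  out <- pmin(pmax(out, 0), 1)
  if (length(fallback)) attr(out, "fallback") <- fallback
  out
}

#' Subpopulation-adjusted covariate correlation
#'
#' Fits the component on the subpopulation labels, then Pearson-correlates
#' the residuals with the covariate of interest, quantifying how much of a
#' component's variation is attributable to a technical covariate after the
#' biological structure is accounted for. The squared value is the
#' "variance explained" reading. Constant residuals give 0.
#'
#' @param component Numeric vector (e.g. one principal component).
#' @param covariate Numeric covariate (e.g. library size, detection rate).
#' @param truth Subpopulation labels.
#' @return The residual correlation, with the squared value in
#'   `attr(, "r_squared")`.
#' @export
covariate_correlation_adjusted <- function(component, covariate, truth) {
  truth <- factor(as.character(truth))
  .assert(length(component) == length(covariate) &&
            length(component) == length(truth), "length mismatch")
  res <- resid(lm(component ~ truth))
  # numerically constant residuals (component fully determined by the
  # subpopulations) are treated as zero association
  r <- if (sd(res) <= 1e-10 * (sd(component) + 1) || sd(covariate) == 0) 0
       else cor(res, covariate)
  structure(r, r_squared = r^2)
}

#' Cumulative explained signal captured by top-k features
#'
#' For each k, the sum of the explained metric over the ranking's top-k genes
#' divided by the sum over the best possible top-k (the oracle ranking by the
#' metric itself); the curve lies in [0, 1] and equals 1 for the oracle
#' ranking.
#'
#' @param ranking A `pg_ranking` (or a character vector of gene names in
#'   ranked order).
#' @param explained Named numeric vector of the explained metric per gene
#'   (e.g. [variance_explained()] or [deviance_explained()] output).
#' @param k_grid Integer vector of k values (clipped to the gene count).
#' @return Data frame with `k` and `fraction`.
#' @export
cumulative_explained_topk <- function(ranking, explained,
                                      k_grid = c(100, 200, 500, 1000, 2000)) {
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  .assert(!is.null(names(explained)), "'explained' must be named by gene")
  .assert(all(genes %in% names(explained)),
          "ranking and explained cover different genes")
  explained <- explained[!is.na(explained)]
  genes <- genes[genes %in% names(explained)]
  oracle <- sort(explained, decreasing = TRUE)
  k_grid <- pmin(as.integer(k_grid), length(genes))
  frac <- vapply(k_grid, function(k) {
    best <- sum(oracle[seq_len(k)])
    if (best <= 0) return(1)
    sum(explained[genes[seq_len(k)]]) / best
  }, numeric(1))
  data.frame(k = k_grid, fraction = frac)
}

#' Truth-based dimensionality of an embedding
#'
#' Number of leading components whose variance explained by the true
#' subpopulations (one-way R-squared) is at least `threshold`; counting stops
#' at the first component below the threshold, reflecting the sharp drop of
#' subpopulation signal after the informative components.
#'
#' @param embedding A `pg_embedding` (or cells x components matrix).
#' @param truth Subpopulation labels.
#' @param threshold Minimum per-component R-squared (default 0.05).
#' @return Integer count (possibly 0).
#' @export
true_dimensionality <- function(embedding, truth, threshold = 0.05) {
  X <- if (inherits(embedding, "pg_embedding")) embedding$coords
       else as.matrix(embedding)
  r2 <- variance_explained(t(X), truth)
  below <- which(r2 < threshold)
  if (!length(below)) length(r2) else below[1] - 1L
}
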