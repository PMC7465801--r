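# helper: wrap a plain QC data.frame so apply_filter_set accepts it
as_qc <- function(df, has_mito = TRUE) {
  structure(df, class = c("pg_qc", "data.frame"), has_mito = has_mito)
}

# a QC table with controlled outliers: 200 cells from tight distributions,
# with chosen cells displaced by a given number of (sample) MADs
make_qc_table <- function(seed = 1, n = 200) {
  set.seed(seed)
  data.frame(
    log10_total_counts = rnorm(n, 3.5, 0.1),
    log10_total_features = rnorm(n, 3.0, 0.08),
    pct_counts_in_top_20_features = runif(n, 0.2, 0.4),
    featcount_dist = rnorm(n, 0, 0.02),
    pct_counts_Mt = runif(n, 0.02, 0.04))
}

displace <- function(x, i, nmads) {
  x[i] <- median(x) + nmads * mad(x)
  x
}

test_that("QC metrics match direct arithmetic on toy cells", {
  m <- matrix(c(9, 1,
                5, 5), nrow = 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  qc <- compute_cell_qc(m, is_mito = c(FALSE, FALSE))
  expect_equal(qc$log10_total_counts[1], 1)
  expect_equal(qc$log10_total_features[1], log10(2), tolerance = 1e-12)
  expect_equal(qc$pct_counts_in_top_20_features[1], 1)
  expect_equal(qc$pct_counts_Mt, c(0, 0))
  # all counts in mito genes
  qc_mt <- compute_cell_qc(m, is_mito = c(TRUE, TRUE))
  expect_equal(qc_mt$pct_counts_Mt, c(1, 1))
  # zero-total cell: -Inf log metrics, flagged
  z <- cbind(m, c0 = c(0, 0))
  qz <- compute_cell_qc(z, is_mito = c(FALSE, FALSE))
  expect_equal(qz$log10_total_counts[3], -Inf)
  expect_true(qz$zero_total[3])
  expect_false(apply_filter_set(qz, "default")[3])
})

test_that("featcount_dist is the OLS residual of the counts/features trend", {
  # cells that are scalar multiples of one profile lie on the trend exactly
  base <- c(50, 30, 10, 5, 2, 1, 1, 0, 0, 0)
  m <- sapply(c(1, 2, 4, 8, 16), function(k) k * base)
  qc <- compute_cell_qc(m)
  expect_equal(qc$featcount_dist, rep(0, 5), tolerance = 1e-8)
  # hand-computed residuals on 5 cells
  set.seed(2)
  m2 <- matrix(rpois(5 * 40, 5), 40, 5) + 1
  qc2 <- compute_cell_qc(m2)
  lc <- log10(colSums(m2)); lf <- log10(colSums(m2 > 0))
  fit <- lm(lf ~ lc)
  expect_equal(qc2$featcount_dist, unname(resid(fit)), tolerance = 1e-10)
})

test_that("mad_outlier matches direct median/MAD computation", {
  v <- c(1:10, 100)
  # median 6, MAD = 3 * 1.4826; upper bound 6 + 2.5 * 4.4478 = 17.1
  expect_equal(which(mad_outlier(v, 2.5, 2.5)), 11L)
  expect_equal(sum(mad_outlier(rep(3, 10), 2, 2)), 0L)
  # affine invariance for a > 0
  set.seed(4)
  x <- rnorm(50)
  expect_equal(mad_outlier(x, 2, 3), mad_outlier(7 * x - 2, 2, 3))
  # one-sided disabling
  expect_equal(which(mad_outlier(v, Inf, 2.5)), 11L)
  expect_equal(sum(mad_outlier(v, 2.5, Inf)), 0L)
  expect_error(mad_outlier(c(1, Inf)), "finite")
})

test_that("filter sets implement their rules exactly", {
  df <- make_qc_table()
  # cell 1: 3 MADs high on log10_total_counts only
  df$log10_total_counts <- displace(df$log10_total_counts, 1, 3)
  # cell 2: high on both counts and features (two criteria)
  df$log10_total_counts <- displace(df$log10_total_counts, 2, 3)
  df$log10_total_features <- displace(df$log10_total_features, 2, 3)
  # cell 3: Mt at 5 MADs high but absolute value below the 0.08 floor
  df$pct_counts_Mt[3] <- median(df$pct_counts_Mt) + 5 * mad(df$pct_counts_Mt)
  stopifnot(df$pct_counts_Mt[3] < 0.08)
  qc <- as_qc(df)
  keep_def <- apply_filter_set(qc, "default")
  keep_str <- apply_filter_set(qc, "stringent")
  expect_true(keep_def[1])       # one criterion: kept by default
  expect_false(keep_str[1])      # removed by stringent
  expect_false(keep_def[2])      # two criteria: removed by default
  expect_true(keep_def[3] && keep_str[3])  # Mt floor not met
  # no outliers anywhere (bounded uniform metrics): all kept by every set
  set.seed(99)
  calm <- as_qc(data.frame(
    log10_total_counts = runif(100, 3, 4),
    log10_total_features = runif(100, 2.5, 3),
    pct_counts_in_top_20_features = runif(100, 0.2, 0.4),
    featcount_dist = runif(100, -0.05, 0.05),
    pct_counts_Mt = runif(100, 0.02, 0.06)))
  for (s in c("default", "lenient", "stringent", "veryStringent"))
    expect_true(all(apply_filter_set(calm, s)))
})

test_that("filter masks equal direct rule-by-rule evaluation", {
  df <- make_qc_table(seed = 10)
  for (i in 1:8) df[[sample(names(df), 1)]][i] <-
    displace(df[[sample(names(df), 1)]], i, sample(c(-6, -3, 3, 6), 1))[i]
  qc <- as_qc(df)
  out2 <- function(x, lo, hi) {
    med <- median(x); s <- mad(x)
    x < med - lo * s | x > med + hi * s
  }
  crit <- cbind(out2(df$log10_total_counts, 5, 2.5),
                out2(df$log10_total_features, 5, 2.5),
                out2(df$pct_counts_in_top_20_features, 5, 5),
                out2(df$featcount_dist, 5, 5),
                out2(df$pct_counts_Mt, Inf, 2.5) & df$pct_counts_Mt > 0.08)
  expect_equal(apply_filter_set(qc, "default"), rowSums(crit) < 2)
  expect_equal(apply_filter_set(qc, "stringent"), rowSums(crit) == 0)
  crit_len <- cbind(out2(df$log10_total_counts, 5, 5),
                    out2(df$log10_total_features, 5, 5),
                    out2(df$pct_counts_in_top_20_features, 5, 5),
                    out2(df$featcount_dist, 5, 5),
                    out2(df$pct_counts_Mt, Inf, 3) & df$pct_counts_Mt > 0.08)
  expect_equal(apply_filter_set(qc, "lenient"), rowSums(crit_len) < 2)
  crit_vs <- cbind(out2(df$log10_total_counts, 2, 2),
                   out2(df$log10_total_features, 2, 2),
                   out2(df$pct_counts_Mt, 2, 2),
                   out2(df$pct_counts_in_top_20_features, 2, 2))
  expect_equal(apply_filter_set(qc, "veryStringent"), rowSums(crit_vs) == 0)
})

test_that("default-excluded cells are a subset of stringent-excluded cells", {
  for (seed in 1:100) {
    df <- make_qc_table(seed = seed, n = 60)
    i <- sample(60, 5)
    for (j in i) df[[sample(names(df), 1)]][j] <- df[[sample(names(df), 1)]][j] +
      sample(c(-1, 1), 1) * runif(1, 0, 1)
    qc <- as_qc(df)
    excl_def <- !apply_filter_set(qc, "default")
    excl_str <- !apply_filter_set(qc, "stringent")
    expect_true(all(!excl_def | excl_str))
  }
})

test_that("cluster-wise filtering spares subpopulations with distinct libraries", {
  # two subpopulations with very different library sizes
  set.seed(21)
  big <- simulate_dataset(sim_params(n_genes = 300, n_cells = 300,
                                     n_subpops = 1, doublet_rate = 0,
                                     lowq_rate = 0, seed = 1))
  small <- simulate_dataset(sim_params(n_genes = 300, n_cells = 150,
                                       n_subpops = 1, frac_de_genes = 0,
                                       baseline_logmean_range = c(-4, 0),
                                       doublet_rate = 0, lowq_rate = 0,
                                       seed = 2))
  counts <- cbind(big$counts, small$counts)
  colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  ds <- pg_dataset(counts,
                   data.frame(phenoid = rep(c("big", "small"), c(300, 150))),
                   data.frame(gene = rownames(big$counts),
                              is_mito = big$gene_meta$is_mito))
  qc <- compute_cell_qc(ds)
  global_excl <- !apply_filter_set(qc, "default")
  cw_excl <- !clusterwise_filter(ds, "default",
                                 clusters = as.integer(factor(ds$cell_meta$phenoid)))
  # the global filter hits the small-library subpopulation; cluster-wise
  # removes (near) none of it
  expect_gt(sum(global_excl[301:450]), sum(cw_excl[301:450]))
  expect_lt(mean(cw_excl[301:450]), 0.05)
  # single-cluster reduction: identical to the plain filter set
  one <- clusterwise_filter(ds, "default", clusters = rep(1L, 450))
  expect_equal(one, apply_filter_set(qc, "default"))
})

test_that("multivariate PCA outlier filter flags planted outliers", {
  set.seed(31)
  n <- 500
  df <- data.frame(log10_total_counts = rnorm(n),
                   log10_total_features = rnorm(n),
                   pct_counts_in_top_20_features = rnorm(n),
                   featcount_dist = rnorm(n),
                   pct_counts_Mt = rnorm(n))
  # one extreme multivariate outlier
  df[1, ] <- c(6, -6, 6, -6, 6)
  keep <- pca_outlier_filter(as_qc(df), "all")
  expect_false(keep[1])
  # distance oracle: classical Mahalanobis on the clean cloud flags the same cell
  d2 <- mahalanobis(scale(df), colMeans(scale(df)), cov(scale(df)))
  expect_equal(which.max(d2), 1L)
  # spherical Gaussian: at most ~0.5% flagged at the 0.999 quantile
  clean <- df[-1, ]
  expect_lt(mean(!pca_outlier_filter(as_qc(clean), "selected")), 0.005 * 4)
  # duplicate covariates: the run continues (fallback path if singular)
  dup <- df; dup$log10_total_features <- dup$log10_total_counts
  expect_length(suppressWarnings(pca_outlier_filter(as_qc(dup), "all")), n)
})
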