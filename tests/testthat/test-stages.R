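test_that("log-normalization matches its arithmetic definition", {
  m <- matrix(c(10, 0,
                5, 5), 2, 2, byrow = FALSE)
  nm <- lognormalize(m, scale_target = 10)
  # cell [10, 0] at scale 10 -> [log1p(10), 0]
  expect_equal(as.matrix(nm$mat)[, 1], c(log1p(10), 0), ignore_attr = TRUE)
  expect_equal(as.matrix(nm$mat)[, 2], log1p(c(5, 5) / 10 * 10),
               ignore_attr = TRUE)
  # size-factor invariance: doubling a cell's counts leaves it unchanged
  m2 <- m; m2[, 1] <- 2 * m[, 1]
  expect_equal(as.matrix(lognormalize(m2, 10)$mat)[, 1],
               as.matrix(nm$mat)[, 1])
  # zero rows stay zero
  m3 <- rbind(m, 0)
  expect_equal(as.matrix(lognormalize(m3, 10)$mat)[3, ], c(0, 0))
  expect_error(lognormalize(cbind(m, 0)), "zero total")
})

test_that("feature scaling centers, standardizes and regresses out covariates", {
  set.seed(3)
  X <- matrix(rnorm(40 * 30, sd = 2), 40, 30)
  S <- scale_features(X)
  expect_equal(rowMeans(S), rep(0, 40), tolerance = 1e-10)
  expect_equal(apply(S, 1, var), rep(1, 40), tolerance = 1e-10)
  # zero-variance genes become 0
  Xc <- rbind(X, 5)
  expect_equal(scale_features(Xc)[41, ], rep(0, 30))
  # a gene exactly linear in a covariate is annihilated
  cov <- data.frame(v = rnorm(30))
  Xl <- rbind(X, 2 * cov$v + 1)
  expect_equal(scale_features(Xl, covariates = cov)[41, ], rep(0, 30),
               tolerance = 1e-8)
  # residuals match the normal-equations oracle on a 5-gene toy
  Y <- matrix(rnorm(5 * 30), 5, 30)
  mm <- cbind(1, cov$v)
  beta <- solve(t(mm) %*% mm, t(mm) %*% t(Y))
  res_oracle <- t(Y) - mm %*% beta
  S2 <- scale_features(Y, covariates = cov)
  ref <- t(scale(res_oracle))
  expect_equal(S2, ref, ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(scale_features(Y, covariates = data.frame(v = rnorm(10))),
               "covariate rows")
})

test_that("binomial deviance matches termwise hand computation", {
  counts <- matrix(c(1, 2, 3, 4,
                     10, 20, 30, 40,
                     5, 0, 0, 5), 3, 4, byrow = TRUE)
  n <- colSums(counts)
  dev_hand <- sapply(1:3, function(g) {
    y <- counts[g, ]; pi <- sum(y) / sum(n)
    t1 <- ifelse(y > 0, y * log(y / (n * pi)), 0)
    t2 <- ifelse(n - y > 0, (n - y) * log((n - y) / (n * (1 - pi))), 0)
    2 * sum(t1 + t2)
  })
  expect_equal(binomial_deviance(counts), dev_hand, tolerance = 1e-10)
  # constant-proportion gene has ~0 deviance
  m <- rbind(c(10, 20, 40), c(1, 2, 4), c(9, 18, 36))
  expect_lt(max(binomial_deviance(m)), 1e-10)
})

test_that("feature rankings order genes by their criterion", {
  set.seed(5)
  X <- matrix(rpois(50 * 30, 5), 50, 30)
  rownames(X) <- paste0("g", 1:50)
  nm <- lognormalize(X)
  for (meth in c("variance", "mean_expression", "standardized_variance")) {
    rk <- rank_features(nm, meth)
    expect_equal(nrow(rk), 50L)
    expect_true(all(diff(rk$value) <= 1e-12))
  }
  # a constant normalized gene has variance 0 and is ranked last
  Z <- matrix(rnorm(49 * 30), 49, 30, dimnames = list(paste0("g", 2:50), NULL))
  Z <- rbind(g1 = rep(3, 30), Z)
  rk_var <- rank_features(Z, "variance")
  expect_equal(rk_var$gene[50], "g1")
  expect_equal(rk_var$value[50], 0)
  # mean_expression ordering is invariant to cell permutation
  set.seed(6)
  perm <- sample(30)
  nm_p <- lognormalize(X[, perm])
  expect_equal(rank_features(nm, "mean_expression")$gene,
               rank_features(nm_p, "mean_expression")$gene)
  # deviance requires counts; a constant-proportion gene is ranked last
  expect_error(rank_features(nm, "deviance"), "raw counts")
  Xd <- X
  Xd[1, ] <- colSums(X[-1, ])       # y/n = 1/2 in every cell
  rk_dev <- rank_features(Xd, "deviance")
  expect_equal(rk_dev$gene[50], "g1")
  expect_lt(rk_dev$value[50], 1e-8)
})

test_that("feature-type exclusion equals set arithmetic", {
  ds <- small_dataset(seed = 9, n_genes = 120, n_cells = 80)
  expect_equal(dim(filter_features_by_type(ds)$counts), dim(ds$counts))
  n_mito <- sum(ds$gene_meta$is_mito)
  expect_gt(n_mito, 0)
  ds_m <- filter_features_by_type(ds, "mito")
  expect_equal(nrow(ds_m$counts), nrow(ds$counts) - n_mito)
  ds_all <- filter_features_by_type(ds, c("mito", "ribo", "noncoding"))
  keep_oracle <- with(ds$gene_meta, !is_mito & !is_ribo & is_coding)
  expect_equal(ds_all$gene_meta$gene, ds$gene_meta$gene[keep_oracle])
  expect_error(filter_features_by_type(ds, "mystery"), "subset")
})

test_that("PCA embedding satisfies the SVD identities", {
  set.seed(8)
  # planted rank-10 matrix: 19 components capture it exactly
  X <- matrix(rnorm(20 * 10), 20, 10) %*% matrix(rnorm(10 * 30), 10, 30)
  emb <- pca_embed(X, n_components = 19, weight_by_variance = TRUE)
  expect_true(all(diff(emb$variance) <= 1e-10))
  # weighted column norms proportional to singular values
  d <- sqrt(emb$variance * (30 - 1))
  expect_equal(apply(emb$coords, 2, function(v) sqrt(sum(v^2))), d,
               ignore_attr = TRUE, tolerance = 1e-8)
  # unweighted columns are unit-normalized
  embu <- pca_embed(X, 5, weight_by_variance = FALSE)
  expect_equal(apply(embu$coords, 2, function(v) sqrt(sum(v^2))), rep(1, 5),
               ignore_attr = TRUE, tolerance = 1e-10)
  # reconstruction with all (rank-covering) components reproduces the matrix
  Xc <- X - rowMeans(X)
  rec <- emb$loadings %*% t(emb$coords)
  expect_equal(rec, Xc, tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:5) expect_gt(emb$loadings[which.max(abs(emb$loadings[, j])), j], 0)
  expect_error(pca_embed(X, 25), "n_components")
})

test_that("neighbor graphs match geometric expectations and a brute-force oracle", {
  set.seed(10)
  blob1 <- matrix(rnorm(30, 0, 0.1), 15, 2)
  blob2 <- matrix(rnorm(30, 5, 0.1), 15, 2)
  X <- rbind(blob1, blob2)
  for (gt in c("knn", "snn_jaccard", "snn_rank")) {
    g <- build_neighbor_graph(X, k = 4, graph_type = gt)
    comp <- igraph::components(g)
    expect_equal(comp$no, 2L)
    expect_equal(as.integer(table(comp$membership)), c(15L, 15L))
  }
  # knn edge set equals a brute-force all-pairs oracle on 30 points
  g <- build_neighbor_graph(X, k = 4, graph_type = "knn")
  D <- as.matrix(dist(X))
  edges_oracle <- unique(t(apply(do.call(rbind, lapply(1:30, function(i) {
    nb <- order(D[i, -i])[1:4]
    cbind(i, (1:30)[-i][nb])
  })), 1, sort)))
  got <- igraph::as_edgelist(g)
  got <- got[order(got[, 1], got[, 2]), ]
  eo <- edges_oracle[order(edges_oracle[, 1], edges_oracle[, 2]), ]
  expect_equal(unname(got), unname(eo))
  # two cells with identical neighbor sets have Jaccard weight 1
  Y <- rbind(c(0, 0), c(0, 0), matrix(rnorm(20, 3, 0.2), 10, 2))
  gj <- build_neighbor_graph(Y, k = 3, graph_type = "snn_jaccard")
  w12 <- igraph::E(gj)$weight[igraph::get_edge_ids(gj, c(1, 2))]
  expect_equal(w12, 1)
})

test_that("graph clustering honors structure, method and resolution", {
  # two disconnected cliques -> 2 clusters for every method
  g <- igraph::disjoint_union(igraph::make_full_graph(8),
                              igraph::make_full_graph(8))
  igraph::E(g)$weight <- 1
  for (m in c("modularity_resolution", "walk_based", "greedy_modularity")) {
    cl <- cluster_graph(g, method = m, seed = 1)
    expect_equal(length(unique(cl)), 2L)
    expect_equal(length(unique(cl[1:8])), 1L)
  }
  # singleton graph
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  expect_equal(cluster_graph(g1, "modularity_resolution"), 1L)
  # number of clusters non-decreasing in resolution (approximate monotonicity
  # on a seeded toy graph)
  set.seed(2)
  pts <- rbind(matrix(rnorm(60, 0, 0.4), 30, 2),
               matrix(rnorm(60, 3, 0.4), 30, 2),
               matrix(rnorm(60, c(0, 6), 0.4), 30, 2))
  gg <- build_neighbor_graph(pts, k = 8, graph_type = "snn_jaccard")
  ks <- vapply(c(0.05, 0.5, 2, 8),
               function(r) length(unique(cluster_graph(gg, resolution = r,
                                                       seed = 3))), numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_gt(ks[4], ks[1])
})
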