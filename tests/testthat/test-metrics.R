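test_that("contingency tables cross-tabulate correctly", {
  tr <- c("a", "a", "b", "b", "c", "c")
  pr <- c(1, 1, 2, 2, 3, 2)
  tab <- contingency(tr, pr)
  expect_equal(dim(tab), c(3L, 3L))
  expect_equal(sum(tab), 6)
  expect_equal(tab["c", "2"], 1L, ignore_attr = TRUE)
  expect_equal(tab["c", "3"], 1L, ignore_attr = TRUE)
  # identical labels give a diagonal table
  expect_equal(as.numeric(diag(contingency(tr, tr))), c(2, 2, 2))
  # one predicted cluster: one column
  expect_equal(ncol(contingency(tr, rep(1, 6))), 1L)
  expect_error(contingency(tr, pr[-1]), "length")
})

test_that("ARI matches a brute-force pair-counting oracle", {
  ari_pairs <- function(a, b) {
    n <- length(a)
    s11 <- s00 <- s10 <- s01 <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1 else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1 else s01 <- s01 + 1
    }
    tot <- choose(n, 2)
    exp_idx <- (s11 + s10) * (s11 + s01) / tot
    max_idx <- ((s11 + s10) + (s11 + s01)) / 2
    if (max_idx == exp_idx) return(ifelse(s11 == max_idx, 1, 0))
    (s11 - exp_idx) / (max_idx - exp_idx)
  }
  set.seed(20)
  for (r in 1:30) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(ari(a, b), ari_pairs(a, b), tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
  }
  expect_equal(ari(1:5, 1:5), 1)
  # all singletons vs one cluster: boundary handled (<= 0)
  expect_lte(ari(1:6, rep(1, 6)), 0)
})

test_that("ARI of random partitions is centered at zero", {
  set.seed(21)
  vals <- replicate(200, ari(sample(1:4, 200, replace = TRUE),
                             sample(1:5, 200, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("mutual information matches direct summation", {
  # independent margins: MI = 0
  tab <- outer(c(10, 20), c(5, 15, 30)) / 10
  expect_equal(mutual_information(round(tab)), 0, tolerance = 1e-10)
  # identical partitions: MI equals the truth entropy
  tr <- rep(c("a", "b", "c"), c(10, 20, 30))
  p <- c(10, 20, 30) / 60
  expect_equal(mutual_information(tr, tr), -sum(p * log(p)), tolerance = 1e-12)
  # termwise oracle on random 3x3 tables
  set.seed(22)
  for (r in 1:20) {
    tt <- matrix(rpois(9, 8) + 1, 3, 3)
    n <- sum(tt); pp <- tt / n
    mi_oracle <- sum(pp * log(pp / outer(rowSums(pp), colSums(pp))))
    expect_equal(mutual_information(tt), mi_oracle, tolerance = 1e-12)
  }
  # label-permutation invariance of ARI and MI
  set.seed(23)
  a <- sample(1:3, 40, replace = TRUE); b <- sample(1:4, 40, replace = TRUE)
  pa <- c(3, 1, 2)[a]; pb <- c(2, 4, 1, 3)[b]
  expect_equal(ari(a, b), ari(pa, pb), tolerance = 1e-12)
  expect_equal(mutual_information(a, b), mutual_information(pa, pb),
               tolerance = 1e-12)
})

test_that("Hungarian matching equals exhaustive permutation search", {
  set.seed(24)
  for (r in 1:60) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    tab <- matrix(rpois(nr * nc, 6), nr, nc)
    ms <- match_and_score(tab)
    m <- max(nr, nc)
    full <- matrix(0, m, m); full[1:nr, 1:nc] <- tab
    best <- max(vapply(perms_of(m), function(p)
      sum(full[cbind(1:m, p)]), numeric(1)))
    got <- sum(vapply(1:nr, function(i)
      if (is.na(ms$matching[i])) 0 else tab[i, ms$matching[i]], numeric(1)))
    expect_equal(got, best)
  }
})

test_that("matched precision/recall/F1 follow the padding rules", {
  d <- diag(c(5, 7, 9))
  ms <- match_and_score(d)
  expect_equal(unname(ms$F1), c(1, 1, 1))
  expect_equal(ms$mean_F1, 1)
  # fewer clusters than classes: the unmatched class gets F1 = 0
  tab <- matrix(c(10, 0,
                  0, 10,
                  5, 5), 3, 2, byrow = TRUE)
  ms2 <- match_and_score(tab)
  expect_equal(sum(ms2$F1 == 0), 1L)
  expect_true(is.na(ms2$matching[which(ms2$F1 == 0)]))
  # mean_F1 = 1 iff the partitions are identical up to relabeling
  set.seed(25)
  a <- sample(1:3, 30, replace = TRUE)
  relab <- c(2, 3, 1)[a]
  expect_equal(match_and_score(contingency(a, relab))$mean_F1, 1)
  noisy <- relab; noisy[1] <- setdiff(1:3, relab[1])[1]
  expect_lt(match_and_score(contingency(a, noisy))$mean_F1, 1)
})

test_that("ARI at the true k scans the resolution sweep", {
  evals <- data.frame(n_clusters = c(2, 3, 3, 5), ari = c(0.2, 0.6, 0.8, 0.9))
  expect_equal(ari_at_true_k(evals, 3), 0.8)
  expect_equal(ari_at_true_k(evals, 5), 0.9)
  expect_true(is.na(ari_at_true_k(evals, 4)))
  expect_equal(ari_at_true_k(evals[2, , drop = FALSE], 3), 0.6)
})

test_that("silhouette per subpopulation matches an all-pairs oracle", {
  set.seed(26)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
             matrix(rnorm(30, 10, 0.2), 15, 2))
  lab <- rep(c("a", "b"), each = 15)
  s <- silhouette_per_subpop(X, lab)
  expect_gt(min(s), 0.9)
  # one blob split into two labels: negative-to-zero means
  blob <- matrix(rnorm(120, 0, 0.2), 60, 2)
  s2 <- silhouette_per_subpop(blob, rep(c("a", "b"), length.out = 60))
  expect_lt(max(s2), 0.15)
  expect_lt(mean(s2), 0.05)
  # 30-point cross-check against the reference implementation
  Y <- matrix(rnorm(60), 30, 2)
  laby <- sample(c("u", "v", "w"), 30, replace = TRUE)
  sy <- silhouette_per_subpop(Y, laby)
  if (requireNamespace("cluster", quietly = TRUE)) {
    ref <- cluster::silhouette(as.integer(factor(laby)), dist(Y))
    ref_means <- tapply(ref[, "sil_width"], laby, mean)
    expect_equal(sy, ref_means[names(sy)], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("misclassification rates compare clusterings via matched classes", {
  tr <- rep(c("a", "b"), each = 5)
  perfect <- rep(1:2, each = 5)
  mr <- misclassification_rates(list(perfect, perfect, perfect), tr)
  expect_equal(mr$rate, rep(0, 10))
  expect_equal(mr$adjusted_rate, rep(0, 10))
  # one always-misassigned cell in an otherwise perfect subpopulation
  bad <- perfect; bad[1] <- 2
  mr2 <- misclassification_rates(list(bad, bad, bad), tr)
  expect_equal(mr2$rate[1], 1)
  expect_equal(mr2$adjusted_rate[1], 1)   # subpop median stays 0
  expect_equal(mr2$rate[2:10], rep(0, 9))
  # adjusted rates have per-subpopulation median 0 by construction
  set.seed(27)
  outs <- replicate(5, sample(1:2, 10, replace = TRUE), simplify = FALSE)
  mr3 <- misclassification_rates(outs, tr)
  med <- tapply(mr3$adjusted_rate, tr, median)
  expect_equal(as.numeric(med), c(0, 0))
  expect_error(misclassification_rates(list(perfect, perfect[-1]), tr),
               "mismatched")
})
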