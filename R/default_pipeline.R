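# The shipped six-step scRNA-seq pipeline: doublet identification, cell
# filtering, normalization, feature selection, dimension reduction and
# clustering, with truth-based evaluators attached to the steps where ground
# truth makes them meaningful.
#
# The pipeline state is a list carrying the current dataset plus the
# intermediates (normalized matrix, selected features, embedding, labels).

.scrna_init <- function(ds) {
  .assert(inherits(ds, "pg_dataset"), "datasets must be pg_dataset objects")
  true_k <- length(unique(ds$cell_meta$phenoid[!ds$cell_meta$is_doublet]))
  list(ds = ds, true_k = true_k)
}

.st_doublet <- function(state, args) {
  method <- args$doubletmethod
  if (identical(method, "none")) return(state)
  .assert(identical(method, "cluster_artificial"),
          paste0("unknown doublet method: ", method))
  ds <- state$ds
  cl <- quick_cluster(ds$counts)
  dp <- doublet_params(expected_rate = 0.05, rate_uncertainty = 0.02)
  art <- generate_artificial_doublets(ds$counts, cl, dp)
  sc <- call_doublets(score_doublets(ds$counts, art, dp), dp)
  state$doublet_scores <- sc
  state$ds <- subset_dataset(ds, cells = !sc$call)
  state
}

.ev_doublet <- function(state) {
  out <- list(n_cells = as.numeric(ncol(state$ds$counts)))
  sc <- state$doublet_scores
  if (!is.null(sc)) out$n_called <- as.numeric(sum(sc$call))
  out
}

.st_filter <- function(state, args) {
  fl <- args$filt
  ds <- state$ds
  if (identical(fl, "none")) return(state)
  keep <- switch(fl,
    default = , lenient = , stringent = , veryStringent =
      apply_filter_set(compute_cell_qc(ds), fl),
    pca.all = pca_outlier_filter(compute_cell_qc(ds), "all"),
    pca.sel = pca_outlier_filter(compute_cell_qc(ds), "selected"),
    cluster.default = clusterwise_filter(ds, "default"),
    stop("unknown filter set: ", fl))
  state$ds <- subset_dataset(ds, cells = keep)
  state
}

.ev_filter <- function(state) {
  cm <- state$ds$cell_meta
  list(n_cells = as.numeric(nrow(cm)),
       frac_lowq_remaining = as.numeric(mean(cm$is_lowq)))
}

.st_norm <- function(state, args) {
  nm <- args$norm
  counts <- state$ds$counts
  keep <- Matrix::colSums(counts) > 0
  if (!all(keep)) {
    state$ds <- subset_dataset(state$ds, cells = keep)
    counts <- state$ds$counts
  }
  state$norm <- switch(nm,
    lognorm = lognormalize(counts),
    none = {
      m <- .as_dgc(counts)
      m@x <- log1p(m@x)
      structure(list(mat = m, size_factors = rep(1, ncol(counts)),
                     transform = "log1p"), class = "pg_norm")
    },
    stop("unknown normalization: ", nm))
  state
}

.st_sel <- function(state, args) {
  method <- args$sel
  n <- as.integer(args$n_features)
  rk <- if (identical(method, "deviance"))
    rank_features(state$ds$counts, "deviance")
  else rank_features(state$norm, method)
  genes <- rk$gene[seq_len(min(n, nrow(rk)))]
  idx <- match(genes, state$ds$gene_meta$gene)
  state$sel_genes <- genes
  state$sel_mat <- as.matrix(state$norm$mat[idx, , drop = FALSE])
  rownames(state$sel_mat) <- genes
  state
}

.st_dr <- function(state, args) {
  dims <- as.integer(args$dims)
  X <- scale_features(state$sel_mat)
  state$scaled <- X
  state$embedding <- pca_embed(X, n_components = min(dims, min(dim(X)) - 1L))
  state
}

.ev_dr <- function(state) {
  cm <- state$ds$cell_meta
  singlet <- !cm$is_doublet
  out <- list(elbow_dim = as.numeric(elbow_dims(state$embedding)))
  if (length(unique(cm$phenoid[singlet])) >= 2 && sum(singlet) >= 10) {
    emb_s <- state$embedding$coords[singlet, , drop = FALSE]
    out$true_dim <- as.numeric(true_dimensionality(emb_s, cm$phenoid[singlet]))
    sil <- silhouette_per_subpop(emb_s, cm$phenoid[singlet])
    out$mean_silhouette <- as.numeric(mean(sil))
    libsize <- Matrix::colSums(state$ds$counts)[singlet]
    cc <- covariate_correlation_adjusted(emb_s[, 1], libsize,
                                         cm$phenoid[singlet])
    out$pc1_libsize_r2 <- as.numeric(attr(cc, "r_squared"))
  }
  out
}

.st_clust <- function(state, args) {
  g <- build_neighbor_graph(state$embedding, k = 10,
                            graph_type = args$graph_type %||% "snn_jaccard")
  state$labels <- cluster_graph(g, method = args$clustmethod,
                                resolution = as.numeric(args$resolution),
                                seed = 0L)
  state
}

.ev_clust <- function(state) {
  cm <- state$ds$cell_meta
  singlet <- !cm$is_doublet
  truth <- cm$phenoid[singlet]
  pred <- state$labels[singlet]
  out <- list(n_clusters = as.numeric(length(unique(state$labels))))
  if (length(unique(truth)) >= 2 && length(truth) >= 2) {
    tab <- contingency(truth, pred)
    ms <- match_and_score(tab)
    out$ari <- as.numeric(ari(tab))
    out$mi <- as.numeric(mutual_information(tab))
    out$mean_F1 <- as.numeric(ms$mean_F1)
    out$min_precision <- as.numeric(min(ms$precision))
    out$min_recall <- as.numeric(min(ms$recall))
    out$true_k <- as.numeric(state$true_k)
  }
  out
}

#' The shipped default scRNA-seq pipeline
#'
#' Six steps — doublet identification, cell filtering, normalization,
#' feature selection, dimension reduction, clustering — with truth-based
#' evaluators on the filtering, reduction and clustering steps. Step
#' parameters: `doubletmethod`, `filt`, `norm`, `sel` + `n_features`,
#' `dims`, `graph_type` + `clustmethod` + `resolution`.
#'
#' @return A `pg_pipeline`.
#' @export
default_scrna_pipeline <- function() {
  define_pipeline(list(
    pg_step("doublet", .st_doublet, params = "doubletmethod",
            evaluator = .ev_doublet),
    pg_step("filtering", .st_filter, params = "filt", evaluator = .ev_filter),
    pg_step("normalization", .st_norm, params = "norm"),
    pg_step("selection", .st_sel, params = c("sel", "n_features")),
    pg_step("reduction", .st_dr, params = "dims", evaluator = .ev_dr),
    pg_step("clustering", .st_clust,
            params = c("graph_type", "clustmethod", "resolution"),
            evaluator = .ev_clust)),
    initiator = .scrna_init)
}

#' Default parameter alternatives of the shipped pipeline
#'
#' Mirrors the customary defaults: artificial-doublet identification on, the
#' default filter set, standard log-normalization, 2000 selected features,
#' dimensions 5/10/15/20/30/50, and a resolution sweep over 0.005-4 wide
#' enough to reach the true cluster number.
#'
#' @param dims Dimension grid.
#' @param resolutions Resolution grid.
#' @return Named list of alternatives for [run_pipeline()].
#' @export
default_scrna_alternatives <- function(
    dims = c(5, 10, 15, 20, 30, 50),
    resolutions = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5,
                    0.8, 1, 1.2, 1.5, 2, 4)) {
  list(doubletmethod = "cluster_artificial",
       filt = "default",
       norm = "lognorm",
       sel = "variance",
       n_features = 2000,
       dims = dims,
       graph_type = "snn_jaccard",
       clustmethod = "modularity_resolution",
       resolution = resolutions)
}
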