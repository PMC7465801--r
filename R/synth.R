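# Seeded synthetic scRNA-seq count data with known subpopulations, injected
# heterotypic doublets and degraded (low-quality) cells. The generator is the
# testbed for every evaluation module: truth labels and flags are carried in
# the cell metadata.

#' Simulation parameters
#'
#' Parameters of the synthetic count generator. Counts are negative binomial
#' around per-subpopulation gene means; a fraction of genes is differentially
#' expressed between subpopulations with log fold changes (natural log) drawn
#' from `de_logfc_range`; per-cell library factors are log-normal; doublets
#' are entrywise sums of two freshly drawn cells from different
#' subpopulations; low-quality cells have their non-mitochondrial counts
#' binomially thinned so their mitochondrial share rises and their library
#' size drops, emulating cell degradation.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param n_subpops Number of subpopulations.
#' @param subpop_proportions Simplex vector of length `n_subpops` (defaults to
#'   equal proportions).
#' @param baseline_logmean_range Range (natural log) of per-gene baseline
#'   means.
#' @param frac_de_genes Fraction of genes differentially expressed in one
#'   randomly assigned subpopulation.
#' @param de_logfc_range Range of absolute log fold changes (natural log) for
#'   DE genes; the sign is random.
#' @param nb_dispersion Negative binomial dispersion (size = 1/dispersion),
#'   shared across genes.
#' @param libsize_lognormal_sd Standard deviation (log scale) of per-cell
#'   library factors.
#' @param frac_mito_genes,frac_ribo_genes,frac_coding_genes Fractions of genes
#'   flagged mitochondrial / ribosomal / protein-coding.
#' @param doublet_rate Probability that a barcode is a (heterotypic) doublet.
#' @param lowq_rate Probability that a singlet is a low-quality cell.
#' @param lowq_mito_inflation Multiplier by which the mitochondrial share of a
#'   low-quality cell is inflated (non-mito counts are thinned with
#'   probability 1/`lowq_mito_inflation`).
#' @param hierarchical If `TRUE`, subpopulation means are derived along a
#'   random tree of fold-change perturbations, producing pairs of closely
#'   related subpopulations.
#' @param seed Integer seed; identical parameters give identical datasets.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000, n_cells = 2000, n_subpops = 3,
                       subpop_proportions = NULL,
                       baseline_logmean_range = c(-2, 2),
                       frac_de_genes = 0.2, de_logfc_range = c(1, 2),
                       nb_dispersion = 0.5, libsize_lognormal_sd = 0.3,
                       frac_mito_genes = 0.05, frac_ribo_genes = 0.05,
                       frac_coding_genes = 0.8,
                       doublet_rate = 0.05, lowq_rate = 0.05,
                       lowq_mito_inflation = 5, hierarchical = FALSE,
                       seed = 42L) {
  if (is.null(subpop_proportions))
    subpop_proportions <- rep(1 / n_subpops, n_subpops)
  p <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
            n_subpops = as.integer(n_subpops),
            subpop_proportions = subpop_proportions,
            baseline_logmean_range = baseline_logmean_range,
            frac_de_genes = frac_de_genes, de_logfc_range = de_logfc_range,
            nb_dispersion = nb_dispersion,
            libsize_lognormal_sd = libsize_lognormal_sd,
            frac_mito_genes = frac_mito_genes,
            frac_ribo_genes = frac_ribo_genes,
            frac_coding_genes = frac_coding_genes,
            doublet_rate = doublet_rate, lowq_rate = lowq_rate,
            lowq_mito_inflation = lowq_mito_inflation,
            hierarchical = isTRUE(hierarchical), seed = as.integer(seed))
  .validate_sim_params(p)
  structure(p, class = "sim_params")
}

.validate_sim_params <- function(p) {
  .assert(p$n_genes >= 1L && p$n_cells >= 1L, "need at least one gene and one cell")
  .assert(p$n_subpops >= 1L && p$n_subpops <= p$n_cells,
          "n_subpops must be between 1 and n_cells")
  .assert(length(p$subpop_proportions) == p$n_subpops &&
            all(p$subpop_proportions > 0) &&
            abs(sum(p$subpop_proportions) - 1) < 1e-8,
          "subpop_proportions must be positive and sum to 1")
  fr <- c(p$frac_de_genes, p$frac_mito_genes, p$frac_ribo_genes,
          p$frac_coding_genes, p$doublet_rate, p$lowq_rate)
  .assert(all(fr >= 0 & fr <= 1), "fractions must lie in [0, 1]")
  .assert(p$nb_dispersion > 0, "nb_dispersion must be positive")
  .assert(p$lowq_mito_inflation >= 1, "lowq_mito_inflation must be >= 1")
  invisible(p)
}

# subpopulation mean matrix (genes x subpops)
.subpop_means <- function(p) {
  mu0 <- exp(runif(p$n_genes, p$baseline_logmean_range[1],
                   p$baseline_logmean_range[2]))
  M <- matrix(mu0, p$n_genes, p$n_subpops)
  n_de <- round(p$frac_de_genes * p$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(p$n_genes, n_de)) else integer(0)
  de_subpop <- rep(NA_integer_, p$n_genes)
  de_lfc <- rep(NA_real_, p$n_genes)
  if (p$n_subpops > 1 && n_de > 0) {
    if (p$hierarchical) {
      # grow subpopulations along a random tree: each new subpopulation
      # branches off an existing one with its own DE perturbations
      parent <- c(NA_integer_, vapply(2:p$n_subpops, function(s)
        sample.int(s - 1L, 1L), integer(1)))
      for (s in 2:p$n_subpops) {
        pick <- sample(de_idx, max(1L, round(n_de / p$n_subpops)))
        lfc <- runif(length(pick), p$de_logfc_range[1], p$de_logfc_range[2]) *
          sample(c(-1, 1), length(pick), replace = TRUE)
        M[, s] <- M[, parent[s]]
        M[pick, s] <- M[pick, s] * exp(lfc)
      }
      de_subpop[de_idx] <- NA_integer_   # tree structure: no single owner
    } else {
      de_subpop[de_idx] <- sample.int(p$n_subpops, n_de, replace = TRUE)
      de_lfc[de_idx] <- runif(n_de, p$de_logfc_range[1], p$de_logfc_range[2]) *
        sample(c(-1, 1), n_de, replace = TRUE)
      for (g in de_idx)
        M[g, de_subpop[g]] <- M[g, de_subpop[g]] * exp(de_lfc[g])
    }
  }
  list(M = M, is_de = seq_len(p$n_genes) %in% de_idx,
       de_subpop = de_subpop, de_logfc = de_lfc)
}

#' Simulate a synthetic count dataset
#'
#' Generates a seeded gene-by-cell raw count matrix with known subpopulation
#' labels (`phenoid`), injected heterotypic doublets (`is_doublet`, with both
#' parent labels recorded) and injected low-quality cells (`is_lowq`).
#'
#' @param params A [sim_params()] object.
#' @return A `pg_dataset`: list with sparse integer `counts` (genes x cells),
#'   `cell_meta` (phenoid, is_doublet, is_lowq, libfactor, parent labels and
#'   pre-degradation parent totals) and `gene_meta` (is_mito, is_ribo,
#'   is_coding, DE annotation and true per-subpopulation means).
#' @export
simulate_dataset <- function(params = sim_params()) {
  p <- .validate_sim_params(params)
  set.seed(p$seed)
  sp <- .subpop_means(p)
  pop_names <- paste0("pop", seq_len(p$n_subpops))

  n_mito <- round(p$frac_mito_genes * p$n_genes)
  n_ribo <- round(p$frac_ribo_genes * p$n_genes)
  flags <- sample(seq_len(p$n_genes))
  is_mito <- seq_len(p$n_genes) %in% flags[seq_len(n_mito)]
  is_ribo <- seq_len(p$n_genes) %in% flags[n_mito + seq_len(n_ribo)]
  is_coding <- runif(p$n_genes) < p$frac_coding_genes
  gene_ids <- ifelse(is_mito, paste0("MT-", seq_len(p$n_genes)),
                     paste0("G", seq_len(p$n_genes)))

  subpop <- sample.int(p$n_subpops, p$n_cells, replace = TRUE,
                       prob = p$subpop_proportions)
  is_doublet <- runif(p$n_cells) < p$doublet_rate
  is_lowq <- !is_doublet & runif(p$n_cells) < p$lowq_rate
  libf <- rlnorm(p$n_cells, 0, p$libsize_lognormal_sd)

  draw_cell <- function(s, f)
    rnbinom(p$n_genes, mu = f * sp$M[, s], size = 1 / p$nb_dispersion)

  counts <- matrix(0L, p$n_genes, p$n_cells)
  phenoid <- character(p$n_cells)
  parent1 <- parent2 <- rep(NA_character_, p$n_cells)
  ptot1 <- ptot2 <- rep(NA_real_, p$n_cells)
  pairs <- if (p$n_subpops >= 2) combn(p$n_subpops, 2) else NULL
  for (i in seq_len(p$n_cells)) {
    if (is_doublet[i] && !is.null(pairs)) {
      pr <- pairs[, sample.int(ncol(pairs), 1L)]
      f2 <- rlnorm(1, 0, p$libsize_lognormal_sd)
      c1 <- draw_cell(pr[1], libf[i])
      c2 <- draw_cell(pr[2], f2)
      counts[, i] <- c1 + c2
      phenoid[i] <- paste(pop_names[pr], collapse = "+")
      parent1[i] <- pop_names[pr[1]]; parent2[i] <- pop_names[pr[2]]
      ptot1[i] <- sum(c1); ptot2[i] <- sum(c2)
    } else {
      is_doublet[i] <- FALSE
      counts[, i] <- draw_cell(subpop[i], libf[i])
      phenoid[i] <- pop_names[subpop[i]]
    }
  }
  # degrade low-quality cells: thin non-mito counts so the mito share rises
  # by ~lowq_mito_inflation while the library size drops
  if (any(is_lowq) && p$lowq_mito_inflation > 1) {
    keep_p <- 1 / p$lowq_mito_inflation
    nonmito <- which(!is_mito)
    for (i in which(is_lowq))
      counts[nonmito, i] <- rbinom(length(nonmito), counts[nonmito, i], keep_p)
  }

  barcodes <- sprintf("cell%04d", seq_len(p$n_cells))
  cell_meta <- data.frame(
    barcode = barcodes, phenoid = phenoid, is_doublet = is_doublet,
    is_lowq = is_lowq, libfactor = libf,
    parent1 = parent1, parent2 = parent2,
    parent_total1 = ptot1, parent_total2 = ptot2,
    stringsAsFactors = FALSE)
  gene_meta <- data.frame(
    gene = gene_ids, is_mito = is_mito, is_ribo = is_ribo,
    is_coding = is_coding, is_de = sp$is_de,
    de_subpop = ifelse(is.na(sp$de_subpop), NA_character_,
                       pop_names[sp$de_subpop]),
    de_logfc = sp$de_logfc, stringsAsFactors = FALSE)
  tm <- as.data.frame(sp$M)
  names(tm) <- paste0("mean_", pop_names)
  gene_meta <- cbind(gene_meta, tm)

  cm <- .as_dgc(counts)
  dimnames(cm) <- list(gene_ids, barcodes)
  pg_dataset(cm, cell_meta, gene_meta)
}

#' Construct a count dataset
#'
#' @param counts Non-negative integer gene-by-cell matrix (coerced to sparse).
#' @param cell_meta Data frame with one row per cell; must contain a
#'   `phenoid` column (truth label). `is_doublet`/`is_lowq` flags are added
#'   as `FALSE` when absent.
#' @param gene_meta Data frame with one row per gene; `is_mito`, `is_ribo`,
#'   `is_coding` flags are added as `FALSE` when absent.
#' @return A `pg_dataset`.
#' @export
pg_dataset <- function(counts, cell_meta, gene_meta = NULL) {
  counts <- .as_dgc(counts)
  .assert(all(counts@x >= 0), "counts must be non-negative")
  .assert(is.data.frame(cell_meta) && nrow(cell_meta) == ncol(counts),
          "cell_meta rows must match count columns")
  if (is.null(gene_meta))
    gene_meta <- data.frame(gene = rownames(counts) %||%
                              paste0("G", seq_len(nrow(counts))))
  .assert(nrow(gene_meta) == nrow(counts),
          "gene_meta rows must match count rows")
  .assert("phenoid" %in% names(cell_meta), "cell_meta must contain 'phenoid'")
  for (fl in c("is_doublet", "is_lowq"))
    if (is.null(cell_meta[[fl]])) cell_meta[[fl]] <- FALSE
  for (fl in c("is_mito", "is_ribo", "is_coding"))
    if (is.null(gene_meta[[fl]])) gene_meta[[fl]] <- FALSE
  if (is.null(cell_meta$barcode))
    cell_meta$barcode <- colnames(counts) %||%
      sprintf("cell%04d", seq_len(ncol(counts)))
  if (is.null(gene_meta$gene))
    gene_meta$gene <- rownames(counts) %||% paste0("G", seq_len(nrow(counts)))
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta), class = "pg_dataset")
}

#' @export
print.pg_dataset <- function(x, ...) {
  cat("A count dataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      length(unique(x$cell_meta$phenoid[!x$cell_meta$is_doublet])),
      "singlet subpopulation(s),", sum(x$cell_meta$is_doublet), "doublet(s),",
      sum(x$cell_meta$is_lowq), "low-quality cell(s)\n")
  invisible(x)
}

#' Subset a dataset by cells and/or genes
#'
#' @param ds A `pg_dataset`.
#' @param cells,genes Index/logical vectors (default: keep all).
#' @return The subset `pg_dataset`.
#' @export
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  .assert(inherits(ds, "pg_dataset"), "'ds' must be a pg_dataset")
  if (is.null(cells)) cells <- seq_len(ncol(ds$counts))
  if (is.null(genes)) genes <- seq_len(nrow(ds$counts))
  pg_dataset(ds$counts[genes, cells, drop = FALSE],
             ds$cell_meta[cells, , drop = FALSE],
             ds$gene_meta[genes, , drop = FALSE])
}

# --- disk round trip ----------------------------------------------------------

.fmt_num_cols <- function(df) {
  for (cn in names(df))
    if (is.double(df[[cn]]))
      df[[cn]] <- ifelse(is.na(df[[cn]]), NA, sprintf("%.17g", df[[cn]]))
  df
}

.refmt_num_cols <- function(df, template) {
  for (cn in names(template))
    if (is.double(template[[cn]]) && cn %in% names(df))
      df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Write a dataset to disk
#'
#' Writes `matrix.mtx` (Matrix Market, 1-based indices), `features.tsv`
#' (gene metadata), `barcodes.tsv` and `cell_meta.csv` into a directory.
#' The round trip through [read_dataset()] is lossless.
#'
#' @param ds A `pg_dataset`.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  .assert(inherits(ds, "pg_dataset"), "'ds' must be a pg_dataset")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(ds$counts, file.path(path, "matrix.mtx"))
  write.table(.fmt_num_cols(ds$gene_meta), file.path(path, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ds$cell_meta$barcode, file.path(path, "barcodes.tsv"))
  write.csv(.fmt_num_cols(ds$cell_meta), file.path(path, "cell_meta.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset from disk
#'
#' @param path Directory written by [write_dataset()].
#' @return A `pg_dataset`.
#' @export
read_dataset <- function(path) {
  .assert(dir.exists(path), paste0("no such directory: ", path))
  counts <- Matrix::readMM(file.path(path, "matrix.mtx"))
  counts <- .as_dgc(counts)
  gene_meta <- read.delim(file.path(path, "features.tsv"),
                          stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  cell_meta <- read.csv(file.path(path, "cell_meta.csv"),
                        stringsAsFactors = FALSE)
  .assert(nrow(gene_meta) == nrow(counts),
          "features.tsv row count does not match matrix rows")
  .assert(length(barcodes) == ncol(counts),
          "barcodes.tsv row count does not match matrix columns")
  .assert(nrow(cell_meta) == ncol(counts),
          "cell_meta.csv row count does not match matrix columns")
  dimnames(counts) <- list(gene_meta$gene, barcodes)
  pg_dataset(counts, cell_meta, gene_meta)
}
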