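# Result transformation and export: the cross-dataset comparable heatmap
# scaling and CSV export of aggregated benchmark tables.

#' MAD-centered square-root transform of a metric matrix
#'
#' Centers each entry on its column (dataset) median, pools the deviations
#' matrix-wide into a single MAD, and maps each deviation to the signed
#' square root of its number of pooled MADs:
#' `t_ij = sign(d_ij) * sqrt(|d_ij| / s)`. With this mapping, color
#' differences mean the same thing across datasets while column medians stay
#' at zero. Missing entries (e.g. true cluster number never reached) are
#' preserved as missing. A zero pooled MAD yields an all-zero matrix (with a
#' warning).
#'
#' @param m Numeric matrix: pipeline variants x datasets (NAs allowed).
#' @param constant MAD consistency constant.
#' @return Transformed matrix of the same shape.
#' @export
mad_center_transform <- function(m, constant = 1.4826) {
  m <- as.matrix(m)
  .assert(any(is.finite(m)), "matrix has no finite entries")
  colmed <- apply(m, 2, median, na.rm = TRUE)
  d <- sweep(m, 2, colmed)
  s <- mad(d, center = 0, constant = constant, na.rm = TRUE)
  if (s == 0) {
    warning("pooled MAD is zero; returning zeros")
    t <- d * 0
  } else t <- sign(d) * sqrt(abs(d) / s)
  t
}

#' Sign-preserving square-root transform for silhouette values
#'
#' @param values Numeric values in [-1, 1].
#' @return `sign(values) * sqrt(|values|)`.
#' @export
sqrt_silhouette_transform <- function(values) {
  .assert(all(abs(values) <= 1 + 1e-12, na.rm = TRUE),
          "silhouette values must lie in [-1, 1]")
  sign(values) * sqrt(abs(values))
}

#' Export aggregated benchmark results
#'
#' Writes one long-format CSV per step, `timings.csv` and `errors.csv`, plus
#' — for each numeric metric of the final step — a variants x datasets metric
#' matrix in raw and MAD-centered form (raw values are always preserved
#' alongside the transformed ones).
#'
#' @param results A `pg_results` object, or the list from
#'   [aggregate_results()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(results, out_dir) {
  tabs <- if (inherits(results, "pg_results")) aggregate_results(results)
          else results
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tabs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  step_tabs <- tabs[setdiff(names(tabs), c("timings", "errors"))]
  if (length(step_tabs)) {
    final <- step_tabs[[length(step_tabs)]]
    idcols <- c("dataset", "status", "elapsed")
    metrics <- names(final)[vapply(final, is.numeric, logical(1))]
    metrics <- setdiff(metrics, idcols)
    params <- setdiff(names(final), c(idcols, metrics))
    if (length(metrics) && nrow(final) && length(unique(final$dataset)) >= 1) {
      variant <- apply(final[, params, drop = FALSE], 1, paste, collapse = ";")
      for (met in metrics) {
        mm <- tapply(final[[met]], list(variant, final$dataset),
                     function(v) v[1])
        raw_p <- file.path(out_dir, paste0("matrix_", met, "_raw.csv"))
        write.csv(mm, raw_p)
        tr_p <- file.path(out_dir, paste0("matrix_", met, "_scaled.csv"))
        tr <- tryCatch(mad_center_transform(mm), warning = function(w) mm * 0,
                       error = function(e) NULL)
        if (!is.null(tr)) write.csv(tr, tr_p)
        paths <- c(paths, raw_p, tr_p)
      }
    }
  }
  invisible(paths)
}
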