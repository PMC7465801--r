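.onLoad <- function(libname, pkgname) {
  # shipped registry entries: the default pipeline and its stage routines
  pg_register("scrna_default", default_scrna_pipeline())
  pg_register("lognormalize", lognormalize)
  pg_register("rank_features", rank_features)
  pg_register("pca_embed", pca_embed)
  pg_register("quick_cluster", quick_cluster)
  invisible(NULL)
}
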