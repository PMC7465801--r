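# User-extensible registry mapping string alternatives (and pipeline names)
# to functions, so configurations can refer to subroutines by name.

.pg_registry <- new.env(parent = emptyenv())

#' Register a named subroutine or pipeline
#'
#' Alternatives in a configuration may be plain strings; step operations
#' resolve them to functions through this registry. Shipped stages are
#' pre-registered; users may add or override entries.
#'
#' @param name Registry key.
#' @param value A function (or a `pg_pipeline` for pipeline entries).
#' @export
pg_register <- function(name, value) {
  .assert(is.character(name) && length(name) == 1L, "'name' must be a string")
  assign(name, value, envir = .pg_registry)
  invisible(value)
}

#' Resolve a registry entry
#'
#' @param name Registry key, or a function (returned as is).
#' @return The registered object.
#' @export
pg_resolve <- function(name) {
  if (is.function(name)) return(name)
  .assert(is.character(name) && length(name) == 1L, "'name' must be a string")
  if (!exists(name, envir = .pg_registry, inherits = FALSE))
    stop("no registry entry named '", name, "'", call. = FALSE)
  get(name, envir = .pg_registry, inherits = FALSE)
}

#' List registry entries
#' @return Character vector of registered names.
#' @export
pg_registry_names <- function() sort(ls(.pg_registry))
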