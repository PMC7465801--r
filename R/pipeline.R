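# Core engine: pipeline declaration, combination enumeration, prefix-sharing
# execution with on-the-fly evaluation, timing, and tidy aggregation.

#' Declare a pipeline step
#'
#' A step owns an operation (state + step arguments -> new state), the names of
#' the parameters it consumes, and optionally an evaluator run on the state
#' produced at every node of this step's level, plus an aggregator used when
#' compiling that step's tidy table.
#'
#' @param name Step identifier, unique within a pipeline.
#' @param fn Operation: `function(state, args, ...)` returning the new state.
#'   `args` is a named list with one entry per parameter of this step.
#'   Stochastic operations must rely only on R's RNG: the engine seeds it
#'   deterministically per node.
#' @param params Character vector of parameter names owned by this step (may
#'   be empty).
#' @param evaluator Optional `function(state)` returning a named list of
#'   scalar metrics (the evaluation payload).
#' @param aggregator Optional `function(payloads, meta)` where `payloads` is a
#'   list of payloads and `meta` the matching id table; must return a
#'   data.frame with one row per payload. Defaults to flattening payloads into
#'   columns.
#' @return An object of class `pg_step`.
#' @export
pg_step <- function(name, fn, params = character(), evaluator = NULL,
                    aggregator = NULL) {
  .assert(is.character(name) && length(name) == 1L && nzchar(name),
          "step 'name' must be a non-empty string")
  .assert(is.function(fn), "step 'fn' must be a function")
  .assert(is.character(params), "'params' must be a character vector")
  .assert(anyDuplicated(params) == 0L, "duplicated parameter names in a step")
  if (!is.null(evaluator)) .assert(is.function(evaluator), "'evaluator' must be a function")
  if (!is.null(aggregator)) .assert(is.function(aggregator), "'aggregator' must be a function")
  structure(list(name = name, fn = fn, params = params,
                 evaluator = evaluator, aggregator = aggregator),
            class = "pg_step")
}

#' Define a pipeline
#'
#' Validates and assembles an ordered list of steps into a pipeline
#' definition. Step names must be unique and parameter names disjoint across
#' steps, so every parameter maps to exactly one step.
#'
#' @param steps List of [pg_step()] objects (at least one).
#' @param initiator Optional `function(dataset)` preparing a raw dataset into
#'   the input state of the first step. Defaults to the identity.
#' @return An object of class `pg_pipeline`.
#' @export
define_pipeline <- function(steps, initiator = NULL) {
  .assert(is.list(steps) && length(steps) >= 1L, "need at least one step")
  .assert(all(vapply(steps, inherits, logical(1), "pg_step")),
          "all steps must be pg_step objects")
  nm <- vapply(steps, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate step name: ", nm[duplicated(nm)][1])
  allp <- unlist(lapply(steps, `[[`, "params"))
  if (anyDuplicated(allp))
    stop("parameter owned by two steps: ", allp[duplicated(allp)][1])
  if (!is.null(initiator)) .assert(is.function(initiator), "'initiator' must be a function")
  structure(list(steps = steps, initiator = initiator), class = "pg_pipeline")
}

#' @export
print.pg_pipeline <- function(x, ...) {
  cat("A pipeline with", length(x$steps), "steps:\n")
  for (s in x$steps)
    cat("  -", s$name,
        if (length(s$params)) paste0("(", paste(s$params, collapse = ", "), ")") else "",
        if (!is.null(s$evaluator)) "[evaluated]" else "", "\n")
  invisible(x)
}

# ordered parameter metadata of a pipeline
.pipeline_params <- function(pipeline) {
  steps <- pipeline$steps
  params <- unlist(lapply(steps, `[[`, "params"))
  step_of <- rep(seq_along(steps), vapply(steps, function(s) length(s$params), integer(1)))
  list(params = as.character(params), step_of = as.integer(step_of),
       step_names = vapply(steps, `[[`, character(1), "name"))
}

.label_of <- function(v, nm) {
  if (!is.null(nm) && nzchar(nm)) return(nm)
  if (is.character(v) && length(v) == 1L) return(v)
  if ((is.numeric(v) || is.logical(v)) && length(v) == 1L) return(as.character(v))
  stop("alternative values that are not named must be scalars ",
       "(name function/complex alternatives)", call. = FALSE)
}

#' Enumerate parameter combinations
#'
#' Builds the Cartesian product of the per-parameter alternatives, in
#' lexicographic order: parameters are ordered by step order (then declaration
#' order within a step) and later parameters vary fastest. An optional subset
#' filter retains only some combinations.
#'
#' @param pipeline A `pg_pipeline`.
#' @param alts Named list mapping every pipeline parameter to a non-empty
#'   vector/list of alternative values. Entries may be named; names become the
#'   combination labels (required for function-valued alternatives).
#' @param subset Optional filter: either a predicate `function(labels)` taking
#'   the named character vector of a combination's labels, or a named list of
#'   allowed labels per parameter.
#' @return An object of class `pg_plan`.
#' @export
enumerate_combinations <- function(pipeline, alts, subset = NULL) {
  .assert(inherits(pipeline, "pg_pipeline"), "'pipeline' must be a pg_pipeline")
  pp <- .pipeline_params(pipeline)
  unknown <- setdiff(names(alts), pp$params)
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(pp$params, names(alts))
  if (length(missing)) stop("no alternatives given for parameter(s): ",
                            paste(missing, collapse = ", "))
  values <- lapply(pp$params, function(p) {
    v <- alts[[p]]
    .assert(length(v) >= 1L, paste0("empty alternative list for '", p, "'"))
    if (!is.list(v)) v <- as.list(v)
    v
  })
  names(values) <- pp$params
  labels <- lapply(pp$params, function(p) {
    v <- values[[p]]
    nms <- names(v) %||% rep("", length(v))
    lab <- mapply(.label_of, v, nms)
    .assert(anyDuplicated(lab) == 0L, paste0("duplicate labels for '", p, "'"))
    lab
  })
  names(labels) <- pp$params
  lens <- vapply(values, length, integer(1))
  # last parameter varies fastest -> lexicographic order by parameter order
  g <- do.call(expand.grid, c(rev(lapply(lens, seq_len)),
                              list(KEEP.OUT.ATTRS = FALSE)))
  idx <- as.matrix(g[, rev(seq_along(lens)), drop = FALSE])
  colnames(idx) <- pp$params
  labmat <- vapply(pp$params, function(p) labels[[p]][idx[, p]],
                   character(nrow(idx)))
  if (nrow(idx) == 1L) labmat <- matrix(labmat, nrow = 1L,
                                        dimnames = list(NULL, pp$params))
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(subset)) {
    if (is.function(subset)) {
      keep <- vapply(seq_len(nrow(idx)), function(i)
        isTRUE(subset(setNames(labmat[i, ], pp$params))), logical(1))
    } else if (is.list(subset)) {
      for (p in names(subset)) {
        .assert(p %in% pp$params, paste0("subset refers to unknown parameter '", p, "'"))
        keep <- keep & labmat[, p] %in% as.character(subset[[p]])
      }
    } else stop("'subset' must be a predicate function or a named list")
  }
  if (!any(keep)) stop("subset filter removed all combinations")
  structure(list(params = pp$params, step_of = pp$step_of,
                 step_names = pp$step_names, values = values,
                 idx = idx[keep, , drop = FALSE],
                 labels = labmat[keep, , drop = FALSE]),
            class = "pg_plan")
}

#' @export
print.pg_plan <- function(x, ...) {
  cat("A combination plan:", nrow(x$idx), "combinations over",
      length(x$params), "parameters\n")
  invisible(x)
}

# prefix key of combination row i at step j (all parameters of steps <= j)
.prefix_key <- function(plan, i, j) {
  sel <- plan$step_of <= j
  paste(plan$labels[i, sel], collapse = "\x1f")
}

#' Build the prefix tree of a combination plan
#'
#' Each node is a distinct assignment of all parameters of steps up to a given
#' index; leaves correspond one-to-one to plan combinations. Children are
#' ordered by alternative declaration order.
#'
#' @param plan A `pg_plan`.
#' @param pipeline The matching `pg_pipeline`.
#' @return An object of class `pg_prefix_tree`: a nested node list with fields
#'   `step` (0 for the root), `key`, `rows` (combination indices covered) and
#'   `children`.
#' @export
build_prefix_tree <- function(plan, pipeline) {
  .assert(inherits(plan, "pg_plan"), "'plan' must be a pg_plan")
  n_steps <- length(pipeline$steps)
  build <- function(rows, j) {
    node <- list(step = j, key = if (j == 0L) "" else .prefix_key(plan, rows[1], j),
                 rows = rows, children = list())
    if (j < n_steps) {
      keys <- vapply(rows, .prefix_key, character(1), plan = plan, j = j + 1L)
      for (k in unique(keys))   # first-occurrence order = declaration order
        node$children[[length(node$children) + 1L]] <-
          build(rows[keys == k], j + 1L)
    }
    node
  }
  structure(build(seq_len(nrow(plan$idx)), 0L),
            class = c("pg_prefix_tree", "list"))
}

#' Number of nodes per tree level
#'
#' @param tree A `pg_prefix_tree`.
#' @return Integer vector: number of distinct prefixes per step.
#' @export
prefix_tree_level_sizes <- function(tree) {
  sizes <- integer(0)
  walk <- function(node) {
    if (node$step > 0L) {
      while (length(sizes) < node$step) sizes[[length(sizes) + 1L]] <<- 0L
      sizes[node$step] <<- sizes[node$step] + 1L
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  sizes
}

# --- execution ----------------------------------------------------------------

.record_key <- function(dataset, step, key) paste(dataset, step, key, sep = "\x1e")

.new_recorder <- function(log_path = NULL) {
  e <- new.env(parent = emptyenv())
  e$recs <- list()
  e$con <- NULL
  if (!is.null(log_path)) {
    e$con <- file(log_path, open = "a")
  }
  e
}

.add_record <- function(rec_env, rec, log = TRUE) {
  rec_env$recs[[.record_key(rec$dataset, rec$step_index, rec$key)]] <- rec
  if (log && !is.null(rec_env$con)) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                                null = "null"), rec_env$con)
    flush(rec_env$con)
  }
  invisible(NULL)
}

.load_log <- function(path) {
  out <- list()
  if (is.null(path) || !file.exists(path)) return(out)
  for (ln in readLines(path, warn = FALSE)) {
    if (!nzchar(ln)) next
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    if (length(rec$payload)) rec$payload <- as.list(rec$payload) else rec$payload <- NULL
    out[[.record_key(rec$dataset, rec$step_index, rec$key)]] <- rec
  }
  out
}

.make_record <- function(dataset, step_name, step_index, key, labels, status,
                         elapsed = NA_real_, payload = NULL,
                         message = NULL, eval_error = NULL) {
  list(dataset = dataset, step = step_name, step_index = step_index, key = key,
       params = as.list(labels), status = status, elapsed = as.numeric(elapsed),
       payload = payload, message = message, eval_error = eval_error)
}

# payloads are coerced to flat named lists of doubles/strings so that the
# JSON-lines resumability log round-trips them exactly
.sanitize_payload <- function(p) {
  if (is.null(p)) return(NULL)
  .assert(is.list(p) && (length(p) == 0L || !is.null(names(p))),
          "evaluator must return a named list of scalars")
  lapply(p, function(v) {
    .assert(length(v) == 1L, "evaluator payload entries must be scalars")
    if (is.numeric(v)) as.numeric(v) else as.character(v)
  })
}

# labels of the parameters of steps <= j for combination row i
.prefix_labels <- function(plan, i, j) {
  sel <- plan$step_of <= j
  setNames(plan$labels[i, sel], plan$params[sel])
}

# mark every node of a subtree (strictly below `node`) as skipped
.skip_subtree <- function(node, plan, dataset, rec_env) {
  for (ch in node$children) {
    i <- ch$rows[1]
    .add_record(rec_env, .make_record(
      dataset, plan$step_names[ch$step], ch$step, ch$key,
      .prefix_labels(plan, i, ch$step), status = "skipped"))
    .skip_subtree(ch, plan, dataset, rec_env)
  }
}

# TRUE when a node and its whole subtree are present in `prior`
.subtree_recorded <- function(node, dataset, prior) {
  if (node$step > 0L &&
      is.null(prior[[.record_key(dataset, node$step, node$key)]])) return(FALSE)
  for (ch in node$children)
    if (!.subtree_recorded(ch, dataset, prior)) return(FALSE)
  TRUE
}

.copy_subtree_records <- function(node, dataset, prior, rec_env) {
  if (node$step > 0L)
    .add_record(rec_env, prior[[.record_key(dataset, node$step, node$key)]],
                log = FALSE)
  for (ch in node$children) .copy_subtree_records(ch, dataset, prior, rec_env)
}

# depth-first execution of one dataset's prefix tree; at most one live state
# per tree depth (the recursion stack), matching the no-stored-intermediates
# memory contract
.run_tree <- function(node, state, pipeline, plan, dataset, seed, rec_env, prior) {
  for (ch in node$children) {
    step <- pipeline$steps[[ch$step]]
    i <- ch$rows[1]
    labels <- .prefix_labels(plan, i, ch$step)
    args <- lapply(setNames(nm = step$params), function(p)
      plan$values[[p]][[plan$idx[i, p]]])
    rkey <- .record_key(dataset, ch$step, ch$key)
    prior_rec <- prior[[rkey]]
    if (!is.null(prior_rec) && .subtree_recorded(ch, dataset, prior)) {
      .copy_subtree_records(ch, dataset, prior, rec_env)
      next
    }
    if (!is.null(prior_rec) && identical(prior_rec$status, "error")) {
      .add_record(rec_env, prior_rec, log = FALSE)
      .skip_subtree(ch, plan, dataset, rec_env)
      next
    }
    set.seed(.mix_seed(seed, paste0(dataset, "\x1e", ch$step, "\x1e", ch$key)))
    t0 <- proc.time()[["elapsed"]]
    new_state <- tryCatch(step$fn(state, args), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(new_state, "error")) {
      .add_record(rec_env, .make_record(
        dataset, step$name, ch$step, ch$key, labels, status = "error",
        elapsed = elapsed, message = conditionMessage(new_state)))
      .skip_subtree(ch, plan, dataset, rec_env)
      next
    }
    if (!is.null(prior_rec)) {
      # node already recorded but its subtree is incomplete: reuse the logged
      # record (payload and timing) and only recompute the state for descendants
      .add_record(rec_env, prior_rec, log = FALSE)
    } else {
      payload <- NULL; eval_error <- NULL
      if (!is.null(step$evaluator)) {
        set.seed(.mix_seed(seed, paste0(dataset, "\x1e", ch$step, "\x1e",
                                        ch$key, "\x1e#eval")))
        payload <- tryCatch(.sanitize_payload(step$evaluator(new_state)),
                            error = function(e) e)
        if (inherits(payload, "error")) {
          eval_error <- conditionMessage(payload); payload <- NULL
        }
      }
      .add_record(rec_env, .make_record(
        dataset, step$name, ch$step, ch$key, labels, status = "ok",
        elapsed = elapsed, payload = payload, eval_error = eval_error))
    }
    .run_tree(ch, new_state, pipeline, plan, dataset, seed, rec_env, prior)
  }
  invisible(NULL)
}

#' Run a pipeline over all parameter combinations
#'
#' Executes the pipeline on every dataset for every combination in the plan,
#' sharing the computation of identical pipeline prefixes: each distinct
#' prefix is executed exactly once per dataset. Step evaluators run on the
#' state at every node of their step's level; wall time is recorded per node.
#' A failing operation marks its node `error` and all of its descendants
#' `skipped`, while sibling subtrees proceed.
#'
#' @param pipeline A `pg_pipeline`.
#' @param alts Alternatives, as in [enumerate_combinations()].
#' @param datasets Named list of datasets accepted by the pipeline's initiator
#'   (unnamed lists are named `ds1`, `ds2`, ...).
#' @param subset Optional combination filter, as in [enumerate_combinations()].
#' @param seed Integer global seed; per-node seeds are derived from it, the
#'   dataset id and the prefix, so sibling subtrees are independent yet
#'   reproducible (and independent of the execution strategy).
#' @param n_workers Parallel workers across datasets (forked; within-dataset
#'   traversal stays serial to preserve prefix sharing).
#' @param resume_log Optional path to an append-only JSON-lines log. When the
#'   file already holds records from a previous (crashed) run, fully recorded
#'   subtrees are skipped and logged payloads are reused.
#' @return A `pg_results` object; see [aggregate_results()].
#' @export
run_pipeline <- function(pipeline, alts, datasets, subset = NULL, seed = 0L,
                         n_workers = 1L, resume_log = NULL) {
  .assert(inherits(pipeline, "pg_pipeline"), "'pipeline' must be a pg_pipeline")
  .assert(is.list(datasets) && length(datasets) >= 1L, "need at least one dataset")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- paste0("ds", seq_along(datasets))
  plan <- enumerate_combinations(pipeline, alts, subset)
  tree <- build_prefix_tree(plan, pipeline)
  prior <- .load_log(resume_log)

  run_one <- function(ds_name) {
    rec_env <- .new_recorder(resume_log)
    on.exit(if (!is.null(rec_env$con)) close(rec_env$con))
    state0 <- tryCatch(
      if (is.null(pipeline$initiator)) datasets[[ds_name]]
      else pipeline$initiator(datasets[[ds_name]]),
      error = function(e) e)
    if (inherits(state0, "error")) {
      for (ch in tree$children) {
        i <- ch$rows[1]
        .add_record(rec_env, .make_record(
          ds_name, plan$step_names[ch$step], ch$step, ch$key,
          .prefix_labels(plan, i, ch$step), status = "error",
          message = paste0("initiator: ", conditionMessage(state0))))
        .skip_subtree(ch, plan, ds_name, rec_env)
      }
    } else {
      .run_tree(tree, state0, pipeline, plan, ds_name, seed, rec_env, prior)
    }
    rec_env$recs
  }

  recs <- if (n_workers > 1L && length(datasets) > 1L &&
              .Platform$OS.type == "unix") {
    .assert(is.null(resume_log) || length(datasets) == 1L,
            "resume_log is only supported with a single worker")
    parallel::mclapply(names(datasets), run_one, mc.cores = n_workers)
  } else {
    lapply(names(datasets), run_one)
  }
  records <- do.call(c, recs)
  records <- records[order(names(records), method = "radix")]
  structure(list(records = records, plan = plan, pipeline = pipeline,
                 datasets = names(datasets), seed = seed),
            class = "pg_results")
}

#' Run a pipeline naively (no prefix sharing)
#'
#' Reference runner that re-executes the full pipeline from scratch for every
#' combination. Per-node seeds are derived exactly as in [run_pipeline()], so
#' a deterministic pipeline yields identical records; used as an independent
#' correctness oracle for the prefix-sharing engine.
#'
#' @inheritParams run_pipeline
#' @return A `pg_results` object.
#' @export
run_pipeline_naive <- function(pipeline, alts, datasets, subset = NULL,
                               seed = 0L) {
  .assert(inherits(pipeline, "pg_pipeline"), "'pipeline' must be a pg_pipeline")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- paste0("ds", seq_along(datasets))
  plan <- enumerate_combinations(pipeline, alts, subset)
  n_steps <- length(pipeline$steps)
  rec_env <- .new_recorder(NULL)
  for (ds_name in names(datasets)) {
    for (i in seq_len(nrow(plan$idx))) {
      state <- if (is.null(pipeline$initiator)) datasets[[ds_name]]
               else pipeline$initiator(datasets[[ds_name]])
      failed <- FALSE
      for (j in seq_len(n_steps)) {
        step <- pipeline$steps[[j]]
        key <- .prefix_key(plan, i, j)
        labels <- .prefix_labels(plan, i, j)
        if (failed) {
          .add_record(rec_env, .make_record(ds_name, step$name, j, key, labels,
                                            status = "skipped"), log = FALSE)
          next
        }
        args <- lapply(setNames(nm = step$params), function(p)
          plan$values[[p]][[plan$idx[i, p]]])
        set.seed(.mix_seed(seed, paste0(ds_name, "\x1e", j, "\x1e", key)))
        t0 <- proc.time()[["elapsed"]]
        state_new <- tryCatch(step$fn(state, args), error = function(e) e)
        elapsed <- proc.time()[["elapsed"]] - t0
        if (inherits(state_new, "error")) {
          .add_record(rec_env, .make_record(
            ds_name, step$name, j, key, labels, status = "error",
            elapsed = elapsed, message = conditionMessage(state_new)),
            log = FALSE)
          failed <- TRUE
          next
        }
        payload <- NULL; eval_error <- NULL
        if (!is.null(step$evaluator)) {
          set.seed(.mix_seed(seed, paste0(ds_name, "\x1e", j, "\x1e", key,
                                          "\x1e#eval")))
          payload <- tryCatch(.sanitize_payload(step$evaluator(state_new)),
                              error = function(e) e)
          if (inherits(payload, "error")) {
            eval_error <- conditionMessage(payload); payload <- NULL
          }
        }
        .add_record(rec_env, .make_record(
          ds_name, step$name, j, key, labels, status = "ok",
          elapsed = elapsed, payload = payload, eval_error = eval_error),
          log = FALSE)
        state <- state_new
      }
    }
  }
  records <- rec_env$recs[order(names(rec_env$recs), method = "radix")]
  structure(list(records = records, plan = plan, pipeline = pipeline,
                 datasets = names(datasets), seed = seed),
            class = "pg_results")
}

#' @export
print.pg_results <- function(x, ...) {
  st <- table(vapply(x$records, `[[`, character(1), "status"))
  cat("Pipeline results:", length(x$datasets), "dataset(s),",
      nrow(x$plan$idx), "combination(s),", length(x$records),
      "step executions (", paste(names(st), st, sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

# --- aggregation --------------------------------------------------------------

.flatten_payloads <- function(payloads) {
  cols <- unique(unlist(lapply(payloads, names)))
  if (!length(cols)) return(data.frame(row.names = seq_along(payloads))[, 0, drop = FALSE])
  out <- lapply(cols, function(cn) {
    vals <- lapply(payloads, function(p) p[[cn]])
    chr <- any(vapply(vals, is.character, logical(1)))
    vapply(vals, function(v) {
      if (is.null(v)) if (chr) NA_character_ else NA_real_
      else if (chr) as.character(v) else as.numeric(v)
    }, if (chr) character(1) else numeric(1))
  })
  names(out) <- cols
  as.data.frame(out, optional = TRUE)
}

#' Aggregate run records into tidy per-step tables
#'
#' Produces, for each step, a long-format table with one row per
#' (dataset, combination): the dataset id, one column per pipeline parameter
#' (the full combination), status, elapsed time of the step's node, and one
#' column per evaluation metric. Also returns a per-node timing table and an
#' error table.
#'
#' @param results A `pg_results` object (or a merge of several via
#'   [merge_results()]).
#' @return Named list with one data.frame per step, plus `timings` and
#'   `errors`.
#' @export
aggregate_results <- function(results) {
  .assert(inherits(results, "pg_results"), "'results' must be a pg_results")
  plan <- results$plan
  pipeline <- results$pipeline
  n_steps <- length(pipeline$steps)
  out <- list()
  for (j in seq_len(n_steps)) {
    step <- pipeline$steps[[j]]
    rows <- list(); payloads <- list(); n <- 0L
    for (ds in results$datasets) {
      for (i in seq_len(nrow(plan$idx))) {
        rec <- results$records[[.record_key(ds, j, .prefix_key(plan, i, j))]]
        if (is.null(rec)) next
        n <- n + 1L
        rows[[n]] <- data.frame(dataset = ds,
                                as.list(setNames(plan$labels[i, ], plan$params)),
                                status = rec$status,
                                elapsed = as.numeric(rec$elapsed %||% NA_real_),
                                check.names = FALSE)
        payloads[n] <- list(rec$payload)   # keep NULL payloads as slots
      }
    }
    meta <- if (n) do.call(rbind, rows) else
      data.frame(dataset = character(), status = character(), elapsed = numeric())
    pay <- if (is.null(step$aggregator)) .flatten_payloads(payloads)
           else step$aggregator(payloads, meta)
    tab <- if (n && ncol(pay)) cbind(meta, pay, row.names = NULL) else meta
    rownames(tab) <- NULL
    out[[step$name]] <- tab
  }
  # per-node timing table
  trows <- lapply(results$records, function(rec) {
    lab <- setNames(rep(NA_character_, length(plan$params)), plan$params)
    lab[names(rec$params)] <- unlist(rec$params) %||% character(0)
    data.frame(dataset = rec$dataset, step = rec$step, as.list(lab),
               status = rec$status, elapsed = as.numeric(rec$elapsed %||% NA_real_),
               check.names = FALSE)
  })
  out$timings <- if (length(trows)) {
    tt <- do.call(rbind, trows); rownames(tt) <- NULL; tt
  } else data.frame(dataset = character(), step = character(),
                    status = character(), elapsed = numeric())
  err <- Filter(function(r) identical(r$status, "error"), results$records)
  erows <- lapply(err, function(rec)
    data.frame(dataset = rec$dataset, step = rec$step,
               message = rec$message %||% NA_character_))
  out$errors <- if (length(erows)) {
    ee <- do.call(rbind, erows); rownames(ee) <- NULL; ee
  } else data.frame(dataset = character(), step = character(), message = character())
  out
}

#' Merge results from disjoint dataset sets
#'
#' @param ... `pg_results` objects from the same pipeline run over disjoint
#'   datasets.
#' @return A combined `pg_results`.
#' @export
merge_results <- function(...) {
  parts <- list(...)
  .assert(length(parts) >= 1L && all(vapply(parts, inherits, logical(1), "pg_results")),
          "all arguments must be pg_results objects")
  base <- parts[[1]]
  for (p in parts[-1]) {
    .assert(identical(p$plan$params, base$plan$params) &&
              identical(p$plan$labels, base$plan$labels),
            "results come from incompatible plans")
    .assert(!any(p$datasets %in% base$datasets), "datasets overlap")
    base$records <- c(base$records, p$records)
    base$datasets <- c(base$datasets, p$datasets)
  }
  base$records <- base$records[order(names(base$records), method = "radix")]
  base
}

#' Read a benchmark configuration file
#'
#' Reads a YAML or JSON configuration with keys `pipeline` (a name resolved in
#' the registry), `alternatives`, optional `subset`, `datasets` (paths),
#' `seed` and `output_dir`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration entries.
#' @export
read_benchmark_config <- function(path) {
  .assert(file.exists(path), paste0("no such file: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  .assert(is.list(cfg), "malformed configuration")
  cfg
}
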