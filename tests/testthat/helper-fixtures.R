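# Shared fixtures: an instrumented arithmetic toy pipeline and small datasets.

# toy 3-step pipeline whose operations count their own invocations and whose
# payloads depend deterministically on the accumulated arguments
make_toy_pipeline <- function(counter = NULL, fail_on = NULL,
                              stochastic = FALSE) {
  bump <- function(slot) if (!is.null(counter))
    counter[[slot]] <- counter[[slot]] + 1L
  op <- function(slot) function(state, args) {
    bump(slot)
    val <- args[[1]]
    if (!is.null(fail_on) && identical(fail_on$step, slot) &&
        identical(val, fail_on$value) &&
        (is.null(fail_on$upstream) || identical(state$trace, fail_on$upstream)))
      stop("injected failure")
    noise <- if (stochastic) rnorm(1) else 0
    list(acc = state$acc + val + noise, trace = c(state$trace, val))
  }
  define_pipeline(list(
    pg_step("A", op("a"), "pa",
            evaluator = function(s) list(acc = s$acc)),
    pg_step("B", op("b"), "pb"),
    pg_step("C", op("c"), "pc",
            evaluator = function(s) list(acc = s$acc,
                                         depth = length(s$trace)))),
    initiator = function(ds) list(acc = ds, trace = numeric(0)))
}

toy_alts <- function() list(pa = c(1, 2), pb = c(10, 20, 30), pc = c(100, 200))

new_counter <- function() {
  e <- new.env(); e$a <- 0L; e$b <- 0L; e$c <- 0L; e
}

# drop wall-time columns before comparing aggregated tables: timing is a
# measurement, not a computation result
strip_timing <- function(tabs) {
  tabs$timings <- NULL
  lapply(tabs, function(t) t[, setdiff(names(t), "elapsed"), drop = FALSE])
}

small_dataset <- function(seed = 7, n_genes = 400, n_cells = 500,
                          n_subpops = 3, doublet_rate = 0.1, lowq_rate = 0.05) {
  simulate_dataset(sim_params(n_genes = n_genes, n_cells = n_cells,
                              n_subpops = n_subpops,
                              doublet_rate = doublet_rate,
                              lowq_rate = lowq_rate, seed = seed))
}

# all permutations of 1..n (n small), for brute-force assignment oracles
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  }
  out
}
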