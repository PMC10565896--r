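# Shared simulated cohorts, built once per test run and cached so several
# test files can reuse them without re-simulating.

.cohort_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

cached <- function(name, expr) {
  if (!exists(name, envir = .cohort_cache)) {
    assign(name, force(expr), envir = .cohort_cache)
  }
  get(name, envir = .cohort_cache)
}

## small mixed cohort with outgroup and fixture on disk (deterministic)
small_fixture <- function() {
  cached("small_fixture", {
    cfg <- simulation_config(
      population_size = 300, sample_size = 12,
      num_genes_per_class = c(cooperative = 4, private = 4, background = 2),
      gene_length_bp = 300, true_relatedness = 0.5,
      missingness_rate = 0, burn_in_generations = 3000, seed = 101)
    sim <- simulate_population(cfg)
    og <- simulate_outgroup(cfg, sim$reference, sim$truth$class)
    dir <- file.path(tempdir(), "kinsig_small_fixture")
    unlink(dir, recursive = TRUE)
    fx <- write_fixture(dir, sim, outgroup = og)
    list(cfg = cfg, sim = sim, og = og, fx = fx, dir = dir)
  })
}
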