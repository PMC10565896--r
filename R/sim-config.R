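#' Configuration for the relaxed-selection Wright-Fisher simulator
#'
#' Encodes the study conditions for a simulated cohort: a haploid
#' Wright-Fisher population of size `population_size` from which
#' `sample_size` strains are sampled after burn-in, with per-gene
#' multiplicative purifying selection against nonsynonymous mutations.
#' Cooperative genes experience the relaxed coefficient `s_eff = r * s`
#' (the first-order inclusive-fitness reduction when only a fraction `r`
#' of beneficiaries carry the gene); private and background genes
#' experience the full `s`.
#'
#' @param population_size Haploid population size N.
#' @param sample_size Number of strains sampled without replacement
#'   (default 31, matching a typical natural-isolate panel).
#' @param num_genes_per_class Named integer vector with entries
#'   `cooperative`, `private`, `background` (entries may be 0).
#' @param gene_length_bp Gene length in bp, a multiple of 3 (includes the
#'   terminal stop codon).
#' @param per_site_mutation_rate Mutation rate u per site per generation.
#' @param selection_coefficient Either a single s > 0 against deleterious
#'   nonsynonymous mutations, or `list(type = "gamma", shape =, scale =)`
#'   for a per-gene gamma-distributed s.
#' @param true_relatedness r in (0, 1] applied to cooperative genes.
#' @param fraction_sites_nonsynonymous Expected fraction of coding changes
#'   that are nonsynonymous (~0.75 for random coding sequence); the
#'   simulator determines each mutation's consequence codon-exactly and
#'   this value documents the expectation used in validation checks.
#' @param burn_in_generations Generations simulated before sampling
#'   (default 10 * N, enough to reach mutation-selection-drift
#'   quasi-equilibrium from a monomorphic start).
#' @param outgroup_expected_Ks Expected synonymous substitutions per
#'   synonymous site on the outgroup branch.
#' @param outgroup_omega Baseline Ka/Ks ratio on the outgroup branch for
#'   non-cooperative genes.
#' @param outgroup_omega_asymmetry If TRUE (default) cooperative genes use
#'   `outgroup_omega / r` on the outgroup branch, so the divergence
#'   contrast predicted under relaxed selection is present in fixtures.
#' @param missingness_rate Per-genotype missing probability (MCAR) applied
#'   when fixtures are written.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(population_size = 1000,
                              sample_size = 31,
                              num_genes_per_class = c(cooperative = 25,
                                                      private = 50,
                                                      background = 50),
                              gene_length_bp = 900,
                              per_site_mutation_rate = 5e-6,
                              selection_coefficient = 0.01,
                              true_relatedness = 1,
                              fraction_sites_nonsynonymous = 0.75,
                              burn_in_generations = 10 * population_size,
                              outgroup_expected_Ks = 0.3,
                              outgroup_omega = 0.2,
                              outgroup_omega_asymmetry = TRUE,
                              missingness_rate = 0.05,
                              seed = 1L) {
  N <- as.integer(population_size)
  n <- as.integer(sample_size)
  L <- as.integer(gene_length_bp)
  u <- per_site_mutation_rate
  r <- true_relatedness
  if (n > N) stopf("sample_size (%d) must not exceed population_size (%d)", n, N)
  if (!(r > 0 && r <= 1)) stopf("true_relatedness must lie in (0, 1], got %g", r)
  if (L %% 3L != 0L) stopf("gene_length_bp must be divisible by 3, got %d", L)
  for (nm in c("per_site_mutation_rate", "missingness_rate",
               "fraction_sites_nonsynonymous")) {
    v <- get(nm)
    if (!(v >= 0 && v <= 1)) stopf("%s must lie in [0, 1], got %g", nm, v)
  }
  classes <- c("cooperative", "private", "background")
  ng <- num_genes_per_class
  if (is.null(names(ng)) || !all(classes %in% names(ng))) {
    stopf("num_genes_per_class must be named with %s",
          paste(classes, collapse = ", "))
  }
  ng <- as.integer(ng[classes])
  names(ng) <- classes
  if (any(ng < 0) || sum(ng) < 1) stopf("need at least one gene")
  s <- selection_coefficient
  if (is.numeric(s)) {
    if (length(s) != 1 || s < 0) stopf("selection_coefficient must be a single s >= 0")
  } else if (is.list(s)) {
    if (!identical(s$type, "gamma") || is.null(s$shape) || is.null(s$scale))
      stopf("distributional selection_coefficient must be list(type='gamma', shape=, scale=)")
  } else stopf("invalid selection_coefficient")
  ## mutation-pressure guard: more than half the sites expected to
  ## segregate breaks the infinite-sites approximation
  a_N <- sum(1 / seq_len(N - 1))
  if (2 * N * u * a_N > 0.5) {
    stopf("u*L*N too large: expected segregating fraction %.2f per site exceeds 0.5",
          2 * N * u * a_N)
  }
  structure(
    list(population_size = N, sample_size = n,
         num_genes_per_class = ng, gene_length_bp = L,
         per_site_mutation_rate = u, selection_coefficient = s,
         true_relatedness = r,
         fraction_sites_nonsynonymous = fraction_sites_nonsynonymous,
         burn_in_generations = as.integer(burn_in_generations),
         outgroup_expected_Ks = outgroup_expected_Ks,
         outgroup_omega = outgroup_omega,
         outgroup_omega_asymmetry = isTRUE(outgroup_omega_asymmetry),
         missingness_rate = missingness_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> N=%d n=%d genes=%s L=%d u=%g ",
                     "s=%s r=%g burn-in=%d seed=%d\n"),
              x$population_size, x$sample_size,
              paste(x$num_genes_per_class, collapse = "/"),
              x$gene_length_bp, x$per_site_mutation_rate,
              if (is.numeric(x$selection_coefficient))
                format(x$selection_coefficient) else "gamma",
              x$true_relatedness, x$burn_in_generations, x$seed))
  invisible(x)
}

## draw per-gene selection coefficients from the configured distribution
draw_selection_coefficients <- function(config, n_genes) {
  s <- config$selection_coefficient
  if (is.numeric(s)) rep(s, n_genes)
  else stats::rgamma(n_genes, shape = s$shape, scale = s$scale)
}
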