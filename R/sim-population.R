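## ---- codon-aware mutation consequence tables ------------------------------

## For each reference base, the 3 alternative bases in alphabetical order.
alt_base_table <- function() {
  tab <- .kinsig_env$alt_tab
  if (is.null(tab)) {
    tab <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
    rownames(tab) <- BASES
    .kinsig_env$alt_tab <- tab
  }
  tab
}

## For each of the 64 codons: 3x3 logical matrix, [position within codon,
## alternative index] -> is the single-base change nonsynonymous?
codon_consequence_table <- function() {
  tab <- .kinsig_env$cons_tab
  if (is.null(tab)) {
    codons <- names(genetic_code_11())
    alt_tab <- alt_base_table()
    tab <- lapply(codons, function(cd) {
      b <- seq_chars(cd)
      m <- matrix(NA, 3, 3)
      for (p in 1:3) {
        alts <- alt_tab[b[p], ]
        for (j in 1:3) m[p, j] <- change_is_nonsyn(cd, p, alts[j])
      }
      m
    })
    names(tab) <- codons
    .kinsig_env$cons_tab <- tab
  }
  tab
}

## Build the L x 3 alt-base-code and nonsynonymous-consequence matrices for a
## reference CDS. Base codes are 0..3 = A,C,G,T (alternatives in
## alphabetical order). Consequences are evaluated on the reference codon,
## the same rule the downstream per-SNP classifier applies.
consequence_matrices <- function(ref_chars) {
  L <- length(ref_chars)
  stopifnot(L %% 3 == 0)
  codons <- vapply(seq_len(L / 3), function(i)
    chars_seq(ref_chars[codon_positions(i)]), character(1))
  cons <- codon_consequence_table()
  nonsyn <- matrix(FALSE, L, 3)
  for (i in seq_along(codons)) {
    nonsyn[codon_positions(i), ] <- cons[[codons[i]]]
  }
  alt_tab <- alt_base_table()
  alt_chars <- alt_tab[ref_chars, , drop = FALSE]
  alt_code <- matrix(match(alt_chars, BASES) - 1L, L, 3)
  list(alt_code = alt_code, nonsyn = nonsyn,
       alt_chars = alt_chars)
}

## random coding sequence: non-stop codons plus a terminal TAA stop
random_cds <- function(n_codons) {
  gc <- genetic_code_11()
  pool <- names(gc)[gc != "*"]
  body <- sample(pool, n_codons - 1L, replace = TRUE)
  seq_chars(paste(c(body, "TAA"), collapse = ""))
}

## ---- forward simulation ----------------------------------------------------

#' Simulate a cohort of genes under relaxed purifying selection
#'
#' Runs an independent haploid Wright-Fisher forward simulation for every
#' gene (free recombination between genes, full linkage within a gene):
#' multiplicative fitness across sites, infinite-sites mutation within the
#' gene, and purifying selection with coefficient `s_eff` against every
#' nonsynonymous mutation, where `s_eff = r * s` for cooperative genes and
#' `s` otherwise. Each mutation's consequence is determined codon-exactly
#' from the reference codon and the drawn alternative base under
#' translation table 11, so downstream codon-aware classification agrees
#' with the simulation truth. After `burn_in_generations` the configured
#' number of strains is sampled without replacement.
#'
#' @param config A [simulation_config()].
#' @return A list of class `kinsig_simulation` with elements:
#'   `alignments` (named list of [haplotype_alignment()]), `truth`
#'   (per-gene data frame: class, s, s_eff, true r, realized sample
#'   segregating sites `S_sample`, variant rows vs reference
#'   `n_variant_rows`), `mutations` (per-mutation truth: gene, CDS site,
#'   ref/alt base, consequence, sample count), `reference` (named vector
#'   of reference CDS strings) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$num_genes_per_class
  classes <- rep(names(ng), ng)
  n_genes <- length(classes)
  ids <- sprintf("gene_%04d", seq_len(n_genes))
  strains <- sprintf("strain_%02d", seq_len(config$sample_size))

  s_vec <- draw_selection_coefficients(config, n_genes)
  s_eff <- ifelse(classes == "cooperative",
                  config$true_relatedness * s_vec, s_vec)

  L <- config$gene_length_bp
  alignments <- vector("list", n_genes)
  refs <- character(n_genes)
  truth <- vector("list", n_genes)
  muts <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    ref_chars <- random_cds(L / 3L)
    cm <- consequence_matrices(ref_chars)
    res <- .wf_sim_gene(config$population_size, config$sample_size, L,
                        config$per_site_mutation_rate, s_eff[g],
                        cm$alt_code, cm$nonsyn,
                        config$burn_in_generations,
                        floor(runif(8) * 2^32))

    mat <- matrix(rep(ref_chars, each = config$sample_size),
                  nrow = config$sample_size)
    ## population-fixed substitutions: carried by every sampled strain
    if (length(res$fixed_sites) > 0) {
      for (i in seq_along(res$fixed_sites)) {
        mat[, res$fixed_sites[i]] <- BASES[res$fixed_alt[i] + 1L]
      }
    }
    k <- length(res$sites)
    counts <- integer(k)
    if (k > 0) {
      for (c in seq_len(k)) {
        carriers <- res$genotypes[, c] == 1L
        counts[c] <- sum(carriers)
        if (counts[c] > 0) {
          mat[carriers, res$sites[c]] <- BASES[res$alt[c] + 1L]
        }
      }
    }

    ## truth labels recomputed from the consequence table (covers the
    ## neutral case, where fitness flags are all FALSE by construction)
    lab_nonsyn <- function(sites, alts) {
      if (length(sites) == 0) return(logical(0))
      vapply(seq_along(sites), function(i) {
        j <- match(BASES[alts[i] + 1L], cm$alt_chars[sites[i], ])
        cm$nonsyn[sites[i], j]
      }, logical(1))
    }
    seg <- counts > 0 & counts < config$sample_size
    sample_fixed <- counts == config$sample_size
    S_sample <- sum(seg)
    n_variant_rows <- sum(counts > 0) + length(res$fixed_sites)

    gm <- NULL
    if (k > 0 && any(counts > 0)) {
      keep <- counts > 0
      gm <- data.frame(
        gene_id = ids[g],
        site = res$sites[keep],
        ref = ref_chars[res$sites[keep]],
        alt = BASES[res$alt[keep] + 1L],
        is_nonsyn = lab_nonsyn(res$sites[keep], res$alt[keep]),
        sample_count = counts[keep],
        fixed_in_population = FALSE,
        stringsAsFactors = FALSE)
    }
    if (length(res$fixed_sites) > 0) {
      fm <- data.frame(
        gene_id = ids[g],
        site = res$fixed_sites,
        ref = ref_chars[res$fixed_sites],
        alt = BASES[res$fixed_alt + 1L],
        is_nonsyn = lab_nonsyn(res$fixed_sites, res$fixed_alt),
        sample_count = config$sample_size,
        fixed_in_population = TRUE,
        stringsAsFactors = FALSE)
      gm <- rbind(gm, fm)
    }
    muts[[g]] <- gm

    refs[g] <- chars_seq(ref_chars)
    alignments[[g]] <- haplotype_alignment(
      ids[g], strains, mat, reference = refs[g])
    truth[[g]] <- data.frame(
      gene_id = ids[g], class = classes[g], s = s_vec[g],
      s_eff = s_eff[g], true_r = config$true_relatedness,
      S_sample = S_sample, n_variant_rows = n_variant_rows,
      n_sample_fixed = sum(sample_fixed),
      n_population_fixed = length(res$fixed_sites),
      stringsAsFactors = FALSE)
  }

  names(alignments) <- ids
  names(refs) <- ids
  structure(
    list(alignments = alignments,
         truth = do.call(rbind, truth),
         mutations = do.call(rbind, muts),
         reference = refs,
         config = config),
    class = "kinsig_simulation")
}

#' @export
print.kinsig_simulation <- function(x, ...) {
  cat(sprintf("<kinsig_simulation> %d genes (%s), n=%d strains, seed=%d\n",
              nrow(x$truth),
              paste(names(x$config$num_genes_per_class),
                    x$config$num_genes_per_class,
                    sep = "=", collapse = ", "),
              x$config$sample_size, x$config$seed))
  invisible(x)
}
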