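#' Compute the full per-gene statistic vector
#'
#' Assembles the complete battery for one gene: segregating sites and
#' singletons, pi at all/nonsynonymous/synonymous sites (each scaled by
#' the relevant effective site count, i.e. the NG86 fractional site
#' totals shrunk by the gene's mapped fraction), Tajima's D, Fu & Li's
#' D*/F* (and polarized D/F when an outgroup is present), the
#' McDonald-Kreitman table with Fisher p, neutrality index and direction
#' of selection, and NG86 Ka/Ks of the reference against the outgroup.
#' Undefined statistics are `NA` (flagged missing), never silently 0.
#'
#' @param aln A [haplotype_alignment()] (outgroup row optional).
#' @param gene Optional `gene_models` row supplying `category`,
#'   `trait_group` and `operon_id` annotations.
#' @return One-row data frame of class `gene_stats`.
#' @export
compute_gene_stats <- function(aln, gene = NULL) {
  ss <- if (aln_n(aln) >= 2) site_summary(aln) else NULL
  nd <- nucleotide_diversity(aln, .ss = ss)
  L <- aln_len(aln)
  mf <- aln$effective_length / L

  pi_N <- pi_S <- NA_real_
  syn_sites <- nonsyn_sites <- NA_real_
  if (!is.null(aln$reference) && L %% 3 == 0) {
    sp <- pi_raw_split(aln, .ss = ss)
    syn_sites <- sp$cls$syn_sites
    nonsyn_sites <- sp$cls$nonsyn_sites
    pi_N <- safe_div(sp$pi_raw_N, nonsyn_sites * mf)
    pi_S <- safe_div(sp$pi_raw_S, syn_sites * mf)
  }

  D <- if (!is.na(nd$S) && nd$S >= 1) tajimas_d(nd$S, nd$pi_raw, nd$n)
       else NA_real_
  fl <- if (!is.na(nd$S) && nd$S >= 1) fu_li_statistics(aln, .ss = ss)
        else list(D_star = NA_real_, F_star = NA_real_, D = NA_real_,
                  F = NA_real_)

  mk <- list(Pn = NA_real_, Ps = NA_real_, Dn = NA_real_, Ds = NA_real_,
             fisher_p = NA_real_, NI = NA_real_, DoS = NA_real_)
  kk <- list(Ka = NA_real_, Ks = NA_real_, ratio = NA_real_)
  if (!is.null(aln$outgroup) && !is.null(aln$reference) && L %% 3 == 0) {
    mk <- mcdonald_kreitman(aln, .ss = ss)
    kk <- ka_ks(aln$reference, aln$outgroup)
  }

  out <- data.frame(
    gene_id = aln$gene_id,
    n_samples = nd$n,
    effective_length = aln$effective_length,
    S = nd$S, eta_s = nd$eta_s,
    pi = nd$pi, pi_N = pi_N, pi_S = pi_S,
    pi_N_over_pi_S = safe_div(pi_N, pi_S),
    tajimas_D = D,
    fu_li_D_star = fl$D_star, fu_li_F_star = fl$F_star,
    fu_li_D = fl$D, fu_li_F = fl$F,
    Pn = mk$Pn, Ps = mk$Ps, Dn = mk$Dn, Ds = mk$Ds,
    mk_p = mk$fisher_p, NI = mk$NI, DoS = mk$DoS,
    Ka = kk$Ka, Ks = kk$Ks, Ka_over_Ks = kk$ratio,
    stringsAsFactors = FALSE)
  out$category <- if (!is.null(gene)) gene$category else NA_character_
  out$trait_group <- if (!is.null(gene)) gene$trait_group else NA_character_
  out$operon_id <- if (!is.null(gene)) gene$operon_id else NA_character_
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Compute gene statistics for a whole cohort
#'
#' @param alignments Named list of [haplotype_alignment()] objects.
#' @param genes Optional `gene_models` data frame (matched by `gene_id`)
#'   supplying annotations.
#' @param outgroups Optional named character vector of outgroup CDS
#'   sequences attached before computing (outgroup-dependent statistics
#'   are skipped for genes without one).
#' @return A `gene_stats` data frame with one row per gene.
#' @export
compute_gene_stats_table <- function(alignments, genes = NULL,
                                     outgroups = NULL) {
  rows <- lapply(alignments, function(aln) {
    if (!is.null(outgroups) && aln$gene_id %in% names(outgroups)) {
      aln <- add_outgroup(aln, outgroups[[aln$gene_id]])
    }
    g <- NULL
    if (!is.null(genes)) {
      hit <- which(genes$gene_id == aln$gene_id)
      if (length(hit) == 1) g <- genes[hit, ]
    }
    compute_gene_stats(aln, gene = g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_stats", "data.frame")
  out
}
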