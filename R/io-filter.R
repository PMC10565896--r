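#' Filter variant records for the population-genetic analysis
#'
#' Applies the two quality rules used throughout: sites must have been
#' called in at least `min_call_rate` of strains (ties at the threshold
#' are retained, reading "at least" inclusively), and indels are excluded
#' from all population-genetic statistics but kept in a side channel for
#' deleterious-mutation annotation. The filter is idempotent.
#'
#' @param records A `variant_records` data frame from [read_vcf()].
#' @param min_call_rate Minimum fraction of called strains (default 0.8).
#' @param drop_indels Route indels to the side channel (default TRUE; the
#'   popgen statistics require it).
#' @return List with `snps` (filtered SNP records) and `indels` (all
#'   indel records, not call-rate filtered).
#' @export
filter_variants <- function(records, min_call_rate = 0.8,
                            drop_indels = TRUE) {
  if (is.list(records) && !is.data.frame(records) &&
      all(c("snps", "indels") %in% names(records))) {
    ## already-filtered input: re-filtering is a no-op on the SNP set
    indels <- records$indels
    records <- records$snps
  } else {
    indels <- NULL
  }
  if (!drop_indels) {
    stopf("drop_indels = FALSE is not supported: indels are excluded from all popgen statistics by contract")
  }
  is_snp <- records$variant_class == "SNP"
  snps <- records[is_snp & records$call_rate >= min_call_rate, , drop = FALSE]
  new_indels <- records[!is_snp, , drop = FALSE]
  if (!is.null(indels) && nrow(indels) > 0) {
    new_indels <- if (nrow(new_indels) > 0) rbind(indels, new_indels) else indels
  }
  list(snps = snps, indels = new_indels)
}

#' Filter gene models by mapped length and polymorphism data
#'
#' Keeps genes whose mapped fraction is at least `min_mapped_fraction`
#' (ties retained) and, when `require_polymorphism_data` is TRUE and
#' variants are supplied, that contain at least one retained SNP.
#' Downstream per-site statistics divide by the effective (mapped)
#' length, not the annotated length.
#'
#' @param genes A `gene_models` data frame.
#' @param min_mapped_fraction Minimum mapped fraction (default 0.5).
#' @param require_polymorphism_data Drop genes without any SNP.
#' @param variants Optional filtered SNP records used for the
#'   polymorphism-data requirement.
#' @return The surviving `gene_models` rows.
#' @export
filter_genes <- function(genes, min_mapped_fraction = 0.5,
                         require_polymorphism_data = TRUE,
                         variants = NULL) {
  keep <- genes$mapped_fraction >= min_mapped_fraction
  if (require_polymorphism_data && !is.null(variants)) {
    has_poly <- vapply(seq_len(nrow(genes)), function(g) {
      any(variants$contig == genes$contig[g] &
            variants$pos >= genes$start[g] &
            variants$pos <= genes$end[g])
    }, logical(1))
    keep <- keep & has_poly
  }
  genes[keep, , drop = FALSE]
}
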