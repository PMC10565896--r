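#' Annotate deleterious (stop-gain and frameshift) variants per gene
#'
#' First-principles annotation of the two loss-of-function categories:
#' a stop-gain is a SNP whose alt codon is a stop (TAA/TAG/TGA under
#' table 11, strand-aware) while the reference codon is not, excluding
#' the annotated terminal stop codon; a frameshift is an indel anchored
#' inside a CDS whose length change is not a multiple of 3. A variant
#' whose anchor lies in a gene but which spans past its boundary is
#' counted by the anchoring gene with a warning.
#'
#' @param variants Either a `variant_records` data frame containing SNPs
#'   and indels, or the list returned by [filter_variants()] (its `snps`
#'   and `indels` are combined).
#' @param genes A `gene_models` data frame.
#' @param reference Named character vector of contig sequences.
#' @return Data frame with one row per gene: `gene_id`, `category`,
#'   `stop_gain_count`, `frameshift_count`, `deleterious_count` (their
#'   sum) and `has_deleterious`.
#' @export
annotate_deleterious <- function(variants, genes, reference) {
  if (is.list(variants) && !is.data.frame(variants) &&
      all(c("snps", "indels") %in% names(variants))) {
    v <- variants
    variants <- v$snps
    if (!is.null(v$indels) && nrow(v$indels) > 0) {
      variants <- rbind(variants, v$indels)
    }
  }
  stop_gain <- integer(nrow(genes))
  frameshift <- integer(nrow(genes))

  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    inside <- variants$contig == gene$contig &
      variants$pos >= gene$start & variants$pos <= gene$end
    vv <- variants[inside, , drop = FALSE]
    if (nrow(vv) == 0) next
    width <- gene$end - gene$start + 1L
    cds <- substr(reference[[gene$contig]], gene$start, gene$end)
    if (gene$strand == "-") cds <- revcomp(cds)
    n_codons <- width %/% 3L

    for (i in seq_len(nrow(vv))) {
      if (vv$variant_class[i] == "SNP") {
        carried <- any(vv$calls[i, ] == 1L, na.rm = TRUE)
        if (!carried) next
        site <- if (gene$strand == "+") vv$pos[i] - gene$start + 1L
                else gene$end - vv$pos[i] + 1L
        alt_cds <- if (gene$strand == "+") vv$alt[i]
                   else unname(comp_base(vv$alt[i]))
        ci <- codon_of(site)
        if (ci == n_codons) next   # annotated terminal stop codon
        codon <- substr(cds, 3 * ci - 2, 3 * ci)
        altc <- codon
        p <- site - 3L * (ci - 1L)
        substr(altc, p, p) <- alt_cds
        if (!is_stop_codon(codon) && is_stop_codon(altc)) {
          stop_gain[g] <- stop_gain[g] + 1L
        }
      } else {
        span_end <- vv$pos[i] + nchar(vv$ref[i]) - 1L
        if (span_end > gene$end) {
          warnf("indel at %s:%d spans past gene %s; counted by anchor gene",
                vv$contig[i], vv$pos[i], gene$gene_id)
        }
        shift <- abs(nchar(vv$ref[i]) - nchar(vv$alt[i]))
        if (shift %% 3L != 0L) frameshift[g] <- frameshift[g] + 1L
      }
    }
  }
  data.frame(gene_id = genes$gene_id, category = genes$category,
             stop_gain_count = stop_gain, frameshift_count = frameshift,
             deleterious_count = stop_gain + frameshift,
             has_deleterious = (stop_gain + frameshift) > 0,
             stringsAsFactors = FALSE)
}
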