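#' Build a per-gene haplotype alignment from reference plus SNPs
#'
#' Realizes each strain's gene sequence by substituting its alt alleles
#' into the reference slice, mirroring the pseudogenome logic. A missing
#' call leaves `NA` at that site for that strain, which excludes the site
#' from pairwise comparisons involving the strain (pairwise deletion).
#' Minus-strand genes are reverse-complemented so the returned matrix is
#' in CDS orientation.
#'
#' @param gene One row of a `gene_models` data frame.
#' @param variants Filtered SNP `variant_records`.
#' @param reference Named character vector of contig sequences.
#' @param strains Strain ids (defaults to the VCF sample columns).
#' @return A [haplotype_alignment()]; its effective length is the mapped
#'   fraction of the gene width, rounded to the nearest base.
#' @export
build_alignment <- function(gene, variants, reference, strains = NULL) {
  if (!gene$contig %in% names(reference)) {
    stopf("contig %s not in reference", gene$contig)
  }
  if (is.null(strains)) strains <- colnames(variants$calls)
  slice <- substr(reference[[gene$contig]], gene$start, gene$end)
  width <- gene$end - gene$start + 1L
  ref_chars <- seq_chars(slice)
  n <- length(strains)
  mat <- matrix(rep(ref_chars, each = n), nrow = n)

  inside <- variants$contig == gene$contig &
    variants$pos >= gene$start & variants$pos <= gene$end
  vv <- variants[inside, , drop = FALSE]
  for (i in seq_len(nrow(vv))) {
    col <- vv$pos[i] - gene$start + 1L
    if (ref_chars[col] != vv$ref[i]) {
      stopf("variant at %s:%d has REF %s but reference base is %s",
            vv$contig[i], vv$pos[i], vv$ref[i], ref_chars[col])
    }
    calls <- vv$calls[i, strains]
    mat[which(calls == 1L), col] <- vv$alt[i]
    mat[which(is.na(calls)), col] <- NA_character_
  }

  ref_cds <- slice
  if (gene$strand == "-") {
    mat <- matrix(comp_base(mat)[seq_along(mat)], nrow = n)[, width:1,
                                                           drop = FALSE]
    ref_cds <- revcomp(slice)
  }
  haplotype_alignment(
    gene$gene_id, strains, mat, reference = ref_cds,
    effective_length = as.integer(round(gene$mapped_fraction * width)))
}

#' Attach an outgroup sequence to an alignment
#'
#' @param aln A [haplotype_alignment()].
#' @param outgroup_seq Outgroup CDS sequence (same length and orientation).
#' @return The alignment with the outgroup row set.
#' @export
add_outgroup <- function(aln, outgroup_seq) {
  haplotype_alignment(aln$gene_id, aln$strains, aln$mat,
                      reference = aln$reference, outgroup = outgroup_seq,
                      effective_length = aln$effective_length)
}

## CDS-oriented outgroup slice for a gene from a pseudogenome
outgroup_slice <- function(gene, pseudogenome) {
  s <- substr(pseudogenome[[gene$contig]], gene$start, gene$end)
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Build an outgroup pseudogenome by substituting outgroup SNP alleles
#'
#' Returns the reference with every outgroup SNP allele substituted in;
#' the sequence length is preserved, so indels in the outgroup VCF are
#' skipped with a warning.
#'
#' @param reference Named character vector of contig sequences.
#' @param outgroup_variants `variant_records` for the outgroup (single
#'   pseudo-sample; any record whose call is 1 is substituted).
#' @return Named character vector of pseudogenome contigs.
#' @export
build_outgroup_pseudogenome <- function(reference, outgroup_variants) {
  out <- reference
  v <- outgroup_variants
  indels <- v$variant_class != "SNP"
  if (any(indels)) {
    warnf("skipping %d indel(s) in outgroup VCF (length preservation)",
          sum(indels))
    v <- v[!indels, , drop = FALSE]
  }
  for (i in seq_len(nrow(v))) {
    if (!v$contig[i] %in% names(out)) {
      stopf("outgroup variant on unknown contig %s", v$contig[i])
    }
    carried <- any(v$calls[i, ] == 1L, na.rm = TRUE)
    if (!carried) next
    if (substr(out[[v$contig[i]]], v$pos[i], v$pos[i]) != v$ref[i] &&
        substr(reference[[v$contig[i]]], v$pos[i], v$pos[i]) != v$ref[i]) {
      stopf("outgroup variant at %s:%d disagrees with reference base",
            v$contig[i], v$pos[i])
    }
    substr(out[[v$contig[i]]], v$pos[i], v$pos[i]) <- v$alt[i]
  }
  out
}
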