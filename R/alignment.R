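#' Construct a per-gene haplotype alignment
#'
#' A haplotype alignment holds the sampled strain sequences for one gene in
#' CDS orientation (minus-strand genes are reverse-complemented so codon
#' position 1 is column 1), as a character matrix with one row per strain.
#' `NA` cells mark genotypes that were not called; they are excluded from
#' pairwise comparisons site by site (pairwise deletion). An optional
#' outgroup row is carried separately and never counts toward the sample
#' size.
#'
#' @param gene_id Gene identifier.
#' @param strains Character vector of strain ids (row order of `mat`).
#' @param mat Character matrix (strains x positions) of bases, `NA` missing.
#' @param reference Reference CDS for the gene (character scalar), used for
#'   codon-aware site classification.
#' @param outgroup Optional outgroup CDS sequence (character scalar, same
#'   length and orientation).
#' @param effective_length Number of positions that pass the mapping filter;
#'   per-site statistics divide by this, not the annotated length.
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(gene_id, strains, mat, reference = NULL,
                                outgroup = NULL,
                                effective_length = ncol(mat)) {
  stopifnot(is.matrix(mat), nrow(mat) == length(strains))
  if (effective_length > ncol(mat)) {
    stopf("effective_length (%d) exceeds gene length (%d)",
          effective_length, ncol(mat))
  }
  if (!is.null(outgroup) && nchar(outgroup) != ncol(mat)) {
    stopf("outgroup row length (%d) differs from alignment (%d)",
          nchar(outgroup), ncol(mat))
  }
  rownames(mat) <- strains
  structure(
    list(gene_id = gene_id, strains = strains, mat = mat,
         reference = reference, outgroup = outgroup,
         effective_length = as.integer(effective_length)),
    class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("<haplotype_alignment> %s: %d strains x %d bp%s, eff. length %d\n",
              x$gene_id, nrow(x$mat), ncol(x$mat),
              if (is.null(x$outgroup)) "" else " (+outgroup)",
              x$effective_length))
  invisible(x)
}

#' @export
dim.haplotype_alignment <- function(x) dim(x$mat)

## number of sampled strains (outgroup excluded by construction)
aln_n <- function(aln) nrow(aln$mat)

aln_len <- function(aln) ncol(aln$mat)
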