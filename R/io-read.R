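#' Read a haploid multi-strain VCF into variant records
#'
#' Ingests a VCF v4.2 with haploid GT calls ("." for missing) via vcfR and
#' returns one record per contig/position/alt-allele, with multi-allelic
#' rows decomposed into per-alt records (strains carrying a different alt
#' are treated as reference for that record). SNPs and indels are
#' classified from allele lengths.
#'
#' @param path Path to a VCF file.
#' @return A data frame of class `variant_records`: `contig`, `pos`,
#'   `ref`, `alt`, `variant_class` (SNP/insertion/deletion), `call_rate`,
#'   and a `calls` matrix column (records x strains; 1 = alt, 0 = ref,
#'   NA = missing).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    return(empty_variant_records(colnames(v@gt)[-1] %||% character(0)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  strains <- colnames(gt)
  recs <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    g <- gt[i, ]
    for (k in seq_along(alts)) {
      calls <- ifelse(is.na(g) | g == ".", NA_integer_,
                      ifelse(g == as.character(k), 1L, 0L))
      ref <- fix[i, "REF"]
      alt <- alts[k]
      vclass <- if (nchar(ref) == 1 && nchar(alt) == 1) "SNP"
                else if (nchar(alt) > nchar(ref)) "insertion"
                else "deletion"
      recs[[length(recs) + 1L]] <- list(
        contig = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alt, vclass = vclass, calls = calls)
    }
  }
  df <- data.frame(
    contig = vapply(recs, `[[`, character(1), "contig"),
    pos = vapply(recs, `[[`, integer(1), "pos"),
    ref = vapply(recs, `[[`, character(1), "ref"),
    alt = vapply(recs, `[[`, character(1), "alt"),
    variant_class = vapply(recs, `[[`, character(1), "vclass"),
    stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(recs, `[[`, "calls"))
  colnames(calls) <- strains
  df$call_rate <- rowMeans(!is.na(calls))
  df$calls <- calls
  class(df) <- c("variant_records", "data.frame")
  df
}

empty_variant_records <- function(strains = character(0)) {
  df <- data.frame(contig = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   variant_class = character(0), call_rate = numeric(0),
                   stringsAsFactors = FALSE)
  df$calls <- matrix(integer(0), nrow = 0, ncol = length(strains),
                     dimnames = list(NULL, strains))
  class(df) <- c("variant_records", "data.frame")
  df
}

#' Read gene models from a GFF3 file
#'
#' Parses CDS features via `ape::read.gff` and extracts the attributes the
#' pipeline uses: `ID`, the custom `sociality` category
#' (cooperative/private/background; anything else becomes
#' `uncategorized`), optional `trait_group` and `operon_id`, and
#' `mapped_fraction` (fraction of the gene length covered by mapping;
#' defaults to 1 when absent).
#'
#' @param path Path to a GFF3 file.
#' @param contigs Optional character vector of known contig names; a gene
#'   on an unknown contig raises an error naming it.
#' @return A data frame of class `gene_models` with columns `gene_id`,
#'   `contig`, `start`, `end`, `strand`, `category`, `trait_group`,
#'   `operon_id`, `mapped_fraction`.
#' @export
read_gff <- function(path, contigs = NULL) {
  if (!file.exists(path)) stopf("GFF3 not found: %s", path)
  gff <- ape::read.gff(path, GFF3 = TRUE)
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(sprintf("(^|;)%s=[^;]*", key), attrs))
    out <- rep(NA_character_, length(attrs))
    hit <- lengths(regmatches(attrs, gregexpr(sprintf("(^|;)%s=", key), attrs))) > 0
    out[hit] <- sub(sprintf("^;?%s=", key), "", m)
    out
  }
  cat_raw <- attr_field(gff$attributes, "sociality")
  category <- ifelse(cat_raw %in% c("cooperative", "private", "background"),
                     cat_raw, "uncategorized")
  mf <- suppressWarnings(as.numeric(attr_field(gff$attributes,
                                               "mapped_fraction")))
  mf[is.na(mf)] <- 1
  genes <- data.frame(
    gene_id = attr_field(gff$attributes, "ID"),
    contig = as.character(gff$seqid),
    start = gff$start, end = gff$end,
    strand = as.character(gff$strand),
    category = category,
    trait_group = attr_field(gff$attributes, "trait_group"),
    operon_id = attr_field(gff$attributes, "operon_id"),
    mapped_fraction = mf,
    stringsAsFactors = FALSE)
  if (any(is.na(genes$gene_id))) stopf("GFF3 CDS feature without ID attribute")
  if (any(genes$start > genes$end)) stopf("GFF3 feature with start > end")
  if (any(genes$mapped_fraction < 0 | genes$mapped_fraction > 1)) {
    stopf("mapped_fraction outside [0, 1]")
  }
  if (!is.null(contigs)) {
    unknown <- setdiff(unique(genes$contig), contigs)
    if (length(unknown) > 0) {
      stopf("GFF3 references unknown contig(s): %s",
            paste(unknown, collapse = ", "))
    }
  }
  class(genes) <- c("gene_models", "data.frame")
  genes
}

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per contig (names truncated
#'   at the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
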