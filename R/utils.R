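#' @useDynLib kinsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median pbinom pchisq pf pnorm pt ptukey qnorm quantile
#'   rbinom rnorm rpois runif setNames var sd cor fisher.test kruskal.test
#'   oneway.test chisq.test complete.cases
#' @importFrom utils write.table read.table head combn
NULL

.kinsig_env <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' Bacterial genetic code (translation table 11)
#'
#' Named character vector mapping the 64 codons to one-letter amino acids
#' ("*" for stop), as used for all codon-aware computations in the package.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code_11 <- function() {
  gc <- .kinsig_env$gc11
  if (is.null(gc)) {
    gc <- Biostrings::getGeneticCode("11")
    .kinsig_env$gc11 <- gc
  }
  gc
}

#' Translate a codon (or vector of codons) under table 11
#' @param codon Character vector of 3-base strings.
#' @return Character vector of amino acids ("*" = stop).
#' @export
translate_codon <- function(codon) {
  unname(genetic_code_11()[toupper(codon)])
}

#' Reverse complement of nucleotide strings
#' @param x Character vector of DNA strings.
#' @return Character vector, reverse-complemented.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

## split a sequence string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## paste a character vector of bases back into one string
chars_seq <- function(x) paste(x, collapse = "")

## codon index (1-based) for a CDS position
codon_of <- function(pos) (pos - 1L) %/% 3L + 1L

## positions (1-based) covered by codon i
codon_positions <- function(i) (3L * (i - 1L) + 1L):(3L * i)

is_stop_codon <- function(codon) translate_codon(codon) == "*"

## consequence of a single-base change within a codon context:
## TRUE = nonsynonymous (amino acid differs, stop gains/losses included)
change_is_nonsyn <- function(ref_codon, pos_in_codon, alt_base) {
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_base
  translate_codon(alt_codon) != translate_codon(ref_codon)
}

## NG86 fractional synonymous site count for one codon:
## sum over the 3 positions of (#synonymous single-base changes)/3.
## Codons containing ambiguous bases return NA.
ng86_syn_sites_codon <- function(codon) {
  b <- seq_chars(codon)
  if (!all(b %in% BASES)) return(NA_real_)
  syn <- 0
  for (p in 1:3) {
    for (alt in setdiff(BASES, b[p])) {
      if (!change_is_nonsyn(codon, p, alt)) syn <- syn + 1 / 3
    }
  }
  syn
}

## memoized per-codon NG86 synonymous site table over all 64 codons
ng86_site_table <- function() {
  tab <- .kinsig_env$ng86_tab
  if (is.null(tab)) {
    codons <- names(genetic_code_11())
    tab <- vapply(codons, ng86_syn_sites_codon, numeric(1))
    .kinsig_env$ng86_tab <- tab
  }
  tab
}

## flagged-missing representation: statistics that are undefined are NA with
## an attribute-free convention (plain NA_real_); helpers to guard divisions
safe_div <- function(num, den) {
  ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
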