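## per-site allele counts: L x 4 matrix of counts of A,C,G,T among called
## strains (outgroup excluded by construction)
site_base_counts <- function(aln) {
  m <- aln$mat
  cnt <- vapply(BASES, function(b) {
    colSums(!is.na(m) & m == b)
  }, numeric(ncol(m)))
  colnames(cnt) <- BASES
  cnt
}

## summary of the site-frequency structure used by several statistics
site_summary <- function(aln) {
  cnt <- site_base_counts(aln)
  m <- rowSums(cnt)
  sq <- rowSums(cnt^2)
  pairs <- m * (m - 1) / 2
  h <- ifelse(pairs > 0, (m^2 - sq) / 2 / pairs, 0)
  k <- rowSums(cnt > 0)
  maxc <- apply(cnt, 1, max)
  singles <- rowSums(cnt == 1) - (maxc == 1)
  list(counts = cnt, called = m, het = h,
       segregating = k >= 2,
       eta = sum(pmax(k - 1, 0)),
       eta_s = sum(ifelse(k >= 2, singles, 0)),
       S = sum(k >= 2))
}

#' Per-gene nucleotide diversity
#'
#' Computes pi as the average number of pairwise nucleotide differences,
#' site by site with pairwise deletion (each site is averaged over the
#' pairs of strains called there), and scales the per-site value by the
#' effective (mapped) length. With no missing data this equals the
#' classic sum over all strain pairs of per-pair differences divided by
#' C(n,2).
#'
#' @param aln A [haplotype_alignment()].
#' @param .ss Optional precomputed site summary (internal reuse).
#' @return List with `pi_raw` (summed per-site mean pairwise differences),
#'   `pi` (per effective site), `S` (segregating sites), `eta` (total
#'   mutations), `eta_s` (total singletons) and `n`. All values are `NA`
#'   when fewer than 2 strains are present (undefined, flagged).
#' @export
nucleotide_diversity <- function(aln, .ss = NULL) {
  n <- aln_n(aln)
  if (n < 2) {
    return(list(pi_raw = NA_real_, pi = NA_real_, S = NA_integer_,
                eta = NA_integer_, eta_s = NA_integer_, n = n))
  }
  ss <- .ss %||% site_summary(aln)
  pi_raw <- sum(ss$het)
  list(pi_raw = pi_raw,
       pi = safe_div(pi_raw, aln$effective_length),
       S = ss$S, eta = ss$eta, eta_s = ss$eta_s, n = n)
}

#' Codon-aware classification of sites and polymorphisms
#'
#' NG86 fractional site counting on the reference codons (each codon
#' contributes a fractional number of synonymous sites equal to one third
#' of its synonymous single-base changes, the rest nonsynonymous) plus a
#' syn/nonsyn label for every segregating site. A polymorphism is labeled
#' by whether the alternative codon's amino acid differs from the
#' reference codon's (translation table 11); codons with more than one
#' segregating position are resolved by averaging over the orderings in
#' which the changes could have occurred, giving fractional labels.
#' Codons containing a non-ACGT base are excluded from both numerator and
#' denominator with a message.
#'
#' @param aln A [haplotype_alignment()] with its `reference` set; length
#'   must be a multiple of 3.
#' @param .ss Optional precomputed site summary (internal reuse).
#' @return List with `syn_sites`, `nonsyn_sites` (fractional NG86 site
#'   totals over included codons), `labels` (data frame: `site`,
#'   `w_nonsyn` in `[0, 1]`), and `excluded_codons`.
#' @export
classify_sites <- function(aln, .ss = NULL) {
  ref <- aln$reference
  if (is.null(ref)) stopf("alignment has no reference sequence")
  L <- aln_len(aln)
  if (L %% 3 != 0) stopf("alignment length %d not divisible by 3", L)
  ref_chars <- seq_chars(ref)
  n_codons <- L %/% 3
  codons <- substring(ref, seq(1, L, 3), seq(3, L, 3))
  ok <- !grepl("[^ACGT]", codons)
  if (any(!ok)) {
    message(sprintf("excluding %d codon(s) with ambiguous bases", sum(!ok)))
  }
  syn_tab <- ng86_site_table()
  syn_sites <- sum(syn_tab[codons[ok]])
  nonsyn_sites <- 3 * sum(ok) - syn_sites

  ss <- .ss %||% site_summary(aln)
  seg_sites <- which(ss$segregating)
  seg_sites <- seg_sites[ok[codon_of(seg_sites)]]
  labels <- data.frame(site = integer(0), w_nonsyn = numeric(0))
  if (length(seg_sites) > 0) {
    by_codon <- split(seg_sites, codon_of(seg_sites))
    lab <- lapply(by_codon, function(sites) {
      ci <- codon_of(sites[1])
      changes <- codon_changes(ss$counts, sites, ci, ref_chars)
      w <- pathway_average(codons[ci], changes)
      data.frame(site = sites,
                 w_nonsyn = vapply(sites, function(s) {
                   mean(w[changes$pos_in_codon == (s - 3 * (ci - 1))])
                 }, numeric(1)))
    })
    labels <- do.call(rbind, lab)
    rownames(labels) <- NULL
    labels <- labels[order(labels$site), , drop = FALSE]
  }
  list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
       labels = labels, excluded_codons = which(!ok))
}

## describe the allele changes at segregating sites within one codon:
## for each non-reference allele observed, one change (position within
## codon, from ref base to that allele)
codon_changes <- function(counts, sites, ci, ref_chars) {
  pos <- integer(0); from <- character(0); to <- character(0)
  for (s in sites) {
    alleles <- BASES[counts[s, ] > 0]
    alts <- setdiff(alleles, ref_chars[s])
    if (length(alts) == 0) next
    ## if the reference base is absent, the most frequent allele is the
    ## context base and the rest are the changes
    if (!ref_chars[s] %in% alleles && length(alts) > 1) {
      major <- alleles[which.max(counts[s, match(alleles, BASES)])]
      alts <- setdiff(alleles, major)
    }
    for (a in alts) {
      pos <- c(pos, s - 3L * (ci - 1L))
      from <- c(from, ref_chars[s]); to <- c(to, a)
    }
  }
  data.frame(pos_in_codon = pos, from = from, to = to,
             stringsAsFactors = FALSE)
}

## average the syn/nonsyn consequence of each change over all orderings in
## which the changes at distinct codon positions could have occurred;
## returns a nonsynonymous weight in [0, 1] per change row
pathway_average <- function(ref_codon, changes) {
  nch <- nrow(changes)
  if (nch == 0) return(numeric(0))
  if (nch == 1) {
    return(as.numeric(change_is_nonsyn(ref_codon, changes$pos_in_codon,
                                       changes$to)))
  }
  ## enumerate orderings over distinct positions; changes sharing a
  ## position (multi-allelic) are evaluated in the same context slot
  dpos <- unique(changes$pos_in_codon)
  perms <- permutations(length(dpos))
  w <- numeric(nch)
  for (pi in seq_len(nrow(perms))) {
    codon <- ref_codon
    for (step in perms[pi, ]) {
      p <- dpos[step]
      rows <- which(changes$pos_in_codon == p)
      for (rr in rows) {
        w[rr] <- w[rr] + as.numeric(change_is_nonsyn(codon, p,
                                                     changes$to[rr]))
      }
      ## advance the context using the first-listed change at p
      substr(codon, p, p) <- changes$to[rows[1]]
    }
  }
  w / nrow(perms)
}

permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

## pi_raw split into nonsynonymous and synonymous components using the
## per-site labels (sites in excluded codons contribute to neither)
pi_raw_split <- function(aln, cls = NULL, .ss = NULL) {
  ss <- .ss %||% site_summary(aln)
  if (is.null(cls)) cls <- classify_sites(aln, .ss = ss)
  w <- setNames(rep(0, aln_len(aln)), NULL)
  if (nrow(cls$labels) > 0) w[cls$labels$site] <- cls$labels$w_nonsyn
  keep <- rep(TRUE, aln_len(aln))
  if (length(cls$excluded_codons) > 0) {
    keep[unlist(lapply(cls$excluded_codons, codon_positions))] <- FALSE
  }
  list(pi_raw_N = sum(ss$het[keep] * w[keep]),
       pi_raw_S = sum(ss$het[keep] * (1 - w[keep]) * ss$segregating[keep]),
       cls = cls)
}
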