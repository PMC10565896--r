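## shared engine for the McDonald-Kreitman table. A site that segregates
## in the sample counts as polymorphism; a site that is monomorphic in the
## sample but differs from the outgroup counts as divergence; a site that
## is both counts as polymorphism only. Labels are codon-aware with
## pathway averaging, so the four cells may be fractional.
mk_table <- function(aln, min_derived_freq = 0, .ss = NULL) {
  if (is.null(aln$outgroup)) stopf("McDonald-Kreitman requires an outgroup")
  ref <- aln$reference
  if (is.null(ref)) stopf("alignment has no reference sequence")
  L <- aln_len(aln)
  if (L %% 3 != 0) stopf("alignment length %d not divisible by 3", L)
  ref_chars <- seq_chars(ref)
  og <- seq_chars(aln$outgroup)
  ss <- .ss %||% site_summary(aln)
  cnt <- ss$counts

  Pn <- Ps <- Dn <- Ds <- 0
  ## sample-majority allele per site (reference where nothing is called)
  maj <- ifelse(ss$called >= 1, BASES[max.col(cnt, ties.method = "first")],
                ref_chars)
  div_site <- !ss$segregating & ss$called >= 1 & maj != og & og %in% BASES
  active <- unique(codon_of(which(ss$segregating | div_site)))
  for (ci in active) {
    pos <- codon_positions(ci)
    ref_codon <- chars_seq(ref_chars[pos])
    if (!all(ref_chars[pos] %in% BASES) || !all(og[pos] %in% BASES)) next

    seg <- pos[ss$segregating[pos]]
    ## polymorphism labels (reference-codon context, pathway averaged)
    if (length(seg) > 0) {
      changes <- codon_changes(cnt, seg, ci, ref_chars)
      if (nrow(changes) > 0) {
        w <- pathway_average(ref_codon, changes)
        keep <- rep(TRUE, nrow(changes))
        if (min_derived_freq > 0) {
          for (i in seq_len(nrow(changes))) {
            s <- pos[1] + changes$pos_in_codon[i] - 1L
            m <- ss$called[s]
            maf <- min(cnt[s, cnt[s, ] > 0]) / m
            keep[i] <- maf >= min_derived_freq
          }
        }
        Pn <- Pn + sum(w[keep])
        Ps <- Ps + sum((1 - w)[keep])
      }
    }

    ## divergence: sample-monomorphic positions differing from outgroup
    ## (segregating positions provide majority context but never divergence)
    fixed_allele <- maj[pos]
    div <- div_site[pos]
    if (any(div)) {
      sample_codon <- chars_seq(fixed_allele)
      dpos <- which(div)
      if (length(dpos) == 1) {
        nn <- change_is_nonsyn(sample_codon, dpos, og[pos[dpos]])
        Dn <- Dn + as.numeric(nn)
        Ds <- Ds + as.numeric(!nn)
      } else {
        perms <- permutations(length(dpos))
        wn <- 0
        for (pi in seq_len(nrow(perms))) {
          codon <- sample_codon
          for (step in perms[pi, ]) {
            p <- dpos[step]
            wn <- wn + as.numeric(change_is_nonsyn(codon, p, og[pos[p]]))
            substr(codon, p, p) <- og[pos[p]]
          }
        }
        wn <- wn / nrow(perms)
        Dn <- Dn + wn
        Ds <- Ds + (length(dpos) - wn)
      }
    }
  }
  list(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds)
}

mk_result <- function(tab) {
  Pn <- tab$Pn; Ps <- tab$Ps; Dn <- tab$Dn; Ds <- tab$Ds
  counts <- round(matrix(c(Pn, Dn, Ps, Ds), 2, 2))
  fisher_p <- if (sum(counts) > 0) fisher.test(counts)$p.value else NA_real_
  NI <- if (Ps > 0 && Dn > 0 && Ds > 0) (Pn / Ps) / (Dn / Ds) else NA_real_
  DoS <- if ((Dn + Ds) > 0 && (Pn + Ps) > 0) {
    Dn / (Dn + Ds) - Pn / (Pn + Ps)
  } else NA_real_
  list(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds,
       fisher_p = fisher_p, NI = NI, DoS = DoS)
}

#' McDonald-Kreitman test with neutrality index and direction of selection
#'
#' Builds the 2x2 contrast of nonsynonymous/synonymous counts in
#' within-sample polymorphism (Pn, Ps) versus sample-outgroup divergence
#' (Dn, Ds); sites both polymorphic and divergent count as polymorphism
#' only. Returns the two-sided Fisher exact p on the rounded table, the
#' neutrality index NI = (Pn/Ps)/(Dn/Ds) (`NA` when any margin is zero)
#' and the direction of selection DoS = Dn/(Dn+Ds) - Pn/(Pn+Ps) (`NA`
#' only when a full row is empty).
#'
#' @param aln A [haplotype_alignment()] with reference and outgroup set.
#' @param .ss Optional precomputed site summary (internal reuse).
#' @return List with `Pn`, `Ps`, `Dn`, `Ds`, `fisher_p`, `NI`, `DoS`.
#' @export
mcdonald_kreitman <- function(aln, .ss = NULL) {
  mk_result(mk_table(aln, min_derived_freq = 0, .ss = .ss))
}

#' Conservative McDonald-Kreitman variant
#'
#' Identical to [mcdonald_kreitman()] after excluding polymorphisms whose
#' minor-allele frequency is below `min_derived_freq` (default 0.15), a
#' standard guard against slightly deleterious low-frequency variants
#' inflating Pn.
#'
#' @param aln A [haplotype_alignment()] with reference and outgroup set.
#' @param min_derived_freq Minor-allele frequency cutoff.
#' @param .ss Optional precomputed site summary (internal reuse).
#' @return Same structure as [mcdonald_kreitman()].
#' @export
mk_conservative <- function(aln, min_derived_freq = 0.15, .ss = NULL) {
  mk_result(mk_table(aln, min_derived_freq = min_derived_freq, .ss = .ss))
}

#' NG86 Ka/Ks between a reference CDS and an outgroup CDS
#'
#' Nei-Gojobori (1986) counting: fractional synonymous/nonsynonymous site
#' totals averaged over the two sequences, observed differences resolved
#' by pathway averaging over substitution orderings within each codon,
#' and Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3) of each
#' proportion. Codons with ambiguous bases, or carrying a premature
#' internal stop in either sequence, are skipped with a message; a
#' proportion of 3/4 or more leaves the corrected rate undefined
#' (flagged `NA`).
#'
#' @param reference_cds Reference coding sequence (character scalar).
#' @param outgroup_cds Outgroup coding sequence, same length.
#' @return List with `Ka`, `Ks`, `ratio`, plus the raw counts
#'   (`N_sites`, `S_sites`, `Nd`, `Sd`).
#' @export
ka_ks <- function(reference_cds, outgroup_cds) {
  if (nchar(reference_cds) != nchar(outgroup_cds)) {
    stopf("sequences differ in length")
  }
  L <- nchar(reference_cds)
  if (L %% 3 != 0) stopf("length %d not divisible by 3", L)
  syn_tab <- ng86_site_table()
  n_codons <- L %/% 3
  c1v <- substring(reference_cds, seq(1, L, 3), seq(3, L, 3))
  c2v <- substring(outgroup_cds, seq(1, L, 3), seq(3, L, 3))
  ambiguous <- grepl("[^ACGT]", c1v) | grepl("[^ACGT]", c2v)
  internal_stop <- rep(FALSE, n_codons)
  internal_stop[-n_codons] <- !ambiguous[-n_codons] &
    (translate_codon(c1v[-n_codons]) == "*" |
       translate_codon(c2v[-n_codons]) == "*")
  keep <- !ambiguous & !internal_stop
  skipped <- sum(!keep)
  S_sites <- sum((syn_tab[c1v[keep]] + syn_tab[c2v[keep]]) / 2)
  N_sites <- 3 * sum(keep) - S_sites
  Nd <- Sd <- 0
  for (ci in which(keep & c1v != c2v)) {
    c1 <- c1v[ci]; c2 <- c2v[ci]
    b1 <- seq_chars(c1); b2 <- seq_chars(c2)
    dpos <- which(b1 != b2)
    if (length(dpos) == 1) {
      nn <- change_is_nonsyn(c1, dpos, substr(c2, dpos, dpos))
      Nd <- Nd + as.numeric(nn); Sd <- Sd + as.numeric(!nn)
    } else {
      perms <- permutations(length(dpos))
      wn <- 0
      for (pi in seq_len(nrow(perms))) {
        codon <- c1
        for (step in perms[pi, ]) {
          p <- dpos[step]
          tob <- substr(c2, p, p)
          wn <- wn + as.numeric(change_is_nonsyn(codon, p, tob))
          substr(codon, p, p) <- tob
        }
      }
      wn <- wn / nrow(perms)
      Nd <- Nd + wn
      Sd <- Sd + (length(dpos) - wn)
    }
  }
  if (skipped > 0) {
    message(sprintf("ka_ks: skipped %d codon(s) (ambiguous or premature stop)",
                    skipped))
  }
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ka <- jc(safe_div(Nd, N_sites) %||% NA_real_)
  Ks <- jc(safe_div(Sd, S_sites) %||% NA_real_)
  if (N_sites > 0 && Nd == 0) Ka <- 0
  if (S_sites > 0 && Sd == 0) Ks <- 0
  list(Ka = Ka, Ks = Ks,
       ratio = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
       N_sites = N_sites, S_sites = S_sites, Nd = Nd, Sd = Sd)
}
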