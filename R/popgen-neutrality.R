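#' Tajima's D
#'
#' Contrasts the mean pairwise diversity estimator of theta with the
#' Watterson (segregating sites) estimator, normalized by the standard
#' variance constants for sample size n (Tajima 1989). Negative values
#' indicate an excess of rare variants, positive values an excess of
#' intermediate-frequency variants.
#'
#' @param S Number of segregating sites (>= 1 for a defined value).
#' @param pi_raw Mean pairwise differences summed over sites (unscaled).
#' @param n Sample size.
#' @return D, or `NA` (undefined, flagged) when `S` is 0.
#' @export
tajimas_d <- function(S, pi_raw, n) {
  if (is.na(S) || S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_raw - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## variance constants for the Fu & Li (1993) statistics, including the
## starred (outgroup-free) versions with the corrected F* constants
fu_li_constants <- function(n) {
  i <- seq_len(n - 1)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- if (n > 2) 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- 1 + (an^2 / (bn + an^2)) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uDs <- (n / (n - 1)) * (an - n / (n - 1)) - vDs
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
            (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uFs <- ((n / (n - 1)) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vFs
  list(an = an, bn = bn, cn = cn, dn = dn,
       vD = vD, uD = uD, vDs = vDs, uDs = uDs,
       vF = vF, uF = uF, vFs = vFs, uFs = uFs)
}

#' Fu & Li's D*, F* (and D, F when an outgroup is present)
#'
#' The starred statistics contrast total mutations eta against total
#' singletons eta_s; the outgroup-polarized D and F contrast eta against
#' derived singletons eta_e (singletons whose allele is absent from the
#' outgroup). Constants follow the original publication with the
#' standard corrections for the starred variance terms.
#'
#' @param aln A [haplotype_alignment()]; if its outgroup row is set the
#'   polarized statistics are computed as well.
#' @param .ss Optional precomputed site summary (internal reuse).
#' @return List with `D_star`, `F_star`, and `D`, `F` (`NA` when no
#'   outgroup is available). All `NA` when there are no segregating
#'   sites.
#' @export
fu_li_statistics <- function(aln, .ss = NULL) {
  n <- aln_n(aln)
  ss <- .ss %||% (if (n >= 2) site_summary(aln) else NULL)
  nd <- nucleotide_diversity(aln, .ss = ss)
  if (is.na(nd$S) || nd$S < 1) {
    return(list(D_star = NA_real_, F_star = NA_real_,
                D = NA_real_, F = NA_real_))
  }
  k <- fu_li_constants(n)
  eta <- nd$eta
  eta_s <- nd$eta_s
  pi_raw <- nd$pi_raw
  D_star <- ((n / (n - 1)) * eta - k$an * eta_s) /
    sqrt(k$uDs * eta + k$vDs * eta^2)
  F_star <- (pi_raw - ((n - 1) / n) * eta_s) /
    sqrt(k$uFs * eta + k$vFs * eta^2)

  D <- F <- NA_real_
  if (!is.null(aln$outgroup)) {
    og <- seq_chars(aln$outgroup)
    cnt <- (ss %||% site_summary(aln))$counts
    kall <- rowSums(cnt > 0)
    eta_e <- 0
    for (s in which(kall >= 2)) {
      if (!og[s] %in% BASES) next
      derived <- BASES[cnt[s, ] > 0 & BASES != og[s]]
      if (length(derived) == kall[s]) next  # unpolarizable
      eta_e <- eta_e + sum(cnt[s, derived] == 1)
    }
    D <- (eta - k$an * eta_e) / sqrt(k$uD * eta + k$vD * eta^2)
    F <- (pi_raw - eta_e) / sqrt(k$uF * eta + k$vF * eta^2)
  }
  list(D_star = D_star, F_star = F_star, D = D, F = F)
}
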