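# Independent brute-force oracles. These are deliberately naive
# re-derivations from the published formulas / first principles, kept
# separate from the package implementation paths they check.

## mean pairwise differences per site: explicit double loop over all
## strain pairs and sites (pairwise deletion per site)
oracle_pi <- function(mat, effective_length = ncol(mat)) {
  n <- nrow(mat)
  per_site <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    diffs <- 0; pairs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- mat[i, s]; b <- mat[j, s]
        if (is.na(a) || is.na(b)) next
        pairs <- pairs + 1
        if (a != b) diffs <- diffs + 1
      }
    }
    per_site[s] <- if (pairs > 0) diffs / pairs else 0
  }
  list(pi_raw = sum(per_site), pi = sum(per_site) / effective_length)
}

## Tajima (1989) constants, transcribed independently
oracle_tajima <- function(S, pi_raw, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1^2)
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_raw - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## Fu & Li (1993) starred statistics, transcribed independently
oracle_fu_li_star <- function(eta, eta_s, pi_raw, n) {
  an <- sum(1 / seq_len(n - 1))
  bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uDs <- (n / (n - 1)) * (an - n / (n - 1)) - vDs
  vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
            (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vFs
  list(D_star = ((n / (n - 1)) * eta - an * eta_s) /
         sqrt(uDs * eta + vDs * eta^2),
       F_star = (pi_raw - ((n - 1) / n) * eta_s) /
         sqrt(uFs * eta + vFs * eta^2))
}

## two-sided Fisher exact p by exhaustive hypergeometric enumeration
oracle_fisher2x2 <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  if (m + n == 0 || k == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## mean pairwise Spearman by explicit double loop over cor() calls
oracle_mean_spearman <- function(mat, set) {
  k <- length(set)
  tot <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      tot <- tot + cor(mat[set[i], ], mat[set[j], ], method = "spearman")
    }
  }
  tot / (k * (k - 1) / 2)
}

## exact two-sided signed-rank p by full enumeration of all 2^n sign
## assignments (feasible for small n)
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V_obs <- sum(rk[d > 0])
  Vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    Vs[mask + 1] <- sum(rk[signs])
  }
  p_ge <- mean(Vs >= V_obs - 1e-9)
  p_le <- mean(Vs <= V_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

## Welch (1951) heteroscedastic F from the published formulas
oracle_welch <- function(groups) {
  k <- length(groups)
  ni <- lengths(groups)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  B <- 1 + (2 * (k - 2) / (k^2 - 1)) * sum((1 - wi / W)^2 / (ni - 1))
  Fstat <- A / B
  df2 <- (k^2 - 1) / (3 * sum((1 - wi / W)^2 / (ni - 1)))
  list(F = Fstat, df1 = k - 1, df2 = df2,
       p = pf(Fstat, k - 1, df2, lower.tail = FALSE))
}

## all orderings of multi-hit codon changes, enumerated explicitly
oracle_pathway_codon <- function(ref_codon, pos, alts) {
  stopifnot(length(pos) == length(alts))
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  gc <- kinsig::genetic_code_11()
  nsyn_weight <- setNames(numeric(length(pos)), paste0(pos, alts))
  orders <- perm(seq_along(pos))
  for (o in orders) {
    codon <- ref_codon
    for (step in o) {
      before <- gc[[codon]]
      cand <- codon
      substr(cand, pos[step], pos[step]) <- alts[step]
      key <- paste0(pos[step], alts[step])
      nsyn_weight[key] <- nsyn_weight[key] + as.numeric(gc[[cand]] != before)
      codon <- cand
    }
  }
  nsyn_weight / length(orders)
}

## quick random alignment with fully called data
random_alignment <- function(n, L, n_poly = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- kinsig:::random_cds(L / 3)
  mat <- matrix(rep(ref, each = n), nrow = n)
  sites <- sample(L, n_poly)
  for (s in sites) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref[s]), 1)
    carriers <- sample(n, sample(n - 1, 1))
    mat[carriers, s] <- alt
  }
  haplotype_alignment(
    "test_gene", sprintf("s%02d", seq_len(n)), mat,
    reference = paste(ref, collapse = ""))
}
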