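test_that("nucleotide diversity matches hand values and the brute-force oracle", {
  strains <- function(n) sprintf("s%02d", seq_len(n))
  ## identical rows -> 0
  mat <- matrix("A", 4, 12)
  aln <- haplotype_alignment("g", strains(4), mat)
  expect_equal(nucleotide_diversity(aln)$pi, 0)

  ## 2 sequences, 1 difference, 100 sites -> 0.01
  mat2 <- matrix("C", 2, 100)
  mat2[2, 17] <- "T"
  aln2 <- haplotype_alignment("g", strains(2), mat2)
  expect_equal(nucleotide_diversity(aln2)$pi, 0.01)

  ## fewer than 2 strains: flagged undefined
  expect_true(is.na(nucleotide_diversity(
    haplotype_alignment("g", "s1", matrix("A", 1, 9)))$pi))

  ## random alignments match the O(n^2 L) double-loop oracle
  for (seed in 1:10) {
    aln3 <- random_alignment(10, 300, n_poly = 25, seed = seed)
    nd <- nucleotide_diversity(aln3)
    or <- oracle_pi(aln3$mat)
    expect_equal(nd$pi_raw, or$pi_raw, tolerance = 1e-12)
    expect_equal(nd$pi, or$pi, tolerance = 1e-12)
  }

  ## pairwise deletion: site with missing calls averaged over called pairs
  mat4 <- matrix("A", 4, 10)
  mat4[1, 3] <- "G"; mat4[2, 3] <- NA
  aln4 <- haplotype_alignment("g", strains(4), mat4)
  expect_equal(nucleotide_diversity(aln4)$pi_raw, oracle_pi(mat4)$pi_raw)
})

test_that("codon site classification follows the genetic code and pathway averaging", {
  strains <- sprintf("s%d", 1:4)
  ## TTT -> TTC at position 3 is synonymous (both Phe)
  mat <- matrix(rep(c("T", "T", "T"), each = 4), 4, 3)
  mat[1:2, 3] <- "C"
  aln <- haplotype_alignment("g", strains, mat, reference = "TTT")
  cls <- classify_sites(aln)
  expect_equal(cls$labels$w_nonsyn, 0)

  ## every single-base change in an internal ATG is nonsynonymous:
  ## enumerate all 9 changes
  for (p in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"),
                        substr("ATG", p, p))) {
      m <- matrix(rep(strsplit("ATG", "")[[1]], each = 4), 4, 3)
      m[1, p] <- alt
      a <- haplotype_alignment("g", strains, m, reference = "ATG")
      expect_equal(classify_sites(a)$labels$w_nonsyn, 1)
    }
  }
  ## and ATG therefore contributes 0 synonymous sites
  expect_equal(unname(kinsig:::ng86_site_table()[["ATG"]]), 0)

  ## 2-hit codon: fractional labels equal the mean over both orderings,
  ## checked against exhaustive enumeration
  ## AAA with A1->C (segregating) and A3->G (segregating)
  m2 <- matrix("A", 6, 3)
  m2[1:3, 1] <- "C"
  m2[1:2, 3] <- "G"
  a2 <- haplotype_alignment("g", sprintf("s%d", 1:6), m2, reference = "AAA")
  cls2 <- classify_sites(a2)
  or <- oracle_pathway_codon("AAA", c(1, 3), c("C", "G"))
  expect_equal(cls2$labels$w_nonsyn[cls2$labels$site == 1],
               unname(or["1C"]))
  expect_equal(cls2$labels$w_nonsyn[cls2$labels$site == 3],
               unname(or["3G"]))

  ## ambiguous codon excluded from numerator and denominator
  m3 <- matrix(rep(c("T", "T", "T", "A", "N", "A"), each = 4), 4, 6)
  m3[1, 3] <- "C"
  a3 <- haplotype_alignment("g", strains, m3, reference = "TTTANA")
  expect_message(cls3 <- classify_sites(a3), "ambiguous")
  expect_equal(cls3$syn_sites + cls3$nonsyn_sites, 3)
})

test_that("Tajima's D matches its defining constants", {
  ## numerator zero when pi_raw = S / a1
  n <- 17; S <- 9
  a1 <- sum(1 / seq_len(n - 1))
  expect_equal(tajimas_d(S, S / a1, n), 0)
  ## flagged undefined at S = 0
  expect_true(is.na(tajimas_d(0, 0, 31)))
  ## frozen spot check against the independently coded constants oracle
  expect_equal(tajimas_d(10, 2.0, 31), oracle_tajima(10, 2.0, 31),
               tolerance = 1e-10)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:60, 1); S <- sample(1:80, 1); pr <- runif(1, 0, 20)
    expect_equal(tajimas_d(S, pr, n), oracle_tajima(S, pr, n),
                 tolerance = 1e-10)
  }
})

test_that("Fu & Li statistics match the oracle and force the expected signs", {
  ## no singletons with eta > 0 forces D* > 0
  mat <- matrix("A", 8, 30)
  mat[1:4, 5] <- "G"; mat[1:3, 20] <- "C"
  aln <- haplotype_alignment("g", sprintf("s%d", 1:8), mat)
  fl <- fu_li_statistics(aln)
  expect_gt(fl$D_star, 0)

  ## worked 6-sequence alignment equals the independent transcription
  mat2 <- matrix("T", 6, 60)
  mat2[1, 7] <- "A"          # singleton
  mat2[1:3, 21] <- "G"       # intermediate
  mat2[6, 33] <- "C"         # singleton
  mat2[2:5, 48] <- "A"       # intermediate
  aln2 <- haplotype_alignment("g", sprintf("s%d", 1:6), mat2)
  nd <- nucleotide_diversity(aln2)
  expect_equal(nd$S, 4)
  expect_equal(nd$eta_s, 2)
  fl2 <- fu_li_statistics(aln2)
  or <- oracle_fu_li_star(nd$eta, nd$eta_s, nd$pi_raw, 6)
  expect_equal(fl2$D_star, or$D_star, tolerance = 1e-10)
  expect_equal(fl2$F_star, or$F_star, tolerance = 1e-10)

  ## with an outgroup, polarized D/F appear; derived singletons counted
  ## only where the outgroup carries the other allele
  aln3 <- haplotype_alignment("g", sprintf("s%d", 1:6), mat2,
                              outgroup = paste(rep("T", 60), collapse = ""))
  fl3 <- fu_li_statistics(aln3)
  expect_false(is.na(fl3$D))
  expect_false(is.na(fl3$F))
  ## all 4 mutations derived; 2 derived singletons
  k <- kinsig:::fu_li_constants(6)
  expect_equal(fl3$D, (4 - k$an * 2) / sqrt(k$uD * 4 + k$vD * 16),
               tolerance = 1e-10)
  ## without an outgroup the polarized statistics are absent
  expect_true(is.na(fl2$D) && is.na(fl2$F))
})

## build an alignment + outgroup realizing a chosen MK table using clean
## single-change codons (AAA pos1 A->C nonsyn; TTT pos3 T->C syn;
## GGG -> CGG nonsyn divergence; TTT -> TTC syn divergence)
mk_fixture <- function(Pn, Ps, Dn, Ds, n = 4) {
  codons <- c(rep("AAA", Pn), rep("TTT", Ps), rep("GGG", Dn),
              rep("TTT", Ds), "TAA")
  ref <- paste(codons, collapse = "")
  L <- nchar(ref)
  mat <- matrix(rep(strsplit(ref, "")[[1]], each = n), n, L)
  og <- strsplit(ref, "")[[1]]
  idx <- 0
  for (i in seq_len(Pn)) { mat[1:2, 3 * idx + 1] <- "C"; idx <- idx + 1 }
  for (i in seq_len(Ps)) { mat[1:2, 3 * idx + 3] <- "C"; idx <- idx + 1 }
  for (i in seq_len(Dn)) { og[3 * idx + 1] <- "C"; idx <- idx + 1 }
  for (i in seq_len(Ds)) { og[3 * idx + 3] <- "C"; idx <- idx + 1 }
  haplotype_alignment("g", sprintf("s%d", seq_len(n)), mat,
                      reference = ref,
                      outgroup = paste(og, collapse = ""))
}

test_that("McDonald-Kreitman table, NI and DoS behave per definition", {
  ## (2,2,2,2): perfect neutrality
  mk <- mcdonald_kreitman(mk_fixture(2, 2, 2, 2))
  expect_equal(unlist(mk[c("Pn", "Ps", "Dn", "Ds")]),
               c(Pn = 2, Ps = 2, Dn = 2, Ds = 2))
  expect_equal(mk$NI, 1)
  expect_equal(mk$DoS, 0)
  expect_equal(mk$fisher_p, 1)

  ## (0,5,5,0): DoS at its maximum
  mk2 <- mcdonald_kreitman(mk_fixture(0, 5, 5, 0))
  expect_equal(mk2$DoS, 1)
  expect_true(is.na(mk2$NI))  # zero margins flag NI undefined

  ## site both polymorphic and divergent counts as polymorphism only
  aln <- mk_fixture(1, 1, 1, 1)
  og <- strsplit(aln$outgroup, "")[[1]]
  og[1] <- "G"  # outgroup also differs at the polymorphic AAA site
  aln2 <- haplotype_alignment(aln$gene_id, aln$strains, aln$mat,
                              reference = aln$reference,
                              outgroup = paste(og, collapse = ""))
  mk3 <- mcdonald_kreitman(aln2)
  expect_equal(mk3$Pn, 1)
  expect_equal(mk3$Dn, 1)  # unchanged: no extra divergence at that site

  ## fisher p agrees with exhaustive hypergeometric enumeration
  for (seed in 1:25) {
    set.seed(seed)
    tab <- matrix(rpois(4, 4), 2, 2)
    if (sum(tab) == 0) next
    got <- kinsig:::mk_result(list(Pn = tab[1, 1], Ps = tab[2, 1],
                                   Dn = tab[1, 2], Ds = tab[2, 2]))
    expect_equal(got$fisher_p, oracle_fisher2x2(tab), tolerance = 1e-10)
  }
})

test_that("conservative MK drops low-frequency polymorphisms only", {
  ## min_derived_freq = 0 reproduces the standard test
  aln <- mk_fixture(2, 2, 2, 2, n = 8)
  expect_equal(mk_conservative(aln, min_derived_freq = 0),
               mcdonald_kreitman(aln))

  ## a singleton Pn (frequency 1/31 < 0.15) is excluded
  aln31 <- mk_fixture(0, 0, 1, 1, n = 31)
  mat <- aln31$mat
  mat[1, 1] <- "C"   # singleton nonsynonymous polymorphism in codon 1
  alns <- haplotype_alignment(aln31$gene_id, aln31$strains, mat,
                              reference = aln31$reference,
                              outgroup = aln31$outgroup)
  expect_equal(mcdonald_kreitman(alns)$Pn, 1)
  expect_equal(mk_conservative(alns)$Pn, 0)

  ## planted frequency spectrum: counts match a hand-filtered table
  aln2 <- mk_fixture(3, 2, 0, 0, n = 20)
  mat2 <- aln2$mat
  mat2[, 1] <- "A"; mat2[1, 1] <- "C"          # Pn at freq 0.05 (drop)
  mat2[, 4] <- "A"; mat2[1:2, 4] <- "C"        # Pn at freq 0.10 (drop)
  mat2[, 7] <- "A"; mat2[1:3, 7] <- "C"        # Pn at freq 0.15 (keep)
  aln2 <- haplotype_alignment(aln2$gene_id, aln2$strains, mat2,
                              reference = aln2$reference,
                              outgroup = aln2$outgroup)
  expect_equal(mcdonald_kreitman(aln2)$Pn, 3)
  expect_equal(mk_conservative(aln2, 0.15)$Pn, 1)
})

test_that("NG86 Ka/Ks reproduces hand-computed examples", {
  ## identical sequences
  ref <- paste(rep("TTT", 29), collapse = "")
  ref <- paste0(ref, "TAA")
  kk0 <- ka_ks(ref, ref)
  expect_equal(kk0$Ka, 0)
  expect_equal(kk0$Ks, 0)

  ## one synonymous change in a 30-codon gene of TTT codons (+ TAA stop):
  ## per TTT codon 1/3 synonymous sites, TAA has 2/3, so S = 29/3 + 2/3
  out <- sub("^TTT", "TTC", ref)
  kk <- ka_ks(ref, out)
  expect_equal(kk$S_sites, 31 / 3)
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Ka, 0)
  p_s <- 1 / (31 / 3)
  expect_equal(kk$Ks, -0.75 * log(1 - 4 * p_s / 3), tolerance = 1e-12)

  ## 2-hit codon difference: pathway averaging over both orderings
  ## AAA vs CAG: orderings (pos1 then pos3) and (pos3 then pos1)
  or <- oracle_pathway_codon("AAA", c(1, 3), c("C", "G"))
  ## forward: AAA->CAA (K->Q, nonsyn), CAA->CAG (Q->Q, syn)
  ## reverse: AAA->AAG (K->K, syn), AAG->CAG (K->Q, nonsyn)
  kk2 <- ka_ks(paste0("AAA", "TAA"), paste0("CAG", "TAA"))
  expect_equal(kk2$Nd, 1)
  expect_equal(kk2$Sd, 1)

  ## premature internal stop codons are skipped
  expect_message(
    kk3 <- ka_ks(paste0("TAA", "TTT", "TAA"), paste0("TAA", "TTC", "TAA")),
    "skipped")
  expect_equal(kk3$Sd, 1)
  expect_equal(kk3$S_sites, 1)

  ## saturation flags the JC correction as undefined: every TTT codon
  ## diverged at its single synonymous site gives p_S = 3/2 >= 3/4
  expect_true(is.na(ka_ks("TTTTTTTAA", "TTCTTCTAA")$Ks))
})

test_that("gene statistics assemble with correct scaling and flags", {
  ## monomorphic gene without outgroup: pi 0, D flagged, MK absent
  mat <- matrix(rep(strsplit("ATGAAATTTTAA", "")[[1]], each = 5), 5, 12)
  aln <- haplotype_alignment("g", sprintf("s%d", 1:5), mat,
                             reference = "ATGAAATTTTAA")
  gs <- compute_gene_stats(aln)
  expect_equal(gs$pi, 0)
  expect_true(is.na(gs$tajimas_D))
  expect_true(is.na(gs$mk_p))
  expect_true(is.na(gs$Ka))

  ## halving the effective length doubles every per-site measure
  aln_full <- random_alignment(10, 300, n_poly = 12, seed = 99)
  aln_half <- haplotype_alignment(aln_full$gene_id, aln_full$strains,
                                  aln_full$mat,
                                  reference = aln_full$reference,
                                  effective_length = 150)
  g1 <- compute_gene_stats(aln_full)
  g2 <- compute_gene_stats(aln_half)
  expect_equal(g2$pi, 2 * g1$pi)
  expect_equal(g2$pi_N, 2 * g1$pi_N)
  expect_equal(g2$pi_S, 2 * g1$pi_S)
  ## unscaled statistics are unchanged
  expect_equal(g2$tajimas_D, g1$tajimas_D)
  expect_equal(g2$S, g1$S)

  ## label conservation: Pn + Ps equals classifiable segregating sites
  fx <- small_fixture()
  for (gid in names(fx$sim$alignments)[1:4]) {
    aln <- add_outgroup(fx$sim$alignments[[gid]],
                        fx$og$sequences[[gid]])
    mk <- suppressMessages(mcdonald_kreitman(aln))
    cls <- classify_sites(aln)
    expect_equal(mk$Pn + mk$Ps, nrow(cls$labels))
  }
})
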