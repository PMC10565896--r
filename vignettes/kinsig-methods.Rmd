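---
title: "Detecting kin-selection signatures from bacterial variant panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting kin-selection signatures from bacterial variant panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Cooperative genes encode secreted products whose fitness benefits are
shared with neighbouring cells. When interacting cells are related by
*r* < 1, a fraction of those benefits accrues to cells that do not carry
the gene, and the inclusive-fitness effect of an allele at the locus is
reduced by the factor *r*. To first order this is equivalent to scaling
the selection coefficient: a deleterious nonsynonymous mutation in a
cooperative gene experiences *s*~eff~ = *r·s* while the same mutation in
a private gene (one whose fitness effects fall only on the carrier)
experiences the full *s*. Relaxed purifying selection has two visible
consequences in sequence data:

* **polymorphism**: at mutation–selection balance the equilibrium
  deleterious-allele frequency is *q̂ ≈ u/s*~eff~, so per-site
  heterozygosity at selected sites scales as *2u/s*~eff~ and the
  cooperative/private ratio of nonsynonymous diversity approaches
  1/*r*;
* **divergence**: the fixation probability of deleterious mutations
  rises (and that of beneficial mutations falls), elevating
  *K*~a~ on the branch to an outgroup.

Everything in the package is organized around testing these two
predictions on a panel of *n* conspecific strains called against a
reference, with three gene classes: `cooperative`, `private`, and
`background` (private genes outside the focal regulon, used as a second
control).

The relatedness estimator inverts the polymorphism prediction:
*r̂* = median(π~priv~)/median(π~coop~). Medians rather than means are
used because per-gene diversity is right-skewed and a handful of
unusually diverse genes would otherwise dominate the ratio. The
estimator assumes (i) the distribution of raw selection coefficients is
the same in both classes, and (ii) the gene classification is correct;
`recovery_report()` exposes the consequences of violating (i) — a 2×
class difference in *s* biases *r̂* by the same factor, and the harness
reports it rather than hiding it.

## What the simulator does and does not emulate

`simulate_population()` runs an independent haploid Wright–Fisher
forward simulation per gene: multiplicative fitness across sites,
infinite-sites mutation within the gene (each segregating site carries
one mutation origin; sites of lost mutations are recycled, fixed sites
are not re-mutated), full linkage within the gene and free recombination
between genes. Free recombination between genes matches the per-gene
granularity of every downstream statistic and keeps runtime at desk
scale; within-gene linkage is retained because the frequency-spectrum
statistics (Tajima's *D*, Fu & Li) are sensitive to it.

Each mutation's consequence is determined **codon-exactly**: the
simulator draws a site and an alternative base, and classifies the
change as synonymous or nonsynonymous from the reference codon under
translation table 11 — the same rule the downstream classifier applies.
An earlier design sketch labelled sites synonymous/nonsynonymous by a
Bernoulli(0.75) draw; that was abandoned because downstream π~N~ is
computed by codon logic, and disagreement between fitness labels and
codon labels dilutes the π~N~ contrast and breaks end-to-end parameter
recovery. The realized nonsynonymous fraction of random coding sequence
is ~0.75–0.77, so the conventional `fraction_sites_nonsynonymous = 0.75`
default is preserved as the documented expectation.

Key generator conditions (defaults):

| parameter | default | rationale |
|---|---|---|
| `population_size` N | 1000 | large enough that N·s ≫ 1 at the default s, small enough for forward simulation |
| `sample_size` n | 31 | a typical environmental-isolate panel |
| `gene_length_bp` | 900 | a typical bacterial CDS (300 codons, terminal stop included) |
| `per_site_mutation_rate` u | 5·10⁻⁶ /site/gen | gives neutral θ = 2Nu = 0.01/site, a realistic bacterial synonymous diversity |
| `selection_coefficient` s | 0.01 | weakly deleterious nonsynonymous mutations (Ns = 10); a gamma distribution may be supplied instead |
| `burn_in_generations` | 10·N | empirically sufficient for mutation–selection–drift quasi-equilibrium from a monomorphic start |
| `missingness_rate` | 0.05 | MCAR per genotype, so the ≥80% call-rate filter is exercised |
| `outgroup_expected_Ks` | 0.3 | subspecies-level synonymous divergence |
| `outgroup_omega` | 0.2 | purifying-selection ω on the outgroup branch; cooperative genes use ω/r when the asymmetry switch is on |

The outgroup branch is simulated as a per-codon jump process with
per-change hazards Ks/3 (synonymous) and Ks·ω/3 (nonsynonymous),
re-evaluated after every event, so multiple hits occur and the NG86 +
Jukes–Cantor estimator is exercised on data with genuine saturation.
The ω/r asymmetry for cooperative genes is a modelling convenience: the
theory predicts the *direction* of the divergence contrast but supplies
no quantitative link from r to ω, so the 1/r factor should be read as
"relaxation elevates divergence", not as a calibrated magnitude.

What the generator does **not** emulate, and what passing tests
therefore do not establish about real data: demographic structure and
sampling heterogeneity (the strains are drawn from one panmictic
population at quasi-equilibrium), within-gene recombination and gene
conversion, horizontal transfer, selection on synonymous sites (codon
usage), conditional gene expression, and the correlated expression
background of real transcriptomes (random gene sets in the synthetic
expression matrix are uncorrelated, whereas in a real biofilm time
course random sets share global temporal trends — so real-data bootstrap
nulls are centred well above zero).

## Statistical definitions and numerical choices

* **π** is computed site-by-site with pairwise deletion: each site
  contributes its mean pairwise difference among the strains called
  there; the sum is divided by the effective (mapped) length. With
  complete data this equals the classic pairwise-difference average.
  Strand never matters for π and S; codon-aware quantities are computed
  on the CDS orientation.
* **Site classification** is NG86 fractional counting on reference
  codons; per-SNP labels compare the alternative codon's amino acid to
  the reference codon's. Codons with more than one segregating position
  are resolved by averaging over the orderings in which the changes
  could have occurred (pathway averaging), giving fractional labels;
  codons containing ambiguous bases are excluded from numerator and
  denominator.
* **Tajima's D and Fu & Li's statistics** follow the original variance
  constants (with the standard corrections for the starred Fu & Li
  variants). Both the outgroup-free (D\*, F\*) and outgroup-polarized
  (D, F) versions are reported, since analyses in this area have used
  both; the polarized versions require an outgroup allele at the site
  and skip unpolarizable sites. Statistics are flagged `NA` (never 0)
  when S = 0.
* **McDonald–Kreitman**: a site segregating in the sample is
  polymorphism; a sample-monomorphic site differing from the outgroup is
  divergence; a site that is both counts as polymorphism only (the
  standard convention). Divergence labels use the sample-majority codon
  as context. Pathway averaging can make the four cells fractional;
  Fisher's exact test needs integers, so `fisher_p` is computed on the
  rounded table while NI and DoS use the fractional counts directly. NI
  is flagged undefined when any margin is zero; DoS only when a full row
  is empty. The conservative variant drops polymorphisms below a
  minor-allele-frequency cutoff (default 0.15, configurable — a common
  low-frequency exclusion; the exact published variant is not pinned
  down, so the cutoff is explicit rather than hidden).
* **K~a~/K~s~** is NG86 with pathway averaging and Jukes–Cantor
  correction d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 is flagged undefined, and
  codons with a premature internal stop in either sequence are skipped.
* **Filters**: ties at the thresholds (call rate exactly 0.8, mapped
  fraction exactly 0.5) are retained — "at least" is read inclusively.
  Indels never enter the population-genetic statistics; they are routed
  to a side channel used only for frameshift annotation, which is why
  `run_config(drop_indels = FALSE)` is refused rather than honoured.
* **Test families are configuration, not inference**: approximately
  normal per-site measures (π, π~S~, K~s~) default to Welch ANOVA with
  Games–Howell post hocs; skewed measures (π~N~, K~a~, the ratios) to
  Kruskal–Wallis with Dunn post hocs (unadjusted by default, Holm on
  request). The package never auto-selects a family from a normality
  test, trading a little convenience for exact reproducibility. The
  paired six-category mode aggregates per-trait-group medians and uses
  the exact signed-rank test (full null distribution of V, evaluated by
  dynamic programming over rank sums — identical to enumerating all 2ⁿ
  sign assignments — for n ≤ 25; normal approximation with tie and
  continuity corrections above). Zero differences are dropped with the
  count reported.
* **Bootstrap co-expression null**: random sets are drawn from all
  measured genes including the candidate set's members (nothing excludes
  them from a random draw), constant rows are excluded from the
  universe, and the empirical p is add-one, p = (1 + #{null ≥ obs})/(1 + B),
  so it is never exactly zero. Spearman correlations are computed as
  Pearson correlations of average ranks via a single rank-transformed
  matrix product, which makes B = 10,000 draws on a 4,000-gene matrix
  routine.
* **Enrichment** is the one-sided upper-tail exact binomial — the
  prediction is directional (more deleterious mutations in cooperative
  genes). The genome fraction f counts genes of known category only,
  mirroring the removal of genes with unknown localization.
* **Relatedness**: r̂ above 1 (no detectable relaxation) is reported
  as-is with a flag, alongside a clipped value; the CI is a percentile
  bootstrap over genes within each class. Nonsynonymous π is the default
  site class (selection acts there under the model); all-sites π is also
  reported because a whole-genome comparison measures it.

## Cohort sizes used in the test suite

The calibration and recovery experiments in the test suite use cohorts
of 50 cooperative + 50 private genes of 300 bp at the default
conditions (N = 1000, n = 31, s = 0.01), 20 replicate cohorts per point
of the r grid {0.25, 0.5, 1.0}; neutral calibration uses 500 neutral
genes; the planted co-expression experiment uses the full-scale design
(4,000 genes × 11 timepoints, one 178-gene block at target ρ = 0.3,
B = 2,000, 20 seeds). These sizes are the package's own choice of a
desk-scale experiment: large enough that the Monte-Carlo standard error
of each checked quantity is several times smaller than the acceptance
band, small enough to run routinely.

## Known limitations

* The r·s scaling is the first-order inclusive-fitness reduction; no
  group-structured or explicit spatial simulation is attempted, so the
  simulator validates the estimator under its own assumptions, not the
  assumptions themselves.
* At small N·s~eff~ (strong relaxation, r ≪ 1) drift inflates selected
  diversity above the deterministic balance value in both classes; the
  recovery harness quantifies the residual bias of r̂ rather than
  correcting it.
* The median-ratio estimator ignores the contribution of neutral
  (synonymous-like) variation within nonsynonymous π; with strongly
  diverged classes this attenuates r̂ toward 1 slightly.
* Under the simulator, synonymous sites are strictly neutral, so
  all-sites π carries a much weaker class contrast than π~N~ (synonymous
  diversity, which dominates π, is identical between classes). Real
  populations have shown elevated synonymous polymorphism in cooperative
  genes as well — codon-usage selection or linked selection the model
  does not include — so the all-sites estimator is expected to be more
  informative on real data than on these fixtures.
* Fisher's exact test on rounded fractional MK tables is an
  approximation wherever pathway averaging produces non-integer cells;
  affected genes are rare (multi-hit codons) and NI/DoS are unaffected.
* The deleterious-mutation annotator implements exactly two categories
  (stop-gain, frameshift); it is not a general-purpose variant-effect
  predictor.
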