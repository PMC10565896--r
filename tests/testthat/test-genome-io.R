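## hand-built micro-fixture: one contig, a + strand gene and a - strand
## gene, written as real VCF/GFF3/FASTA files
write_micro_fixture <- function(dir, vcf_rows, genome, genes_gff,
                                strains = c("s1", "s2", "s3")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=ctg,length=%d>", nchar(genome)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t"),
    vcf_rows), file.path(dir, "v.vcf"))
  writeLines(c("##gff-version 3", genes_gff), file.path(dir, "g.gff3"))
  writeLines(c(">ctg", genome), file.path(dir, "r.fasta"))
  list(vcf = file.path(dir, "v.vcf"), gff = file.path(dir, "g.gff3"),
       fasta = file.path(dir, "r.fasta"))
}

test_that("readers ingest the standard formats losslessly", {
  dir <- file.path(tempdir(), "micro1")
  #           123456789012345678901234
  genome <- "GGATGAAATTTTAAACCTTTCATGG"
  p <- write_micro_fixture(
    dir,
    vcf_rows = c("ctg\t7\t.\tA\tG\t.\tPASS\t.\tGT\t0\t1\t1",
                 "ctg\t18\t.\tT\tC,A\t.\tPASS\t.\tGT\t0\t1\t2"),
    genome = genome,
    genes_gff = c(
      "ctg\ttest\tCDS\t3\t11\t.\t+\t0\tID=gplus;sociality=cooperative;mapped_fraction=0.9",
      "ctg\ttest\tCDS\t16\t24\t.\t-\t0\tID=gminus;sociality=private"))
  ref <- read_fasta(p$fasta)
  expect_identical(unname(ref["ctg"]), genome)

  genes <- read_gff(p$gff, contigs = names(ref))
  expect_equal(genes$gene_id, c("gplus", "gminus"))
  expect_equal(genes$category, c("cooperative", "private"))
  expect_equal(genes$mapped_fraction, c(0.9, 1))
  expect_error(read_gff(p$gff, contigs = "other"), "unknown contig")

  recs <- read_vcf(p$vcf)
  ## multi-allelic row decomposed into two records
  expect_equal(nrow(recs), 3)
  expect_equal(recs$alt[recs$pos == 18], c("C", "A"))
  expect_equal(unname(recs$calls[1, ]), c(0L, 1L, 1L))

  ## minus-strand alignment equals the reverse complement of the + slice
  aln <- build_alignment(genes[2, ], list(snps = recs)$snps, ref)
  expect_equal(unname(aln$mat[1, ]),
               strsplit(revcomp(substr(genome, 16, 24)), "")[[1]])
  ## strain s2 carries C at genomic 18 -> G at CDS position 24-18+1 = 7
  expect_equal(unname(aln$mat[2, 7]), "G")
  ## strain s3 carries A -> T after complementing
  expect_equal(unname(aln$mat[3, 7]), "T")
})

test_that("empty VCF body yields an empty record stream", {
  dir <- file.path(tempdir(), "micro_empty")
  p <- write_micro_fixture(dir, vcf_rows = character(0), genome = "ACGTACGT",
                           genes_gff = "ctg\tt\tCDS\t1\t6\t.\t+\t0\tID=g1")
  recs <- read_vcf(p$vcf)
  expect_equal(nrow(recs), 0)
  out <- filter_variants(recs)
  expect_equal(nrow(out$snps), 0)
})

test_that("variant filter applies the call-rate rule inclusively and is idempotent", {
  make_rec <- function(called, n = 31, vclass = "SNP") {
    df <- data.frame(contig = "c", pos = 1L, ref = "A",
                     alt = if (vclass == "SNP") "G" else "AG",
                     variant_class = vclass, stringsAsFactors = FALSE)
    calls <- matrix(c(rep(0L, called), rep(NA_integer_, n - called)), 1)
    df$call_rate <- rowMeans(!is.na(calls))
    df$calls <- calls
    df
  }
  recs <- rbind(make_rec(24), make_rec(25), make_rec(31, vclass = "insertion"))
  out <- filter_variants(recs)
  ## 24/31 = 77.4% dropped; 25/31 = 80.6% kept; indel routed aside
  expect_equal(nrow(out$snps), 1)
  expect_equal(out$snps$call_rate, 25 / 31)
  expect_equal(nrow(out$indels), 1)
  out2 <- filter_variants(out)
  expect_identical(out2$snps, out$snps)
  expect_identical(out2$indels, out$indels)
  ## exact threshold tie retained
  tie <- make_rec(25, n = 31)
  tie$call_rate <- 0.8
  expect_equal(nrow(filter_variants(tie)$snps), 1)
  ## all-indel input: popgen set empty
  alli <- rbind(make_rec(31, vclass = "insertion"),
                make_rec(31, vclass = "deletion"))
  expect_equal(nrow(filter_variants(alli)$snps), 0)
  expect_equal(nrow(filter_variants(alli)$indels), 2)
})

test_that("retained fraction under MCAR missingness matches the binomial tail", {
  set.seed(8)
  n <- 31; n_rec <- 3000; miss <- 0.3
  calls <- matrix(ifelse(runif(n_rec * n) < miss, NA_integer_, 0L), n_rec)
  df <- data.frame(contig = "c", pos = seq_len(n_rec), ref = "A", alt = "G",
                   variant_class = "SNP", stringsAsFactors = FALSE)
  df$call_rate <- rowMeans(!is.na(calls))
  df$calls <- calls
  kept <- nrow(filter_variants(df)$snps)
  p_keep <- pbinom(ceiling(0.8 * n) - 1, n, 1 - miss, lower.tail = FALSE)
  se <- sqrt(p_keep * (1 - p_keep) / n_rec)
  expect_lt(abs(kept / n_rec - p_keep), 4 * se)
})

test_that("gene filter respects the mapped-fraction boundary and polymorphism rule", {
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:4), contig = "c",
    start = c(1, 101, 201, 301), end = c(90, 190, 290, 390),
    strand = "+", category = "background",
    trait_group = NA, operon_id = NA,
    mapped_fraction = c(0.49, 0.5, 1, 0),
    stringsAsFactors = FALSE)
  out <- filter_genes(genes, require_polymorphism_data = FALSE)
  expect_equal(out$gene_id, c("g2", "g3"))  # 0.49 removed, 0.50 tie kept

  ## polymorphism-data requirement drops SNP-free genes
  vr <- data.frame(contig = "c", pos = 150L, ref = "A", alt = "G",
                   variant_class = "SNP", call_rate = 1,
                   stringsAsFactors = FALSE)
  vr$calls <- matrix(c(0L, 1L), 1)
  out2 <- filter_genes(genes, variants = vr)
  expect_equal(out2$gene_id, "g2")

  ## construction: 10% of genes set to mapped_fraction 0.3 -> 90% survive
  big <- genes[rep(2, 100), ]
  big$gene_id <- sprintf("b%03d", 1:100)
  big$mapped_fraction <- rep(1, 100)
  big$mapped_fraction[1:10] <- 0.3
  expect_equal(nrow(filter_genes(big, require_polymorphism_data = FALSE)), 90)
})

test_that("alignment construction handles edge cases and errors", {
  ref <- c(ctg = "ATGAAATTTGGGTAA")
  gene <- data.frame(gene_id = "g", contig = "ctg", start = 1L, end = 15L,
                     strand = "+", category = "background",
                     trait_group = NA, operon_id = NA, mapped_fraction = 1,
                     stringsAsFactors = FALSE)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      variant_class = character(0), call_rate = numeric(0),
                      stringsAsFactors = FALSE)
  empty$calls <- matrix(integer(0), 0, 4,
                        dimnames = list(NULL, sprintf("s%d", 1:4)))
  aln <- build_alignment(gene, empty, ref, strains = sprintf("s%d", 1:4))
  expect_true(all(apply(aln$mat, 1, paste, collapse = "") == ref[["ctg"]]))
  expect_equal(nucleotide_diversity(aln)$pi, 0)

  ## one biallelic SNP split 1/3 gives one polymorphic column
  vr <- empty[0, ]
  vr <- data.frame(contig = "ctg", pos = 5L, ref = "A", alt = "G",
                   variant_class = "SNP", call_rate = 1,
                   stringsAsFactors = FALSE)
  vr$calls <- matrix(c(1L, 0L, 0L, 0L), 1,
                     dimnames = list(NULL, sprintf("s%d", 1:4)))
  aln2 <- build_alignment(gene, vr, ref)
  poly <- which(apply(aln2$mat, 2, function(cc) length(unique(cc))) > 1)
  expect_equal(poly, 5L)
  expect_equal(sort(table(aln2$mat[, 5]), decreasing = TRUE),
               sort(table(c("A", "A", "A", "G")), decreasing = TRUE))

  ## allele inconsistent with the reference is an error
  bad <- vr
  bad$ref <- "C"
  expect_error(build_alignment(gene, bad, ref), "reference base")
})

test_that("pi and S are invariant to annotation strand", {
  fx <- small_fixture()
  genes <- read_gff(fx$fx$paths$gff)
  ref <- read_fasta(fx$fx$paths$fasta)
  snps <- filter_variants(read_vcf(fx$fx$paths$vcf))$snps
  for (i in 1:2) {
    gene <- genes[i, ]
    flipped <- gene
    flipped$strand <- if (gene$strand == "+") "-" else "+"
    a1 <- build_alignment(gene, snps, ref)
    a2 <- build_alignment(flipped, snps, ref)
    expect_equal(nucleotide_diversity(a1)$pi, nucleotide_diversity(a2)$pi)
    expect_equal(nucleotide_diversity(a1)$S, nucleotide_diversity(a2)$S)
  }
})

test_that("fixture round-trip reproduces in-memory alignments and statistics", {
  fx <- small_fixture()
  ref <- read_fasta(fx$fx$paths$fasta)
  genes <- read_gff(fx$fx$paths$gff, contigs = names(ref))
  snps <- filter_variants(read_vcf(fx$fx$paths$vcf))$snps
  for (i in seq_len(nrow(genes))) {
    aln <- build_alignment(genes[i, ], snps, ref)
    expect_identical(aln$mat, fx$sim$alignments[[genes$gene_id[i]]]$mat)
    expect_equal(nucleotide_diversity(aln)$pi,
                 nucleotide_diversity(fx$sim$alignments[[genes$gene_id[i]]])$pi)
  }
})

test_that("outgroup pseudogenome substitutes SNPs and skips indels", {
  ref <- c(ctg = paste(rep("A", 100), collapse = ""))
  og <- data.frame(contig = "ctg", pos = c(10L, 50L, 90L), ref = "A",
                   alt = "G", variant_class = "SNP", call_rate = 1,
                   stringsAsFactors = FALSE)
  og$calls <- matrix(1L, 3, 1, dimnames = list(NULL, "outgroup"))
  pg <- build_outgroup_pseudogenome(ref, og)
  diff <- which(strsplit(pg[["ctg"]], "")[[1]] != "A")
  expect_equal(diff, c(10L, 50L, 90L))
  expect_equal(nchar(pg[["ctg"]]), 100)

  ## empty outgroup VCF leaves the reference untouched
  expect_identical(build_outgroup_pseudogenome(ref, og[0, ]), ref)

  ## indel rows are skipped with a warning, length preserved
  ogi <- og
  ogi$variant_class <- c("SNP", "deletion", "SNP")
  expect_warning(pgi <- build_outgroup_pseudogenome(ref, ogi), "indel")
  expect_equal(nchar(pgi[["ctg"]]), 100)
  expect_equal(sum(strsplit(pgi[["ctg"]], "")[[1]] != "A"), 2)
})

test_that("deleterious annotation finds stop-gains and frameshifts from first principles", {
  ## + strand gene, codon 5 TCG -> TAG by an A at CDS position 14
  cds <- paste0("ATG", "AAA", "CCC", "GGG", "TCG", "TTT", "TAA")
  ref <- c(ctg = cds)
  gene <- data.frame(gene_id = "g", contig = "ctg", start = 1L,
                     end = nchar(cds), strand = "+",
                     category = "cooperative", trait_group = NA,
                     operon_id = NA, mapped_fraction = 1,
                     stringsAsFactors = FALSE)
  snp <- data.frame(contig = "ctg", pos = 14L, ref = "C", alt = "A",
                    variant_class = "SNP", call_rate = 1,
                    stringsAsFactors = FALSE)
  snp$calls <- matrix(c(1L, 0L), 1)
  ann <- annotate_deleterious(snp, gene, ref)
  expect_equal(ann$stop_gain_count, 1)
  expect_equal(ann$frameshift_count, 0)
  expect_true(ann$has_deleterious)

  ## in-frame 3-bp deletion is not a frameshift; 1-bp insertion is
  indels <- data.frame(contig = "ctg", pos = c(4L, 7L),
                       ref = c("AAAC", "C"), alt = c("A", "CT"),
                       variant_class = c("deletion", "insertion"),
                       call_rate = 1, stringsAsFactors = FALSE)
  indels$calls <- matrix(c(1L, 0L, 1L, 0L), 2, byrow = TRUE)
  ann2 <- annotate_deleterious(indels, gene, ref)
  expect_equal(ann2$frameshift_count, 1)
  expect_equal(ann2$stop_gain_count, 0)

  ## a change in the annotated terminal stop codon is not a stop-gain
  term <- snp
  term$pos <- 19L; term$ref <- "T"; term$alt <- "A"
  expect_equal(annotate_deleterious(term, gene, ref)$stop_gain_count, 0)
})

test_that("spiked deleterious variants are recovered exactly", {
  fx <- small_fixture()
  dir <- file.path(tempdir(), "spiked_fx")
  unlink(dir, recursive = TRUE)
  ## pick, per gene, an internal codon that can gain a stop by one change
  stop_gainable <- function(cds) {
    for (ci in seq_len(nchar(cds) / 3 - 1)) {
      codon <- substr(cds, 3 * ci - 2, 3 * ci)
      if (kinsig:::is_stop_codon(codon)) next
      for (p in 1:3) {
        for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
          cand <- codon
          substr(cand, p, p) <- alt
          if (kinsig:::is_stop_codon(cand)) return(ci)
        }
      }
    }
    stop("no stop-gainable codon")
  }
  spikes <- data.frame(
    gene_id = c("gene_0001", "gene_0006"),
    codon = c(stop_gainable(fx$sim$reference[["gene_0001"]]),
              stop_gainable(fx$sim$reference[["gene_0006"]])),
    stringsAsFactors = FALSE)
  fs <- data.frame(gene_id = "gene_0003", codon = 7L, len = 2L,
                   stringsAsFactors = FALSE)
  fs_inframe <- data.frame(gene_id = "gene_0004", codon = 7L, len = 3L,
                           stringsAsFactors = FALSE)
  out <- write_fixture(dir, fx$sim, spike_stop_gains = spikes,
                       spike_frameshifts = rbind(fs, fs_inframe))
  ref <- read_fasta(file.path(dir, "reference.fasta"))
  genes <- read_gff(file.path(dir, "genes.gff3"))
  fv <- filter_variants(read_vcf(file.path(dir, "variants.vcf")))
  ann <- annotate_deleterious(fv, genes, ref)
  expect_equal(ann$stop_gain_count[ann$gene_id %in% spikes$gene_id], c(1, 1))
  expect_equal(ann$frameshift_count[ann$gene_id == "gene_0003"], 1)
  ## in-frame spike does not count as a frameshift
  expect_equal(ann$frameshift_count[ann$gene_id == "gene_0004"], 0)
  ## no stop-gains leak into genes without spikes beyond simulated ones
  sim_ann <- annotate_deleterious(
    filter_variants(read_vcf(fx$fx$paths$vcf)), genes, ref)
  extra <- ann$stop_gain_count - sim_ann$stop_gain_count
  expect_equal(extra[match(spikes$gene_id, ann$gene_id)], c(1, 1))
  expect_true(all(extra[!ann$gene_id %in% spikes$gene_id] == 0))
})
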